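// Fan-beam geometry primitives: ray-driven forward projection, filtered
// backprojection onto arbitrary pixel grids, and polygon helpers used by the
// lesion rasterizer.
//
// Conventions (fixed, documented in the package vignette):
//  - view v (1-based) has gantry angle beta = 2*pi*(v-1)/n_views; the source
//    sits at angle pi/2 + beta on the source circle (view 1 at 12 o'clock),
//    rotating counterclockwise.
//  - detector cell i (1-based) subtends fan angle gamma_i = (i - c0)*dgamma
//    with c0 = (n_cells + 1)/2, positive gamma counterclockwise from the
//    central ray; no quarter-detector offset.
//  - image matrices are indexed [ix, iy]; pixel (ix, iy) has world
//    coordinates (x0 + (ix-1)*px, y0 + (iy-1)*px) in mm, isocenter origin.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, double px,
                                  double x0, double y0,
                                  int n_views, int n_cells, double dgamma,
                                  double sid) {
  const int nx = img.nrow(), ny = img.ncol();
  NumericMatrix sino(n_views, n_cells);
  const double c0 = 0.5 * (n_cells + 1);
  // bounding circle of the image grid (for ray clipping)
  const double cx = x0 + 0.5 * (nx - 1) * px;
  const double cy = y0 + 0.5 * (ny - 1) * px;
  const double rad = 0.5 * px * std::sqrt((double)nx * nx + (double)ny * ny) + px;
  const double step = 0.5 * px;
  const double* im = img.begin();

  for (int v = 0; v < n_views; ++v) {
    const double beta = 2.0 * M_PI * v / n_views;
    const double th = M_PI_2 + beta;
    const double sx = sid * std::cos(th), sy = sid * std::sin(th);
    const double d0x = -std::cos(th), d0y = -std::sin(th);
    for (int i = 0; i < n_cells; ++i) {
      const double g = ((i + 1) - c0) * dgamma;
      const double cg = std::cos(g), sg = std::sin(g);
      const double dx = d0x * cg - d0y * sg;
      const double dy = d0x * sg + d0y * cg;
      // clip ray to bounding circle: |s + t d - c|^2 = rad^2
      const double ox = sx - cx, oy = sy - cy;
      const double b = ox * dx + oy * dy;
      const double c = ox * ox + oy * oy - rad * rad;
      const double disc = b * b - c;
      if (disc <= 0.0) continue;
      const double sq = std::sqrt(disc);
      double t0 = -b - sq, t1 = -b + sq;
      if (t1 <= 0.0) continue;
      if (t0 < 0.0) t0 = 0.0;
      const int nstep = (int)std::ceil((t1 - t0) / step);
      if (nstep <= 0) continue;
      const double h = (t1 - t0) / nstep;
      double acc = 0.0;
      // midpoint sampling with bilinear interpolation, incremental stepping
      double fx = (sx + (t0 + 0.5 * h) * dx - x0) / px;
      double fy = (sy + (t0 + 0.5 * h) * dy - y0) / px;
      const double hx = h * dx / px, hy = h * dy / px;
      for (int k = 0; k < nstep; ++k, fx += hx, fy += hy) {
        const int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
        if (ix < 0 || ix >= nx - 1 || iy < 0 || iy >= ny - 1) {
          if (ix < -1 || ix > nx - 1 || iy < -1 || iy > ny - 1) continue;
          const double ax = fx - ix, ay = fy - iy;
          double v00 = 0, v10 = 0, v01 = 0, v11 = 0;
          if (ix >= 0 && iy >= 0)           v00 = im[ix + nx * iy];
          if (ix + 1 < nx && iy >= 0)       v10 = im[ix + 1 + nx * iy];
          if (ix >= 0 && iy + 1 < ny)       v01 = im[ix + nx * (iy + 1)];
          if (ix + 1 < nx && iy + 1 < ny)   v11 = im[ix + 1 + nx * (iy + 1)];
          acc += (1 - ax) * ((1 - ay) * v00 + ay * v01) +
                 ax * ((1 - ay) * v10 + ay * v11);
        } else {
          const double ax = fx - ix, ay = fy - iy;
          const double* p0 = im + ix + nx * iy;
          acc += (1 - ax) * ((1 - ay) * p0[0] + ay * p0[nx]) +
                 ax * ((1 - ay) * p0[1] + ay * p0[nx + 1]);
        }
      }
      sino(v, i) = acc * h;
    }
  }
  return sino;
}

// Backproject a filtered sinogram onto an arbitrary pixel grid with the
// 1/L^2 distance weighting of equiangular fan-beam FBP.  The caller applies
// the delta-beta factor.
// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix q, double dgamma, double sid,
                               double x0, double y0, double px,
                               int nx, int ny) {
  const int n_views = q.nrow(), n_cells = q.ncol();
  const double c0 = 0.5 * (n_cells + 1);
  NumericMatrix out(nx, ny);
  double* o = out.begin();
  const double* qq = q.begin();
  // minimax polynomial for atan on |x| <= 1 (max error ~1e-6 rad,
  // i.e. ~1e-3 detector cells -- far below the interpolation error)
  const double a1 = 0.99997726, a3 = -0.33262347, a5 = 0.19354346,
               a7 = -0.11643287, a9 = 0.05265332, a11 = -0.01172120;
  for (int v = 0; v < n_views; ++v) {
    const double beta = 2.0 * M_PI * v / n_views;
    const double th = M_PI_2 + beta;
    const double sx = sid * std::cos(th), sy = sid * std::sin(th);
    const double d0x = -std::cos(th), d0y = -std::sin(th);
    for (int iy = 0; iy < ny; ++iy) {
      const double vy0 = (y0 + iy * px) - sy;
      double* orow = o + (size_t)nx * iy;
      for (int ix = 0; ix < nx; ++ix) {
        const double vx = (x0 + ix * px) - sx;
        // coordinates of the pixel in the view frame: s along the central
        // ray, t transverse; L^2 = s^2 + t^2, gamma = atan(t/s)
        const double s = d0x * vx + d0y * vy0;
        const double t = d0x * vy0 - d0y * vx;
        const double r = t / s;
        const double r2 = r * r;
        const double g = r * (a1 + r2 * (a3 + r2 * (a5 + r2 * (a7 + r2 * (a9 + r2 * a11)))));
        const double u = g / dgamma + c0 - 1.0;  // 0-based cell coordinate
        if (u < 0.0 || u > n_cells - 1) continue;
        const int u0 = (int)u;
        const int u1 = (u0 + 1 < n_cells) ? u0 + 1 : u0;
        const double a = u - u0;
        const double val = (1 - a) * qq[v + (size_t)n_views * u0] +
                           a * qq[v + (size_t)n_views * u1];
        orow[ix] += val / (s * s + t * t);
      }
    }
  }
  return out;
}

// Even-odd scanline polygon fill on a square pixel grid.  Pixel centers are
// at (cx + (j - (n+1)/2) * px, cy + (i - (n+1)/2) * px); a pixel is set when
// its center lies inside the polygon under the even-odd rule.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize_polygon(NumericMatrix verts, int grid_n,
                                    double px, double cx, double cy) {
  const int n = verts.nrow();
  IntegerMatrix out(grid_n, grid_n);
  const double half = 0.5 * (grid_n + 1);
  std::vector<double> xs;
  for (int iy = 0; iy < grid_n; ++iy) {
    const double y = cy + ((iy + 1) - half) * px;
    xs.clear();
    for (int k = 0; k < n; ++k) {
      const int k2 = (k + 1) % n;
      const double y1 = verts(k, 1), y2 = verts(k2, 1);
      // half-open rule: count edge if y in [min, max)
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        const double t = (y - y1) / (y2 - y1);
        xs.push_back(verts(k, 0) + t * (verts(k2, 0) - verts(k, 0)));
      }
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t m = 0; m + 1 < xs.size(); m += 2) {
      // pixel centers strictly inside [xs[m], xs[m+1])
      int j0 = (int)std::ceil((xs[m] - cx) / px + half - 1.0);
      int j1 = (int)std::floor((xs[m + 1] - cx) / px + half - 1.0);
      // shift ceil result when the boundary falls exactly on a center
      if (j0 < 0) j0 = 0;
      if (j1 > grid_n - 1) j1 = grid_n - 1;
      for (int j = j0; j <= j1; ++j) {
        const double xc = cx + ((j + 1) - half) * px;
        if (xc >= xs[m] && xc < xs[m + 1]) out(j, iy) = 1;
      }
    }
  }
  return out;
}

static inline double cross3(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static bool seg_intersect(double p1x, double p1y, double p2x, double p2y,
                          double q1x, double q1y, double q2x, double q2y) {
  const double d1 = cross3(q1x, q1y, q2x, q2y, p1x, p1y);
  const double d2 = cross3(q1x, q1y, q2x, q2y, p2x, p2y);
  const double d3 = cross3(p1x, p1y, p2x, p2y, q1x, q1y);
  const double d4 = cross3(p1x, p1y, p2x, p2y, q2x, q2y);
  return ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
         ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0));
}

// True when the closed polygon has two properly crossing non-adjacent edges.
// [[Rcpp::export]]
bool cpp_poly_self_intersects(NumericMatrix verts) {
  const int n = verts.nrow();
  std::vector<double> x(n), y(n), lo_x(n), hi_x(n), lo_y(n), hi_y(n);
  for (int i = 0; i < n; ++i) { x[i] = verts(i, 0); y[i] = verts(i, 1); }
  for (int i = 0; i < n; ++i) {
    const int j = (i + 1) % n;
    lo_x[i] = std::min(x[i], x[j]); hi_x[i] = std::max(x[i], x[j]);
    lo_y[i] = std::min(y[i], y[j]); hi_y[i] = std::max(y[i], y[j]);
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent through closure
      if (hi_x[i] < lo_x[j] || hi_x[j] < lo_x[i] ||
          hi_y[i] < lo_y[j] || hi_y[j] < lo_y[i]) continue;
      if (seg_intersect(x[i], y[i], x[(i + 1) % n], y[(i + 1) % n],
                        x[j], y[j], x[(j + 1) % n], y[(j + 1) % n]))
        return true;
    }
  }
  return false;
}

// Point-in-polygon (even-odd) for a batch of points.
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector ptx, NumericVector pty,
                                    NumericMatrix verts) {
  const int n = verts.nrow(), m = ptx.size();
  LogicalVector res(m);
  for (int p = 0; p < m; ++p) {
    bool inside = false;
    for (int i = 0, j = n - 1; i < n; j = i++) {
      const double yi = verts(i, 1), yj = verts(j, 1);
      if ((yi > pty[p]) != (yj > pty[p])) {
        const double xc = verts(j, 0) +
          (pty[p] - yj) / (yi - yj) * (verts(i, 0) - verts(j, 0));
        if (ptx[p] < xc) inside = !inside;
      }
    }
    res[p] = inside;
  }
  return res;
}
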