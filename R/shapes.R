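#' Random fractal lesion shapes
#'
#' Closed polygons in millimeter coordinates are grown from a rough hexagon
#' by repeated midpoint subdivision: each edge midpoint is displaced along
#' the local edge normal by a uniform draw scaled by the edge length and a
#' roughness parameter, doubling the vertex count per pass.  Subdivision
#' stops once adjacent vertices are closer than the target raster spacing,
#' after which a circular moving average over the vertex list controls edge
#' smoothness.
#'
#' @name shapes
#' @keywords internal
NULL

new_polygon_shape <- function(vertices, generation = 0L) {
  structure(list(vertices = vertices, generation = as.integer(generation)),
            class = "polygon_shape")
}

#' @export
print.polygon_shape <- function(x, ...) {
  cat(sprintf("<polygon_shape> %d vertices, generation %d\n",
              nrow(x$vertices), x$generation))
  invisible(x)
}

#' Initialize a rough hexagon
#'
#' Six vertices at nominal 60 degree spacing with radial and angular jitter
#' proportional to `irregularity`: radii are `radius_mm * (1 + U(-irr, irr))`
#' and angles are jittered by `U(-irr, irr) * pi/6`.  Vertices are ordered
#' counterclockwise.
#'
#' @param radius_mm nominal circumradius in mm (> 0).
#' @param irregularity jitter scale in `[0, 1)`; 0 gives a regular hexagon.
#' @return a `polygon_shape` with 6 vertices (generation 0).
#' @export
init_base_hexagon <- function(radius_mm, irregularity = 0) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm <= 0)
    stop("radius_mm must be a single positive number")
  if (irregularity < 0 || irregularity >= 1)
    stop("irregularity must be in [0, 1)")
  ang <- (0:5) * pi / 3
  if (irregularity > 0) {
    ang <- ang + stats::runif(6, -irregularity, irregularity) * pi / 6
    r <- radius_mm * (1 + stats::runif(6, -irregularity, irregularity))
  } else {
    r <- rep(radius_mm, 6)
  }
  new_polygon_shape(cbind(r * cos(ang), r * sin(ang)))
}

#' Subdivide a polygon once
#'
#' Inserts the midpoint of every edge, displaced along the edge normal by a
#' draw from `U(-roughness * L, roughness * L)` where `L` is the edge
#' length.  The vertex count exactly doubles.  Degenerate (zero-length)
#' edges get an unperturbed midpoint.
#'
#' @param shape a `polygon_shape`.
#' @param roughness nonnegative perturbation scale (unitless).
#' @return a `polygon_shape` with `2 n` vertices and generation + 1.
#' @export
subdivide_once <- function(shape, roughness) {
  v <- shape$vertices
  n <- nrow(v)
  if (n < 3) stop("shape must have at least 3 vertices")
  if (roughness < 0) stop("roughness must be >= 0")
  nxt <- v[c(2:n, 1), , drop = FALSE]
  edge <- nxt - v
  len <- sqrt(rowSums(edge^2))
  mid <- (v + nxt) / 2
  if (roughness > 0) {
    # unit normal (left of travel direction); zero-length edges unperturbed
    ok <- len > 0
    nrm <- cbind(-edge[, 2], edge[, 1])
    nrm[ok, ] <- nrm[ok, , drop = FALSE] / len[ok]
    disp <- stats::runif(n, -1, 1) * roughness * len
    disp[!ok] <- 0
    mid <- mid + nrm * disp
  }
  out <- matrix(0, 2 * n, 2)
  out[seq(1, 2 * n, by = 2), ] <- v
  out[seq(2, 2 * n, by = 2), ] <- mid
  new_polygon_shape(out, shape$generation + 1L)
}

max_vertex_separation <- function(shape) {
  v <- shape$vertices
  nxt <- v[c(2:nrow(v), 1), , drop = FALSE]
  max(sqrt(rowSums((nxt - v)^2)))
}

#' Grow a fractal shape to raster resolution
#'
#' Starting from a rough hexagon, applies [subdivide_once()] until the
#' maximum adjacent-vertex separation falls below `target_spacing_mm`.
#' Self-intersecting results (possible at positive roughness) are rejected
#' and regrown, up to `max_attempts` tries.
#'
#' @param radius_mm initial hexagon circumradius (mm).
#' @param roughness midpoint perturbation scale.
#' @param target_spacing_mm subdivision stops below this vertex spacing
#'   (default 0.156 mm, the lesion raster pixel size).
#' @param irregularity initial hexagon jitter.
#' @param max_iter subdivision cap; exceeding it is an error.
#' @param max_attempts rejection budget for self-intersecting samples.
#'   Rejection operates per subdivision level: a level whose displacements
#'   fold the outline is redrawn (up to `max_attempts` times) before the
#'   whole shape is restarted (again up to `max_attempts` times).
#' @param keep_generation if positive, the intermediate shape at this
#'   generation is stored as attribute `"early"` (used to seed inserts).
#' @return a `polygon_shape`; `$generation` records the subdivision count.
#' @export
generate_shape <- function(radius_mm, roughness, target_spacing_mm = 0.156,
                           irregularity = 0.15, max_iter = 12L,
                           max_attempts = 10L, keep_generation = 2L) {
  if (target_spacing_mm <= 0) stop("target_spacing_mm must be > 0")
  for (attempt in seq_len(max_attempts)) {
    sh <- init_base_hexagon(radius_mm, irregularity)
    early <- NULL
    it <- 0L
    failed <- FALSE
    while (max_vertex_separation(sh) >= target_spacing_mm) {
      if (it >= max_iter)
        stop(sprintf("no convergence to spacing %g mm within %d subdivisions",
                     target_spacing_mm, max_iter))
      cand <- subdivide_once(sh, roughness)
      if (roughness > 0) {
        tries <- 1L
        while (cpp_poly_self_intersects(cand$vertices)) {
          if (tries >= max_attempts) { failed <- TRUE; break }
          cand <- subdivide_once(sh, roughness)
          tries <- tries + 1L
        }
      }
      if (failed) break
      sh <- cand
      it <- it + 1L
      if (it == keep_generation) early <- sh
    }
    if (!failed) {
      attr(sh, "early") <- early
      return(sh)
    }
  }
  stop(sprintf("self-intersecting shape in all %d attempts", max_attempts))
}

#' Smooth a polygon with a circular moving average
#'
#' The ordered vertex coordinate list is convolved with a length
#' `smooth_len` moving average with wrap-around, preserving closure and
#' vertex count.  Longer windows give smoother, less fractal outlines.
#'
#' @param shape a `polygon_shape`.
#' @param smooth_len integer window, `1 <= smooth_len <= n/2`.
#' @return the smoothed `polygon_shape`.
#' @export
smooth_shape <- function(shape, smooth_len) {
  v <- shape$vertices
  n <- nrow(v)
  smooth_len <- as.integer(smooth_len)
  if (smooth_len < 1 || smooth_len > n / 2)
    stop("smooth_len must be an integer in [1, vertex count / 2]")
  if (smooth_len == 1) return(shape)
  # circular convolution via padding
  half <- smooth_len %/% 2
  idx <- c((n - half + 1):n, 1:n, 1:half)
  sm <- apply(v, 2, function(col) {
    f <- stats::filter(col[idx], rep(1 / smooth_len, smooth_len), sides = 2)
    as.numeric(f[(half + 1):(half + n)])
  })
  new_polygon_shape(sm, shape$generation)
}

#' Rasterize a closed polygon
#'
#' Pixel-center-in-polygon fill under the even-odd rule on a square grid of
#' `grid_n` x `grid_n` pixels of size `pixel_mm`, centered on `center` (the
#' vertex centroid by default).
#'
#' @param shape a `polygon_shape`.
#' @param grid_n grid size in pixels (default 256).
#' @param pixel_mm pixel size in mm (default 0.156).
#' @param center grid center in mm (length-2), default polygon centroid.
#' @return an integer `grid_n` x `grid_n` 0/1 matrix.
#' @export
rasterize <- function(shape, grid_n = 256L, pixel_mm = 0.156, center = NULL) {
  v <- shape$vertices
  if (is.null(center)) center <- colMeans(v)
  half_extent <- grid_n * pixel_mm / 2
  if (any(abs(sweep(v, 2, center)) > half_extent))
    stop("shape exceeds the raster extent")
  cpp_rasterize_polygon(v, as.integer(grid_n), pixel_mm, center[1], center[2])
}

#' Generate nested heterogeneity inserts
#'
#' Sub-shapes are seeded from an early subdivision generation of the parent
#' shape, rescaled by `U(0.25, 0.6)` about a random interior point, then
#' evolved with independent subdivisions and smoothing.  Confinement to the
#' parent is enforced at the raster stage (pixelwise clip).
#'
#' @param parent a `polygon_shape` grown by [generate_shape()].
#' @param n_subshapes number of sub-shapes, 2 or 3.
#' @param roughness subdivision roughness used for the independent evolution.
#' @param target_spacing_mm raster spacing at which evolution stops.
#' @return list of `polygon_shape` objects (not yet clipped).
#' @export
generate_insert <- function(parent, n_subshapes, roughness = 0.25,
                            target_spacing_mm = 0.156) {
  if (!n_subshapes %in% 2:3) stop("n_subshapes must be 2 or 3")
  pv <- parent$vertices
  area2 <- abs(sum(pv[, 1] * (pv[c(2:nrow(pv), 1), 2] - pv[c(nrow(pv), 1:(nrow(pv) - 1)), 2])))
  if (area2 / 2 < (4 * target_spacing_mm)^2)
    stop("parent region too small to host an insert")
  seed_shape <- attr(parent, "early")
  if (is.null(seed_shape)) seed_shape <- parent
  bb_lo <- apply(pv, 2, min)
  bb_hi <- apply(pv, 2, max)
  out <- vector("list", n_subshapes)
  for (k in seq_len(n_subshapes)) {
    # random interior anchor (rejection sampling in the bounding box)
    anchor <- NULL
    for (try in 1:200) {
      cand <- stats::runif(2, bb_lo, bb_hi)
      if (cpp_points_in_polygon(cand[1], cand[2], pv)) { anchor <- cand; break }
    }
    if (is.null(anchor)) stop("parent region too small to host an insert")
    scl <- stats::runif(1, 0.25, 0.6)
    sv <- seed_shape$vertices
    ctr <- colMeans(sv)
    sv <- sweep(sv, 2, ctr) * scl
    sv <- sweep(sv, 2, anchor, "+")
    sub <- new_polygon_shape(sv, seed_shape$generation)
    it <- 0L
    while (max_vertex_separation(sub) >= target_spacing_mm && it < 12L) {
      sub <- subdivide_once(sub, roughness)
      it <- it + 1L
    }
    n <- nrow(sub$vertices)
    win <- sample.int(max(1L, n %/% 2L), 1L)
    out[[k]] <- smooth_shape(sub, win)
  }
  out
}
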