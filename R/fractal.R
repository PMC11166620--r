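#' Box-counting fractal dimension of a raster edge set
#'
#' The lesion outline is characterized by the box-counting dimension of its
#' edge image: the edge set is covered by grids of boxes of side
#' r in {1, 2, 4, 8, 16, 32} pixels (anchored at the raster origin) and the
#' occupied-box counts `N(r)` are fit by ordinary least squares of
#' `log N(r)` on `-log r`; the slope is the fractal dimension `D_f`.
#'
#' @name fractal
#' @keywords internal
NULL

#' Extract the edge of a binary raster
#'
#' Inner boundary under 4-connectivity: foreground pixels with at least one
#' background 4-neighbor (pixels beyond the raster border count as
#' background).
#'
#' @param binary_raster 0/1 matrix.
#' @return 0/1 matrix of edge pixels.
#' @export
extract_edge <- function(binary_raster) {
  b <- binary_raster != 0
  if (!any(b)) stop("empty foreground: no edge to extract")
  nr <- nrow(b); nc <- ncol(b)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- b
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
        pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  (core & !nb) * 1L
}

#' Count occupied boxes over the edge set
#'
#' `N(r)` is the number of r x r grid cells, anchored at the raster origin,
#' containing at least one edge pixel; partial boxes at the borders count
#' when occupied.
#'
#' @param edge_raster 0/1 matrix of edge pixels.
#' @param scales box sides in pixels (default `c(1, 2, 4, 8, 16, 32)`).
#' @return a `box_count_curve`: list with `scales` and `counts`.
#' @export
box_count <- function(edge_raster, scales = c(1L, 2L, 4L, 8L, 16L, 32L)) {
  e <- edge_raster != 0
  if (!any(e)) stop("empty edge set")
  counts <- vapply(scales, function(r) {
    gi <- (seq_len(nrow(e)) - 1L) %/% r
    gj <- (seq_len(ncol(e)) - 1L) %/% r
    s <- rowsum(e * 1L, gi, reorder = TRUE)
    s <- rowsum(t(s), gj, reorder = TRUE)
    sum(s > 0)
  }, integer(1))
  structure(list(scales = as.integer(scales), counts = counts),
            class = "box_count_curve")
}

#' @export
print.box_count_curve <- function(x, ...) {
  cat("<box_count_curve>\n")
  print(stats::setNames(x$counts, paste0("r=", x$scales)))
  invisible(x)
}

#' Fit the fractal dimension from a box-count curve
#'
#' Ordinary least squares of `log N(r)` on `-log r` (natural logs; the
#' slope is base-invariant, the intercept is not).  Requires at least two
#' distinct scales with positive counts.
#'
#' @param curve a [box_count()] result.
#' @return a `fractal_fit`: list with `D_f`, `b` and the fitted `lm`.
#' @export
fit_fractal_dimension <- function(curve) {
  keep <- curve$counts > 0
  r <- curve$scales[keep]
  N <- curve$counts[keep]
  if (length(unique(r)) < 2)
    stop("need at least two scales with positive counts")
  neg_log_r <- -log(r)
  fit <- stats::lm(log(N) ~ neg_log_r)
  structure(list(D_f = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 fit = fit),
            class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> D_f = %.4f, intercept b = %.4f\n", x$D_f, x$b))
  invisible(x)
}

#' Fractal dimension of a binary shape raster
#'
#' Convenience wrapper: edge extraction, box counting at the default
#' scales, and the log-log regression.  This defines the edge-fractal-
#' dimension label of a lesion.
#'
#' @param binary_raster 0/1 matrix.
#' @return scalar `D_f`.
#' @export
fractal_dimension <- function(binary_raster) {
  fit_fractal_dimension(box_count(extract_edge(binary_raster)))$D_f
}
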