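#' Lesion specification
#'
#' Bundles every generative parameter of one virtual metastasis.  The
#' contrast is the HU difference between the lesion base and the local
#' liver background (hypodense, so negative); the insert scale is the
#' maximum additional HU offset of the nested heterogeneity sub-shapes.
#' Sign convention: inserts are *more* hypodense than the lesion base, so
#' the composed HU offset lies in `[contrast_hu - insert_scale_hu,
#' contrast_hu]` and the lesion never becomes hyperdense relative to liver.
#'
#' @param contrast_hu lesion-vs-background HU offset, in `[-80, -20]`.
#' @param insert_scale_hu maximum insert-vs-base HU offset, in `[0, 80]`.
#' @param blur_sigma_mm isotropic Gaussian edge blur (mm), `>= 0`;
#'   0 means the no-blur condition.
#' @param roughness midpoint-displacement scale of the shape generator.
#' @param smooth_frac moving-average window as a fraction of the final
#'   vertex count, in `(0, 0.5]`.
#' @param radius_mm initial hexagon circumradius (mm).
#' @param irregularity initial hexagon jitter.
#' @param n_insert_subshapes 2 or 3 heterogeneity sub-shapes.
#' @param seed RNG seed used when the lesion is composed.
#' @return a `met_spec` object.
#' @export
met_spec <- function(contrast_hu = -50, insert_scale_hu = 40,
                     blur_sigma_mm = 0, roughness = 0.25,
                     smooth_frac = 0.1, radius_mm = 7,
                     irregularity = 0.15, n_insert_subshapes = 2L,
                     seed = 1L) {
  if (contrast_hu < -80 || contrast_hu > -20)
    stop("contrast_hu must lie in [-80, -20]")
  if (insert_scale_hu < 0 || insert_scale_hu > 80)
    stop("insert_scale_hu must lie in [0, 80]")
  if (blur_sigma_mm < 0) stop("blur_sigma_mm must be >= 0")
  if (smooth_frac <= 0 || smooth_frac > 0.5)
    stop("smooth_frac must lie in (0, 0.5]")
  if (!n_insert_subshapes %in% 2:3) stop("n_insert_subshapes must be 2 or 3")
  structure(list(contrast_hu = contrast_hu,
                 insert_scale_hu = insert_scale_hu,
                 blur_sigma_mm = blur_sigma_mm,
                 roughness = roughness,
                 smooth_frac = smooth_frac,
                 radius_mm = radius_mm,
                 irregularity = irregularity,
                 n_insert_subshapes = as.integer(n_insert_subshapes),
                 seed = as.integer(seed)),
            class = "met_spec")
}

#' Sample a lesion specification from the study distributions
#'
#' Draws the generative parameters of one lesion: contrast uniform on
#' `[-80, -20]` HU, insert scale uniform on `[0, 80]` HU, roughness uniform
#' on `[0.05, 0.33]` (the largest upper bound at which deep subdivisions
#' reliably avoid self-intersection; see the methods vignette), smoothing
#' window uniform up to half the vertex count,
#' circumradius uniform on `[4, 10]` mm, and (in blurred studies) edge blur
#' uniform on `[0, 1.5]` mm.
#'
#' @param blur if `TRUE`, sample a positive edge blur; otherwise 0.
#' @param seed seed stored in the spec (consumed by [compose_met()]).
#' @return a `met_spec`.
#' @export
sample_met_spec <- function(blur = FALSE, seed = 1L) {
  met_spec(contrast_hu = stats::runif(1, -80, -20),
           insert_scale_hu = stats::runif(1, 0, 80),
           blur_sigma_mm = if (blur) stats::runif(1, 0, 1.5) else 0,
           roughness = stats::runif(1, 0.05, 0.33),
           smooth_frac = stats::runif(1, 1e-3, 0.5),
           radius_mm = stats::runif(1, 4, 10),
           n_insert_subshapes = sample(2:3, 1),
           seed = seed)
}

#' @export
print.met_spec <- function(x, ...) {
  cat(sprintf(paste0("<met_spec> contrast %.1f HU, insert %.1f HU, ",
                     "blur %.2f mm, roughness %.2f, radius %.1f mm\n"),
              x$contrast_hu, x$insert_scale_hu, x$blur_sigma_mm,
              x$roughness, x$radius_mm))
  invisible(x)
}

gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  EBImage::gblur(img, sigma = sigma_px)
}

#' Compose a lesion image with ground-truth labels
#'
#' Builds the high-resolution HU-offset raster of one lesion: the base
#' shape raster at `contrast_hu`, minus the heterogeneity insert field
#' rescaled so that the maximum insert-vs-base difference equals
#' `insert_scale_hu` (inserts deepen the hypodensity), then an isotropic
#' Gaussian blur of `blur_sigma_mm` (skipped at 0).  The edge fractal
#' dimension label is measured on the unblurred binary base raster.
#'
#' @param spec a [met_spec()].
#' @param grid_n raster size (default 256).
#' @param pixel_mm raster pixel size (default 0.156 mm).
#' @return a `met_image`: list with `hu_offset` (matrix, 0 outside the
#'   lesion), `pixel_mm`, `labels` (heterogeneity, edge_sharpness,
#'   fractal_dim) and `spec`.
#' @export
compose_met <- function(spec, grid_n = 256L, pixel_mm = 0.156) {
  stopifnot(inherits(spec, "met_spec"))
  set.seed(spec$seed)
  parent <- generate_shape(spec$radius_mm, spec$roughness,
                           target_spacing_mm = pixel_mm,
                           irregularity = spec$irregularity)
  n <- nrow(parent$vertices)
  win <- max(1L, as.integer(round(spec$smooth_frac * n)))
  parent_sm <- smooth_shape(parent, min(win, n %/% 2L))
  attr(parent_sm, "early") <- attr(parent, "early")
  center <- colMeans(parent_sm$vertices)
  base <- rasterize(parent_sm, grid_n, pixel_mm, center = center)
  if (sum(base) == 0) stop("degenerate lesion: empty raster support")

  insert_field <- matrix(0, grid_n, grid_n)
  if (spec$insert_scale_hu > 0) {
    subs <- generate_insert(parent_sm, spec$n_insert_subshapes,
                            roughness = spec$roughness,
                            target_spacing_mm = pixel_mm)
    for (s in subs) {
      r <- tryCatch(rasterize(s, grid_n, pixel_mm, center = center),
                    error = function(e) NULL)
      if (!is.null(r)) insert_field <- insert_field + r
    }
    insert_field <- insert_field * base  # confine to parent support
    mx <- max(insert_field)
    if (mx > 0) insert_field <- insert_field * (spec$insert_scale_hu / mx)
  }

  hu <- spec$contrast_hu * base - insert_field
  fd <- fit_fractal_dimension(box_count(extract_edge(base)))$D_f
  if (spec$blur_sigma_mm > 0)
    hu <- gaussian_blur(hu, spec$blur_sigma_mm / pixel_mm)

  structure(list(hu_offset = hu, pixel_mm = pixel_mm,
                 labels = list(heterogeneity = spec$insert_scale_hu,
                               edge_sharpness = spec$blur_sigma_mm,
                               fractal_dim = fd),
                 spec = spec),
            class = "met_image")
}

#' @export
print.met_image <- function(x, ...) {
  cat(sprintf(paste0("<met_image> %dx%d @ %.3f mm | heterogeneity %.1f HU, ",
                     "blur %.2f mm, fractal dim %.3f\n"),
              nrow(x$hu_offset), ncol(x$hu_offset), x$pixel_mm,
              x$labels$heterogeneity, x$labels$edge_sharpness,
              x$labels$fractal_dim))
  invisible(x)
}
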