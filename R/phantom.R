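#' Synthetic abdominal background with a liver region
#'
#' Parametric stand-in for clinical liver-bearing CT slices: an elliptical
#' soft-tissue body (base ~35 HU) containing a liver-like elliptical region
#' (base ~50 HU) with correlated lumpy texture (a Gaussian random field
#' with configurable correlation length and standard deviation) and a few
#' bright elliptical vessel cross-sections, surrounded by air at -1000 HU.
#' The liver mask marks tissue admissible for lesion insertion: the liver
#' interior, eroded at the boundary, with vessels (dilated by a margin)
#' excluded.  Externally supplied HU rasters and masks in the same layout
#' can be substituted anywhere a `ct_background` is accepted.
#'
#' @param config list of parameters; see Details.  Defaults give a 512 x
#'   512 raster at 0.75 mm pixels.
#' @details Config entries (all optional): `n_px`, `pixel_mm`,
#'   `body_axes_mm`, `body_hu`, `liver_center_mm`, `liver_axes_mm`,
#'   `liver_hu`, `texture_sd_hu` (0 disables texture),
#'   `texture_corr_mm`, `n_vessels`, `vessel_hu`, `vessel_radius_mm`
#'   (range), `mask_erode_mm`, `vessel_margin_mm`.
#' @return a `ct_background`: list with `hu_image`, `pixel_mm`,
#'   `liver_mask`, `body_mask` and `config`.
#' @export
generate_background <- function(config = list()) {
  cf <- utils::modifyList(list(
    n_px = 512L, pixel_mm = 0.75,
    body_axes_mm = c(180, 130), body_hu = 35,
    liver_center_mm = c(-50, 22), liver_axes_mm = c(100, 75),
    liver_angle = -0.35, liver_hu = 50,
    texture_sd_hu = 7, texture_corr_mm = 4,
    n_vessels = 4L, vessel_hu = 110, vessel_radius_mm = c(2, 5),
    mask_erode_mm = 3, vessel_margin_mm = 2
  ), config)
  if (cf$liver_hu < -200 || cf$liver_hu > 200 ||
      abs(cf$liver_hu - cf$body_hu) > 500)
    stop("liver HU band incompatible with the body configuration")
  n <- cf$n_px
  px <- cf$pixel_mm
  co <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(co, n, n)
  Y <- matrix(co, n, n, byrow = TRUE)

  body <- (X / cf$body_axes_mm[1])^2 + (Y / cf$body_axes_mm[2])^2 <= 1
  ca <- cos(cf$liver_angle); sa <- sin(cf$liver_angle)
  Xl <- ca * (X - cf$liver_center_mm[1]) + sa * (Y - cf$liver_center_mm[2])
  Yl <- -sa * (X - cf$liver_center_mm[1]) + ca * (Y - cf$liver_center_mm[2])
  liver_r2 <- (Xl / cf$liver_axes_mm[1])^2 + (Yl / cf$liver_axes_mm[2])^2
  liver <- liver_r2 <= 1 & body

  hu <- matrix(-1000, n, n)
  hu[body] <- cf$body_hu
  hu[liver] <- cf$liver_hu
  if (cf$texture_sd_hu > 0) {
    tex <- gaussian_random_field(n, px, cf$texture_corr_mm)
    hu[liver] <- hu[liver] + cf$texture_sd_hu * tex[liver]
  }

  vessel <- matrix(FALSE, n, n)
  if (cf$n_vessels > 0) {
    for (v in seq_len(cf$n_vessels)) {
      repeat {
        t <- stats::runif(2, -0.6, 0.6)
        cx <- cf$liver_center_mm[1] + t[1] * cf$liver_axes_mm[1]
        cy <- cf$liver_center_mm[2] + t[2] * cf$liver_axes_mm[2]
        ii <- round((cx / px) + (n + 1) / 2)
        jj <- round((cy / px) + (n + 1) / 2)
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && liver[ii, jj]) break
      }
      r <- stats::runif(1, cf$vessel_radius_mm[1], cf$vessel_radius_mm[2])
      vessel <- vessel | ((X - cx)^2 + (Y - cy)^2 <= r^2)
    }
    vessel <- vessel & liver
    hu[vessel] <- cf$vessel_hu
  }

  # insertable mask: liver eroded at its boundary, vessels + margin excluded
  erode_frac_x <- cf$mask_erode_mm / cf$liver_axes_mm[1]
  erode_frac_y <- cf$mask_erode_mm / cf$liver_axes_mm[2]
  shrink <- (1 - max(erode_frac_x, erode_frac_y))^2
  mask <- liver_r2 <= shrink & body
  if (any(vessel)) {
    vm <- cf$vessel_margin_mm
    grown <- vessel
    steps <- max(1L, ceiling(vm / px))
    for (s in seq_len(steps)) {
      grown <- grown |
        rbind(grown[-1, ], FALSE) | rbind(FALSE, grown[-n, ]) |
        cbind(grown[, -1], FALSE) | cbind(FALSE, grown[, -n])
    }
    mask <- mask & !grown
  }
  structure(list(hu_image = hu, pixel_mm = px, liver_mask = mask * 1L,
                 body_mask = body * 1L, config = cf),
            class = "ct_background")
}

# Stationary Gaussian random field with Gaussian correlation, unit variance,
# generated by FFT filtering of white noise (circulant embedding on the
# torus; the correlation length is small relative to the grid, so wrap
# effects are negligible).
gaussian_random_field <- function(n, pixel_mm, corr_mm) {
  w <- matrix(stats::rnorm(n * n), n, n)
  f <- c(0:(n / 2), (n / 2 - 1):1) / (n * pixel_mm)
  F2 <- outer(f^2, f^2, "+")
  # Gaussian correlation exp(-d^2 / (2 l^2))  <->  spectrum exp(-2 pi^2 l^2 f^2)
  spec <- exp(-2 * pi^2 * corr_mm^2 * F2 / 2)
  field <- Re(stats::fft(stats::fft(w) * sqrt(spec), inverse = TRUE)) / (n * n)
  field / stats::sd(field)
}

#' @export
print.ct_background <- function(x, ...) {
  cat(sprintf("<ct_background> %dx%d @ %.2f mm, liver mask %d px\n",
              nrow(x$hu_image), ncol(x$hu_image), x$pixel_mm,
              sum(x$liver_mask)))
  invisible(x)
}

#' Place lesions in the liver without overlap
#'
#' Rejection-samples lesion centers so that every 25 mm x 25 mm exclusion
#' square lies fully inside the liver mask and squares are pairwise
#' disjoint.  Admissible centers are precomputed by an integral-image
#' erosion of the mask with the square footprint.
#'
#' @param background a `ct_background`.
#' @param n_mets number of lesions to place (the studies draw 10-12 per
#'   slice).
#' @param patch_mm exclusion square side (default 25 mm).
#' @param max_attempts rejection budget.
#' @return a `placement_map`: `centers_mm` (n x 2) and `patch_mm`.
#' @export
place_mets <- function(background, n_mets, patch_mm = 25,
                       max_attempts = 10000L) {
  stopifnot(inherits(background, "ct_background"), n_mets >= 1)
  m <- background$liver_mask != 0
  if (!any(m)) stop("empty liver mask")
  n <- nrow(m)
  px <- background$pixel_mm
  k <- ceiling(patch_mm / px)
  # integral image: a center is admissible when the k x k square around it
  # is fully inside the mask
  ii <- t(apply(apply(m * 1L, 2, cumsum), 1, cumsum))  # sum m[1:i, 1:j]
  P <- matrix(0L, n + 1L, n + 1L)
  P[2:(n + 1), 2:(n + 1)] <- ii
  S <- matrix(0L, n, n)
  half <- k %/% 2
  lo <- half + 1L
  hi <- n - (k - half) + 1L
  if (lo > hi) stop(placement_error(0L, n_mets))
  ci <- lo:hi
  i1 <- ci - half
  i2 <- i1 + k - 1L
  sums <- P[i2 + 1L, i2 + 1L] - P[i1, i2 + 1L] - P[i2 + 1L, i1] + P[i1, i1]
  S[ci, ci] <- (sums == k * k) * 1L
  adm <- which(S == 1L)
  if (length(adm) == 0) stop(placement_error(0L, n_mets))
  centers <- matrix(NA_real_, 0, 2)
  attempts <- 0L
  while (nrow(centers) < n_mets && attempts < max_attempts) {
    attempts <- attempts + 1L
    idx <- adm[sample.int(length(adm), 1L)]
    ci <- ((idx - 1L) %% n) + 1L
    cj <- ((idx - 1L) %/% n) + 1L
    cx <- (ci - (n + 1) / 2) * px
    cy <- (cj - (n + 1) / 2) * px
    if (nrow(centers) > 0) {
      dx <- abs(centers[, 1] - cx)
      dy <- abs(centers[, 2] - cy)
      if (any(dx < patch_mm & dy < patch_mm)) next
    }
    centers <- rbind(centers, c(cx, cy))
  }
  if (nrow(centers) < n_mets)
    stop(placement_error(nrow(centers), n_mets))
  structure(list(centers_mm = centers, patch_mm = patch_mm,
                 attempts = attempts),
            class = "placement_map")
}

placement_error <- function(placed, requested) {
  structure(class = c("placement_error", "error", "condition"),
            list(message = sprintf(
                   "could only place %d of %d lesions within the attempt budget",
                   placed, requested),
                 call = NULL, placed = placed, requested = requested))
}

#' @export
print.placement_map <- function(x, ...) {
  cat(sprintf("<placement_map> %d centers, %.0f mm exclusion squares\n",
              nrow(x$centers_mm), x$patch_mm))
  invisible(x)
}
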