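# Shared fixtures and independent oracles, built in code at test time.

# centered disc attenuation image
disc_mu <- function(n, pixel_mm, radius_mm, mu = 0.0193) {
  co <- (seq_len(n) - (n + 1) / 2) * pixel_mm
  (outer(co^2, co^2, "+") <= radius_mm^2) * mu
}

# Koch curve (classic triadic, D = log4/log3): analytic polyline at a given
# iteration, rasterized onto a grid of the stated width by segment walking.
koch_points <- function(iter) {
  p <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  for (k in seq_len(iter)) {
    out <- list()
    for (i in seq_len(nrow(p) - 1)) {
      a <- p[i, ]; b <- p[i + 1, ]
      d <- (b - a) / 3
      m1 <- a + d
      m2 <- a + 2 * d
      # peak of the equilateral bump
      peak <- m1 + c(d[1] * 0.5 - d[2] * sqrt(3) / 2,
                     d[1] * sqrt(3) / 2 + d[2] * 0.5)
      out[[i]] <- rbind(a, m1, peak, m2)
    }
    p <- rbind(do.call(rbind, out), p[nrow(p), ])
  }
  p
}

rasterize_polyline <- function(pts, width) {
  # scale x in [0,1] to [1, width]; walk segments at sub-pixel steps
  img <- matrix(0L, width, width)
  sc <- width - 1
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ] * sc + 1
    b <- pts[i + 1, ] * sc + 1
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) * 3))
    t <- seq(0, 1, length.out = n)
    xs <- round(a[1] + t * (b[1] - a[1]))
    ys <- round(a[2] + t * (b[2] - a[2])) + width %/% 4
    ok <- xs >= 1 & xs <= width & ys >= 1 & ys <= width
    img[cbind(xs[ok], ys[ok])] <- 1L
  }
  img
}

# independent naive box counter: explicit double loop over grid boxes
naive_box_count <- function(edge, scales) {
  vapply(scales, function(r) {
    nb <- 0L
    for (i0 in seq(1, nrow(edge), by = r)) {
      for (j0 in seq(1, ncol(edge), by = r)) {
        blk <- edge[i0:min(nrow(edge), i0 + r - 1),
                    j0:min(ncol(edge), j0 + r - 1)]
        if (any(blk != 0)) nb <- nb + 1L
      }
    }
    nb
  }, integer(1))
}

# toy patch set whose label is linearly decodable (mean intensity)
toy_patch_data <- function(n, px = 32, noise_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    lab <- stats::runif(n)
    X <- array(stats::rnorm(px * px * n, sd = noise_sd), c(px, px, n))
    for (i in seq_len(n)) X[, , i] <- X[, , i] + lab[i]
    list(X = X, y = lab)
  })
}

tiny_arch <- function(px = 8L)
  cnn_arch(px, stem_width = 2L, stem_k = 3L, stem_stride = 2L,
           block_widths = c(3L, 4L), block_strides = c(2L, 1L))

# constant-value sinogram with the product geometry (for noise statistics)
flat_sinogram <- function(p0, n_views = 40L, n_cells = 64L) {
  g <- fan_geometry(n_views = n_views, n_cells = n_cells)
  s <- forward_project(matrix(0, 4, 4), 1, g)
  s$values[] <- p0
  s
}

# shared cache for the scaled-down studies used by several acceptance checks
study_cache <- new.env(parent = emptyenv())

mini_study_config <- function() {
  study_config("fast", n_mets = 150L, n_backgrounds = 1L, epochs = 8L)
}

# run (or fetch) one mini study; key = tag + seed + characteristics
mini_study <- function(tag, seed, characteristics = NULL) {
  key <- paste(tag, seed, paste(characteristics, collapse = "+"), sep = "#")
  if (!is.null(study_cache[[key]])) return(study_cache[[key]])
  cfg <- mini_study_config()
  blur <- grepl("_blur", tag)
  skey <- paste("scans", blur, seed, sep = "#")
  if (is.null(study_cache[[skey]]))
    study_cache[[skey]] <- simulate_study_scans(blur, config = cfg, seed = seed)
  res <- run_study(tag, config = cfg, seed = seed,
                   scans = study_cache[[skey]],
                   characteristics = characteristics)
  study_cache[[key]] <- res
  res
}
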