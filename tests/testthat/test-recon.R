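test_that("kernel responses are apodized ramps with the required ordering", {
  std <- build_kernel("standard")
  hf <- build_kernel("high_frequency")
  ramp <- build_kernel("ramp")
  expect_equal(std$response[1], 0)
  expect_equal(hf$response[1], 0)
  expect_true(all(is.finite(std$response)) && all(is.finite(hf$response)))
  nu <- std$nu
  expect_true(all(hf$response[nu >= 0.5] >= std$response[nu >= 0.5]))
  # pure ramp: |H| = |f| exactly on the tabulation grid
  expect_identical(ramp$response, ramp$nu)
  # high-frequency boost is mild (<= 1.4x ramp)
  expect_true(all(hf$response <= 1.4 * hf$nu + 1e-12))
  expect_error(build_kernel("bone"), "arg")
})

test_that("FBP reconstructs air from an empty sinogram and is linear in mu", {
  g <- fan_geometry(n_views = 96L, n_cells = 256L)
  zero <- forward_project(matrix(0, 16, 16), 1, g)
  rec <- fbp_reconstruct(zero, "standard", fov_mm = 64, pixel_mm = 2)
  expect_equal(max(abs(rec$hu_image + 1000)), 0)

  mu <- disc_mu(128, 1, 40, 0.01)
  s <- forward_project(mu, 1, g)
  r1 <- fbp_reconstruct(s, "standard", fov_mm = 128, pixel_mm = 2)
  s3 <- s; s3$values <- 3 * s$values
  r3 <- fbp_reconstruct(s3, "standard", fov_mm = 128, pixel_mm = 2)
  m1 <- hu_to_mu(r1$hu_image); m3 <- hu_to_mu(r3$hu_image)
  expect_lt(max(abs(m3 - 3 * m1)) / max(m3), 1e-6)

  expect_error(fbp_reconstruct(s, "standard", fov_mm = 600), "covered")
})

test_that("water disc round trip lands within 10 HU in the core", {
  g <- fan_geometry()
  mu <- disc_mu(256, 0.5, 50)
  s <- forward_project(mu, 0.5, g)
  rec <- fbp_reconstruct(s, "standard", fov_mm = 160, pixel_mm = 1)
  n <- nrow(rec$hu_image)
  co <- (seq_len(n) - (n + 1) / 2)
  core <- outer(co^2, co^2, "+") <= 25^2
  expect_lt(abs(mean(rec$hu_image[core])), 10)
})

test_that("piecewise-constant phantom round trip achieves interior RMSE < 15 HU", {
  g <- fan_geometry()
  n <- 240; px <- 0.5
  co <- (seq_len(n) - (n + 1) / 2) * px
  X <- matrix(co, n, n); Y <- matrix(co, n, n, byrow = TRUE)
  hu <- matrix(-1000, n, n)
  hu[(X / 55)^2 + (Y / 45)^2 <= 1] <- 0
  hu[((X - 18) / 16)^2 + (Y / 25)^2 <= 1] <- 50
  hu[((X + 20) / 10)^2 + ((Y - 8) / 14)^2 <= 1] <- -60
  s <- forward_project(hu_to_mu(hu), px, g)
  rec <- fbp_reconstruct(s, "standard", fov_mm = 120, pixel_mm = 0.5)
  co2 <- (seq_len(240) - 120.5) * 0.5
  X2 <- matrix(co2, 240, 240); Y2 <- matrix(co2, 240, 240, byrow = TRUE)
  interior <- (X2 / 55)^2 + (Y2 / 45)^2 <= 0.85^2
  # reconstruction grid coincides with the phantom grid (120 mm, 0.5 mm)
  rmse <- sqrt(mean((rec$hu_image[interior] - hu[interior])^2))
  expect_lt(rmse, 15)
})

test_that("kernel effect direction: sharper edges, noisier flats for high frequency", {
  g <- fan_geometry()
  mu <- disc_mu(320, 0.5, 40, hu_to_mu(50))
  s <- forward_project(mu, 0.5, g)
  esf_width <- function(k) {
    rec <- reconstruct_patches(s, k, matrix(c(40, 0), 1),
                               pixel_mm = 0.2, size_px = 128)[[1]]
    prof <- rowMeans(rec$hu_image[, 62:66])
    x <- seq_len(128) * 0.2
    p <- (prof + 1000) / 1050
    xc <- which(diff(sign(p - 0.5)) != 0)[1]
    i90 <- xc; while (i90 > 1 && p[i90] < 0.9) i90 <- i90 - 1
    i10 <- xc; while (i10 < 128 && p[i10] > 0.1) i10 <- i10 + 1
    x90 <- approx(p[c(i90, i90 + 1)], x[c(i90, i90 + 1)], 0.9)$y
    x10 <- approx(p[c(i10 - 1, i10)], x[c(i10 - 1, i10)], 0.1)$y
    x10 - x90
  }
  expect_lt(esf_width("high_frequency"), esf_width("standard"))

  set.seed(31)
  noisy <- add_poisson_noise(s, noise_model())
  flat_sd <- function(k) {
    rec <- reconstruct_patches(noisy, k, matrix(c(0, 0), 1),
                               pixel_mm = 0.5, size_px = 64)[[1]]
    sd(rec$hu_image)
  }
  expect_gt(flat_sd("high_frequency"), flat_sd("standard"))
})

test_that("patch extraction respects size, centering and bounds", {
  g <- fan_geometry(n_views = 96L, n_cells = 256L)
  mu <- disc_mu(128, 1, 40, 0.0193)
  s <- forward_project(mu, 1, g)
  rec <- fbp_reconstruct(s, "standard", fov_mm = 120, pixel_mm = 1)
  p <- extract_patch(rec, c(0, 0), 64L)
  expect_equal(dim(p$hu_image), c(64L, 64L))
  # symmetric phantom: central patch symmetric under 180 degree rotation
  rot <- p$hu_image[64:1, 64:1]
  expect_lt(mean(abs(p$hu_image - rot)) / diff(range(p$hu_image)), 0.02)
  expect_error(extract_patch(rec, c(45, 45), 64L), "bounds")

  # FBP determinism: identical inputs give identical outputs
  r2 <- fbp_reconstruct(s, "standard", fov_mm = 120, pixel_mm = 1)
  expect_identical(rec$hu_image, r2$hu_image)
})
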