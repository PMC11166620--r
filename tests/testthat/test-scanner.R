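test_that("HU to attenuation conversion is the clipped water-affine map", {
  expect_equal(hu_to_mu(0), 0.0193)
  expect_equal(hu_to_mu(-1000), 0)
  expect_equal(hu_to_mu(-2000), 0)  # clipping below air
  a <- 123; b <- -45
  expect_equal(hu_to_mu(a) + hu_to_mu(b) - 0.0193, hu_to_mu(a + b))
  expect_equal(mu_to_hu(hu_to_mu(50)), 50)
})

test_that("geometry validation and fan coverage", {
  g <- fan_geometry()
  expect_equal(g$n_views, 984L)
  expect_equal(g$n_cells, 888L)
  expect_gt(g$fov_radius_mm, 200)  # covers the 40 cm FOV
  expect_error(fan_geometry(sid_mm = 1000, sdd_mm = 900), "SDD")
})

test_that("forward projection reproduces analytic disc line integrals", {
  g <- fan_geometry()
  expect_true(all(forward_project(matrix(0, 32, 32), 1, g)$values == 0))

  mu <- disc_mu(256, 0.25, 20)
  s <- forward_project(mu, 0.25, g)
  expect_lt(abs(max(s$values) - 2 * 20 * 0.0193) / (2 * 20 * 0.0193), 0.005)
  expect_true(all(s$values >= 0))

  # rebinned-parallel oracle: fan ray (beta, gamma) is a parallel ray at
  # signed distance SID * sin(gamma); a centered disc gives chord
  # 2 sqrt(R^2 - s^2) * mu for every view
  gamma <- (seq_len(g$n_cells) - (g$n_cells + 1) / 2) * g$dgamma
  sdist <- g$sid_mm * sin(gamma)
  keep <- abs(sdist) < 0.9 * 20
  expected <- 2 * sqrt(pmax(20^2 - sdist[keep]^2, 0)) * 0.0193
  for (v in c(1, 250, 777)) {
    rel <- abs(s$values[v, keep] - expected) / max(expected)
    expect_lt(max(rel), 0.01)
  }
})

test_that("projector is linear and superposition matches same-grid projection", {
  g <- fan_geometry(n_views = 64L, n_cells = 256L)
  set.seed(4)
  a <- disc_mu(96, 1, 30, 0.02)
  b <- matrix(0, 96, 96); b[40:55, 30:60] <- 0.01
  sa <- forward_project(a, 1, g)
  sb <- forward_project(b, 1, g)
  sab <- forward_project(a + b, 1, g)
  sup <- superpose(sa, list(sb))
  expect_equal(sup$values, sa$values + sb$values, tolerance = 1e-14)
  expect_lt(max(abs(sab$values - sup$values)) / max(sab$values), 1e-3)
  expect_identical(superpose(sa, list())$values, sa$values)

  g2 <- fan_geometry(n_views = 32L, n_cells = 256L)
  sc <- forward_project(b, 1, g2)
  expect_error(superpose(sa, list(sc)), "mismatch")
})

test_that("Poisson noise statistics follow the photon model", {
  # vanishing-noise limit
  s <- flat_sinogram(6)
  set.seed(9)
  out <- add_poisson_noise(s, noise_model(n0_ref = 1e12 / 600))
  expect_lt(max(abs(out$values - s$values)), 1e-3)

  # variance of post-log values ~ 1 / (N0 exp(-p)) at lambda = 1e4
  p0 <- 3
  n0 <- 1e4 / exp(-p0)
  s2 <- flat_sinogram(p0, n_views = 400L, n_cells = 250L)  # 1e5 rays
  set.seed(10)
  noisy <- add_poisson_noise(s2, noise_model(ma = 1, rotation_s = 1,
                                             n0_ref = n0))
  v_emp <- stats::var(as.numeric(noisy$values))
  expect_lt(abs(v_emp - 1e-4) / 1e-4, 0.10)

  # doubling mAs halves the variance
  set.seed(11)
  noisy2 <- add_poisson_noise(s2, noise_model(ma = 2, rotation_s = 1,
                                              n0_ref = n0))
  ratio <- v_emp / stats::var(as.numeric(noisy2$values))
  expect_lt(abs(ratio - 2) / 2, 0.10)

  expect_error(noise_model(n0_ref = 0), "positive")
  expect_warning(add_poisson_noise(flat_sinogram(20), noise_model()),
                 "photon")
})

test_that("SNR follows its closed form and flags zero-noise regions", {
  img <- matrix(0, 32, 32)
  expect_equal(compute_snr(img, matrix(1, 32, 32)), Inf)
  set.seed(2)
  img <- matrix(rnorm(1e4, 0, 10), 100, 100)
  img <- (img - mean(img)) / sd(img) * 10  # exact mean 0, sd 10
  expect_equal(compute_snr(img, matrix(1, 100, 100)),
               20 * log10(1000 / 10), tolerance = 1e-9)
})
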