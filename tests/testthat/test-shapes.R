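test_that("base hexagon construction honors radius, ordering and jitter bounds", {
  h <- init_base_hexagon(1, 0)
  expect_equal(nrow(h$vertices), 6)
  r <- sqrt(rowSums(h$vertices^2))
  expect_equal(r, rep(1, 6), tolerance = 1e-12)
  ang <- atan2(h$vertices[, 2], h$vertices[, 1]) %% (2 * pi)
  expect_equal(sort(ang), (0:5) * pi / 3, tolerance = 1e-12)
  # counterclockwise orientation: positive signed area
  v <- h$vertices
  area2 <- sum(v[, 1] * v[c(2:6, 1), 2] - v[c(2:6, 1), 1] * v[, 2])
  expect_gt(area2, 0)

  expect_error(init_base_hexagon(0), "positive")
  expect_error(init_base_hexagon(-2), "positive")
  expect_error(init_base_hexagon(1, 1), "irregularity")

  # radial jitter bound from the uniform law, across many seeds
  set.seed(101)
  radii <- replicate(1000, {
    hh <- init_base_hexagon(10, 0.2)
    sqrt(rowSums(hh$vertices^2))
  })
  expect_true(all(radii >= 8 - 1e-12 & radii <= 12 + 1e-12))
})

test_that("midpoint subdivision doubles vertices with bounded normal displacement", {
  set.seed(7)
  h <- init_base_hexagon(5, 0.1)
  s1 <- subdivide_once(h, 0.3)
  expect_equal(nrow(s1$vertices), 12)
  expect_equal(s1$generation, 1L)

  # roughness 0: midpoints exact, geometry unchanged
  s0 <- subdivide_once(h, 0)
  mids <- (h$vertices + h$vertices[c(2:6, 1), ]) / 2
  expect_equal(s0$vertices[seq(2, 12, 2), ], mids, tolerance = 1e-14)

  # displacement magnitude <= roughness * edge length, exhaustively
  set.seed(8)
  rough <- 0.27
  n_checked <- 0
  sh <- init_base_hexagon(6, 0.1)
  while (n_checked < 10000) {
    v <- sh$vertices
    nxt <- v[c(2:nrow(v), 1), , drop = FALSE]
    mids <- (v + nxt) / 2
    len <- sqrt(rowSums((nxt - v)^2))
    sub <- subdivide_once(sh, rough)
    disp <- sqrt(rowSums((sub$vertices[seq(2, 2 * nrow(v), 2), ] - mids)^2))
    expect_true(all(disp <= rough * len + 1e-12))
    n_checked <- n_checked + nrow(v)
    sh <- if (nrow(sub$vertices) > 2000) init_base_hexagon(6, 0.1) else sub
  }
  expect_error(subdivide_once(h, -1), "roughness")
})

test_that("shape growth terminates at raster spacing with 6 * 2^k vertices", {
  sh <- generate_shape(5, 0, target_spacing_mm = 0.156, irregularity = 0)
  expect_equal(nrow(sh$vertices), 6 * 2^sh$generation)
  expect_lt(max_vertex_separation(sh), 0.156)

  # roughness 0: perimeter is exactly that of the initial hexagon
  v <- sh$vertices
  per <- sum(sqrt(rowSums((v[c(2:nrow(v), 1), ] - v)^2)))
  expect_equal(per, 30, tolerance = 1e-9)

  # deterministic across seeds when roughness is 0
  set.seed(1); a <- generate_shape(5, 0, irregularity = 0)
  set.seed(2); b <- generate_shape(5, 0, irregularity = 0)
  expect_identical(a$vertices, b$vertices)

  # subdivision cap
  expect_error(generate_shape(5, 0, target_spacing_mm = 1e-6, max_iter = 5L),
               "subdivisions")
})

test_that("circular moving-average smoothing preserves count, closure and centroid", {
  set.seed(11)
  sh <- generate_shape(6, 0.25)
  n <- nrow(sh$vertices)
  expect_identical(smooth_shape(sh, 1)$vertices, sh$vertices)
  sm <- smooth_shape(sh, 16L)
  expect_equal(nrow(sm$vertices), n)
  expect_equal(colMeans(sm$vertices), colMeans(sh$vertices), tolerance = 1e-9)
  expect_error(smooth_shape(sh, n), "smooth_len")
})

test_that("rasterization fills pixel centers inside the polygon", {
  # square inscribing the full grid: every pixel center is inside
  big <- new_polygon_shape(31.9 * rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)))
  expect_true(all(rasterize(big, 64L, 1) == 1))

  # regular hexagon area: (3 sqrt(3) / 2) r^2, within 2% for r >= 50 px
  r_mm <- 60 * 0.156
  hexa <- init_base_hexagon(r_mm, 0)
  ras <- rasterize(hexa, 256L, 0.156)
  a_true <- 3 * sqrt(3) / 2 * r_mm^2
  expect_lt(abs(sum(ras) * 0.156^2 - a_true) / a_true, 0.02)
  expect_equal(dim(rasterize(hexa)), c(256L, 256L))

  expect_error(rasterize(init_base_hexagon(50, 0), 64L, 0.156), "extent")
})

test_that("nested inserts stay inside the parent and degenerate parents error", {
  set.seed(21)
  parent <- generate_shape(7, 0.2)
  subs <- generate_insert(parent, 3L)
  expect_length(subs, 3)
  # sub-shapes are seeded and scaled down from the parent's early generation
  for (s in subs) expect_gt(nrow(s$vertices), 6)
  # confinement contract on the composed raster: every pixel carrying an
  # insert offset (hu below the homogeneous base) lies inside the support
  m <- compose_met(met_spec(contrast_hu = -40, insert_scale_hu = 40,
                            seed = 33L))
  sup <- m$hu_offset != 0
  ins <- m$hu_offset < -40 - 1e-9
  expect_true(all(sup[ins]))
  expect_true(any(ins))
  degen <- new_polygon_shape(rbind(c(0, 0), c(1e-4, 0), c(2e-4, 0)))
  expect_error(generate_insert(degen, 2L), "small")
  expect_error(generate_insert(parent, 4L), "n_subshapes")
})

test_that("lesion composition obeys HU range, labels and no-blur identity", {
  spec <- met_spec(contrast_hu = -50, insert_scale_hu = 30,
                   blur_sigma_mm = 0, seed = 42L)
  m <- compose_met(spec)
  sup <- m$hu_offset != 0
  expect_true(all(m$hu_offset <= 0))
  expect_gte(min(m$hu_offset), -50 - 30 - 1e-9)
  expect_equal(max(abs(m$hu_offset[!sup])), 0)
  # heterogeneity scaling is exact: deepest insert point at contrast - scale
  expect_equal(min(m$hu_offset), -80, tolerance = 1e-9)
  expect_equal(m$labels$heterogeneity, 30)
  expect_equal(m$labels$edge_sharpness, 0)
  expect_true(m$labels$fractal_dim >= 0 && m$labels$fractal_dim <= 2)

  # zero insert scale: constant at contrast on the support
  m0 <- compose_met(met_spec(insert_scale_hu = 0, seed = 42L))
  vals <- unique(m0$hu_offset[m0$hu_offset != 0])
  expect_equal(vals, -50)

  # blur changes the raster; sigma 0 reproduces the unblurred composition
  mb <- compose_met(met_spec(contrast_hu = -50, insert_scale_hu = 30,
                             blur_sigma_mm = 0.8, seed = 42L))
  expect_false(identical(mb$hu_offset, m$hu_offset))
  expect_identical(compose_met(spec)$hu_offset, m$hu_offset)
  expect_equal(mb$labels$edge_sharpness, 0.8)

  expect_error(met_spec(contrast_hu = -10), "contrast")
  expect_error(met_spec(insert_scale_hu = 90), "insert")
  expect_error(met_spec(blur_sigma_mm = -1), "blur")
})

test_that("sampled lesion specifications follow the study distributions", {
  set.seed(5)
  draws <- replicate(10000, {
    s <- sample_met_spec(blur = TRUE)
    c(s$contrast_hu, s$insert_scale_hu, s$blur_sigma_mm, s$roughness,
      s$radius_mm, s$n_insert_subshapes)
  })
  expect_true(all(draws[1, ] >= -80 & draws[1, ] <= -20))
  expect_true(all(draws[2, ] >= 0 & draws[2, ] <= 80))
  expect_true(all(draws[3, ] >= 0 & draws[3, ] <= 1.5))
  expect_true(all(draws[5, ] >= 4 & draws[5, ] <= 10))
  expect_true(all(draws[6, ] %in% 2:3))
  expect_true(all(sample_met_spec(blur = FALSE)$blur_sigma_mm == 0))
})
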