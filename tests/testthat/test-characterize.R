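test_that("dataset building splits deterministically and normalizes on train only", {
  set.seed(71)
  n <- 1000
  X <- array(rnorm(4 * 4 * n, mean = 5, sd = 2), c(4, 4, n))
  y <- runif(n, 10, 90)
  ds <- build_dataset(X, y, split_frac = 0.9, seed = 3L)
  expect_length(ds$split$train, 900)
  expect_length(ds$split$val, 100)
  expect_length(intersect(ds$split$train, ds$split$val), 0)

  # labels span [0, 1] on the training split
  expect_equal(range(ds$labels_norm[ds$split$train]), c(0, 1))
  # image normalization constants come from the training split
  expect_equal(ds$norm$img_mean, mean(X[, , ds$split$train]))

  ds2 <- build_dataset(X, y, split_frac = 0.9, seed = 3L)
  expect_identical(ds$split, ds2$split)
  ds3 <- build_dataset(X, y, split_frac = 0.9, seed = 4L)
  expect_false(identical(ds$split$val, ds3$split$val))

  expect_error(build_dataset(X[, , 1:5], y[1:5]), "small")
  expect_error(build_dataset(X, rep(1, n)), "constant")
})

test_that("dihedral augmentation is eight-fold and closed", {
  set.seed(72)
  X <- array(rnorm(4 * 4 * 12), c(4, 4, 12))
  y <- seq_len(12)
  ds <- build_dataset(X, y, split_frac = 0.75, seed = 1L)
  aug <- augment(ds)
  n_tr <- length(ds$split$train)
  expect_equal(dim(aug$patches)[3], 8 * n_tr)
  expect_equal(aug$labels_norm, rep(ds$labels_norm[ds$split$train], 8))

  # a rotationally symmetric patch yields 8 identical variants
  co <- seq_len(9) - 5
  disc <- (outer(co^2, co^2, "+") <= 9) * 1
  Xs <- array(disc, c(9, 9, 12))
  dss <- build_dataset(Xs + array(0, c(9, 9, 12)),
                       y, split_frac = 0.75, seed = 1L)
  augs <- augment(dss)
  for (k in 1:8) {
    expect_equal(augs$patches[, , (k - 1) * n_tr + 1], augs$patches[, , 1])
  }

  # dihedral closure: augmenting an augmented set introduces no new images
  key <- function(a) apply(a, 3, function(m) paste(signif(m, 6), collapse = ","))
  once <- aug$patches
  twice <- array(0, c(4, 4, 8 * dim(once)[3]))
  vars <- livermetsim:::dihedral_variants()
  for (k in seq_along(vars)) {
    twice[, , (k - 1) * dim(once)[3] + seq_len(dim(once)[3])] <- vars[[k]](once)
  }
  expect_setequal(unique(key(twice)), unique(key(once)))
})

test_that("concordance correlation matches its closed forms", {
  x <- c(0.2, 0.5, 0.9, 0.1)
  expect_equal(ccc(x, x), 1)
  z <- c(-1, 1, -2, 2)
  expect_equal(ccc(-z, z), -1)
  # y = x + c with population variance 1: 2 / (2 + c^2)
  x2 <- c(-1, 1)
  expect_equal(ccc(x2 + 1, x2), 2 / 3)
  expect_error(ccc(rep(1, 5), rep(2, 5)), "constant")
  expect_error(ccc(1, 1:2), "equal lengths")
})

test_that("bias adjustment is an exact least-squares head refit", {
  arch <- tiny_arch(8L)
  set.seed(81)
  n <- 60
  X <- array(rnorm(8 * 8 * n), c(8, 8, n))
  params <- livermetsim:::cpp_cnn_init(arch, 5L)
  params <- params + rnorm(length(params)) * 0.1
  model <- structure(list(params = params, arch = arch), class = "met_cnn")

  # linear recovery: labels built from a known map of the frozen features
  F <- cnn_features(model, X)
  w_true <- rnorm(ncol(F)); b_true <- 0.7
  y <- drop(F %*% w_true) + b_true
  adj <- bias_adjust(model, X, y)
  head <- livermetsim:::cpp_cnn_head(adj$params, arch)
  expect_equal(head$w, w_true, tolerance = 1e-5)
  expect_equal(head$b, b_true, tolerance = 1e-5)

  # fixed point: adjusting twice changes nothing
  adj2 <- bias_adjust(adj, X, y)
  expect_equal(adj2$params, adj$params, tolerance = 1e-6)

  # the refit never increases training MSE
  y2 <- y + rnorm(n)
  before <- mean((predict(model, X) - y2)^2)
  after <- mean((predict(bias_adjust(model, X, y2), X) - y2)^2)
  expect_lte(after, before + 1e-8)

  # intercept-only mode shifts the mean exactly
  adj3 <- bias_adjust(model, X, y2, mode = "intercept")
  expect_equal(mean(predict(adj3, X)), mean(y2), tolerance = 1e-5)
})

test_that("training is finite, reproducible and learns a decodable label", {
  toy <- toy_patch_data(200, px = 32, seed = 9)
  ds <- build_dataset(toy$X, toy$y, seed = 2L)
  arch <- cnn_arch(32L, stem_width = 4L, stem_k = 3L, stem_stride = 2L,
                   block_widths = c(8L, 8L), block_strides = c(2L, 1L))
  fit <- met_cnn(ds, arch = arch, config = train_config(epochs = 5L),
                 seed = 1L, augment_data = FALSE)
  expect_true(all(is.finite(fit$history)))
  ev <- evaluate(fit, ds)
  expect_gt(ev$ccc, 0.95)

  fit2 <- met_cnn(ds, arch = arch, config = train_config(epochs = 5L),
                  seed = 1L, augment_data = FALSE)
  expect_equal(tail(fit$history, 1), tail(fit2$history, 1), tolerance = 1e-6)

  expect_error(train_config(lr = -1), "positive")
})

test_that("evaluation conventions: mean predictor scores exactly one", {
  set.seed(91)
  n <- 50
  X <- array(rnorm(8 * 8 * n), c(8, 8, n))
  y <- runif(n)
  ds <- build_dataset(X, y, seed = 1L)
  arch <- tiny_arch(8L)
  model <- structure(list(params = livermetsim:::cpp_cnn_init(arch, 3L),
                          arch = arch, norm = ds$norm),
                     class = "met_cnn")
  # zero head weights + intercept at the validation label mean
  yv <- ds$labels_norm[ds$split$val]
  out <- livermetsim:::cpp_cnn_set_head(model$params, arch,
                                        rep(0, 4), mean(yv))
  model$params <- out$params
  ev <- evaluate(model, ds)
  expect_equal(ev$nmse, 1, tolerance = 1e-6)
  expect_true(all(ev$se_norm >= 0))

  # confidence interval shrinks as 1 / sqrt(n)
  se <- abs(rnorm(4000, 0, 1))^2
  width <- function(k) {
    s <- se[seq_len(k)]
    2 * 1.96 * sd(s) / sqrt(k)
  }
  expect_lt(abs(width(1000) / width(4000) - 2), 0.2)
})

test_that("kernel comparison pairs errors and reproduces the t oracle", {
  base <- list(se_norm = rep(0.5, 8), val_idx = 1:8)
  cmp0 <- compare_kernels(structure(base, class = "eval_result"),
                          structure(base, class = "eval_result"))
  expect_equal(cmp0$pct_diff, 0)
  expect_equal(cmp0$p_value, 1)
  expect_true(cmp0$degenerate)

  # constant nonzero differences are degenerate too
  b2 <- base; b2$se_norm <- base$se_norm + 0.3
  cmp1 <- compare_kernels(structure(b2, class = "eval_result"),
                          structure(base, class = "eval_result"))
  expect_true(cmp1$degenerate)

  # textbook paired case: dbar = 1, sd = 1, n = 16 -> t = 4, p ~ 0.00117
  d <- scale(rnorm(16))[, 1] + 1  # exact mean 1, sd 1
  ea <- structure(list(se_norm = d + 2, val_idx = 1:16), class = "eval_result")
  eb <- structure(list(se_norm = rep(2, 16), val_idx = 1:16),
                  class = "eval_result")
  cmp <- compare_kernels(ea, eb)
  expect_equal(cmp$t_stat, 4, tolerance = 1e-10)
  # frozen from the t oracle: 2 * pt(-4, df = 15)
  expect_equal(cmp$p_value, 0.001159317, tolerance = 1e-6)

  ec <- structure(list(se_norm = d, val_idx = 2:17), class = "eval_result")
  expect_error(compare_kernels(ea, ec), "paired")
})

test_that("backpropagation gradients match finite differences", {
  arch <- tiny_arch(8L)
  set.seed(55)
  n <- 3
  X <- array(rnorm(8 * 8 * n), c(8, 8, n))
  y <- rnorm(n)
  p <- livermetsim:::cpp_cnn_init(arch, 7L)
  p <- p + rnorm(length(p)) * 0.05
  g <- livermetsim:::cpp_cnn_grad(X, y, arch, p)
  eps <- 1e-3
  idx <- sample(length(p), 25)
  fd <- vapply(idx, function(i) {
    pp <- p; pp[i] <- pp[i] + eps
    lp <- livermetsim:::cpp_cnn_grad(X, y, arch, pp)$loss
    pm <- p; pm[i] <- pm[i] - eps
    lm <- livermetsim:::cpp_cnn_grad(X, y, arch, pm)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  # float32 forward passes limit the attainable agreement
  expect_lt(max(abs(fd - g$grad[idx])), 0.05 * max(abs(fd), 0.01))
})
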