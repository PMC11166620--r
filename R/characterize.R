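#' Build a labeled patch dataset
#'
#' Deterministic shuffled train/validation split (by patch, which in the
#' study pipeline is one lesion per patch), per-dataset z-score image
#' normalization and min-max label normalization to `[0, 1]`, with all
#' normalization constants computed on the training split only.
#'
#' @param patches array `H x W x n` of HU patches (or list of
#'   `recon_image`s).
#' @param labels numeric vector of length n.
#' @param split_frac training fraction (default 0.9).
#' @param seed split seed.
#' @param split optional precomputed split (list with `train`, `val`
#'   index vectors), used to share one split across kernels.
#' @return a `patch_dataset`: normalized `patches`, `labels_norm`, raw
#'   `labels`, `split`, and the normalization constants.
#' @export
build_dataset <- function(patches, labels, split_frac = 0.9, seed = 1L,
                          split = NULL) {
  if (is.list(patches))
    patches <- simplify2array(lapply(patches, function(p) p$hu_image))
  n <- dim(patches)[3]
  if (length(labels) != n) stop("one label per patch required")
  if (n < 10) stop("dataset too small to split")
  if (is.null(split)) {
    ord <- withr::with_seed(seed, sample.int(n))
    n_train <- floor(split_frac * n)
    split <- list(train = sort(ord[seq_len(n_train)]),
                  val = sort(ord[(n_train + 1):n]))
  }
  mu <- mean(patches[, , split$train])
  sd_ <- stats::sd(patches[, , split$train])
  if (sd_ == 0) sd_ <- 1
  lab_min <- min(labels[split$train])
  lab_max <- max(labels[split$train])
  if (lab_max == lab_min) stop("labels are constant on the training split")
  structure(list(
    patches = (patches - mu) / sd_,
    labels = labels,
    labels_norm = (labels - lab_min) / (lab_max - lab_min),
    split = split,
    norm = list(img_mean = mu, img_sd = sd_,
                lab_min = lab_min, lab_max = lab_max)),
    class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches (%d train / %d val), %dx%d px\n",
              dim(x$patches)[3], length(x$split$train), length(x$split$val),
              dim(x$patches)[1], dim(x$patches)[2]))
  invisible(x)
}

#' Eight-fold dihedral augmentation of the training split
#'
#' Expands every training patch to its 8 dihedral variants (4 right-angle
#' rotations times 2 reflections) with labels copied unchanged; the
#' validation split is untouched.  Returns the augmented training arrays.
#'
#' @param dataset a `patch_dataset`.
#' @return list with `patches` (`H x W x 8n`) and `labels_norm`.
#' @export
augment <- function(dataset) {
  tr <- dataset$split$train
  if (length(tr) == 0) stop("empty training split")
  p <- dataset$patches[, , tr, drop = FALSE]
  n <- dim(p)[3]
  H <- dim(p)[1]
  out <- array(0, c(H, H, 8L * n))
  k <- 0L
  for (v in dihedral_variants()) {
    out[, , k * n + seq_len(n)] <- v(p)
    k <- k + 1L
  }
  list(patches = out, labels_norm = rep(dataset$labels_norm[tr], 8L))
}

dihedral_variants <- function() {
  rot90 <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  flip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  list(
    identity,
    function(a) rot90(a),
    function(a) rot90(rot90(a)),
    function(a) rot90(rot90(rot90(a))),
    function(a) flip(a),
    function(a) rot90(flip(a)),
    function(a) rot90(rot90(flip(a))),
    function(a) rot90(rot90(rot90(flip(a))))
  )
}

#' Architecture of the patch regressor
#'
#' A compact pre-activation residual CNN: a strided stem convolution,
#' `length(block_widths)` residual blocks (ReLU-conv3x3-ReLU-conv3x3 with
#' identity or 1x1-projection skip), a final ReLU, global average pooling,
#' and a scalar affine head.  The default mirrors a small ResNet-V2-style
#' regressor (4 blocks, widths 16/32/64/64); `cnn_arch_fast()` is the
#' reduced variant used by the desk-scale studies.
#'
#' @param in_px input patch width (pixels).
#' @param stem_width,stem_k,stem_stride stem convolution parameters.
#' @param block_widths,block_strides residual block widths and first-conv
#'   strides.
#' @return an architecture list understood by [met_cnn()].
#' @export
cnn_arch <- function(in_px = 128L, stem_width = 16L, stem_k = 5L,
                     stem_stride = 2L,
                     block_widths = c(16L, 32L, 64L, 64L),
                     block_strides = c(2L, 2L, 2L, 1L)) {
  list(in_h = as.integer(in_px), in_w = as.integer(in_px),
       stem_k = as.integer(stem_k), stem_stride = as.integer(stem_stride),
       stem_width = as.integer(stem_width),
       block_widths = as.integer(block_widths),
       block_strides = as.integer(block_strides))
}

#' @rdname cnn_arch
#' @export
cnn_arch_fast <- function(in_px = 64L) {
  cnn_arch(in_px, stem_width = 8L, stem_k = 5L, stem_stride = 2L,
           block_widths = c(12L, 24L, 32L), block_strides = c(2L, 2L, 2L))
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam at learning rate 4e-5,
#' mean-squared-error loss, batch size 40.  The reference protocol trains
#' 120 epochs; the desk-scale default is 20.  After every epoch the final
#' affine layer is refit by least squares on the penultimate features of
#' the whole training set (`bias_adjust = "full"`; `"intercept"` refits
#' only the bias, `"none"` disables the adjustment).
#'
#' @param lr Adam learning rate.
#' @param batch batch size.
#' @param epochs training epochs.
#' @param bias_adjust `"full"`, `"intercept"` or `"none"`.
#' @return a list of training settings.
#' @export
train_config <- function(lr = 4e-5, batch = 40L, epochs = 20L,
                         bias_adjust = c("full", "intercept", "none")) {
  if (lr <= 0 || batch < 1 || epochs < 1) stop("hyperparameters must be positive")
  list(lr = lr, batch = as.integer(batch), epochs = as.integer(epochs),
       bias_adjust = match.arg(bias_adjust))
}

#' Fit the patch regressor
#'
#' Trains the residual CNN on (augmented) training patches with Adam and
#' MSE loss, applying the per-epoch bias adjustment.  `met_cnn` is the
#' generic fitting entry point of the package: it accepts either a
#' `patch_dataset` (augmented internally) or explicit arrays.
#'
#' @param x a `patch_dataset`, or an `H x W x n` array of inputs.
#' @param y labels (ignored when `x` is a `patch_dataset`).
#' @param arch architecture from [cnn_arch()] (default sized to the input).
#' @param config a [train_config()].
#' @param seed seed for weight initialization and batch shuffling.
#' @param augment_data expand the training split eight-fold first.
#' @return a `met_cnn` model with elements `params`, `arch`, `history`,
#'   `config` and the dataset normalization (when available).
#' @export
met_cnn <- function(x, y = NULL, arch = NULL, config = train_config(),
                    seed = 1L, augment_data = TRUE) {
  if (inherits(x, "patch_dataset")) {
    norm <- x$norm
    if (augment_data) {
      aug <- augment(x)
      X <- aug$patches
      y <- aug$labels_norm
    } else {
      X <- x$patches[, , x$split$train, drop = FALSE]
      y <- x$labels_norm[x$split$train]
    }
  } else {
    norm <- NULL
    X <- x
    if (is.null(y)) stop("labels required when fitting on a plain array")
  }
  if (is.null(arch)) arch <- cnn_arch(dim(X)[1])
  p0 <- cpp_cnn_init(arch, seed)
  fit <- cpp_cnn_train(X, y, arch, config, p0, seed + 1L)
  structure(list(params = fit$params, arch = arch,
                 history = as.numeric(fit$history),
                 config = config, norm = norm, seed = seed),
            class = "met_cnn")
}

#' @export
print.met_cnn <- function(x, ...) {
  cat(sprintf(paste0("<met_cnn> %d parameters, %d epochs trained, ",
                     "final training MSE %.4g\n"),
              length(x$params), length(x$history),
              utils::tail(x$history, 1)))
  invisible(x)
}

#' @export
predict.met_cnn <- function(object, newdata, denormalize = FALSE, ...) {
  if (inherits(newdata, "patch_dataset")) {
    X <- newdata$patches
  } else X <- newdata
  pred <- cpp_cnn_predict(X, object$arch, object$params)
  if (denormalize && !is.null(object$norm))
    pred <- pred * (object$norm$lab_max - object$norm$lab_min) +
      object$norm$lab_min
  pred
}

#' Penultimate features of the regressor
#'
#' Global-average-pooled activations feeding the affine head, one row per
#' patch.
#'
#' @param model a `met_cnn`.
#' @param X `H x W x n` array.
#' @return `n x F` feature matrix.
#' @export
cnn_features <- function(model, X) {
  cpp_cnn_features(X, model$arch, model$params)
}

#' Bias adjustment: least-squares refit of the affine head
#'
#' Computes penultimate features for the whole training set and replaces
#' the final affine layer with the ordinary-least-squares solution from
#' features (plus intercept) to labels; falls back to a small ridge
#' penalty with a warning when the feature matrix is rank-deficient.  By
#' least-squares optimality this never increases the training MSE.
#'
#' @param model a `met_cnn`.
#' @param X `H x W x n` training array.
#' @param y training labels.
#' @param mode `"full"` (all head parameters) or `"intercept"` only.
#' @return the adjusted `met_cnn`.
#' @export
bias_adjust <- function(model, X, y, mode = c("full", "intercept")) {
  mode <- match.arg(mode)
  F <- cpp_cnn_features(X, model$arch, model$params)
  if (mode == "intercept") {
    head <- cpp_cnn_head(model$params, model$arch)
    pred <- drop(F %*% head$w) + head$b
    out <- cpp_cnn_set_head(model$params, model$arch, head$w,
                            head$b + mean(y - pred))
  } else {
    D <- cbind(F, 1)
    G <- crossprod(D)
    theta <- tryCatch(solve(G, crossprod(D, y)), error = function(e) {
      warning("rank-deficient feature matrix; ridge fallback used")
      lam <- 1e-6 * sum(diag(G)) / ncol(G)
      solve(G + lam * diag(ncol(G)), crossprod(D, y))
    })
    out <- cpp_cnn_set_head(model$params, model$arch,
                            theta[-length(theta)], theta[length(theta)])
  }
  model$params <- out$params
  model
}

#' Concordance correlation coefficient
#'
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments; 1 means perfect agreement.
#'
#' @param predictions,labels equal-length numeric vectors (n >= 2).
#' @return scalar CCC in `[-1, 1]`.
#' @export
ccc <- function(predictions, labels) {
  x <- predictions; y <- labels
  n <- length(x)
  if (n != length(y) || n < 2) stop("need equal lengths >= 2")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx + vy == 0) stop("CCC undefined for two constant inputs")
  2 * mean((x - mx) * (y - my)) / (vx + vy + (mx - my)^2)
}

#' Evaluate a fitted regressor on the validation split
#'
#' Per-sample squared errors on normalized labels, divided by the
#' population variance of the validation labels; reports their mean with a
#' normal-approximation 95% confidence interval, and the CCC between
#' predictions and labels.  Predicting the label mean for every sample
#' gives a normalized MSE of exactly 1 under this convention.
#'
#' @param model a `met_cnn`.
#' @param dataset the `patch_dataset` it was fit on.
#' @return an `eval_result`: `se_norm` (per-sample), `nmse`, `ci95`,
#'   `ccc`, `predictions`, `labels`, `val_idx`.
#' @export
evaluate <- function(model, dataset) {
  idx <- dataset$split$val
  if (length(idx) == 0) stop("empty validation split")
  y <- dataset$labels_norm[idx]
  v <- mean((y - mean(y))^2)
  if (v == 0) stop("zero label variance on the validation split")
  pred <- predict(model, dataset$patches[, , idx, drop = FALSE])
  se <- (pred - y)^2 / v
  nmse <- mean(se)
  half <- 1.96 * stats::sd(se) / sqrt(length(se))
  structure(list(se_norm = se, nmse = nmse,
                 ci95 = c(nmse - half, nmse + half),
                 ccc = ccc(pred, y),
                 predictions = pred, labels = y, val_idx = idx),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> NMSE %.3f [%.3f, %.3f], CCC %.3f (n = %d)\n",
              x$nmse, x$ci95[1], x$ci95[2], x$ccc, length(x$se_norm)))
  invisible(x)
}

#' Compare reconstruction kernels on paired validation errors
#'
#' Two-tailed paired t-test on the per-sample normalized squared errors of
#' the same validation lesions under the two kernels, plus the percent
#' difference of mean errors `(standard - high_frequency) / standard x
#' 100` (positive when the high-frequency kernel is better).  Identical
#' error vectors (zero-variance differences) are reported with `p = 1` and
#' a degenerate flag.
#'
#' @param eval_std,eval_hf `eval_result`s for the standard and
#'   high-frequency kernels on the same validation lesions.
#' @return a `kernel_comparison`: `t_stat`, `p_value`, `pct_diff`,
#'   `mean_std`, `mean_hf`, `degenerate`.
#' @export
compare_kernels <- function(eval_std, eval_hf) {
  a <- eval_std$se_norm
  b <- eval_hf$se_norm
  if (length(a) != length(b) ||
      !identical(eval_std$val_idx, eval_hf$val_idx))
    stop("evaluations are not paired on the same validation lesions")
  d <- a - b
  degenerate <- stats::sd(d) == 0
  if (degenerate) {
    t_stat <- NA_real_
    p <- 1
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(t_stat = t_stat, p_value = p,
                 pct_diff = (mean(a) - mean(b)) / mean(a) * 100,
                 mean_std = mean(a), mean_hf = mean(b),
                 degenerate = degenerate),
            class = "kernel_comparison")
}

#' @export
print.kernel_comparison <- function(x, ...) {
  cat(sprintf(paste0("<kernel_comparison> NMSE standard %.3f vs ",
                     "high-frequency %.3f (%+.1f%%), t = %s, p = %.4g%s\n"),
              x$mean_std, x$mean_hf, x$pct_diff,
              ifelse(is.na(x$t_stat), "NA", sprintf("%.2f", x$t_stat)),
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
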