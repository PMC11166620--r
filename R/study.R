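#' Configuration of a characterization study
#'
#' Bundles every knob of the end-to-end pipeline.  Two preset scales:
#'
#' * `"fast"` - the desk scale: 1,500 lesions on 2 synthetic backgrounds,
#'   patches reconstructed at 0.4 mm pixels, the reduced CNN
#'   ([cnn_arch_fast()]), 20 training epochs.
#' * `"paper"` - the reference scale: 10,000 lesions, 0.2 mm
#'   reconstruction pixels, the full CNN, 120 epochs.
#'
#' Any entry can be overridden through `...`.
#'
#' @param scale `"fast"` or `"paper"`.
#' @param ... overrides (e.g. `n_mets`, `epochs`, `recon_pixel_mm`).
#' @return a `study_config` list.
#' @export
study_config <- function(scale = c("fast", "paper"), ...) {
  scale <- match.arg(scale)
  base <- list(
    scale = scale,
    n_mets = if (scale == "paper") 10000L else 1500L,
    n_backgrounds = if (scale == "paper") 20L else 2L,
    mets_per_slice = 10:12,
    # 25.6 mm patches: 128 px at the 0.2 mm paper scale, 64 px at 0.4 mm
    patch_px = if (scale == "paper") 128L else 64L,
    recon_pixel_mm = if (scale == "paper") 0.2 else 0.4,
    met_grid_n = 256L,
    met_pixel_mm = 0.156,
    geometry = fan_geometry(),
    noise = noise_model(),
    arch = if (scale == "paper") cnn_arch(128L) else cnn_arch_fast(64L),
    epochs = if (scale == "paper") 120L else 20L,
    batch = 40L,
    lr = 4e-5,
    background = list()
  )
  utils::modifyList(base, list(...))
}

study_tags <- c("noiseless_noblur", "noiseless_blur",
                "noisy_noblur", "noisy_blur")

study_characteristics <- function(study) {
  if (grepl("noblur", study)) c("heterogeneity", "fractal_dim")
  else "edge_sharpness"
}

#' Simulate the noiseless scans of one study condition
#'
#' Runs the scan half of the pipeline: lesion generation, fractal
#' labeling, placement on synthetic backgrounds, separate high-resolution
#' reprojection of every lesion, and sinogram-domain superposition.  The
#' result is noise-free; noiseless and noisy studies at the same seed
#' share these scans exactly (noise is injected downstream).
#'
#' @param blur whether lesions receive a positive edge blur.
#' @param n_mets number of lesions (default from `config`).
#' @param config a [study_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @return a `study_scans` object: per-slice superposed sinograms and
#'   lesion centers, plus the ground-truth `labels` data frame.
#' @export
simulate_study_scans <- function(blur = FALSE, n_mets = NULL,
                                 config = study_config("fast"), seed = 1L) {
  if (is.null(n_mets)) n_mets <- config$n_mets
  geom <- config$geometry

  set.seed(derive_seed(seed, "phantom"))
  bgs <- lapply(seq_len(config$n_backgrounds),
                function(i) generate_background(config$background))
  bg_sinos <- lapply(bgs, function(bg)
    forward_project(hu_to_mu(bg$hu_image), bg$pixel_mm, geom))

  # assign lesions to slices (10-12 per slice)
  set.seed(derive_seed(seed, "slices"))
  counts <- integer(0)
  left <- n_mets
  while (left > 0) {
    k <- min(sample(config$mets_per_slice, 1), left)
    counts <- c(counts, k)
    left <- left - k
  }

  slices <- vector("list", length(counts))
  labels <- vector("list", n_mets)
  met_id <- 0L
  for (s in seq_along(counts)) {
    bg_i <- ((s - 1L) %% length(bgs)) + 1L
    set.seed(derive_seed(seed, paste0("place", s)))
    pm <- place_mets(bgs[[bg_i]], counts[s])
    met_sinos <- vector("list", counts[s])
    ids <- met_id + seq_len(counts[s])
    for (j in seq_len(counts[s])) {
      id <- ids[j]
      set.seed(derive_seed(seed, paste0("metspec", id)))
      spec <- sample_met_spec(blur = blur,
                              seed = derive_seed(seed, paste0("met", id)))
      met <- compose_met(spec, config$met_grid_n, config$met_pixel_mm)
      # lesion rasters are HU *offsets*: project the attenuation delta,
      # cropped to the lesion support (line integrals are unchanged)
      cr <- crop_to_support(0.0193 * met$hu_offset / 1000, met$pixel_mm)
      met_sinos[[j]] <- forward_project(cr$img, met$pixel_mm, geom,
                                        center_offset_mm =
                                          pm$centers_mm[j, ] + cr$shift_mm)
      labels[[id]] <- data.frame(
        met_id = id, slice = s,
        cx_mm = pm$centers_mm[j, 1], cy_mm = pm$centers_mm[j, 2],
        contrast_hu = spec$contrast_hu,
        insert_scale_hu = met$labels$heterogeneity,
        blur_sigma_mm = met$labels$edge_sharpness,
        fractal_dim = met$labels$fractal_dim,
        seed = spec$seed)
    }
    slices[[s]] <- list(sino = superpose(bg_sinos[[bg_i]], met_sinos),
                        centers_mm = pm$centers_mm, ids = ids)
    met_id <- met_id + counts[s]
  }
  structure(list(blur = blur, slices = slices,
                 labels = do.call(rbind, labels),
                 config = config, seed = seed),
            class = "study_scans")
}

#' @export
print.study_scans <- function(x, ...) {
  cat(sprintf("<study_scans> %d lesions on %d slices (%s)\n",
              nrow(x$labels), length(x$slices),
              if (x$blur) "blurred" else "no blur"))
  invisible(x)
}

#' Simulate the labeled patch datasets of one study
#'
#' Runs the physics half of the pipeline for one study condition: the
#' noiseless scans (or precomputed ones), Poisson noise for the noisy
#' studies, and patch reconstruction with both kernels.
#'
#' @param study one of `"noiseless_noblur"`, `"noiseless_blur"`,
#'   `"noisy_noblur"`, `"noisy_blur"`.
#' @param n_mets number of lesions (default from `config`).
#' @param config a [study_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @param scans optional [simulate_study_scans()] result to reuse (its
#'   blur setting must match the study tag).
#' @return a `study_patches` object: arrays `patches` (per kernel,
#'   `H x W x n` in HU) and the ground-truth `labels` data frame.
#' @export
simulate_study_patches <- function(study = study_tags, n_mets = NULL,
                                   config = study_config("fast"),
                                   seed = 1L, scans = NULL) {
  study <- match.arg(study)
  noisy <- grepl("noisy", study)
  blur <- grepl("_blur", study)
  if (is.null(scans)) {
    scans <- simulate_study_scans(blur, n_mets, config, seed)
  } else if (scans$blur != blur) {
    stop("precomputed scans have the wrong blur setting for this study")
  }
  config <- scans$config
  seed <- scans$seed
  n_mets <- nrow(scans$labels)

  kernels <- c("standard", "high_frequency")
  np <- config$patch_px
  patches <- lapply(kernels, function(k) array(0, c(np, np, n_mets)))
  names(patches) <- kernels
  for (s in seq_along(scans$slices)) {
    sl <- scans$slices[[s]]
    sino <- sl$sino
    if (noisy) {
      set.seed(derive_seed(seed, paste0("noise", s)))
      sino <- add_poisson_noise(sino, config$noise)
    }
    for (k in kernels) {
      pl <- reconstruct_patches(sino, k, sl$centers_mm,
                                pixel_mm = config$recon_pixel_mm,
                                size_px = np)
      for (j in seq_along(sl$ids))
        patches[[k]][, , sl$ids[j]] <- pl[[j]]$hu_image
    }
  }
  structure(list(study = study, patches = patches,
                 labels = scans$labels,
                 config = config, seed = seed),
            class = "study_patches")
}

#' @export
print.study_patches <- function(x, ...) {
  cat(sprintf("<study_patches> %s: %d lesions, %d slices, %dx%d px patches\n",
              x$study, nrow(x$labels), max(x$labels$slice),
              dim(x$patches[[1]])[1], dim(x$patches[[1]])[2]))
  invisible(x)
}

# crop a raster to the bounding box of its nonzero support (plus padding);
# shift_mm locates the cropped grid's center relative to the original center
crop_to_support <- function(img, pixel_mm, pad = 3L) {
  nz <- which(img != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(list(img = img, shift_mm = c(0, 0)))
  i1 <- max(1L, min(nz[, 1]) - pad); i2 <- min(nrow(img), max(nz[, 1]) + pad)
  j1 <- max(1L, min(nz[, 2]) - pad); j2 <- min(ncol(img), max(nz[, 2]) + pad)
  list(img = img[i1:i2, j1:j2, drop = FALSE],
       shift_mm = c((i1 + i2 - 1 - nrow(img)) / 2,
                    (j1 + j2 - 1 - ncol(img)) / 2) * pixel_mm)
}

label_column <- c(heterogeneity = "insert_scale_hu",
                  edge_sharpness = "blur_sigma_mm",
                  fractal_dim = "fractal_dim")

#' Run one characterization study end to end
#'
#' Full pipeline for one study condition: simulate (or reuse) the labeled
#' patch datasets, then for every characteristic of the study train one
#' regressor per kernel on a shared train/validation split, evaluate on
#' the validation lesions, and compare kernels with a paired t-test.
#' No-blur studies evaluate insert heterogeneity and edge fractal
#' dimension; blurred studies evaluate edge sharpness.
#'
#' @param study the study tag.
#' @param n_mets number of lesions (>= 100 recommended).
#' @param config a [study_config()].
#' @param seed master seed.
#' @param patches optional precomputed [simulate_study_patches()] result.
#' @param scans optional precomputed [simulate_study_scans()] result.
#' @param characteristics subset of the study's characteristics to train
#'   (default: all of them).
#' @return a `study_result`: per characteristic the two `eval_result`s and
#'   the `kernel_comparison`, plus a tidy summary `table`.
#' @export
run_study <- function(study = study_tags, n_mets = NULL,
                      config = study_config("fast"), seed = 1L,
                      patches = NULL, scans = NULL, characteristics = NULL) {
  study <- match.arg(study)
  if (is.null(patches))
    patches <- simulate_study_patches(study, n_mets, config, seed, scans)
  labs <- patches$labels
  chars <- study_characteristics(study)
  if (!is.null(characteristics)) {
    stopifnot(all(characteristics %in% chars))
    chars <- characteristics
  }
  tcfg <- train_config(lr = config$lr, batch = config$batch,
                       epochs = config$epochs)
  results <- list()
  rows <- list()
  for (ch in chars) {
    y <- labs[[label_column[[ch]]]]
    ds_std <- build_dataset(patches$patches$standard, y,
                            seed = derive_seed(seed, "split"))
    ds_hf <- build_dataset(patches$patches$high_frequency, y,
                           split = ds_std$split)
    fits <- list()
    evals <- list()
    for (k in c("standard", "high_frequency")) {
      ds <- if (k == "standard") ds_std else ds_hf
      fit <- met_cnn(ds, arch = config$arch, config = tcfg,
                     seed = derive_seed(seed, paste0("train_", ch, "_", k)))
      fits[[k]] <- fit
      evals[[k]] <- evaluate(fit, ds)
    }
    cmp <- compare_kernels(evals$standard, evals$high_frequency)
    results[[ch]] <- list(eval_std = evals$standard,
                          eval_hf = evals$high_frequency,
                          comparison = cmp)
    for (k in c("standard", "high_frequency")) {
      e <- evals[[k]]
      rows[[paste(ch, k)]] <- data.frame(
        study = study, characteristic = ch, kernel = k,
        n_val = length(e$se_norm), mean_nmse = e$nmse,
        ci95_lo = e$ci95[1], ci95_hi = e$ci95[2], ccc = e$ccc,
        t_stat = cmp$t_stat, p_value = cmp$p_value,
        pct_diff = cmp$pct_diff)
    }
  }
  structure(list(study = study, results = results,
                 table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 n_mets = nrow(labs), seed = seed, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s (%d lesions)\n", x$study, x$n_mets))
  print(x$table, digits = 3)
  invisible(x)
}

#' Actual-vs-predicted scatter plots of a study
#'
#' One panel per characteristic and kernel, on normalized labels, with the
#' identity line and the CCC in the panel title.
#'
#' @param x a `study_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.study_result <- function(x, ...) {
  chars <- names(x$results)
  old <- graphics::par(mfrow = c(length(chars), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chars) {
    for (k in c("eval_std", "eval_hf")) {
      e <- x$results[[ch]][[k]]
      graphics::plot(e$labels, e$predictions, xlim = c(0, 1), ylim = c(0, 1),
                     xlab = "actual", ylab = "predicted",
                     main = sprintf("%s / %s (CCC %.2f)", ch,
                                    ifelse(k == "eval_std", "standard",
                                           "high-frequency"), e$ccc), ...)
      graphics::abline(0, 1, col = "grey")
    }
  }
  invisible(x)
}

#' Write the study summary table as CSV
#' @param result a `study_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}

#' Write the ground-truth label table of simulated lesions as CSV
#' @param patches a `study_patches`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(patches, path) {
  cols <- c("met_id", "contrast_hu", "insert_scale_hu", "blur_sigma_mm",
            "fractal_dim", "seed")
  utils::write.csv(patches$labels[cols], path, row.names = FALSE)
  invisible(path)
}
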