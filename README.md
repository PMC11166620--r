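# livermetsim

A virtual CT imaging trial for liver-metastasis characterization, in R.

CT texture and edge features of colorectal liver metastases are candidate
prognostic markers, but whether they survive the imaging chain depends on
the reconstruction kernel: smooth ("standard") kernels suppress noise *and*
high-frequency detail, while high-frequency ("edge") kernels preserve more
sinogram information at the cost of noisier images. Real lesions come with
no ground truth, so this package builds the whole experiment in silico:

1. **Fractal lesion generator** — random shapes grown from a hexagon by
   midpoint-displacement subdivision (vertex count 6·2^k), smoothed by a
   circular moving average, with 2–3 nested "insert" sub-shapes. Every
   lesion carries exact labels: insert heterogeneity (0–80 HU), edge
   sharpness (Gaussian blur 0–1.5 mm) and edge fractal dimension.
2. **Fractal measurement** — edge detection and box counting
   (r ∈ {1, 2, 4, 8, 16, 32} px) with the dimension from the least-squares
   slope of log N(r) on −log r.
3. **Scanner** — monoenergetic 2D equiangular fan-beam projector
   (984 views, 888 cells, 1.0239 mm pitch, SID 538.52 mm, SDD 946.75 mm);
   lesions are reprojected at 0.156 mm and superposed on synthetic
   liver-bearing backgrounds *in the sinogram domain*; Poisson noise at a
   calibrated 600 mAs operating point (≈48 dB liver SNR).
4. **Reconstruction** — fan-beam filtered back projection with two
   parameterized apodized-ramp kernels (`standard`, `high_frequency`) and
   128×128-equivalent lesion patches (25.6 mm).
5. **Deep characterization** — a compact pre-activation residual CNN
   (RcppArmadillo; Adam, lr 4e-5, MSE, batch 40, eight-fold dihedral
   augmentation) with a per-epoch "bias adjustment" that refits the affine
   head by least squares; recovery scored by variance-normalized squared
   error, concordance correlation (CCC) and paired two-tailed t-tests
   between kernels.

## Worked example

```r
library(livermetsim)

# one lesion with known ground truth
set.seed(1)
spec <- sample_met_spec(blur = FALSE, seed = 7L)
met  <- compose_met(spec)
met
#> <met_image> 256x256 @ 0.156 mm | heterogeneity 29.8 HU, blur 0.00 mm,
#>   fractal dim 0.938

# a tiny end-to-end study (12 lesions, 1 epoch — a smoke run)
cfg <- study_config("fast", n_mets = 12L, n_backgrounds = 1L, epochs = 1L,
                    batch = 16L)
res <- run_study("noiseless_noblur", config = cfg, seed = 2L)
res
#> <study_result> noiseless_noblur (12 lesions)
#>              study characteristic         kernel n_val mean_nmse   ccc pct_diff
#> 1 noiseless_noblur  heterogeneity       standard     2     0.427 0.622     5.72
#> 2 noiseless_noblur  heterogeneity high_frequency     2     0.403 0.737     5.72
#> 3 noiseless_noblur    fractal_dim       standard     2     0.279 0.800  -460.18
#> 4 noiseless_noblur    fractal_dim high_frequency     2     1.561 0.473  -460.18
```

(At this smoke scale a ridge-fallback warning from the head refit and wild
`pct_diff` values on a 2-lesion validation split are expected; the real
checks run 150 lesions per study.)

`mean_nmse` is the mean validation squared error divided by the label
variance (1.0 = no better than predicting the mean), `ccc` the agreement
between predictions and truth, and `pct_diff` the percent error reduction
of the high-frequency kernel over the standard one; at smoke scale these
numbers are noisy — the desk scale used for real checks is 150 lesions
and 4 epochs per study (see the methods vignette).

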