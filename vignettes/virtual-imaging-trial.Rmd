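---
title: "A virtual CT imaging trial for liver-metastasis characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual CT imaging trial for liver-metastasis characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(livermetsim)
```

## The question the pipeline answers

Colorectal liver metastases are routinely monitored with CT, and image
texture, edge character and lesion heterogeneity are candidate prognostic
features.  Whether those features survive the imaging chain depends
strongly on the reconstruction kernel: a smooth ("standard") kernel
suppresses noise but also the high spatial frequencies that carry edge
detail, while a high-frequency ("edge") kernel preserves more of the raw
sinogram information at the price of noisier-looking images.

Because no clinical dataset comes with *known* lesion characteristics,
the package builds a virtual imaging trial: lesions are synthesized with
exactly known ground truth, inserted into a liver-bearing background,
scanned and reconstructed with both kernels, and a convolutional
regressor is trained to recover each characteristic from the
reconstructed patches.  The quality of recovery, compared across
kernels and noise conditions, quantifies what the imaging chain
preserves.

Three characteristics are crafted into every lesion:

* **insert heterogeneity** — the maximum HU offset of nested internal
  sub-shapes (0–80 HU);
* **edge sharpness** — the width of the Gaussian blur applied to the
  lesion before scanning (0–1.5 mm; 0 in the "no-blur" studies);
* **edge fractal dimension** — the box-counting dimension of the binary
  outline, measured on a 256 × 256 bitmap with box sizes 1–32 px.

## Lesion synthesis

Shapes grow from six vertices of a jittered hexagon.  Each subdivision
pass inserts every edge's midpoint, displaced along the local edge
normal by `U(-roughness * L, +roughness * L)` where `L` is the edge
length; the vertex count doubles per pass and subdivision stops when
adjacent vertices are closer than the 0.156 mm raster pixel.  Normal-
direction displacement (rather than isotropic) is chosen because it
cannot scramble the vertex ordering.  A circular moving average over the
vertex list (window up to half the vertex count) then smooths the
outline; longer windows lower the measured fractal dimension, which is
what makes the fractal label controllable.

Choices the literature leaves open, fixed here once:

* `roughness ~ U(0.05, 0.33)`.  The upper bound is the largest value at
  which deep subdivisions reliably avoid self-intersection under
  normal-direction displacement: at 0.40 + the outline folds in
  essentially every draw regardless of rejection budget, because a
  displacement approaching half the edge length routinely crosses the
  neighboring edge.  Rejection operates per subdivision level (a folded
  level is redrawn up to 10 times) with whole-shape restarts as a
  backstop.
* initial hexagon irregularity 0.15; circumradius `U(4, 10)` mm so a
  lesion fits a 25 mm patch with margin.
* inserts: 2–3 sub-shapes seeded from the parent's second subdivision
  generation, rescaled by `U(0.25, 0.6)` about a random interior point,
  evolved independently, and clipped to the parent support at the
  raster stage.  The summed sub-shape indicators are rescaled so the
  deepest insert point sits exactly `insert_scale_hu` below the lesion
  base.  Inserts *deepen* the hypodensity: the lesion HU offset stays in
  `[contrast - insert_scale, contrast] <= 0`, so a lesion can never turn
  hyperdense relative to liver.  (The alternative convention — inserts
  pushing toward 0 HU — can produce +60 HU lesions from a −20 HU base
  with an 80 HU insert, which contradicts both the hypodense character
  of these lesions and the intended HU range.)

The fractal label is measured on the *unblurred* binary raster: edge
extraction (4-connectivity inner boundary), box counts `N(r)` for
`r = 1, 2, 4, 8, 16, 32` on grids anchored at the raster origin, and an
ordinary least-squares fit of `log N(r)` against `-log r` whose slope is
`D_f`.  Natural logarithms are used throughout; the slope is
base-invariant, the intercept is not.

## Backgrounds

The clinical slices behind the original study are private, so the
package generates a parametric surrogate: an elliptical soft-tissue body
(35 HU) with air at exactly −1000 HU outside, a liver-like ellipse
(base 50 HU, axes 100 × 75 mm — a clinical-scale cross-section, large
enough to host 10–12 disjoint 25 mm exclusion squares), correlated lumpy
texture (Gaussian random field, Gaussian correlation with 4 mm length,
7 HU standard deviation), and a few bright vessel cross-sections that
are excluded (with a 2 mm margin) from the insertable mask.  The mask is
additionally eroded 3 mm from the liver boundary.  Real HU rasters with
masks can be substituted anywhere a `ct_background` is accepted; the
surrogate reproduces liver-like first- and second-order HU statistics
but none of the anatomy, so conclusions about *relative* kernel behavior
transfer more safely than absolute accuracies.

## Scan and reconstruction

The scanner is a monoenergetic 2D equiangular fan-beam system with the
geometry of a clinical multislice scanner: 984 views over 360°, 888
cells of 1.0239 mm pitch, source–isocenter 538.52 mm, source–detector
946.75 mm.  Attenuation is `mu = mu_water (1 + HU/1000)` with
`mu_water = 0.0193 mm^-1` (≈70 keV effective, the monoenergetic stand-in
for a 140 kVp beam); polychromatic effects, bowtie filtration and
scatter are out of scope.  Line integrals are computed by ray-driven
bilinear interpolation at half-pixel steps — that sampling rule is part
of the projector's definition.  Conventions are fixed: view 1 has the
source at 12 o'clock, the gantry rotates counterclockwise, detector cell
1 sits at the negative-angle fan edge, no quarter-detector offset.

Lesions are rasterized at 0.156 mm and reprojected *separately* from the
background (at its own 0.75 mm resolution); sinograms are summed, which
is exact for additive attenuation and never resamples either image.
Poisson noise, when enabled, is injected once into the superposed
sinogram: counts `~ Poisson(N0 exp(-p))` with a 0.5-count floor before
the log.  `N0 = n0_ref × mAs`; `n0_ref = 23,000` photons/ray/mAs was
calibrated once so that a 600 mAs scan reconstructed with the standard
kernel gives a liver-region SNR of ≈48 dB
(`20 log10(mean(HU + 1000)/sd(HU))`), the operating point of a clinical
abdominal protocol.  The SNR estimator itself is a package definition;
published SNR figures depend on an unstated estimator and are matched in
regime, not digit-for-digit.

Reconstruction is equiangular fan-beam FBP: cosine pre-weighting,
per-view frequency-domain filtering (FFT zero-padded to twice the next
power of two), and 1/L²-weighted backprojection.  The two proprietary
product kernels are represented by documented parametric surrogates on
normalized frequency `nu = f / f_Nyquist`:

* `standard`: ramp × cosine taper rolling off to zero at `0.9 nu`;
* `high_frequency`: ramp × a mild boost (peak 1.4× at `nu = 0.7`,
  returning to 1 at DC and Nyquist), full support to Nyquist.

By construction the high-frequency response dominates the standard one
for `nu >= 0.5`.  The surrogates reproduce the qualitative shapes of the
commercial kernels, not their exact responses (which are not public).
Verified behavior: a 50 mm water disc round-trips to within ±10 HU in
its core; the high-frequency kernel yields a strictly narrower 10–90%
edge-spread width and strictly larger flat-region noise than the
standard kernel.

The filter's `|H|` is tabulated as exactly `nu × A(nu)` on the FFT grid
(so the pure ramp is exactly `|f|`); the DC bin is forced to zero.

## Deep characterization

Patches are 25.6 mm squares centered on each lesion: 128 px at the
0.2 mm reference scale, 64 px at the 0.4 mm desk scale.  Patch images
are z-scored with constants from the training split; labels are min-max
normalized to [0, 1] on the training split.  The split is 90/10 by
lesion, shared between kernels so that validation lesions pair exactly.
Training patches are expanded eight-fold with the full dihedral group
(4 right-angle rotations × 2 reflections) — the deterministic expansion
realizes the stated eight-fold factor without duplicate-prone random
draws.

The regressor is a compact pre-activation residual CNN (stem convolution
→ residual blocks of ReLU–conv3×3–ReLU–conv3×3 with identity or
1×1-projection skips → ReLU → global average pooling → affine head),
implemented in RcppArmadillo with float32 arithmetic.  The reference
configuration has 4 blocks of widths 16/32/64/64; the desk-scale variant
has 3 blocks of widths 12/24/32.  Training uses Adam (learning rate
4 × 10⁻⁵), MSE loss, batch 40.  After every epoch a *bias adjustment*
refits the entire affine head by ordinary least squares on the
penultimate features of the whole training set (solved in double
precision; ridge fallback `lambda = 1e-6 × trace/dim` with a warning if
the normal equations are singular).  Refitting all head parameters, not
only the intercept, is the chosen reading of "the parameters of the
final dense layer were adjusted"; a flag restricts it to the intercept.
The refit is a projection, so it can never increase training MSE — a
property the tests assert.  Gradient correctness is verified against
finite differences (float32 limits agreement to a few percent at
`eps = 1e-3`).

Evaluation reports per-sample squared errors on normalized labels
divided by the population variance of the validation labels (so the
constant mean predictor scores exactly 1), their mean with a normal-
approximation 95% CI, and the concordance correlation coefficient with
population moments.  Kernels are compared by a two-tailed paired t-test
on the per-lesion squared errors — pairing is exact because both
reconstructions come from the same sinogram.  Noiseless-vs-noisy
comparisons use the NMSE directly (different noise realizations are
different datasets).

## Study conditions and problem sizes

Four studies mirror the reference protocol: noiseless/no-blur and
noisy/no-blur (evaluating heterogeneity and fractal dimension) and
noiseless/blurred and noisy/blurred (evaluating edge sharpness), with
10–12 lesions per slice and noise at 600 mA × 1 s.  The reference scale
is 10,000 lesions per study, 120 epochs, 0.2 mm reconstruction; that
configuration is available (`study_config("paper")`) but takes days of
desktop CPU.

The package's desk scale, used by the test suite and the acceptance
script, is: **150 lesions per study, one synthetic background, 0.4 mm
reconstruction pixels with 64 px patches, the 3-block CNN, 8 epochs, 3
pipeline seeds** for the kernel-ordering check and one seed for the
noise-degradation check.  At this scale the large effects (noise
degradation of edge sharpness, heterogeneity recoverability, the kernel
noise/resolution trade-off, non-significance of the kernel difference
under noise) reproduce stably, while the *small* kernel-ordering
effects (≈8–12% squared-error differences at full scale) sit at or
below the resolution limit of a 15-lesion validation split: the
sharpness ordering reproduces as a majority over seeds, whereas the
fractal-dimension ordering does not reproduce at this scale — the
under-trained head overfits the high-frequency kernel's aliasing noise,
and the corresponding check is expected to fail until the study is
re-run nearer the reference scale.  The same checks re-run at larger
`n_mets` and `epochs` without code changes.

## Numerical choices and degenerate inputs

* Rasterization: pixel-center-in-polygon, even-odd rule, scanline
  implementation; 256 is divisible by every box scale, so no partial
  boxes arise at the default size (partial border boxes count when
  occupied otherwise).
* Box grids are anchored at the raster origin; no grid-offset averaging.
* Backprojection interpolates linearly between detector cells and
  evaluates the fan angle with a polynomial arctangent (max error
  ~1e-6 rad ≈ 1e-3 detector cells, far below interpolation error);
  identical inputs give bit-identical reconstructions.
* Zero-length edges in subdivision keep unperturbed midpoints; an empty
  edge set, a constant label vector, a single box scale, unpaired
  evaluations, or an over-small liver mask raise errors rather than
  degrade silently (placement failures report how many lesions fit).
* Every stage derives its RNG seed from the master seed and a stage
  name, so studies are reproducible end to end and noiseless/noisy
  twins at the same seed share their scans exactly.

## Known limitations

* Monoenergetic physics; no scatter, bowtie, focal-spot blur or
  detector crosstalk.
* Kernel surrogates are qualitative stand-ins for proprietary
  responses.
* The synthetic background carries liver-like statistics, not anatomy.
* 2D axial slices only; no 3D lesions or growth dynamics.
* Desk-scale kernel-ordering results are directional (see above);
  absolute error levels depend on training scale and are far from the
  converged full-scale regime.
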