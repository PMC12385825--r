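---
title: "Methods: GAF encoding, CARS selection and the dual-input SE network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GAF encoding, CARS selection and the dual-input SE network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
what is computed, which parameters matter, what the synthetic data generator
does and does not emulate, and where genuinely open design choices were
resolved.

## The classification problem

Transmittance VIS–NIR spectroscopy of large fruit yields weak, noisy
one-dimensional signals: light traverses the whole fruit, so cultivar
differences (rind/flesh density, composition) appear as small, correlated
changes across many wavelengths, buried under large sample-to-sample
brightness variation. Direct one-dimensional classifiers must untangle that;
the approach here instead re-expresses each spectrum as two-dimensional
Gramian Angular Field images, in which every pixel couples a *pair* of
wavelengths, and lets a convolutional network exploit the resulting texture.

## GAF encoding

Each spectrum is min–max normalized to `[0, 1]` — this deliberately discards
per-sample brightness and offset, so image models see spectral *shape* only
— then angles `α_i = arccos(x̃_i)` define

* GASF `= cos(α_m + α_k)`: symmetric; its diagonal is `2 x̃_i² − 1`;
* GADF `= sin(α_m − α_k)`: antisymmetric with zero diagonal.

The first wavelength occupies the top-left matrix corner and the matrices
are rendered row-1-at-top, so wavelength order is preserved visually. The
radius `r_i = i/n` is computed and exposed for polar plots but does not
enter the matrices.

Rendering maps matrix values linearly from `[-1, 1]` through a fixed
perceptual colormap (default `"viridis"` via `grDevices::hcl.colors`, 256
levels) to 8-bit RGB. When the matrix size differs from the configured image
size (default 300 pixels; reduced grids after wavelength selection are
*upsampled* to the same size so one network input shape serves both
variants), the matrix is resampled **bilinearly before colormapping**, with
exact corner alignment so a same-size resize is the identity. Interpolating
the matrix rather than the colored pixels avoids palette-mixing artifacts
and keeps the operation deterministic. No source names the colormap or
interpolation used originally; both are explicit configuration here and are
recorded in the image metadata and run manifest.

Degenerate inputs are errors, not silent results: constant spectra (zero
normalization range), values outside `[0, 1]` at the polar stage (beyond a
1e-12 numerical tolerance, which is clamped), and matrix entries outside
`[-1, 1]` beyond 1e-9.

## Synthetic cohorts

No measured spectra ship with the package; `generate_cohort()` produces the
study conditions instead. Each spectrum is

    brightness × (baseline(λ) + p₁(λ) + h₂ · p₂(λ)) + noise,

with Gaussian transmission peaks `p₁, p₂` centred at 715 and 800 nm (SD 30
and 45 nm) on a slowly varying baseline, on the 630–1000 nm / 501-point
grid. Class structure enters twice:

* **brightness**: class 2 is on average `class_intensity_ratio = 1.3` times
  brighter (class 1 dimmer), with log-normal within-class spread
  `within_class_cv = 0.2` — the kind of overall-intensity separation with
  heavy overlap that makes single-wavelength thresholding unreliable;
* **shape**: the relative height of the 800 nm peak differs slightly by
  class (`peak_height_ratio = 0.84` vs `0.96`, within-class SD 0.02), so
  models that only see the normalized shape (the GAF pipeline) still have
  signal.

Additive Gaussian noise has SD `noise_sd = 0.02` of the base intensity, and
values are floored at a small positive detector level so both the
absorbance logarithm and the min–max normalization are well defined. An
optional set of `informative_band_indices` multiplies class-2 values at
those wavelengths only — used to test that CARS recovers planted signal.

The defaults were calibrated once, as part of the generator's design, to the
prescribed study conditions: PLS-DA separates the classes at ≥ 95 % while
the best single-wavelength threshold stays below ~90 %, echoing the
observation that univariate intensities cannot separate the cultivars but
multivariate models can. What the generator does **not** emulate: realistic
radiative transfer, wavelength-correlated noise, instrument drift,
absorption-band chemistry, or any relation between brightness and fruit
size. Passing tests therefore demonstrate that the pipeline's mechanics are
correct and that it can exploit shape signal under brightness nuisance; they
say nothing about accuracy on real fruit.

## Kennard–Stone splitting

The 3:1 calibration:prediction split is deterministic max–min selection on
Euclidean distances between raw intensity vectors, applied within each
class (per-class application is inferred from the reference counts
163 → 122 + 41 and 160 → 120 + 40, which match `floor(3n/4)` exactly).
Whether distances should be computed on raw or normalized spectra is not
specified anywhere; raw intensity was chosen and logged. Distance ties break
toward sample order, making the split reproducible without a seed.

## CARS wavelength selection

`cars_select` regresses the class as a 0/1 dummy (standard PLS-DA coding)
with an in-package SIMPLS kernel (cross-checked against mixOmics in the test
suite). Per Monte-Carlo run it: (1) fits PLS on a random 80 % of the
calibration samples over the surviving wavelengths; (2) retains the top
fraction of wavelengths by `|coefficient|` following the exponentially
decreasing schedule `exp(−k(i−1))` with `k = log(p/2)/(N−1)`, so run 1
retains all `p` wavelengths and run `N` retains 2; (3) resamples
competitively (weighted, with replacement, deduplicated) among the
survivors; (4) records the cross-validated RMSE of the current subset. The
subset at the RMSECV minimum wins.

Deliberate details: one CV fold partition is drawn per call and reused for
every run, so the argmin comparison (and the guarantee that the selected
subset's RMSECV is ≤ the full grid's) is like-for-like; run 1 skips the
competitive resampling so the full grid is genuinely evaluated; the final
subset size is floored at 2 when deduplication would go below it; ties in
`|coefficient|` at the retention cutoff break toward the lower wavelength
index. Defaults (`n_mc_runs = 50`, `cv_folds = 5`, `max_pls_components =
10`, 80 % sampling) are conventional values — none are stated in the source
material — and all are configuration-exposed and logged. The selected subset
size is data-driven; the reference outcome of 84 of 501 wavelengths (16.8 %)
is a property of the original measured data and is used here only as
structural arithmetic.

## Network architecture and training

The image branch follows the published layer table exactly: Conv1–2 (8
channels), pool, Conv3–4 (16), pool, Conv5–7 (32), pool; all convolutions
3×3, stride 1, ReLU; pooling 2×2 stride 2; an SE block (global average
pool → fc → ReLU → fc → sigmoid, weights multiplied back onto the channels)
after Conv7. Standalone single-input networks end in fc1/fc2 with 2 nodes;
fusion branches use 100-node fc1/fc2, and the fused head is fc3 (100, ReLU,
dropout 0.1) and fc4 (2, softmax). Training follows the stated protocol:
Adam, learning rate 0.001, batch size 10, cross-entropy; the reference
epoch count is 100.

Choices the sources leave open, resolved here and visible in
`architecture_table()` / the run manifest:

* **Fusion point.** The text describes fusing the branch outputs after the
  single-input networks, while the fusion figure draws channel-wise map
  concatenation. The package concatenates the two branch fc2 vectors
  (100 + 100 = 200) before fc3 — the only reading under which the published
  node counts balance. Channel-wise concatenation remains a documented
  alternative, not implemented.
* **Padding.** Convolutions are size-preserving ("same"), so pooling alone
  halves dimensions: 300 → 150 → 75 → 37 (floor). The flattened post-SE maps
  feed fc1.
* **SE reduction.** Default 4 (32 → 8 → 32); no value is published.
* **Initialisation.** Kaiming-uniform fan-in with a logged seed; biases 0.
* **1-D CNN baseline.** The cited structure is not reprinted in the source;
  the package defines a mirrored 1-D stack (conv-pool blocks of 8/16/32
  channels, kernel 3, ReLU, fc 100 → 2 softmax, per-wavelength
  standardisation learned on the calibration set) and labels it a
  "Tian-style" analogue rather than claiming equivalence.
* **Dropout** is active only between fc3 and fc4 of the fused head,
  matching the layer table.

Determinism: building and training are reproducible bit-for-bit for fixed
seeds within one runtime configuration (BLAS/compiler); the loss history is
recorded on the model object.

The convolution kernels (im2col/GEMM, max pooling) are implemented in
C++/Armadillo; all gradients are verified against central-difference
numerical differentiation in the development process and the engine is
exercised end-to-end in the test suite.

## Evaluation conventions

Class 1 (the seedless cultivar in the motivating study) is the positive
class: TP/TN are correct class-1/class-2 predictions, FP is class 2
predicted class 1, FN is class 1 predicted class 2 — the standard 2×2
layout. The source's verbal glosses of FP and FN are internally inconsistent
with that layout (they describe FN as seeded-classified-as-seedless); the
package adopts the standard convention, under which the published formulas
are the usual accuracy/precision/recall/F1 definitions. Zero-denominator
ratios are returned as `NaN` with a warning rather than silently dropped.

## Interpretation tools

* **PCA** uses `stats::prcomp`; the first two score columns plus
  explained-variance fractions are returned.
* **t-SNE** is an exact O(n²) implementation (per-point bandwidths by
  bisection to the target perplexity, Student-t output kernel, momentum
  gradient descent with early exaggeration), appropriate for cohort-sized
  n; defaults are perplexity 30 (clamped to `(n−1)/3`), 500 iterations, and
  a seeded initialisation. No t-SNE package is a dependency.
* **Wavelength attribution** is a permutation-sampling Shapley estimate:
  each random feature permutation walks from one randomly drawn background
  spectrum to the explained spectrum, crediting each wavelength with its
  marginal output change. Pairing each permutation with a single background
  makes per-sample attributions exactly additive (they sum to `f(x)` minus
  the mean output over drawn backgrounds), which the tests assert. The
  profile reported is the global mean absolute attribution, with a default
  background of calibration spectra and a seeded, fixed number of
  permutations.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen for a single-CPU
desktop run: the end-to-end check trains the dual-input network on the
default synthetic cohort (100 spectra per class, CARS-selected subset,
96 × 96 images, 30 epochs — a few minutes), and unit tests use reduced grids
(16–64 points or pixels) with few epochs. The full-size 300 × 300
architecture is built and structurally verified, but trained networks in the
tests use the reduced image size; nothing in the implementation is specific
to either size.

## Known limitations

* The CNN engine is CPU-only and single-image-at-a-time; it is sized for
  cohort-scale experiments, not large-scale training.
* SVM class probabilities are a logistic transform of the decision value
  (monotone, not calibrated); PLS-DA pseudo-probabilities are clipped latent
  scores. Hard labels, the quantity evaluated throughout, are unaffected.
* CARS subset sizes shrink faster than the retention schedule alone implies
  (deduplication in the competitive resampling), so late runs explore very
  small subsets; the RMSECV argmin in practice lands on moderate sizes.
* Synthetic cohorts are a mechanism testbed, not a fruit simulator; see the
  generator section for what they do not model.
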