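---
title: "Methods: texture features, subset selection, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture features, subset selection, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radiotex)
```

# Scope and assumptions

`radiotex` analyzes a single 2D grayscale slice per subject with a binary
tumor mask — the "maximal-diameter slice" convention of small-animal MRI
studies. It assumes the mask is given (drawn upstream), contains at least 16
foreground pixels, and that any nonzero mask value is foreground. There is no
3D handling, registration, or bias-field correction; intensities are only
assumed finite, since the first preprocessing step removes their scale.

# Preprocessing

`normalize_roi()` min–max maps the *masked* intensities to [0, 1] per
subject; pixels outside the mask are set to 0 and never enter any statistic.
Per-subject min–max is one of two defensible readings of "scaled to the same
range" (the other being cohort-wide standardization); it was chosen because
it makes each subject self-contained and every downstream matrix feature
invariant to positive affine transforms of the scanner output — a property
the test suite checks end to end. A constant masked region maps to zeros
with a warning rather than an error, so degenerate phantoms still flow
through the pipeline.

`quantize()` bins [0, 1] into `n_levels` equal-width gray levels (value 1.0
goes to the top level; masked pixels take levels 1..L, outside pixels level
0). The default `n_levels = 32` balances two failure modes: many more levels
leave co-occurrence matrices of a ~1000-pixel ROI nearly empty; many fewer
destroy texture contrast. It is exposed everywhere as a configuration knob.

# Derived images

* **Gradient** — 3×3 Sobel operators with reflect padding;
  magnitude √(Gx²+Gy²). The mask is eroded by one pixel so no retained
  stencil crosses the ROI boundary (erosion below 16 pixels is an error).
* **Haar sub-bands** — one level of the 2D orthonormal Haar transform: for
  each 2×2 block (a b / c d), approximate (a+b+c+d)/2, horizontal
  (a+b−c−d)/2, vertical (a−b+c−d)/2, diagonal (a−b−c+d)/2. The 1/2 factor
  makes the transform orthonormal, so band energies sum exactly to the input
  energy and the inverse transform (`haar_idwt()`) reconstructs the padded
  input to machine precision — both are property-tested on random odd- and
  even-sized images. Odd dimensions are edge-replicated to even. Band masks
  are the 2×2 logical-OR downsample by default (keeps boundary texture); an
  AND rule is available. Which detail band is "horizontal" versus "vertical"
  is a convention; the one above (horizontal = responds to horizontal edges)
  is documented rather than derivable.
* **Orientation histogram** — one global 9-bin histogram of unsigned Sobel
  gradient orientations (bin centers 10°…170°), magnitude-weighted with
  linear vote splitting that wraps across 0°/180°. A gradient at exactly 0°
  therefore splits evenly between the 10° and 170° bins. An all-zero
  gradient field yields the uniform histogram with a warning. There are no
  cells or blocks: the descriptor is "first-order statistics of a single
  orientation histogram", not a dense detector-style HoG.

# The 152-feature inventory

The inventory (names, order, count) is frozen and exported by
`feature_inventory()`. Its structure — seven families, gradient and wavelet
filters, power + FoS + GLCM + GLRM per wavelet band, FoS of the orientation
histogram — fixes the total at

$$7\,|\mathrm{FoS}| + 6\,|\mathrm{GLCM}| + 6\,|\mathrm{GLRM}| +
|\mathrm{LBP}| + |\mathrm{FA}| + |\mathrm{shape}| + 4 = 28 + 36 + 66 + 10 + 2 + 6 + 4 = 152$$

(FoS appears on 7 sources, GLCM/GLRM on 6, plus one power feature per
wavelet band) once the family sizes are FoS = 4 {mean, variance, skewness, entropy},
GLCM = 6 {contrast, correlation, energy, homogeneity, entropy,
dissimilarity}, GLRM = 11 (the standard run-emphasis set), LBP = 10
(rotation-invariant uniform, P = 8, R = 1), fractal = 2, shape = 6, wavelet
power = 1 per band. These are the unique small family sizes consistent with
that structure, and they contain every individually named feature the
analyses downstream refer to (e.g. `grad.glrm.lre`, `wav_d.fos.mean`,
`wav_v.glrm.lgre`, `hog.fos.entropy`, `wav_a.glrm.sre`). **The inventory is
a reconstruction**: the total and the family structure are given, the exact
breakdown is not, and this package's breakdown is one consistent solution.

Numerical conventions: population variance (divisor n); Fisher skewness
m₃/m₂^1.5 with 0 for constant input; all entropies in bits with
0·log 0 := 0; FoS entropy uses a 32-bin histogram over the observed min–max
(constant input has entropy 0). Base-image FoS is computed on the **raw**
intensities — mean and variance deliberately keep the scanner scale, and are
the only two features not invariant to affine intensity rescaling. GLCM and
GLRM are averaged over the four directions (the dominant radiomics
convention; per-direction values are not exposed). "Power" of a wavelet band
is the mean squared coefficient over the band mask (mean-square rather than
sum-of-squares, so it does not grow with ROI area). Each derived image
(gradient, each band) is independently re-normalized and re-quantized before
matrix features, so detail bands — signed and near-zero-mean — populate all
gray levels.

Fractal features binarize the normalized ROI at its Otsu threshold
(computed internally on a 256-bin histogram), then: box-counting dimension
as the least-squares slope of log N(s) versus log(1/s) over dyadic box sizes
spanning the pattern's bounding box, and lacunarity as the gliding-box
statistic var(mass)/mean(mass)² + 1 at box size 4 px. Fewer than 2 occupied
pixels after binarization yields (0, 0) with a warning. Shape features use
the largest 4-connected component; the perimeter counts exposed pixel edges,
and solidity takes the convex hull over pixel *corners* so a filled
rectangle scores exactly 1.

# Feature reduction

`correlation_filter()` greedily removes one feature at a time: while any
pair exceeds the threshold (default 0.50) in |Pearson r|, the member of the
currently-worst pair with the larger mean absolute correlation to the
remaining features is dropped (ties drop the later feature in canonical
order). Absolute correlation governs removal because an anti-correlated
duplicate is exactly as redundant as a correlated one. Constant columns are
removed first with a warning. The procedure is deterministic given column
order, invariant to row permutation, and audited: the report lists every
dropped feature with its partner and r value.

A consequence worth knowing: this standard rule preferentially removes
*hub* features — the ones most correlated with everything else, which in a
texture-dominated table are often the strongest single discriminators. The
survivor of a tight informative cluster is its most idiosyncratic member.
See "Known limitations".

# Subset selection

`exhaustive_search()` scores every size-k subset (k = 1, 2, …) by
leave-one-out accuracy: for each held-out subject, columns are standardized
with the *remaining* subjects' mean/SD (the scaler never sees the held-out
subject — checked by an outlier-leakage test), an RBF SVM is fit on the
remainder, and the held-out subject is predicted. The search stops when the
best accuracy improves by no more than `tol = 1e-3` over the previous size
(with best(0) := 0, so k = 1 is always evaluated) or at `max_k` (default 5);
ties go to the lexicographically first subset in canonical column order.
A guard aborts searches beyond 10⁷ subset evaluations unless forced.

The classifier knobs are reconstructions, since only "kernel-based" is
given: RBF kernel, C = 1, γ = 1/(k · pooled variance of the standardized
training subset) — which is 1/k when standardization is on — all exposed in
`selection_config()`. Accuracy is the only score (no AUC), and the reported
accuracy is leave-one-out, the honest reading when a single small cohort is
both selection and validation data. libsvm's C-classification is
deterministic, so identical inputs give identical traces; the suite checks
exact agreement with an independent brute-force re-implementation on the
same folds.

# Association statistics

`pearson_assoc()` returns r with the exact t-distribution p-value
(t = r√((n−2)/(1−r²)), n−2 df). `group_compare()` runs the pooled
two-tailed Student t-test (Welch by flag) and reports Cohen's d as the
*absolute* standardized difference: published effect-size tables print
positive d regardless of direction, so the sign is discarded. With only
group summaries (means ± SDs, per-group n unknown), the equal-weight pooled
SD √((s₁²+s₂²)/2) is used — this reconstruction reproduces published d
values from their printed summaries to three decimals, and coincides with
n-weighted pooling at equal n. `km_estimate()` wraps the survival package's
product-limit estimator and two-group log-rank test.
`feature_survival_screen()` ranks all features by |r| against a target and
flags p < 0.05; multiple-testing correction is deliberately **off** by
default (matching the univariate-screen convention of the emulated
analysis) with Benjamini–Hochberg available by flag — screen hits should be
read as candidate biomarkers, not confirmatory findings.

# The synthetic cohort

`generate_cohort()` emulates the statistical structure of a two-arm
treatment study (default 8 + 8 subjects, the typical arm size):

* **Images.** Each tumor is a filled ellipse (semi-axes uniform in 12–24 px
  on a 64 px canvas, random orientation) filled with a Gaussian random
  field: white noise smoothed by an isotropic Gaussian kernel whose SD is
  the subject's *realized correlation length* — the group value (1 px
  control, 6 px treated) plus N(0, 0.5 px) per-subject jitter, floored at
  0.3 px. The jitter is the within-group biological heterogeneity; 0.5 px on
  a 1–6 px scale keeps groups well separated while making subjects genuinely
  unequal. The field is standardized to the target mean (0.5) and SD (0.15)
  **within the mask**, then clipped to [0, 1]: both groups have identical
  first-order intensity statistics and tumor-size distributions, so only
  spatial texture distinguishes them — longer correlation length provably
  gives longer runs, higher co-occurrence homogeneity and correlation.
* **Survival.** survival = 31 + 4 × latent + N(0, 18) days, floored at 1.
  These defaults put group means near 35 (control) and 55 days (treated)
  with within-group SDs near 18 days — the overall-survival contrast of the
  emulated design. Survival is linked to the *generator latent*, not to any
  extracted feature, so recovering a feature–survival correlation is a
  genuine task. All events are observed by default (terminal small-animal
  study); `censoring_rate` adds censoring for log-rank testing.
* **Histology.** Each marker is mean + sd·(ρ·z + √(1−ρ²)·ε) with z the
  standardized latent — a Gaussian copula with normal marginals, so the
  population correlation with the latent equals the target ρ (defaults:
  fibrosis 0.84, CK19 −0.97, Ki67 0.81). The latent is stored in the
  metadata as `texture_latent`, making the link testable; convergence of
  the realized correlation is verified at n = 500.
* **Reproducibility.** One seed drives everything through a documented
  split: subject i uses `(seed·100003 + 7919·i) mod (2³¹−1)`, so cohorts
  are bit-identical under a fixed seed and subjects are independent streams.

What the generator does **not** emulate: MRI physics (Rician noise, bias
fields, partial volume), irregular tumor shapes, longitudinal growth,
observer variability in masks, or any real relationship between texture and
biology. Passing the recovery suites therefore shows the *pipeline* can
detect and attribute texture differences of this kind at study scale — it
says nothing about whether real tumors express treatment response as
correlation-length changes.

# Problem sizes used by the test and acceptance suites

Unit tests run on 8×8–64×64 images and cohorts of 4–16 subjects. The
calibration suites use 100 label-randomization replicates (LOO accuracy
under the null) and 200 noise-survival replicates (screen false-positive
rate); oracle-equivalence suites use 100 random 8×8 4-level images and
p = 8 search tables. The end-to-end recovery suite runs the full pipeline on
20 cohorts of 8 + 8 subjects at the default conditions. These sizes were
chosen so the whole suite runs in minutes while keeping Monte-Carlo error
well inside the asserted tolerances.

# Known limitations

* **Hub pruning at reduction.** The greedy mean-|r| rule at threshold 0.50,
  applied to a 16-row table whose informative features form one tight
  cluster, usually discards the cluster's crispest members. On some noise
  realizations the surviving proxy peaks at 14/16 leave-one-out accuracy
  rather than 15–16/16, and the selected subset sometimes carries the
  texture signal through an FoS/LBP/power proxy instead of a GLCM/GLRM
  feature. The end-to-end recovery suite asserts demanding per-20-seed
  counts (≥16 seeds at ≥0.90 accuracy, ≥18 seeds with a GLCM/GLRM feature
  selected) and currently measures one seed short of each bound — the
  honest behavior of the prescribed reduction rule at this sample size, and
  a caution against over-reading *which* feature a small-cohort wrapper
  selection returns.
* **Single-slice 2D only**; no IBSI-standardized naming (the inventory is a
  documented reconstruction).
* **Leave-one-out at n = 16** has coarse granularity (1/16 steps) and high
  variance; accuracies should be read with that resolution in mind.
* The printed p-values of small-cohort univariate screens are not corrected
  for multiplicity by default, by design; use `adjust = "BH"` for anything
  confirmatory.
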