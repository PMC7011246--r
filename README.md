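# radiotex

Quantitative MRI texture analysis ("radiomics") for small 2D tumor cohorts,
of the kind used to monitor treatment response in small-animal imaging
studies. From a grayscale slice and a binary tumor mask, the package extracts
a canonical vector of **152 texture features**, prunes redundant features by
pairwise correlation, selects a small discriminative subset with an
exhaustive-search kernel SVM under leave-one-out cross-validation, and
quantifies univariate associations between features and group labels,
survival, and histology markers. A synthetic-cohort generator produces
two-group tumor phantoms with texture-linked survival, so the complete
pipeline is testable end to end without any imaging data.

## The feature inventory

Features are named `<source>.<family>.<feature>` and the inventory is frozen
(count, names, order):

| source | families | count |
|---|---|---|
| `base` (normalized ROI) | FoS (4), GLCM (6), GLRM (11), LBP riu2 (10), fractal (2), shape (6) | 39 |
| `grad` (Sobel magnitude) | FoS, GLCM, GLRM | 21 |
| `wav_a`, `wav_h`, `wav_v`, `wav_d` (Haar sub-bands) | power (1), FoS, GLCM, GLRM | 4 × 22 = 88 |
| `hog` (9-bin orientation histogram) | FoS | 4 |

FoS = {mean, variance (population), Fisher skewness, Shannon entropy of a
32-bin histogram}; GLCM features are the Haralick-style contrast,
correlation, energy, homogeneity, entropy, and dissimilarity of
distance-1 symmetric co-occurrence matrices averaged over 0°/45°/90°/135°;
GLRM gives the eleven standard run-emphasis statistics (SRE, LRE, GLN, RLN,
RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE), averaged over the same four
directions. Every matrix-based feature is computed after per-image min–max
normalization and 32-level quantization, which makes it invariant to
positive affine rescaling of the input intensities.

## The statistics

* **Feature reduction** — greedy elimination of feature pairs with
  |Pearson r| > 0.50: the member of the worst pair with the larger mean
  absolute correlation to the remaining features is dropped.
* **Model selection** — for subset sizes k = 1, 2, …, every size-k subset is
  scored by leave-one-out accuracy of an RBF SVM (C = 1,
  γ = 1/(k · pooled variance), per-fold standardization); the search stops
  when the best accuracy improves by ≤ 10⁻³.
* **Associations** — Pearson r with t = r·√((n−2)/(1−r²)) p-values; pooled
  two-tailed Student t with Cohen's d = |m₁−m₂|/s_pooled (equal-weight
  pooling √((s₁²+s₂²)/2) when only group summaries are available);
  Kaplan–Meier curves with the two-group log-rank test.

## Worked example

```r
library(radiotex)
library(purrr)

cohort <- generate_cohort(cohort_config(seed = 42))
#> <cohort_dataset> 16 subjects (8 control + 8 treated)

features <- extract_feature_table(map(cohort$subjects, "roi"))
dim(features)
#> [1]  16 153        # subject_id + 152 features

reduction <- correlation_filter(features, threshold = 0.50)
#> <reduction_report> kept 13 / dropped 139 features at |r| > 0.50 (0 constant)

trace <- exhaustive_search(reduction$table, cohort$metadata$group)
#> <selection_trace> stopped at k = 2; selected {wav_v.glrm.lrhge}
#>   with LOO accuracy 1.0000

head(feature_survival_screen(features, cohort$metadata$survival_days), 3)
#>   feature           target            r t_stat       p     n significant
#> 1 base.glrm.srlge   survival_days 0.647   3.17 0.00678    16 TRUE
#> 2 base.glrm.lgre    survival_days 0.638   3.10 0.00784    16 TRUE
#> 3 wav_a.glcm.energy survival_days 0.629   3.03 0.00899    16 TRUE

km <- km_estimate(cohort$metadata$survival_days, cohort$metadata$event,
                  cohort$metadata$group)
glance(km)
#>   logrank_chi2 logrank_p
#> 1         3.74    0.0532
```

The two synthetic groups differ only in the spatial correlation length of
their intensity texture (1 px vs 6 px Gaussian random fields with matched
within-mask mean and SD); a run-length feature of a wavelet detail band
separates them perfectly under leave-one-out validation, and run-length /
co-occurrence features dominate the survival screen because survival is
generated from the same latent texture scale. Results objects come with
`tidy()`, `glance()` and `autoplot()` methods; `run_pipeline()` executes the
whole chain from an on-disk cohort directory and writes versioned CSV/JSON
outputs, and `inst/scripts/radiotex.R` wraps it for shell use.

Cohen's d from published-style group summaries:

```r
cohens_d_from_summary(19.98, 13.2, -12.10, 5.63)
#>   feature cohens_d
#> 1 feature     3.16
```

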