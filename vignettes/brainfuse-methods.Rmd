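---
title: "Brain-age prediction with multimodal compact bilinear fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age prediction with multimodal compact bilinear fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

brainfuse estimates a person's "brain age" from a gray-matter density volume
with a 3D residual convolutional network, and sharpens that estimate by
fusing the network's image embedding with a 14-parameter blood panel through
multimodal compact bilinear (MCB) pooling. The difference between predicted
and chronological age — the age gap — is a candidate marker of brain health.
This vignette explains the models, the choices behind them, and what the
package's synthetic cohorts can and cannot establish.

## The imaging model

The regressor is a 3D residual network. Each of its `n_blocks` (default 5)
blocks applies two 3×3×3 convolutions with batch normalization and ReLU
activations around an identity skip (a 1×1×1 projection when the channel
count changes), followed by 3×3×3 max pooling with stride 2×2×2. Pooling is
ceil-mode: each spatial dimension maps to `ceiling(d/2)`. That convention is
forced by the reference geometry — a 121×145×121 gray-matter grid at 1.5 mm
must arrive at 128 feature maps of size 4×5×4 after five blocks
(121→61→31→16→8→4; floor-mode would give 3×4×3). The maps are flattened into
a fully-connected layer producing a 256-dimensional embedding, and a final
fully-connected layer maps the embedding to a single age in years.

Training minimizes mean absolute error (MAE) with Adam at learning rate
1e-4, per-update decay 1e-6 (`lr/(1 + decay*t)`, the classical
interpretation of that constant rather than weight decay), β₁ = 0.9,
β₂ = 0.999, batch size 4 — the package defaults in `network_spec()`. A large
cohort is split 60/20/20 into train/validation/test with floor/floor/
remainder sizes, and the weights of the epoch with the lowest validation
MAE are kept. Volumes are min-max scaled to [0, 1] per cohort before
training, with the constants stored for reuse on held-out data.

The residual block internals (activation placement, normalization) follow
the standard two-convolution residual design; the channel progression
defaults to {8, 16, 32, 64, 128} so the final width is 128. Both are
configurable.

Transfer learning (`fine_tune()`) freezes every convolutional tensor —
weights, biases, batch-norm parameters *and* running statistics — and trains
only the two fully-connected layers. Because the frozen stage is
deterministic, its features are computed once and cached, which makes
fine-tuning orders of magnitude cheaper than full training. The freeze is
testable as exact equality of tensors before and after.

The network is implemented directly in vectorized R: convolutions are an
im2col gather followed by one BLAS matrix product, the data gradient is a
transposed convolution with the offset-flipped kernel, and all gradients are
derived by hand. A finite-difference gradient check in the test suite pins
every parameter tensor's analytic gradient to ~1e-7 relative error; all
stochastic stages take explicit seeds and runs are bit-reproducible.

Two small departures from a naive reading of the training recipe, made after
convergence benchmarks against the constant-mean-age predictor:

* scratch training initializes the output bias at the train-mean age, so
  the optimizer fits deviations instead of spending its budget on a ~60-year
  offset (a standard regression-head initialization; a zero-epoch budget
  still returns the untouched initialization);
* the *desk-scale* configurations used in tests and in
  `scripts/acceptance.R` keep the architecture, loss, decay and batch
  semantics but raise the learning rate to 3e-3 and narrow the channels
  (e.g. {2, 4, 8, 8, 8}, 32-dimensional embedding). A small synthetic run
  takes ~15 optimizer steps per epoch versus the hundreds of thousands of a
  full-scale study, and the step budget, not the architecture, is what has
  to be rescaled.

## Fusion with the blood panel

The blood panel carries 14 features per subject: GLU, TG, TC, ApoA1, ApoB,
HCY, NFL, TREM2, Aβ40, Aβ42, T-tau, TIMP1, VLDLR (columns `Abeta40`,
`Abeta42`, `Ttau` in the package's ASCII naming) plus the APOE genotype
encoded as the ε4 allele count (0/1/2) — a carrier dichotomy loses
information the count keeps. The derived ratios Aβ42/Aβ40 and Aβ42/T-tau are
analysis-only columns (`add_ratios()`); they never enter the fusion panel.
Blood features are z-scored with training-fold statistics only, so
held-out folds never leak into the transform.

MCB pooling approximates the outer product of the image embedding x and the
blood vector y without materializing it: each modality is count-sketched —
`out[j] = Σ_{i: h(i)=j} s(i)·v[i]` with hash h and signs s drawn once per
`make_sketch_spec()` — and the two sketches are circularly convolved via an
element-wise product in FFT space. This equals, exactly, the count sketch of
the flattened outer product under the combined hash
`h(i,j) = (h₁(i)+h₂(j)) mod d`, which is the brute-force oracle the test
suite compares against at small dimensions (max |difference| < 1e-8 over 100
random triples).

One representational subtlety: a z-scored blood vector has no constant
direction, so sketches of the raw outer product span only bilinear
interaction terms and a linear head could not even express the image-only
signal. `fit_fusion_model()` therefore augments each modality with a
constant unit coordinate before sketching (homogeneous coordinates), making
the fused vector span both main effects and all pairwise interactions.
`mcb_pool()` itself remains the pure MCB primitive. The sketch dimension d
defaults to 1024; the brute-force oracle comparisons use d = 8–64 where the
outer product is enumerable, while the fusion experiments keep the default —
at small d the hash collisions among the ~500 outer-product terms add noise
that can swamp the blood signal. The signed-square-root/L2 post-processing
common in the MCB literature is available as a manual step but off by
default.

The default fusion head is a linear (fully-connected) layer solved by
minimum-norm least squares; `regressor_spec()` also provides RBF-kernel
support vector regression (C ∈ {0.1, 1, 10, 100}, ε ∈ {0.01, 0.1, 0.5, 1},
selected by inner 3-fold CV MAE), random forest, and lasso heads, plus
optional univariate feature screening at p < .05, for the single-modality
comparisons. All hyperparameter searches run inside the training folds of
the 5-fold cross-validation, never on test folds.

## Attention and region importance

`grad_cam()` explains a prediction by weighting the final convolutional
block's feature maps with the spatial average of ∂(predicted age)/∂(map),
rectifying the weighted sum, and upsampling trilinearly to the input grid
(nearest-neighbour available for label-boundary work). Per-subject maps from
the evaluation cohort are averaged (`average_attention()`), and
`region_importance()` scores each atlas label as (sum of attention)/(voxel
count), averages hemisphere partners to one score per pair — 45 scores for a
90-label parcellation — min-max normalizes to [0, 1], and ranks. If every
pair scores identically (an untrained or constant model) the normalized
scores are defined as 1 with a warning, preserving "top region = 1.00"
semantics. Negative weighted sums are clipped to zero, the standard Grad-CAM
rectification.

Desk-scale caveat: Grad-CAM needs spatial structure in the target layer. A
5-block network collapses a 24×28×24 grid to 1×1×1 cells, where localization
is undefined, so the attribution experiments use a 3-block spec whose final
maps are 3×4×3. They also widen the final block (16 channels): channel
specialization is what lets the global gradient weights separate the
informative region from other structures of similar mean intensity.

## Evaluation statistics

* `mae()`, `reduction_of_mae()` (`(before − after)/before × 100`, negative
  when fusion hurts), and `group_breakdown()` over the age bins [50,60),
  [60,70), [70,85] with the population (divide-by-n) variance of the signed
  error by default.
* `correlation_with_policy()` gates the method on Shapiro–Wilk normality of
  each variable at α = .05: Spearman if either fails, else Pearson.
* `permutation_test()` compares two error sets by pooling them and
  re-splitting into groups of the original sizes 999 times; the null set is
  the 999 permuted mean differences plus the observed one, and the one-sided
  p is the observed difference's rank in that set. "Divided equally" is
  resolved as size-preserving splits — with unequal groups an equal split
  would make the observed statistic non-exchangeable with the null. The
  one-sided ("top 5%") reading is the default; two-sided is available. With
  a Monte-Carlo null the p-value at a zero observed difference concentrates
  near 1/2 rather than sitting deterministically at or above it; the test
  suite asserts the calibration property (rejection rate ≈ 5% under the
  null) rather than a per-draw inequality.

## Mediation, screening, PCA

`mediate()` implements linear product-of-coefficients mediation: `m ~ x`
gives path a, `y ~ x + m` gives the direct effect c′ (ADE) and path b;
ACME = a·b and total = c′ + a·b. Uncertainty comes from 1,000 subject
bootstraps with bias-corrected (BC, no acceleration term) percentile 95%
intervals; BCa would need a jackknife acceleration estimate that the
bootstrap count does not support. Classification: partial mediation when
both ACME and ADE intervals exclude zero, full when only ACME's does.
Bootstrap p-values are twice the smaller tail proportion at zero, floored at
1/n_boot. `mediation_grid()` runs an exposures × mediators grid and adjusts
the ACME p-values with Benjamini–Hochberg (`bh_correct()`, a validated
wrapper over `p.adjust`). Exposure screening (`screen_predictors()`) keeps
features whose univariate regression on age has p < .05.

`compare_groups()` applies the covariate-gated policy: categorical variables
get an uncorrected chi-squared test; continuous variables are fit as an
ANCOVA with sex and APOE-ε4 carriage, kept (with η² = group SS/total SS and
Bonferroni-adjusted contrasts on adjusted means via emmeans) if either
covariate is significant at .05, otherwise refit as one-way ANOVA with
Bonferroni pairwise t-tests. η² is classical (not partial). Note that with a
null covariate the ANCOVA and ANOVA group F agree only up to the residual
degrees of freedom; exact equality is not a theorem and the tests assert
close agreement instead.

`pca_stitched()` z-scores the concatenated 256 + 14 = 270-column matrix
(constants dropped with a warning) and returns the first two principal
components, their scores, and explained-variance fractions.

## The synthetic cohort generator

`simulate_cohort()` emulates the *statistical structure* of an elderly
brain-aging cohort, not its anatomy:

* ages uniform on [50, 85] by default (the study population's range; its age
  distribution tested non-normal, so no Gaussian assumption is built in), with
  a truncated-normal option (mean 62.1, SD 8.6);
* a mirror-symmetric parcellation of axis-aligned ellipsoids placed on a
  jittered cell grid (`make_atlas()`; up to 45 pairs = 90 labels),
  guaranteeing disjoint, equal-size hemisphere partners;
* per region pair, mean intensity `baseline − slope·(age − 50) + u` with a
  subject-level deviation u ~ N(0, region_sd) shared by both hemispheres,
  plus voxel noise; background sits near 0.08; everything clamps at 0;
* blood parameters generated on the log scale and exponentiated, so they are
  strictly positive and a log transform is exactly Gaussianizing. Default
  slopes encode the reported age-correlation signs — ApoA1, NFL and Aβ40
  rise, VLDLR falls, Aβ42 stays flat so the derived Aβ42/Aβ40 ratio falls;
* APOE allele pairs with ε4 frequency 0.15 (carrier = ≥1 ε4); MMSE ≥ 25 and
  MoCA ≥ 18 as clipped integers, mirroring screening rules (carried for
  interface completeness, unused downstream);
* optional mediation wiring: a blood parameter's log value can load on a
  region's standardized idiosyncratic deviation (path a) and on
  standardized age (direct path), with everything recorded in the returned
  ground truth. For quantitative mediation recovery the package provides
  `simulate_mediation_triple()`, whose structural equations make ACME = a·b
  exact in expectation; the cohort-level wiring is validated by sign and
  significance, since age is exogenous in the cohort model and regression
  coefficients are not structurally identified there.

Identical configurations are bit-identical (`write_cohort()` directories
hash identically), and the generator's defaults are held fixed across the
test suite.

What passing tests on these cohorts show: that the implementation trains,
transfers, fuses, attributes and tests exactly as specified, with effect
directions recoverable at the configured strengths. What they do not show:
performance on real morphometry — there is no cortical geometry, no scanner
or registration artifact, no site effect, and the intensity-age relationship
is linear by construction. The study's headline numbers (e.g. MAE 3.96
years, r = .76 on recruited subjects) require the original cohorts and
full-scale training and are out of reach of any synthetic check.

## Problem sizes in the shipped experiments

The test suite and `scripts/acceptance.R` run, per experiment: fusion
benefit on n = 300 subjects (24×28×24 grid, 6 region pairs, 5 epochs,
5 seeds); transfer benefit with one n = 1000 pretraining cohort (16³ grid)
against five n = 80 target cohorts; attention localization on n = 100 with
one atrophying pair among five (10 epochs, 5 seeds); 500 permutation-test
null replicates; 200 mediation coverage replicates and 10 recovery
replicates at n = 1000. Point estimates with ~0.02 sampling SD (the ACME at
n = 1000) are assessed on means over replicate datasets rather than single
draws.

## Known limitations

* The pure-R network is CPU-bound and meant for method validation and small
  studies, not for 121×145×121 training at cohort scale.
* Mediation is strictly linear: no exposure-mediator interaction, no
  sensitivity analysis.
* No age-gap bias correction (regression toward the mean) is applied; the
  signed errors returned by `prediction_set()` make such corrections easy to
  layer on.
* The ANCOVA post-hoc uses Bonferroni-adjusted contrasts on
  covariate-adjusted means; other adjustment families are not exposed.
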