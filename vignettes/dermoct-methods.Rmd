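---
title: "Models and methods behind dermoct"
author: "dermoct authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dermoct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermoct)
```

## Scope

`dermoct` quantifies dermatological optical coherence tomography (OCT)
B-scans: it separates epidermis from dermis at the dermal-epidermal
junction (DEJ), extracts an optical feature (the depth attenuation
coefficient) together with first-order, co-occurrence (GLCM) and
run-length (GLRLM) texture statistics from rectangular regions of
interest, selects discriminative features by principal-component loadings,
and classifies lesion versus healthy ROIs with a repeated, stratified,
cross-validated suite of standard classifiers. Because clinical OCT image
sets are rarely shareable, the package ships a synthetic B-scan generator
that reproduces the image properties these estimators rely on; every
stage of the pipeline is exercised against it in the test suite.

## The synthetic imaging model

A B-scan is modeled as single-scattering depth decay under correlated
multiplicative speckle:

$$ I(z, x) = \big(I_0\, e^{-\int_0^z \mu(u,x)\,du} + b\big)\; s(z, x), $$

where $\mu(z,x)$ is the per-pixel attenuation rate (epidermis above the
DEJ, dermis below, optionally an ellipsoidal lesion override), $b$ a
background floor, and $s$ a unit-mean speckle field. The DEJ trace is a
sinusoid in the lateral coordinate; its amplitude, period and phase are
configurable, and the ground truth records exactly the rows at which
$\mu$ switches.

Default geometry is a 512 x 600 pixel frame at 4 um axial / 10 um lateral
spacing, i.e. roughly 2 mm depth by 6 mm width, matching the scan format
of clinical dermatological swept-source scanners. The default epidermis is
100 um: thin skin runs roughly 70-120 um, while palmar/plantar ("thick")
skin carries a stratum corneum of the order of 300 um and is emulated by
raising `epidermis_thickness_um`. Typical literature values motivated the
default layer rates ($\mu_{epi}$ = 3 mm^-1, $\mu_{dermis}$ = 1.5 mm^-1):
the epidermis of healthy skin attenuates markedly faster than the dermis,
and that contrast is exactly what the segmentation exploits.

Speckle is modeled as a stationary, positive, unit-mean multiplicative
field: white Gaussian noise smoothed by a Gaussian kernel of standard
deviation $\sigma_c$ (the correlation length, default 2 px), exponentiated
with a log-amplitude chosen so the field's contrast (std/mean) matches the
requested value, then normalized to unit sample mean. Two consequences are
used as oracles: the field's autocovariance is Gaussian with FWHM
$4\sigma_c\sqrt{\ln 2}$, and averaging $n$ independent A-scans shrinks the
speckle deviation around the noiseless decay like $1/\sqrt{n}$. This is a
phenomenological speckle model — it reproduces contrast and grain size,
which is what the despeckler, the speckle-size estimator and the texture
features respond to, not the underlying coherent scattering physics.
Confocal-gate and sensitivity roll-off factors are deliberately not
simulated, mirroring multi-beam dynamic-focus acquisition in which those
corrections are negligible and left unapplied.

What the generator does *not* emulate: hair follicles, sweat-duct spirals,
vasculature, the stratum lucidum of thick skin, lesion subtype morphology
(nodular/superficial/infiltrative), multiple scattering, and 3-D
structure. Passing tests therefore demonstrate correctness of the
estimators under the stated image model, not clinical performance.

## Despeckling

The default `despeckle()` method is a homomorphic patch-based non-local
means: the image is log-transformed so the multiplicative speckle becomes
additive and stationary, the noise level is estimated robustly as the
median absolute deviation of vertical pixel differences taken at a lag of
4 px (first differences underestimate the noise when the speckle is
correlated), and each pixel is replaced by a similarity-weighted average
over an 11 x 11 search window with 3 x 3 patches. Weights decay with the
*noise-corrected* mean squared patch distance,
$\exp(-\max(d^2 - 2\hat\sigma^2, 0)/h^2)$ with bandwidth
$h = 2.5\,\hat\sigma$: same-tissue patches, whose expected distance is
$2\sigma^2$, receive weight near one, while across an edge the distance
term dominates and the weight collapses — which is why a generous
bandwidth smooths aggressively without displacing boundaries. The result
is exponentiated back and rescaled to preserve the global mean. A median
filter and a hook for an external BM3D-style collaborative filter are also
exposed; the pipeline contract is speckle-contrast reduction, not any one
filter.

Feature extraction operates on the original (non-despeckled) ROI by
default, with `feature_config(use_despeckled = TRUE)` as the alternative;
which image feeds a texture bank is a genuine modeling choice and both
paths are exposed.

## DEJ segmentation

Two mechanisms are provided.

`detect_dej()` is the generic minimum-cost boundary search: per-column
node costs are one minus the normalized vertical-gradient magnitude of a
cost source (an attenuation map or the image itself), and a
least-cost-first search over the left-to-right column graph — virtual
source and sink spanning the first and last columns, lateral moves bounded
by `r_max` rows — returns the globally optimal row trace. On this directed
acyclic graph the search is realized as exact column-by-column dynamic
programming; the test suite checks its optimality against exhaustive path
enumeration on small frames.

`segment_bscan()`, the pipeline default, instead fits the two-layer
attenuation model itself. After subtracting the estimated background
floor, each column's log intensity is piecewise linear with a slope change
at the DEJ. The algorithm (1) estimates the two slopes from an
unconstrained two-piece fit of the lateral-mean profile, (2) localizes the
per-column changepoint with the slopes held fixed, reporting the posterior
mean of the break under a Gaussian residual model rather than the argmin
(the argmin of a shallow residual valley wanders; the posterior mean is
close to the information bound), (3) regularizes laterally with a
REML-smoothed thin-plate spline fitted to column-block means (block size
15 — speckle correlation makes neighboring columns' errors dependent, so
blocks are averaged before smoothing and the REML criterion then sees
approximately independent noise), and (4) re-estimates the slopes from
boundary-excluded bands pooled over all columns and repeats the
localization once. The slope estimates are returned as per-layer
attenuation rates.

This deviates from building a gradient cost on the windowed attenuation
map and searching it, which is also implemented and exposed: at realistic
speckle (contrast 0.2, correlation 2 px) the slope-kink ridge has
per-column signal-to-noise near one, and no path search can recover a
boundary to a few pixels from a statistic that weak, whereas the
constrained changepoint uses every depth sample in the column. The
fuzzy-logic border smoothing of the original interactive tool is likewise
replaced by explicit, documented smoothers (`smooth_boundary()` is a
centered moving average; `segment_bscan()` uses the spline above); no
claim of algorithmic fidelity to that tool is made.

Layer masks and ROI placement follow the boundary: the epidermis spans
surface to boundary, the dermis boundary to frame bottom, and `n` ROIs per
layer are placed at the evenly distributed lateral centers
$\lfloor (k-1/2)\,W/n \rfloor + 1$, vertically centered in the local layer
band, shrinking (with a warning) where the band is thinner than the
requested ROI.

## The feature bank

One ROI yields 56 named values, in fixed order: `attenuation_mu`, 7
first-order statistics, 5 GLCM statistics x 4 directions, and 7 GLRLM
statistics x 4 directions. (The source work counts "sixty-three features"
while enumerating a bank of this shape, which totals 56; the discrepancy
is documented rather than resolved by inventing seven features, and the
schema is configurable.)

**Attenuation.** The ROI's A-scans are averaged into one depth profile and
$I(z) = A e^{-\mu z}$ is fitted by Levenberg-Marquardt nonlinear least
squares (`minpack.lm`), initialized from the ordinary-least-squares slope
of $\log I$; the two estimates agree exactly on noiseless exponentials,
and the log-linear estimate is kept alongside (and returned with a warning
if the nonlinear step fails). The default fit range skips 5 px below the
ROI top to avoid boundary transients. The fit is invariant to uniform
intensity scaling. Note that with correlated speckle the effective number
of independent A-scans in an ROI is the column count divided by the
lateral correlation length, so per-ROI attenuation values on small ROIs
scatter substantially around the planted rate even though they are
unbiased; the recovery tests therefore average enough columns to make the
check sharp.

**First-order statistics** are computed on the ROI's 8-bit log-compressed
display image: population mean/variance/std, sample skewness $g_1$ and
excess kurtosis $g_2$ (both defined as 0 for constant input), median, and
Shannon entropy (base 2) of the 256-bin histogram.

**GLCM.** Gray levels are quantized to L = 32 by linear min-max binning
over the ROI (monotone; constant ROIs map to level 0). Pairs at
displacement d = 1 along 0/45/90/135 degrees are counted symmetrically and
normalized. The five statistics are contrast, energy, entropy,
homogeneity (inverse difference moment) and correlation, with correlation
defined as 1 when a marginal variance vanishes (a constant ROI is
perfectly correlated with itself, and the value stays finite).

**GLRLM.** Maximal runs of equal level are counted along the lines of each
direction; the seven statistics are SRE, LRE, GLN, RP, RLN, LGRE and HGRE,
with the gray index 1-based so that low/high gray-level emphasis stays
finite for level 0. Construction of both matrices is verified exactly
against brute-force pair/run enumerators.

**Speckle size.** `speckle_size()` implements the classic estimator used
to compare imaging modalities: the FWHM of the normalized, mean-subtracted
2-D autocovariance of a homogeneous region, along the axial and lateral
axes with linear interpolation between lag samples, reported in pixels and
(given spacings) in um.

## Feature selection and classification

Features are z-scored with population standard deviation; constant
features are dropped with a warning, and the fitted parameters are stored
so held-out data can be transformed with training-fold parameters.
`pca_select_features()` interprets "greatest contribution" as: for
principal components 1..n in order, take the feature with the largest
absolute loading not already selected — with loading signs fixed so each
component's largest entry is positive, making selection deterministic; six
components yield six features, matching the selection cardinality of the
workflow it reproduces.

`cross_validate()` runs repeated stratified k-fold cross-validation
(default 10 x 10) over linear SVM, quadratic (degree-2 polynomial kernel)
SVM, logistic regression, k-nearest neighbors, linear discriminant
analysis and a single-hidden-layer neural network. Normalization
parameters are fitted on training folds only; per-fold confusion counts
are accumulated; out-of-fold decision scores are pooled for ROC analysis
(`roc_points()` sweeps thresholds and integrates by the trapezoid rule;
its area equals the Mann-Whitney U statistic over $n_1 n_2$, which the
tests check). Unstated hyperparameters were fixed once at common defaults:
SVM cost 1, polynomial kernel offset 1, K = 5 neighbors, 10 logistic
hidden units with weight decay 0.01 — all exposed in
`classifier_config()`. The reported figure of merit is the mean over all
folds, with per-repeat spread retained. Sensitivity is defined on the
lesion (non-"healthy") class.

## Body-site statistics

`interval_summary()` reports $\bar{x} \pm t_{0.975,\,n-1}\, s/\sqrt{n}$
per site; `anova_by_site()` is classical equal-variance one-way ANOVA (its
F equals the squared pooled t statistic for two sites, checked
numerically); `pairwise_ttest_map()` uses the Welch unequal-variance
t-test for every site pair, arranged as a symmetric matrix with unit
diagonal and a significance mask at 0.05. Raw p-values are the default,
matching the presentation style of p-value maps; Bonferroni and
Benjamini-Hochberg adjustments are available but off by default. The
pooled-versus-Welch choice and the ROI-pooling question (ROIs from one
subject are treated as independent) are both documented limitations; a
mixed-effects treatment of subject-level correlation is out of scope.
Degenerate inputs follow explicit conventions: identical zero-variance
samples give p = 1 (flagged), zero within-group variance with unequal
means gives F = Inf with p reported as the 0 limit (flagged).

## Numerical conventions and degenerate inputs

* Indices are 1-based and ranges inclusive, as is idiomatic in R; ROI
  extents are `top_row .. top_row + height - 1`.
* Quantization uses a `1e-9` guard in the denominator so the maximum maps
  to L - 1; constant input maps to level 0.
* `0 log 0 = 0` throughout entropy calculations.
* Attenuation fitting refuses non-positive intensities (log domain) and
  profiles shorter than 8 samples; a constant profile gives mu = 0.
* All generators are deterministic functions of their seed; cohort items
  derive per-item seeds from the master seed, so any scan can be
  regenerated in isolation.
* Seeds are 32-bit; seed derivation keeps every derived seed below 2^31.

## Problem sizes used by the tests

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes while keeping every check sharp: texture oracles
on one hundred 8 x 8 frames in all four directions; attenuation recovery
from 200 averaged A-scans of 400 samples; segmentation on twenty 512 x 600
scans with a 20 px / 300 px sinusoidal DEJ at speckle contrast 0.2;
classification on a 60 + 60 cohort of 320 x 360 scans (lesions with twice
the dermal attenuation and doubled speckle correlation length) under
10 x 10-fold cross-validation, plus a label-permutation null; PCA recovery
over one hundred 60 x 56 tables; and t-test calibration over 200 null
simulations with 50 samples per site.

## Known limitations

* The synthetic lesion is an ellipse with altered attenuation and texture
  correlation; no morphological subtype structure.
* The segmentation model assumes exactly two layers below a detectable
  surface; multi-layer skin (stratum corneum/lucidum of palms and soles)
  is not sub-segmented.
* The attenuation model is single-scattering; extended Huygens-Fresnel
  multiple-scattering corrections are out of scope.
* BM3D despeckling is an external hook, not a bundled implementation.
* Classification is binary (lesion versus healthy); the multi-class
  problem is out of scope.
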