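# dermoct

Quantitative texture and attenuation analysis of dermatological optical
coherence tomography (OCT) B-scans.

Skin diagnosis from OCT currently leans on visual pattern recognition.
`dermoct` implements the computational counterpart for R users — imaging
scientists and dermatology researchers who want objective, reproducible
numbers out of B-scans: it segments skin into epidermis and dermis at the
dermal-epidermal junction (DEJ), extracts a 56-value feature bank per
region of interest, compares healthy body sites statistically, and
classifies lesion versus healthy regions with a cross-validated classifier
suite. A built-in synthetic OCT generator with ground truth makes the
whole pipeline testable without clinical data.

## What it computes

* **Optical feature.** The attenuation coefficient μ (mm⁻¹) of a region:
  the ROI's A-scans are averaged and *I(z) = A·e^(−μz)* is fitted by
  Levenberg–Marquardt nonlinear least squares, initialized from the
  log-linear slope.
* **Texture features.** First-order statistics (mean, variance, std,
  skewness, kurtosis, median, histogram entropy); gray-level co-occurrence
  matrix (GLCM) contrast, energy, correlation, homogeneity and entropy in
  the four directions 0°/45°/90°/135°; gray-level run-length matrix
  (GLRLM) SRE, LRE, GLN, RP, RLN, LGRE and HGRE in the same directions —
  1 + 7 + 20 + 28 = 56 named values per ROI.
* **Segmentation.** The DEJ as the depth where each A-scan's log-intensity
  slope switches from the epidermal to the dermal attenuation rate —
  localized per column under a fitted two-layer model and regularized
  laterally; a generic minimum-cost path search over a gradient cost map
  (`detect_dej()`) is also provided. Layer masks and evenly distributed
  per-layer ROIs follow the boundary.
* **Modeling.** Z-score normalization, PCA-loading feature selection,
  feature correlation maps, repeated stratified 10×10-fold cross-validation
  of LSVM, QSVM, logistic regression, KNN, LDA and a small neural network,
  with confusion-count metrics and pooled out-of-fold ROC/AUC.
* **Site statistics.** Per-site means with 95% t-intervals, one-way ANOVA,
  and pairwise Welch t-test p-value maps across body sites.
* **Synthetic data.** Two-layer skin B-scans with depth-exponential decay,
  an undulating DEJ, correlated multiplicative speckle of controllable
  contrast and grain size, insertable ellipsoidal lesions, and exact
  ground truth (boundary, lesion mask, μ map).

## Worked example

Simulate a speckled scan with a sinusoidal DEJ, segment it, and extract
features:

```r
library(dermoct)

spec <- synthetic_spec(surface_row = 40, epidermis_thickness_um = 640,
                       mu_epidermis_per_mm = 3, mu_dermis_per_mm = 1.5,
                       boundary_amplitude_px = 20, boundary_period_px = 300,
                       speckle_contrast = 0.2, seed = 42)
scan <- generate_bscan(spec)
scan$bscan
#> OCT B-scan 'synthetic-42': 512 x 600 px (2.05 x 6 mm), linear domain

seg <- segment_bscan(scan$bscan)
seg$boundary
#> DEJ boundary over 600 columns, rows 178..215, confidence 0.898
sprintf("mu_epidermis = %.2f /mm, mu_dermis = %.2f /mm",
        seg$mu_epidermis_per_mm, seg$mu_dermis_per_mm)
#> "mu_epidermis = 3.01 /mm, mu_dermis = 1.51 /mm"
mean(abs(seg$boundary$rows - scan$truth$boundary))   # vs ground truth
#> 4.41
```

The recovered boundary tracks the planted sinusoid to a few pixels and the
layer attenuation rates come back at the planted 3 and 1.5 mm⁻¹. Features
for the third of ten evenly distributed epidermal ROIs:

```r
lay <- layer_masks_and_rois(scan$bscan, seg$boundary, seg$surface_row,
                            n_rois = 10, roi_height_px = 64, roi_width_px = 64)
v <- assemble_feature_vector(scan$bscan, lay$rois[[3]])
round(v[c("attenuation_mu", "fos_entropy", "glcm_contrast_0",
          "glcm_correlation_135", "glrlm_SRE_0")], 3)
#>       attenuation_mu          fos_entropy      glcm_contrast_0
#>                2.816                7.270                1.454
#> glcm_correlation_135          glrlm_SRE_0
#>                0.936                0.775
```

`attenuation_mu` is the ROI's decay rate in mm⁻¹ (single epidermal ROIs
scatter around the planted rate because speckle limits the number of
independent A-scans); `fos_entropy` is histogram entropy in bits;
`glcm_contrast_0` measures gray-level variation between horizontal
neighbors; `glcm_correlation_135` the diagonal neighborhood correlation;
`glrlm_SRE_0` the short-run emphasis (1 = fully fragmented runs).

Classify a labeled synthetic cohort — lesions carry twice the dermal
attenuation and a coarser speckle texture:

```r
spec_h <- synthetic_spec(image_height_px = 320, image_width_px = 360,
                         surface_row = 30, epidermis_thickness_um = 150,
                         boundary_amplitude_px = 6, boundary_period_px = 180,
                         speckle_contrast = 0.3, seed = 1)
spec_l <- do.call(synthetic_spec, c(unclass(spec_h)[setdiff(names(unclass(spec_h)), "lesion")],
  list(lesion = list(center_rowcol = c(180, 180), semi_axes_px = c(45, 70),
                     mu_lesion_per_mm = 3, texture_corr_px = 4))))
cohort <- generate_cohort(spec_h, spec_l, n_per_class = 20, seed = 7)
tab <- cohort_feature_table(cohort)
cv <- cross_validate(tab, classifiers = c("lsvm", "qsvm", "lda"),
                     folds = 10, repeats = 5, seed = 0)
cv
#> Repeated cross-validation (seed 0, positive class 'lesion')
#>  classifier accuracy sensitivity specificity error_rate accuracy_sd_repeats   auc
#>        lsvm    1.000        1.00        1.00      0.000              0.0000 1.000
#>        qsvm    1.000        1.00        1.00      0.000              0.0000 1.000
#>         lda    0.965        0.94        0.99      0.035              0.0224 0.992
```

Accuracy/sensitivity/specificity are fold means; `auc` comes from the
pooled out-of-fold decision scores. `run_pipeline()` chains all stages
from a YAML or list config and writes a hashed manifest; a thin command
line (`inst/cli/dermoct`) exposes the same stages as subcommands
(`simulate`, `despeckle`, `segment`, `extract`, `select`, `classify`,
`site-stats`, `speckle-size`, `run`).

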