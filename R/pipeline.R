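#' Extract lesion-matched feature vectors from a synthetic cohort
#'
#' For each cohort item the ROI is centered on the lesion (using the item's
#' ground-truth lesion mask) for lesion scans, and at the matching location
#' for healthy scans, so that class differences come from tissue properties
#' rather than ROI placement.
#'
#' @param cohort List from [generate_cohort()].
#' @param roi_height_px,roi_width_px ROI size (must fit inside the lesion).
#' @param config A [feature_config()].
#' @return A `feature_table` with one row per scan.
#' @export
cohort_feature_table <- function(cohort, roi_height_px = 48L,
                                 roi_width_px = 48L,
                                 config = feature_config()) {
  centers <- lapply(cohort, function(item) {
    if (any(item$truth$lesion_mask)) {
      idx <- which(item$truth$lesion_mask, arr.ind = TRUE)
      round(colMeans(idx))
    } else NULL
  })
  default_center <- centers[!vapply(centers, is.null, logical(1))]
  default_center <- if (length(default_center)) default_center[[1]] else {
    d <- dim(cohort[[1]]$bscan$pixels)
    c(round(d[1] * 0.6), round(d[2] / 2))
  }
  vectors <- vector("list", length(cohort))
  rois <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    item <- cohort[[i]]
    ctr <- centers[[i]] %||% default_center
    r <- roi(top_row = ctr[1] - roi_height_px %/% 2L,
             left_col = ctr[2] - roi_width_px %/% 2L,
             height_px = roi_height_px, width_px = roi_width_px,
             layer = if (item$truth$class_label == "lesion") "lesion" else "dermis",
             class_label = item$truth$class_label,
             subject_id = sprintf("s%03d", i))
    vectors[[i]] <- assemble_feature_vector(item$bscan, r, config)
    rois[[i]] <- r
  }
  feature_table(vectors, rois)
}

#' Run the full analysis pipeline from a configuration
#'
#' Chains the stages: simulate (or load) a labeled cohort, extract the
#' feature bank per scan, optionally select features by PCA loadings, run
#' the repeated cross-validated classifier suite, and write a run manifest
#' (inputs, parameters, seed, output hashes) so a run can be reproduced
#' bit-identically.
#'
#' @param config Named list (or path to a YAML file with the same fields):
#'   \describe{
#'     \item{out_dir}{Output directory (created).}
#'     \item{seed}{Master seed (default 0).}
#'     \item{simulate}{List: `n_per_class`, plus optional [synthetic_spec()]
#'       overrides under `healthy` and `lesion` (`lesion` must carry a
#'       `lesion` element). Omit to use `input_features` instead.}
#'     \item{input_features}{Path to an existing feature CSV (alternative to
#'       `simulate`).}
#'     \item{roi_height_px, roi_width_px}{Cohort ROI size (default 48).}
#'     \item{features}{Optional [feature_config()] overrides.}
#'     \item{select}{Optional list: `n_components` to run PCA selection and
#'       classify on the selected subset.}
#'     \item{classify}{Optional list: `classifiers`, `folds`, `repeats`.}
#'   }
#' @return The manifest (also written to `out_dir/manifest.json`), listing
#'   output files and their MD5 hashes.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir))
    stop_dermoct("config$out_dir is required", "invalid_parameter")
  if (is.null(config$simulate) && is.null(config$input_features))
    stop_dermoct("config needs either 'simulate' or 'input_features'",
                 "invalid_parameter")
  if (!is.null(config$input_features) && !file.exists(config$input_features))
    stop_dermoct(sprintf("input_features not found: %s", config$input_features),
                 "invalid_parameter")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 0L
  outputs <- character(0)

  fcfg <- do.call(feature_config, config$features %||% list())
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_per_class <- sim$n_per_class %||% 10L
    spec_h <- do.call(synthetic_spec, sim$healthy %||% list())
    lesion_args <- sim$lesion %||% default_lesion_args(spec_h)
    spec_l <- do.call(synthetic_spec, lesion_args)
    cohort <- generate_cohort(spec_h, spec_l, n_per_class, seed = seed)
    table <- cohort_feature_table(cohort,
                                  roi_height_px = config$roi_height_px %||% 48L,
                                  roi_width_px = config$roi_width_px %||% 48L,
                                  config = fcfg)
  } else {
    table <- read_feature_table(config$input_features)
  }
  features_csv <- file.path(config$out_dir, "features.csv")
  write_feature_table(table, features_csv)
  outputs <- c(outputs, features_csv)

  selection <- NULL
  if (!is.null(config$select)) {
    ncomp <- config$select$n_components %||% 6L
    selection <- pca_select_features(normalize_features(table), ncomp)
    sel_json <- file.path(config$out_dir, "selection.json")
    jsonlite::write_json(list(selected = selection$selected,
                              explained_variance = selection$explained_variance),
                         sel_json, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, sel_json)
    table <- as_feature_table(as.data.frame(table), selection$selected)
  }

  report <- NULL
  if (!identical(config$classify, FALSE)) {
    cc <- if (is.list(config$classify)) config$classify else list()
    report <- cross_validate(table,
                             classifiers = cc$classifiers %||%
                               c("lsvm", "qsvm", "lr", "knn", "lda", "ann"),
                             folds = cc$folds %||% 10L,
                             repeats = cc$repeats %||% 10L,
                             seed = seed)
    report_json <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(list(summary = report$summary,
                              auc = lapply(report$roc, `[[`, "auc"),
                              seed = seed),
                         report_json, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, report_json)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dermoct")),
    seed = seed,
    parameters = config[setdiff(names(config), "out_dir")],
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# Default lesion variant of a healthy spec: a dermal ellipse with twice the
# dermal attenuation and a coarser speckle texture.
default_lesion_args <- function(spec_h) {
  epi_px <- round(spec_h$epidermis_thickness_um / spec_h$axial_spacing_um)
  args <- unclass(spec_h)
  args$lesion <- list(
    center_rowcol = c(min(spec_h$surface_row + epi_px + 60L,
                          spec_h$image_height_px - 50L),
                      round(spec_h$image_width_px / 2)),
    semi_axes_px = c(40L, 60L),
    mu_lesion_per_mm = 2 * spec_h$mu_dermis_per_mm,
    texture_corr_px = 2 * spec_h$speckle_corr_px)
  args
}
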