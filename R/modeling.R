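#' Z-score normalize the features of a table
#'
#' Each feature column is centered to mean 0 and scaled to population
#' standard deviation 1. Constant features are dropped with a warning. The
#' fitted parameters are stored in `attr(, "normalization_params")` so they
#' can be re-applied to held-out data.
#'
#' @param table A `feature_table` with at least 2 rows.
#' @return The normalized `feature_table`.
#' @export
normalize_features <- function(table) {
  if (nrow(table) < 2L)
    stop_dermoct("at least 2 rows required", "invalid_parameter")
  feats <- attr(table, "feature_names")
  X <- feature_matrix(table)
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  constant <- sd_pop == 0
  if (all(constant))
    stop_dermoct("all features are constant", "degenerate_table")
  if (any(constant)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(feats[constant], collapse = ", ")))
    table <- table[, !(names(table) %in% feats[constant]), drop = FALSE]
    feats <- feats[!constant]; X <- X[, !constant, drop = FALSE]
    mu <- mu[!constant]; sd_pop <- sd_pop[!constant]
  }
  Z <- sweep(sweep(X, 2, mu), 2, sd_pop, "/")
  table[, feats] <- Z
  out <- as_feature_table(as.data.frame(table), feats)
  attr(out, "normalization_params") <- data.frame(feature = feats, mean = mu,
                                                  sd = sd_pop,
                                                  row.names = NULL)
  out
}

# z-scoring helpers used inside cross-validation (training-fold parameters
# applied to test folds).
fit_zscore <- function(X) {
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  sd_pop[sd_pop == 0] <- 1
  list(mean = mu, sd = sd_pop)
}
apply_zscore <- function(X, par) sweep(sweep(X, 2, par$mean), 2, par$sd, "/")

#' Select features by principal-component loadings
#'
#' Runs PCA on the feature matrix and, for components 1..n in order, selects
#' the feature with the largest absolute loading not already selected.
#' Loading signs are fixed so each component's largest-magnitude entry is
#' positive, making the result deterministic.
#'
#' @param table A (normally normalized) `feature_table` with >= 3 rows.
#' @param n_components Number of leading components / selected features
#'   (default 6).
#' @return A `selection_result`: `selected` (ordered feature names),
#'   `loadings` (feature x component), `explained_variance`.
#' @export
pca_select_features <- function(table, n_components = 6L) {
  n_components <- check_count(n_components, "n_components", 1L)
  feats <- attr(table, "feature_names")
  if (n_components > length(feats))
    stop_dermoct("n_components exceeds the number of features",
                 "invalid_parameter")
  if (nrow(table) < 3L)
    stop_dermoct("at least 3 rows required for PCA", "invalid_parameter")
  X <- feature_matrix(table)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (cc in seq_len(k)) {
    top <- which.max(abs(load[, cc]))
    if (load[top, cc] < 0) load[, cc] <- -load[, cc]
  }
  selected <- character(0)
  for (cc in seq_len(k)) {
    ord <- order(abs(load[, cc]), decreasing = TRUE)
    pick <- ord[!(feats[ord] %in% selected)][1]
    selected <- c(selected, feats[pick])
  }
  structure(list(selected = selected, loadings = load,
                 explained_variance = pc$sdev[seq_len(k)]^2),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("PCA-selected features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Pearson correlation map of a feature table
#'
#' @param table A `feature_table` with >= 3 rows.
#' @return Symmetric feature x feature correlation matrix with unit
#'   diagonal; rows/columns of constant features are set to 0 off-diagonal
#'   with a warning.
#' @export
correlation_map <- function(table) {
  if (nrow(table) < 3L)
    stop_dermoct("at least 3 rows required", "invalid_parameter")
  X <- feature_matrix(table)
  sds <- apply(X, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    warning(sprintf("constant feature(s) have undefined correlations: %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Classification metrics from confusion counts
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (positive = lesion
#'   class).
#' @return List: `accuracy = (tp+tn)/total`, `sensitivity = tp/(tp+fn)`,
#'   `specificity = tn/(tn+fp)`; undefined denominators yield `NA`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  for (v in c(tp, tn, fp, fn))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_dermoct("confusion counts must be non-negative numbers",
                   "invalid_parameter")
  total <- tp + tn + fp + fn
  if (total == 0) stop_dermoct("empty confusion matrix", "invalid_parameter")
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' ROC points and area from decision scores
#'
#' Sweeps thresholds over the unique scores (larger score = more
#' positive-like), yielding points monotone in false-positive rate, and
#' integrates the area under the curve by the trapezoid rule. The AUC equals
#' the Mann-Whitney U statistic divided by `n1 * n2` (ties counted half).
#'
#' @param scores Numeric decision values, one per sample.
#' @param labels Binary labels, same length.
#' @param positive The positive label; default the non-"healthy" level if
#'   present, otherwise the last sorted level.
#' @return List: `points` (data.frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L)
    stop_dermoct("both classes must be present", "label_error")
  if (is.null(positive))
    positive <- if ("healthy" %in% lv) setdiff(lv, "healthy") else lv[2]
  y <- labels == positive
  np <- sum(y); nn <- sum(!y)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / nn, numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, thr, -Inf))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Classifier hyperparameters for the cross-validated suite
#'
#' @param svm_cost Soft-margin cost for both SVMs (default 1).
#' @param qsvm_coef0 Polynomial kernel offset (default 1; degree fixed at 2).
#' @param knn_k Neighbors for KNN (default 5).
#' @param ann_size,ann_decay,ann_maxit Single hidden layer width (default
#'   10 logistic units), weight decay and iteration cap of the neural net.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(svm_cost = 1, qsvm_coef0 = 1, knn_k = 5L,
                              ann_size = 10L, ann_decay = 0.01,
                              ann_maxit = 200L) {
  structure(list(svm_cost = svm_cost, qsvm_coef0 = qsvm_coef0,
                 knn_k = check_count(knn_k, "knn_k", 1L),
                 ann_size = check_count(ann_size, "ann_size", 1L),
                 ann_decay = ann_decay,
                 ann_maxit = check_count(ann_maxit, "ann_maxit", 10L)),
            class = "classifier_config")
}

# One train/predict round per classifier. Returns predicted labels and a
# score oriented so that larger means more positive-like.
fit_predict <- function(name, Xtr, ytr, Xte, positive, cfg) {
  lv <- levels(ytr)
  other <- setdiff(lv, positive)
  switch(name,
    lsvm = , qsvm = {
      m <- if (name == "lsvm")
        e1071::svm(Xtr, ytr, kernel = "linear", cost = cfg$svm_cost,
                   scale = FALSE)
      else
        e1071::svm(Xtr, ytr, kernel = "polynomial", degree = 2,
                   coef0 = cfg$qsvm_coef0, gamma = 1 / ncol(Xtr),
                   cost = cfg$svm_cost, scale = FALSE)
      pr <- stats::predict(m, Xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      score <- if (grepl(paste0("^", positive, "/"), colnames(dv)[1]))
        dv[, 1] else -dv[, 1]
      list(pred = as.character(pr), score = as.numeric(score))
    },
    lr = {
      y01 <- as.numeric(ytr == positive)
      fit <- suppressWarnings(stats::glm.fit(cbind(1, Xtr), y01,
                                             family = stats::binomial()))
      eta <- as.numeric(cbind(1, Xte) %*% fit$coefficients)
      list(pred = ifelse(eta > 0, positive, other), score = eta)
    },
    knn = {
      pr <- class::knn(Xtr, Xte, ytr, k = cfg$knn_k, prob = TRUE)
      frac <- attr(pr, "prob")
      score <- ifelse(as.character(pr) == positive, frac, 1 - frac)
      list(pred = as.character(pr), score = score)
    },
    lda = {
      # collinear features are tolerated (lda drops them internally)
      m <- suppressWarnings(MASS::lda(Xtr, grouping = ytr))
      pr <- stats::predict(m, Xte)
      list(pred = as.character(pr$class),
           score = as.numeric(pr$posterior[, positive]))
    },
    ann = {
      y01 <- as.numeric(ytr == positive)
      m <- nnet::nnet(Xtr, y01, size = cfg$ann_size, decay = cfg$ann_decay,
                      maxit = cfg$ann_maxit, entropy = TRUE, trace = FALSE)
      sc <- as.numeric(stats::predict(m, Xte))
      list(pred = ifelse(sc > 0.5, positive, other), score = sc)
    },
    stop_dermoct(sprintf("unknown classifier '%s'", name), "invalid_parameter"))
}

#' Repeated stratified cross-validation of the classifier suite
#'
#' Runs `repeats` rounds of stratified `folds`-fold cross-validation for
#' each requested classifier: linear and quadratic (degree-2 polynomial
#' kernel) support vector machines, logistic regression, k-nearest
#' neighbors, linear discriminant analysis, and a single-hidden-layer neural
#' network. Per fold, z-score normalization parameters are fitted on the
#' training rows only and applied to the held-out rows; confusion counts are
#' accumulated and out-of-fold decision scores pooled for ROC analysis.
#'
#' @param table A `feature_table` with a binary `class_label` column and at
#'   least `folds` rows per class.
#' @param classifiers Subset of `c("lsvm","qsvm","lr","knn","lda","ann")`.
#' @param folds,repeats Cross-validation layout (default 10 x 10).
#' @param seed Integer master seed; fold assignments and all stochastic
#'   classifiers are reproducible given the seed.
#' @param positive Positive-class label; defaults to the non-"healthy" one.
#' @param config A [classifier_config()].
#' @return A `cv_report`: `summary` data.frame (per-classifier mean
#'   accuracy/sensitivity/specificity, error rate, per-repeat sd), `folds`
#'   (per-fold metrics), `roc` (per-classifier points + auc from pooled
#'   out-of-fold scores), `fold_assignments`, `seed`.
#' @export
cross_validate <- function(table, classifiers = c("lsvm", "qsvm", "lr", "knn",
                                                  "lda", "ann"),
                           folds = 10L, repeats = 10L, seed = 0L,
                           positive = NULL, config = classifier_config()) {
  folds <- check_count(folds, "folds", 2L)
  repeats <- check_count(repeats, "repeats", 1L)
  unknown <- setdiff(classifiers, c("lsvm", "qsvm", "lr", "knn", "lda", "ann"))
  if (length(unknown))
    stop_dermoct(sprintf("unknown classifier(s): %s",
                         paste(unknown, collapse = ", ")), "invalid_parameter")
  labels <- as.character(table$class_label)
  lv <- sort(unique(labels))
  if (length(lv) < 2L)
    stop_dermoct("classification needs two classes", "label_error")
  if (length(lv) > 2L)
    stop_dermoct("only binary classification is supported", "label_error")
  if (min(table(labels)) < folds)
    stop_dermoct(sprintf(paste("smallest class has %d samples, fewer than %d",
                               "folds; reduce 'folds' or enlarge the cohort"),
                         min(table(labels)), folds), "fold_error")
  if (is.null(positive))
    positive <- if ("healthy" %in% lv) setdiff(lv, "healthy") else lv[2]
  y <- factor(labels, levels = c(setdiff(lv, positive), positive))
  X <- feature_matrix(table)
  n <- nrow(X)

  set.seed(seed)
  assignments <- lapply(seq_len(repeats), function(rep) {
    fold <- integer(n)
    for (cl in lv) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })

  fold_rows <- list()
  scores <- stats::setNames(vector("list", length(classifiers)), classifiers)
  labs_pooled <- character(0)
  for (rep_i in seq_len(repeats)) {
    fold <- assignments[[rep_i]]
    for (f in seq_len(folds)) {
      te <- which(fold == f); tr <- which(fold != f)
      zp <- fit_zscore(X[tr, , drop = FALSE])
      Xtr <- apply_zscore(X[tr, , drop = FALSE], zp)
      Xte <- apply_zscore(X[te, , drop = FALSE], zp)
      labs_pooled <- c(labs_pooled, labels[te])
      for (cl in classifiers) {
        res <- fit_predict(cl, Xtr, y[tr], Xte, positive, config)
        tp <- sum(res$pred == positive & labels[te] == positive)
        tn <- sum(res$pred != positive & labels[te] != positive)
        fp <- sum(res$pred == positive & labels[te] != positive)
        fn <- sum(res$pred != positive & labels[te] == positive)
        fold_rows[[length(fold_rows) + 1L]] <-
          data.frame(classifier = cl, repeat_i = rep_i, fold = f,
                     tp = tp, tn = tn, fp = fp, fn = fn,
                     accuracy = (tp + tn) / length(te))
        scores[[cl]] <- c(scores[[cl]], res$score)
      }
    }
  }
  per_fold <- do.call(rbind, fold_rows)

  summarize <- function(cl) {
    d <- per_fold[per_fold$classifier == cl, ]
    m <- classification_metrics(sum(d$tp), sum(d$tn), sum(d$fp), sum(d$fn))
    rep_acc <- tapply(d$accuracy, d$repeat_i, mean)
    data.frame(classifier = cl, accuracy = mean(d$accuracy),
               sensitivity = m$sensitivity, specificity = m$specificity,
               error_rate = 1 - mean(d$accuracy),
               accuracy_sd_repeats = stats::sd(rep_acc))
  }
  summary_df <- do.call(rbind, lapply(classifiers, summarize))
  roc <- lapply(stats::setNames(classifiers, classifiers), function(cl)
    roc_points(scores[[cl]], labs_pooled, positive = positive))
  structure(list(summary = summary_df, folds = per_fold, roc = roc,
                 fold_assignments = assignments, seed = seed,
                 positive = positive, classifiers = classifiers),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Repeated cross-validation (seed %d, positive class '%s')\n",
              x$seed, x$positive))
  df <- x$summary
  df$auc <- vapply(df$classifier, function(cl) x$roc[[cl]]$auc, numeric(1))
  print(format(df, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) object$summary

#' @export
plot.cv_report <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "gray",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "Pooled out-of-fold ROC", ...)
  for (i in seq_along(x$roc))
    graphics::lines(x$roc[[i]]$points$fpr, x$roc[[i]]$points$tpr, col = i)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.2f)", names(x$roc),
                                    vapply(x$roc, `[[`, numeric(1), "auc")),
                   col = seq_along(x$roc), lty = 1, cex = 0.8)
  invisible(x)
}
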