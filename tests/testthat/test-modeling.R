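test_that("feature normalization z-scores with population std and is idempotent", {
  vectors <- list(c(f1 = 1, f2 = 5), c(f1 = 2, f2 = 6), c(f1 = 3, f2 = 9))
  small <- feature_table(vectors, lapply(1:3, function(i) roi(1, 1, 8, 8)))
  norm <- normalize_features(small)
  expect_equal(norm$f1, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  norm2 <- normalize_features(norm)
  expect_equal(as.matrix(norm2[, attr(norm2, "feature_names")]),
               as.matrix(norm[, attr(norm, "feature_names")]),
               tolerance = 1e-12)
  params <- attr(norm, "normalization_params")
  expect_equal(params$mean[params$feature == "f1"], 2)
})

test_that("constant features are dropped with a warning", {
  tab <- toy_feature_table(5, 3, seed = 3)
  tab$f2 <- 7
  expect_warning(norm <- normalize_features(tab), "constant")
  expect_false("f2" %in% attr(norm, "feature_names"))
  allconst <- tab
  for (f in attr(tab, "feature_names")) allconst[[f]] <- 1
  expect_error(normalize_features(allconst), class = "degenerate_table")
})

test_that("PCA selection finds planted dominant features deterministically", {
  set.seed(4)
  n <- 60
  X <- matrix(rnorm(n * 3, sd = 0.1), n, 3)
  X[, 1] <- rnorm(n, sd = 10)
  colnames(X) <- c("A", "B", "C")
  vectors <- lapply(seq_len(n), function(i) stats::setNames(X[i, ], colnames(X)))
  rois <- lapply(seq_len(n), function(i) roi(1, 1, 8, 8))
  tab <- feature_table(vectors, rois)
  sel <- pca_select_features(tab, 1)
  expect_equal(sel$selected, "A")
  # duplicated feature: never selected twice
  tab$B <- 2 * tab$A
  sel2 <- pca_select_features(tab, 2)
  expect_length(unique(sel2$selected), 2L)
  expect_error(pca_select_features(tab, 10), class = "invalid_parameter")
  # row order invariance
  perm <- tab[sample(seq_len(n)), ]
  attr(perm, "feature_names") <- attr(tab, "feature_names")
  class(perm) <- class(tab)
  expect_equal(pca_select_features(perm, 2)$selected, sel2$selected)
})

test_that("explained variance is non-increasing and loadings sign-fixed", {
  tab <- toy_feature_table(20, 6, seed = 5)
  sel <- pca_select_features(tab, 4)
  expect_true(all(diff(sel$explained_variance) <= 1e-9))
  for (k in seq_len(ncol(sel$loadings)))
    expect_gt(sel$loadings[which.max(abs(sel$loadings[, k])), k], 0)
})

test_that("correlation maps are symmetric with unit diagonal", {
  tab <- toy_feature_table(30, 4, seed = 6)
  cm <- correlation_map(tab)
  expect_equal(diag(cm), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm, t(cm))
  tab$f2 <- 2 * tab$f1
  cm2 <- correlation_map(tab)
  expect_equal(cm2["f1", "f2"], 1, tolerance = 1e-12)
  tab$f3 <- 5
  expect_warning(cm3 <- correlation_map(tab), "constant")
  expect_equal(cm3["f3", "f1"], 0)
  expect_equal(cm3["f3", "f3"], 1)
})

test_that("classification metrics follow the confusion-count definitions", {
  m <- classification_metrics(9, 8, 2, 1)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  perfect <- classification_metrics(5, 5, 0, 0)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1, specificity = 1))
  degen <- classification_metrics(0, 10, 3, 0)
  expect_true(is.na(degen$sensitivity))
  expect_error(classification_metrics(-1, 1, 1, 1), class = "invalid_parameter")
})

test_that("ROC points and AUC behave at the extremes and match Mann-Whitney", {
  labels <- rep(c("healthy", "lesion"), each = 10)
  sep <- c(rnorm(10, 0), rnorm(10, 100))
  expect_equal(roc_points(sep, labels)$auc, 1)
  expect_equal(roc_points(-sep, labels)$auc, 0)
  set.seed(10)
  scores <- rnorm(20)
  r <- roc_points(scores, labels)
  u <- sum(rank(scores)[labels == "lesion"]) - 10 * 11 / 2
  expect_equal(r$auc, u / 100, tolerance = 1e-12)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_error(roc_points(scores, rep("lesion", 20)), class = "label_error")
})

test_that("cross-validation separates a strong single-feature signal", {
  tab <- toy_feature_table(30, 5, shift = 10, seed = 7)
  cv <- cross_validate(tab, classifiers = c("lsvm", "qsvm", "lr", "knn",
                                            "lda", "ann"),
                       folds = 5, repeats = 2, seed = 1)
  expect_true(all(cv$summary$accuracy >= 0.95))
  expect_true(all(cv$summary$sensitivity >= 0.9))
  expect_equal(cv$summary$error_rate, 1 - cv$summary$accuracy)
  aucs <- vapply(cv$roc, `[[`, numeric(1), "auc")
  expect_true(all(aucs >= 0.95))
})

test_that("cross-validation is reproducible and validates its inputs", {
  tab <- toy_feature_table(15, 4, shift = 2, seed = 8)
  cv1 <- cross_validate(tab, classifiers = c("lsvm", "ann"), folds = 5,
                        repeats = 2, seed = 9)
  cv2 <- cross_validate(tab, classifiers = c("lsvm", "ann"), folds = 5,
                        repeats = 2, seed = 9)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  expect_identical(cv1$summary, cv2$summary)
  single <- tab[tab$class_label == "healthy", ]
  attr(single, "feature_names") <- attr(tab, "feature_names")
  class(single) <- class(tab)
  expect_error(cross_validate(single, "lsvm"), class = "label_error")
  expect_error(cross_validate(tab, "lsvm", folds = 40), class = "fold_error")
  expect_error(cross_validate(tab, "boost"), class = "invalid_parameter")
})

test_that("fold normalization parameters never see held-out rows", {
  tab <- toy_feature_table(15, 3, shift = 1, seed = 11)
  X <- as.matrix(tab[, attr(tab, "feature_names")])
  fold <- rep(1:3, length.out = nrow(X))
  tr <- which(fold != 1)
  par1 <- dermoct:::fit_zscore(X[tr, ])
  Xcorrupt <- X
  Xcorrupt[fold == 1, ] <- 1e6
  par2 <- dermoct:::fit_zscore(Xcorrupt[tr, ])
  expect_identical(par1, par2)
})

test_that("stratified folds keep class balance within one sample", {
  tab <- toy_feature_table(20, 3, seed = 12)
  cv <- cross_validate(tab, "lda", folds = 5, repeats = 1, seed = 3)
  fold <- cv$fold_assignments[[1]]
  for (f in 1:5) {
    cls <- table(tab$class_label[fold == f])
    expect_lte(abs(diff(as.numeric(cls))), 1)
  }
})
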