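make_blobs <- function(n_per_class = 50, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      stat_x = c(rnorm(n_per_class), rnorm(n_per_class) + sep),
      stat_y = c(rnorm(n_per_class), rnorm(n_per_class) + sep),
      label = rep(0:1, each = n_per_class)
    )
  })
}

test_that("feature fusion concatenates families in fixed order", {
  tab <- tibble::tibble(label = rep(0:1, 3),
                        stat_mean = rnorm(6), stat_variance = rnorm(6),
                        glcm_inertia = rnorm(6), shape_solidity = rnorm(6))
  f <- fuse_features(tab, c("shape", "stat"))
  expect_identical(names(f), c("label", "stat_mean", "stat_variance",
                               "shape_solidity"))
  only <- fuse_features(tab, "glcm")
  expect_identical(setdiff(names(only), "label"), "glcm_inertia")
  expect_error(fuse_features(tab, character()), "no families selected")
  expect_error(fuse_features(tab, "wavelet"), "unknown feature family")
  expect_error(fuse_features(tab, c("stat", "hog")), "absent")
})

test_that("a full feature table fuses to the documented widths", {
  ph <- generate_phantom(phantom_spec("benign", seed = 31))
  sp <- ph$spec
  rec <- featurize_single(ph$pixels,
                          list(ref_id = "p1", center_x = sp$center[2],
                               center_y = sp$center[1],
                               radius = sp$base_radius + 3),
                          origin = "top-left")
  feature_cols <- setdiff(names(rec), c("ref_id", "mask_area"))
  expect_length(feature_cols, 6 + 7 + 1764 + 256 + 7) # 2040
  expect_length(setdiff(names(fuse_features(rec, "shape")),
                        c("ref_id", "mask_area")), 7)
  expect_length(setdiff(names(fuse_features(rec, c("stat", "glcm"))),
                        c("ref_id", "mask_area")), 13)
})

test_that("k-fold splits partition rows with balanced strata", {
  lab <- rep(0:1, each = 50)
  folds <- kfold_splits(lab, k = 10, seed = 3)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), 1:100)
  for (f in folds) {
    expect_length(f, 10)
    expect_equal(sum(lab[f] == 0), 5)
  }
  # uneven n: fold sizes differ by at most one, union is everything
  lab2 <- rep(0:1, c(58, 51))
  folds2 <- kfold_splits(lab2, k = 10, seed = 3)
  sizes <- lengths(folds2)
  expect_true(all(sizes %in% c(10, 11)))
  expect_setequal(unlist(folds2), seq_along(lab2))
  expect_equal(sum(duplicated(unlist(folds2))), 0)
  # determinism
  expect_identical(folds, kfold_splits(lab, k = 10, seed = 3))
  expect_error(kfold_splits(rep(0:1, c(4, 96)), k = 10), "smallest class")
  expect_error(kfold_splits(lab, k = 1), "at least 2")
})

test_that("knn distance is Euclidean", {
  expect_equal(knn_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(knn_distance(1:7, 1:7), 0)
  for (i in 1:10) {
    u <- withr::with_seed(i, rnorm(10)); v <- withr::with_seed(i + 50, rnorm(10))
    expect_equal(knn_distance(u, v), sqrt(sum((u - v)^2)), tolerance = 1e-12)
  }
  expect_error(knn_distance(1:3, 1:4), "length")
})

test_that("all five classifiers separate well-separated Gaussian blobs", {
  tab <- make_blobs(50, sep = 6, seed = 7)
  tr <- tab[c(1:40, 51:90), ]
  te <- tab[c(41:50, 91:100), ]
  for (clf in c("knn", "svm", "lda", "dtree", "ensemble")) {
    pred <- train_predict(clf, tr, te)
    expect_gte(mean(pred == te$label), 0.95)
  }
  # bagged-tree ensemble variant also works
  predb <- train_predict("ensemble", tr, te, ensemble_type = "bagged-tree")
  expect_gte(mean(predb == te$label), 0.95)
  expect_error(train_predict("knn", tr[tr$label == 0, ], te), "single class")
})

test_that("knn agrees with the class package on tie-free neighbourhoods", {
  tab <- make_blobs(25, sep = 3, seed = 15)
  tr <- tab[c(1:20, 26:45), ]
  te <- tab[c(21:25, 46:50), ]
  Xtr <- scale(as.matrix(tr[, 1:2]))
  Xte <- scale(as.matrix(te[, 1:2]),
               center = attr(Xtr, "scaled:center"),
               scale = attr(Xtr, "scaled:scale"))
  ref <- as.integer(as.character(class::knn(Xtr, Xte, cl = tr$label, k = 5)))
  expect_equal(train_predict("knn", tr, te), ref)
})

test_that("knn honours an exact training-point match and lda matches MASS", {
  tab <- make_blobs(20, sep = 8, seed = 9)
  tr <- tab[c(1:19, 21:39), ]
  te <- tr[c(1, 25), ]
  expect_equal(train_predict("knn", tr, te, k_neighbors = 1),
               te$label)
  # on well-conditioned data our ridged Fisher rule agrees with MASS::lda
  fitm <- MASS::lda(tr[, c("stat_x", "stat_y")], grouping = tr$label)
  predm <- as.integer(as.character(
    predict(fitm, tab[, c("stat_x", "stat_y")])$class))
  ours <- train_predict("lda", tr, tab, standardize = FALSE)
  expect_equal(ours, predm)
  # Woodbury branch (p > n) agrees with the direct solve on duplicated runs
  wide <- dplyr::bind_cols(tab,
    tibble::as_tibble(withr::with_seed(4,
      matrix(rnorm(40 * 60), 40, 60,
             dimnames = list(NULL, sprintf("stat_r%02d", 1:60))))))
  pw <- train_predict("lda", wide[1:30, ], wide[31:40, ])
  expect_true(all(pw %in% 0:1))
})

test_that("ensemble vote follows the majority with svm tie-break", {
  # construct a case where knn and lda agree: expect their common label
  tab <- make_blobs(30, sep = 5, seed = 11)
  tr <- tab[c(1:25, 31:55), ]
  te <- tab[c(26:30, 56:60), ]
  pk <- train_predict("knn", tr, te)
  ps <- train_predict("svm", tr, te)
  pl <- train_predict("lda", tr, te)
  pe <- train_predict("ensemble", tr, te)
  expect_equal(pe, as.integer(pk + ps + pl >= 2))
})

test_that("confusion metrics reproduce closed-form and reported values", {
  perfect <- confusion_and_metrics(rep(0:1, each = 50), rep(0:1, each = 50))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$mcc, 100)

  # the shape-family ensemble confusion matrix on 109 ROIs
  truth <- rep(c(1, 0), c(51, 58))
  pred <- rep(c(1, 0, 0, 1), c(48, 3, 57, 1))
  m <- confusion_and_metrics(truth, pred)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(48, 3, 57, 1))
  expect_equal(m$accuracy, 96.33028, tolerance = 1e-5)
  expect_equal(m$sensitivity, 94.11765, tolerance = 1e-5)
  expect_equal(m$specificity, 98.27586, tolerance = 1e-5)
  expect_equal(m$mcc, 92.67591, tolerance = 1e-5)

  allneg <- confusion_and_metrics(rep(0:1, each = 25), rep(0, 50))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 100)
  expect_equal(allneg$mcc, 0)
  expect_error(confusion_and_metrics(0:1, 0), "length")
})

test_that("MCC is symmetric under simultaneous class swap", {
  truth <- rep(c(1, 0), c(51, 58))
  pred <- rep(c(1, 0, 0, 1), c(48, 3, 57, 1))
  a <- confusion_and_metrics(truth, pred)$mcc
  b <- confusion_and_metrics(1 - truth, 1 - pred)$mcc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("kappa matches its definition and degenerate conventions", {
  expect_equal(kappa_statistic(rep(0:1, 10), rep(0:1, 10)), 1)
  # independent predictions: agreement at chance level
  truth <- rep(c(0, 1), each = 4)
  pred <- rep(c(0, 1, 0, 1), 2) # g0 = ge = 0.5
  expect_equal(kappa_statistic(truth, pred), 0)
  expect_equal(kappa_statistic(rep(1, 5), rep(1, 5)), 1)
  truth2 <- rep(c(1, 0), c(51, 58))
  pred2 <- rep(c(1, 0, 0, 1), c(48, 3, 57, 1))
  expect_equal(kappa_statistic(truth2, pred2), 0.9261267, tolerance = 1e-6)
})

test_that("cross-validated evaluation pools counts and keeps identities", {
  tab <- make_blobs(20, sep = 5, seed = 13)
  ev <- evaluate(tab, k = 5, seed = 2, classifiers = c("knn", "svm"))
  res <- tidy(ev)
  expect_equal(nrow(res), 2)
  expect_true(all(res$tp + res$fp + res$tn + res$fn == 40))
  expect_metric_identity(ev)
  expect_s3_class(glance(ev), "tbl_df")
  # leave-one-out: n singleton folds still partition and pool to n
  loo <- evaluate(tab[c(1:10, 21:30), ], k = 20, seed = 2,
                  stratified = FALSE, classifiers = "knn")
  expect_equal(sum(tidy(loo)[, c("tp", "fp", "tn", "fn")]), 20)
  # determinism of the whole report
  ev2 <- evaluate(tab, k = 5, seed = 2, classifiers = c("knn", "svm"))
  expect_identical(tidy(ev), tidy(ev2))
})

test_that("training-fold standardisation never sees test statistics", {
  tab <- make_blobs(15, sep = 4, seed = 21)
  folds <- kfold_splits(tab$label, k = 5, seed = 8)
  fold <- folds[[1]]
  tr <- tab[-fold, ]
  te <- tab[fold, ]
  # shifting the test fold by a huge constant must not change the fitted
  # training standardisation, hence predictions for the training points of a
  # 1-nn self-classification stay identical
  te_shifted <- te
  te_shifted$stat_x <- te_shifted$stat_x + 1e6
  p1 <- train_predict("knn", tr, tr, k_neighbors = 1)
  # recompute with a polluted test fold present in the same session
  invisible(train_predict("knn", tr, te_shifted))
  p2 <- train_predict("knn", tr, tr, k_neighbors = 1)
  expect_identical(p1, p2)
  expect_equal(p1, tr$label) # 1-nn reproduces its own training labels
})
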