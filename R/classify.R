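FEATURE_FAMILIES <- c("stat", "glcm", "hog", "cslbp", "shape")

feature_family_cols <- function(table, family) {
  grep(paste0("^", family, "_"), names(table), value = TRUE)
}

meta_cols <- function(table) {
  intersect(c("ref_id", "label", "mask_area"), names(table))
}

#' Fuse feature families into a composite feature table
#'
#' Selects the requested feature families (column prefixes `stat_`, `glcm_`,
#' `hog_`, `cslbp_`, `shape_`) and concatenates them column-wise in the
#' fixed family order above, keeping row order, labels and provenance
#' columns unchanged.
#'
#' @param table Feature tibble with a `label` column (0 benign, 1 malignant)
#'   and prefixed feature columns, e.g. from [run_pipeline()] or
#'   [featurize_single()].
#' @param families Character vector, a subset of
#'   `c("stat", "glcm", "hog", "cslbp", "shape")`.
#' @return A tibble with the metadata columns plus the selected feature
#'   columns.
#' @export
fuse_features <- function(table, families) {
  if (length(families) == 0L) stop("no families selected", call. = FALSE)
  bad <- setdiff(families, FEATURE_FAMILIES)
  if (length(bad) > 0L) {
    stop("unknown feature family: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  families <- FEATURE_FAMILIES[FEATURE_FAMILIES %in% families]
  cols <- unlist(lapply(families, feature_family_cols, table = table))
  missing <- families[!vapply(families, function(f)
    length(feature_family_cols(table, f)) > 0L, logical(1L))]
  if (length(missing) > 0L) {
    stop("requested families absent from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  table[, c(meta_cols(table), cols), drop = FALSE]
}

#' Stratified k-fold split indices
#'
#' Partitions row indices into `k` disjoint test folds. Stratified folds
#' (the default) balance the two classes so per-class fold counts differ by
#' at most one. Deterministic for a fixed seed.
#'
#' @param labels Vector of class labels (one per row).
#' @param k Number of folds, at least 2, and at most the smallest class
#'   count when stratified.
#' @param seed Integer seed.
#' @param stratified Stratify folds by label.
#' @return A list of `k` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
kfold_splits <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (stratified) {
    if (k > min(table(labels))) {
      stop("cross-validation k (", k, ") exceeds the smallest class count (",
           min(table(labels)), ")", call. = FALSE)
    }
  } else if (k > n) {
    stop("k exceeds the number of rows", call. = FALSE)
  }
  folds <- vector("list", k)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      offset <- 0L # rotate the deal so per-class remainders spread over folds
      for (cls in unique(labels)) {
        idx <- sample(which(labels == cls))
        assign_to <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
        offset <- (offset + length(idx)) %% k
      }
    } else {
      idx <- sample(n)
      assign_to <- rep_len(seq_len(k), n)
      for (f in seq_len(k)) folds[[f]] <- idx[assign_to == f]
    }
  })
  lapply(folds, sort)
}

#' Euclidean feature-space distance
#'
#' @param u,v Numeric feature vectors of equal length.
#' @return `sqrt(sum((u - v)^2))`.
#' @export
knn_distance <- function(u, v) {
  if (length(u) != length(v)) stop("feature vectors differ in length", call. = FALSE)
  sqrt(sum((u - v)^2))
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(X, fit) {
  sweep(sweep(X, 2L, fit$mean, "-"), 2L, fit$sd, "/")
}

split_xy <- function(table) {
  feat <- setdiff(names(table), c("ref_id", "label", "mask_area"))
  list(X = as.matrix(table[, feat, drop = FALSE]),
       y = as.integer(table$label))
}

predict_knn <- function(Xtr, ytr, Xte, k_neighbors = 5L) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  d2[d2 < 0] <- 0
  apply_row <- function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2))) # stable: index breaks distance ties
    nn <- ytr[ord[seq_len(min(k_neighbors, length(ytr)))]]
    votes <- table(nn)
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) as.integer(as.character(nn[1L])) else as.integer(top)
  }
  vapply(seq_len(nrow(Xte)), apply_row, integer(1L))
}

# Fisher LDA with pooled covariance and a diagonal ridge; Woodbury identity
# when the feature dimension exceeds the sample count
lda_fit_predict <- function(Xtr, ytr, Xte, ridge = 1e-6) {
  i0 <- ytr == 0L; i1 <- ytr == 1L
  mu0 <- colMeans(Xtr[i0, , drop = FALSE])
  mu1 <- colMeans(Xtr[i1, , drop = FALSE])
  Xc <- rbind(sweep(Xtr[i0, , drop = FALSE], 2L, mu0, "-"),
              sweep(Xtr[i1, , drop = FALSE], 2L, mu1, "-"))
  nu <- nrow(Xtr) - 2L
  b <- mu1 - mu0
  p <- ncol(Xtr)
  w <- if (nu <= 0L) {
    b / ridge
  } else if (p <= nrow(Xtr)) {
    S <- crossprod(Xc) / nu + diag(ridge, p)
    solve(S, b)
  } else {
    # (ridge I + Xc'Xc/nu)^{-1} b via the low-rank identity
    G <- Xc %*% t(Xc)
    A <- diag(ridge * nu, nrow(Xc)) + G
    (b - t(Xc) %*% solve(A, Xc %*% b)) / ridge
  }
  w <- as.numeric(w)
  pi0 <- mean(i0); pi1 <- mean(i1)
  thresh <- sum((mu0 + mu1) / 2 * w) - log(pi1 / pi0)
  as.integer(Xte %*% w > thresh)
}

predict_dtree <- function(Xtr, ytr, Xte) {
  tr <- as.data.frame(Xtr)
  te <- as.data.frame(Xte)
  names(te) <- names(tr)
  tr$.outcome <- factor(ytr, levels = c(0L, 1L))
  fit <- rpart::rpart(
    .outcome ~ ., data = tr, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(minsplit = 4L, minbucket = 2L, cp = 0.01,
                                   xval = 0L, maxcompete = 0L, maxsurrogate = 0L)
  )
  as.integer(as.character(predict(fit, te, type = "class")))
}

predict_svm <- function(Xtr, ytr, Xte, cost = 1) {
  fit <- e1071::svm(x = Xtr, y = factor(ytr, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  as.integer(as.character(predict(fit, Xte)))
}

#' Train a classifier on one fold and predict the test fold
#'
#' The five classifiers of the evaluation protocol: `knn` (majority vote
#' among the `k_neighbors = 5` Euclidean nearest neighbours, ties broken
#' toward the single nearest), `svm` (soft-margin linear SVM, cost 1),
#' `lda` (Fisher discriminant with pooled covariance and ridge `1e-6`),
#' `dtree` (Gini-impurity top-down tree, minimum leaf 2), and `ensemble`
#' (majority vote of knn, svm and lda, ties toward svm; or bagged trees with
#' `ensemble_type = "bagged-tree"`). Features are z-scored with statistics
#' fitted on the training fold only.
#'
#' @param classifier One of `"knn"`, `"svm"`, `"lda"`, `"dtree"`,
#'   `"ensemble"`.
#' @param train,test Feature tibbles (see [fuse_features()]); `train` must
#'   contain both classes.
#' @param k_neighbors KNN neighbourhood size.
#' @param cost SVM soft-margin cost.
#' @param ridge LDA covariance ridge.
#' @param standardize Z-score features on training statistics.
#' @param ensemble_type `"vote"` (knn + svm + lda majority) or
#'   `"bagged-tree"` (25 bootstrap Gini trees, seeded).
#' @param seed Seed for the bagged-tree ensemble resampling.
#' @return Integer vector of predicted labels (0/1), one per test row.
#' @export
train_predict <- function(classifier = c("knn", "svm", "lda", "dtree", "ensemble"),
                          train, test, k_neighbors = 5L, cost = 1,
                          ridge = 1e-6, standardize = TRUE,
                          ensemble_type = c("vote", "bagged-tree"),
                          seed = 1L) {
  classifier <- match.arg(classifier)
  ensemble_type <- match.arg(ensemble_type)
  tr <- split_xy(train)
  te <- split_xy(test)
  if (length(unique(tr$y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  if (standardize) {
    fit <- standardize_fit(tr$X)
    tr$X <- standardize_apply(tr$X, fit)
    te$X <- standardize_apply(te$X, fit)
  }
  switch(classifier,
    knn = predict_knn(tr$X, tr$y, te$X, k_neighbors),
    svm = predict_svm(tr$X, tr$y, te$X, cost),
    lda = lda_fit_predict(tr$X, tr$y, te$X, ridge),
    dtree = predict_dtree(tr$X, tr$y, te$X),
    ensemble = {
      if (ensemble_type == "bagged-tree") {
        preds <- withr::with_seed(as.integer(seed), {
          vapply(seq_len(25L), function(b) {
            idx <- sample(nrow(tr$X), replace = TRUE)
            if (length(unique(tr$y[idx])) < 2L) idx <- seq_len(nrow(tr$X))
            predict_dtree(tr$X[idx, , drop = FALSE], tr$y[idx], te$X)
          }, integer(nrow(te$X)))
        })
        as.integer(rowMeans(matrix(preds, nrow = nrow(te$X))) > 0.5)
      } else {
        pk <- predict_knn(tr$X, tr$y, te$X, k_neighbors)
        ps <- predict_svm(tr$X, tr$y, te$X, cost)
        pl <- lda_fit_predict(tr$X, tr$y, te$X, ridge)
        votes <- pk + ps + pl
        ifelse(votes >= 2L, 1L, 0L)
      }
    }
  )
}

#' Confusion counts and classification metrics
#'
#' Pools true and predicted 0/1 labels (malignant = positive) into a
#' confusion matrix and derives accuracy, sensitivity, specificity and the
#' Matthews correlation coefficient, each expressed in percent. The MCC
#' denominator takes the square root of the product of the four marginal
#' sums; any zero denominator yields 0.
#'
#' @param truth,pred Equal-length vectors of labels in `{0, 1}`.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `mcc` (percent).
#' @examples
#' confusion_and_metrics(rep(c(1, 0), c(51, 58)),
#'                       rep(c(1, 0, 0, 1), c(48, 3, 57, 1)))
#' @export
confusion_and_metrics <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  tp <- sum(truth == 1L & pred == 1L)
  tn <- sum(truth == 0L & pred == 0L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  denom2 <- as.numeric(tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  mcc <- if (denom2 == 0) 0 else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  }
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = 100 * safe_div(tp + tn, tp + tn + fp + fn),
    sensitivity = 100 * safe_div(tp, tp + fn),
    specificity = 100 * safe_div(tn, tn + fp),
    mcc = 100 * mcc
  )
}

#' Cohen's kappa between truth and predictions
#'
#' Chance-corrected agreement `(g0 - ge) / (1 - ge)` where `g0` is the
#' observed agreement fraction and `ge` the expected agreement from the
#' label marginals; 1 when both are degenerate and fully correct.
#'
#' @inheritParams confusion_and_metrics
#' @return Kappa, at most 1.
#' @export
kappa_statistic <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  n <- length(truth)
  g0 <- mean(truth == pred)
  classes <- union(unique(truth), unique(pred))
  ge <- sum(vapply(classes, function(cl) {
    mean(truth == cl) * mean(pred == cl)
  }, numeric(1L)))
  if (ge == 1) return(1)
  (g0 - ge) / (1 - ge)
}

#' Cross-validated evaluation of feature families and classifiers
#'
#' Runs each requested classifier on each requested feature-family set under
#' stratified k-fold cross-validation: test-fold predictions are pooled over
#' the k folds, then one confusion matrix and all metrics (accuracy,
#' sensitivity, specificity, MCC in percent, and Cohen's kappa) are computed
#' from the pooled predictions. Fold assignment and standardisation are
#' refitted per training fold so no test statistics leak into training.
#'
#' @param table Feature tibble with `label` and prefixed feature columns.
#' @param family_sets Named list of family subsets to evaluate; defaults to
#'   every family present plus, when more than one is present, their fusion
#'   (`"fused"`).
#' @param classifiers Subset of `c("knn", "svm", "lda", "dtree",
#'   "ensemble")`.
#' @param k,seed,stratified See [kfold_splits()].
#' @param standardize Z-score per training fold.
#' @param ... Passed to [train_predict()] (e.g. `k_neighbors`, `cost`).
#' @return An object of class `cad_eval`; use [tidy()] for the per-run
#'   metric tibble, [glance()] for a one-row summary, and [autoplot()] for
#'   a metric chart.
#' @export
evaluate <- function(table, family_sets = NULL,
                     classifiers = c("knn", "svm", "lda", "dtree", "ensemble"),
                     k = 10L, seed = 1L, stratified = TRUE,
                     standardize = TRUE, ...) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (anyNA(table)) stop("feature table contains missing values", call. = FALSE)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  present <- FEATURE_FAMILIES[vapply(FEATURE_FAMILIES, function(f)
    length(feature_family_cols(table, f)) > 0L, logical(1L))]
  if (is.null(family_sets)) {
    family_sets <- as.list(present)
    names(family_sets) <- present
    if (length(present) > 1L) family_sets$fused <- present
  }
  labels <- as.integer(table$label)
  folds <- kfold_splits(labels, k = k, seed = seed, stratified = stratified)
  rows <- list()
  for (set_name in names(family_sets)) {
    ftab <- fuse_features(table, family_sets[[set_name]])
    for (clf in classifiers) {
      pred <- integer(length(labels))
      for (fold in folds) {
        pred[fold] <- train_predict(clf, ftab[-fold, , drop = FALSE],
                                    ftab[fold, , drop = FALSE],
                                    standardize = standardize, seed = seed, ...)
      }
      met <- confusion_and_metrics(labels, pred)
      met$kappa <- kappa_statistic(labels, pred)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(family_set = set_name, classifier = clf), met
      )
    }
  }
  structure(
    list(results = dplyr::bind_rows(rows), k = k, seed = seed,
         n = length(labels), family_sets = family_sets),
    class = "cad_eval"
  )
}

#' @export
print.cad_eval <- function(x, ...) {
  cat("<cad_eval> ", x$n, " ROIs, ", x$k, "-fold stratified CV (seed ",
      x$seed, ")\n", sep = "")
  print(x$results, n = Inf)
  invisible(x)
}
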