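# Classification evaluation of subnetwork markers: activity feature matrices,
# 10-fold cross-validation with two dissimilar classifiers (a recursive-
# partitioning decision tree and a radial-basis-function network), and
# train-on-one-half / test-on-the-other cross-testing with leakage-free
# z-scoring.

#' Build a feature matrix from subnetworks or a gene list
#'
#' Subnetwork features are the per-sample activity (mean member z-score) of
#' each selected group; gene-list features are the per-gene z-scores
#' themselves. Member genes missing from the dataset are dropped with a
#' warning; a fully missing subnetwork is an error.
#'
#' @param ds An `ExpressionDataset` (z-scored internally).
#' @param subnets A `consensus_result` (its selected groups), a
#'   `subnetwork_set`, a list of gene-id vectors, or a plain character vector
#'   of gene ids (one feature per gene).
#' @return A `feature_matrix`: list with `values` (features x samples) and
#'   `labels`.
#' @export
build_features <- function(ds, subnets) {
  ds_z <- .as_zscored(ds)
  gene_sets <- .as_gene_sets(subnets)
  if (is.character(gene_sets)) {  # plain gene list -> per-gene features
    missing <- setdiff(gene_sets, gene_ids(ds_z))
    if (length(missing) == length(gene_sets))
      stop("feature error: none of the genes are measured")
    if (length(missing))
      warning("dropping ", length(missing), " unmeasured gene(s)")
    keep <- setdiff(gene_sets, missing)
    vals <- ds_z$values[keep, , drop = FALSE]
  } else {
    if (!length(gene_sets)) stop("feature error: no subnetworks given")
    vals <- matrix(0, length(gene_sets), n_samples(ds_z),
                   dimnames = list(names(gene_sets) %||%
                                     sprintf("subnetwork_%03d", seq_along(gene_sets)),
                                   sample_ids(ds_z)))
    for (i in seq_along(gene_sets)) {
      members <- gene_sets[[i]]
      present <- intersect(members, gene_ids(ds_z))
      if (!length(present))
        stop("feature error: subnetwork ", i, " has zero measured members")
      if (length(present) < length(members))
        warning("subnetwork ", i, ": dropping ",
                length(members) - length(present), " unmeasured member(s)")
      vals[i, ] <- subnetwork_activity(ds_z, present)
    }
  }
  structure(list(values = vals, labels = ds_z$labels),
            class = "feature_matrix")
}

.as_gene_sets <- function(subnets) {
  if (inherits(subnets, "consensus_result"))
    return(lapply(subnets$selected, `[[`, "members"))
  if (inherits(subnets, "subnetwork_set"))
    return(lapply(subnets$subnetworks, `[[`, "members"))
  if (is.character(subnets)) return(subnets)
  if (is.list(subnets)) return(lapply(subnets, as.character))
  stop("unsupported subnetwork specification")
}

# ---- classifiers ----------------------------------------------------------

# samples x features data.frame with stable syntactic column names
.feature_df <- function(fm_values) {
  df <- as.data.frame(t(fm_values))
  colnames(df) <- sprintf("F%03d", seq_len(ncol(df)))
  df
}

.fit_classifier <- function(classifier, X, y) {
  switch(classifier,
    tree = {
      dat <- cbind(.class = y, X)
      rpart::rpart(.class ~ ., data = dat, method = "class",
                   control = rpart::rpart.control(xval = 0, cp = 0.01))
    },
    rbf = .fit_rbf(X, y),
    stop("unknown classifier '", classifier, "'"))
}

.predict_classifier <- function(classifier, fit, X) {
  switch(classifier,
    tree = as.character(predict(fit, newdata = X, type = "class")),
    rbf = .predict_rbf(fit, X))
}

# RBF network: k-means centers on the training points, Gaussian hidden units
# with a shared width set to the mean inter-center distance, and a linear
# logistic output layer. Center count = min(10, floor(sqrt(n_train))).
.fit_rbf <- function(X, y) {
  Xm <- as.matrix(X)
  n <- nrow(Xm)
  nc <- max(1L, min(10L, as.integer(floor(sqrt(n))), nrow(unique(Xm))))
  km <- suppressWarnings(kmeans(Xm, centers = nc, nstart = 5, iter.max = 50))
  centers <- km$centers
  sigma <- if (nc > 1) mean(dist(centers)) else {
    mean(sqrt(rowSums(sweep(Xm, 2, centers[1, ])^2)))
  }
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  Phi <- .rbf_design(Xm, centers, sigma)
  yy <- as.integer(y == levels(y)[2])
  fit <- suppressWarnings(glm.fit(cbind(1, Phi), yy, family = binomial()))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  list(centers = centers, sigma = sigma, coef = coefs, levels = levels(y))
}

.rbf_design <- function(X, centers, sigma) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * X %*% t(centers)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

.predict_rbf <- function(fit, X) {
  Phi <- .rbf_design(as.matrix(X), fit$centers, fit$sigma)
  eta <- drop(cbind(1, Phi) %*% fit$coef)
  fit$levels[(eta > 0) + 1L]
}

# ---- cross-validation -----------------------------------------------------

#' k-fold cross-validated classification accuracy
#'
#' Samples are shuffled (seeded) and divided into `k` uniformly sized folds
#' (sizes differing by at most 1; optionally stratified by class); each fold
#' is predicted by a classifier trained on the other `k - 1`.
#'
#' @param fm A `feature_matrix` from [build_features()].
#' @param classifier `"tree"` (recursive-partitioning decision tree) or
#'   `"rbf"` (RBF network with k-means centers).
#' @param k Number of folds.
#' @param seed Seed for the fold shuffle (and the RBF k-means).
#' @param stratified Stratify folds by class (off by default).
#' @param skip_bad_folds If a training fold misses a class: error (default) or
#'   skip that fold with a warning.
#' @return A `cv_result`: `classifier`, `fold_accuracies` (percent),
#'   `mean_accuracy_pct` (mean of folds), `pooled_accuracy_pct` (all held-out
#'   predictions pooled), `k`, `seed`.
#' @export
kfold_cv <- function(fm, classifier = c("tree", "rbf"), k = 10, seed = 1,
                     stratified = FALSE, skip_bad_folds = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(inherits(fm, "feature_matrix"))
  n <- ncol(fm$values)
  if (n < k) stop("need at least k samples")
  df <- .feature_df(fm$values)
  y <- fm$labels
  with_seed(seed, {
    fold_of <- integer(n)
    if (stratified) {
      for (lev in levels(y)) {
        idx <- sample(which(y == lev))
        fold_of[idx] <- rep(seq_len(k), length.out = length(idx))
      }
    } else {
      fold_of[sample(n)] <- rep(seq_len(k), length.out = n)
    }
    fold_acc <- rep(NA_real_, k)
    n_correct <- 0; n_pred <- 0
    for (f in seq_len(k)) {
      test_i <- which(fold_of == f)
      train_i <- which(fold_of != f)
      if (nlevels(droplevels(y[train_i])) < 2) {
        msg <- paste0("fold ", f, ": training data misses a class")
        if (skip_bad_folds) { warning(msg); next } else stop("fold error: ", msg)
      }
      fit <- .fit_classifier(classifier, df[train_i, , drop = FALSE],
                             droplevels(y[train_i]))
      pred <- .predict_classifier(classifier, fit, df[test_i, , drop = FALSE])
      hits <- pred == as.character(y[test_i])
      fold_acc[f] <- 100 * mean(hits)
      n_correct <- n_correct + sum(hits)
      n_pred <- n_pred + length(hits)
    }
    structure(list(classifier = classifier,
                   fold_accuracies = fold_acc,
                   mean_accuracy_pct = mean(fold_acc, na.rm = TRUE),
                   pooled_accuracy_pct = 100 * n_correct / n_pred,
                   k = k, seed = seed),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: %.2f%% mean accuracy over %d folds\n",
              x$classifier, x$mean_accuracy_pct, x$k))
  invisible(x)
}

#' Train on one dataset, test on another
#'
#' The classifier is trained on all of `train_ds` and its accuracy reported on
#' `test_ds`. Z-scoring parameters (per-gene mean and SD) are learned on the
#' training data only and applied unchanged to the test data, so no test-set
#' statistic leaks into the features.
#'
#' @param train_ds,test_ds `ExpressionDataset`s sharing the subnetwork genes.
#'   Case samples should be disjoint (shared controls, as in half-to-half
#'   validation, are fine); overlapping case ids trigger a warning.
#' @param subnets Subnetworks accepted by [build_features()].
#' @param classifier `"tree"` or `"rbf"`.
#' @param seed Seed (RBF k-means).
#' @return Accuracy on `test_ds`, in percent.
#' @export
cross_test <- function(train_ds, test_ds, subnets,
                       classifier = c("tree", "rbf"), seed = 1) {
  classifier <- match.arg(classifier)
  if (nlevels(droplevels(train_ds$labels)) < 2 ||
      nlevels(droplevels(test_ds$labels)) < 2)
    stop("contract error: both datasets need both classes")
  shared_cases <- intersect(
    sample_ids(train_ds)[train_ds$labels == "case"],
    sample_ids(test_ds)[test_ds$labels == "case"])
  if (length(shared_cases))
    warning("case samples overlap between train and test (",
            length(shared_cases), " shared)")
  gene_sets <- .as_gene_sets(subnets)
  genes <- unique(if (is.character(gene_sets)) gene_sets else unlist(gene_sets))
  genes <- intersect(genes, intersect(gene_ids(train_ds), gene_ids(test_ds)))
  if (!length(genes)) stop("no subnetwork gene measured in both datasets")

  mu <- rowMeans(train_ds$values[genes, , drop = FALSE])
  sdv <- apply(train_ds$values[genes, , drop = FALSE], 1, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z_train <- (train_ds$values[genes, , drop = FALSE] - mu) / sdv
  z_test <- (test_ds$values[genes, , drop = FALSE] - mu) / sdv

  fm_train <- .features_from_z(z_train, train_ds$labels, gene_sets, genes)
  fm_test <- .features_from_z(z_test, test_ds$labels, gene_sets, genes)

  with_seed(seed, {
    fit <- .fit_classifier(classifier, .feature_df(fm_train$values),
                           droplevels(fm_train$labels))
    pred <- .predict_classifier(classifier, fit, .feature_df(fm_test$values))
    100 * mean(pred == as.character(fm_test$labels))
  })
}

.features_from_z <- function(z, labels, gene_sets, genes) {
  if (is.character(gene_sets)) {
    vals <- z[intersect(gene_sets, genes), , drop = FALSE]
  } else {
    vals <- t(vapply(gene_sets, function(members) {
      present <- intersect(members, genes)
      if (!length(present)) stop("feature error: subnetwork with zero measured members")
      colMeans(z[present, , drop = FALSE])
    }, numeric(ncol(z))))
    rownames(vals) <- sprintf("subnetwork_%03d", seq_along(gene_sets))
  }
  structure(list(values = vals, labels = labels), class = "feature_matrix")
}
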