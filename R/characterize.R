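#' Stratified cross-validated cluster-membership classifier
#'
#' Stratified F-fold cross-validation of the gradient-boosted classifier on
#' cluster labels: out-of-fold predictions are pooled into a single
#' confusion matrix, and the headline `mean_accuracy` is the pooled
#' out-of-fold accuracy (per-fold accuracies are also reported). A model
#' refit on the full data is returned alongside the report.
#'
#' @param fm `feature_matrix` (or matrix)
#' @param labels 0-based cluster labels
#' @param n_folds number of folds (default 10)
#' @param seed integer seed for fold assignment
#' @param hyperparams list overriding `n_trees`, `depth`, `learning_rate`,
#'   `min_leaf`
#' @param run_id identifier carried into the report
#' @return list with `model` (full-data `gbt_model`) and `report` (class
#'   `classifier_report`: `fold_accuracies`, `mean_accuracy`, `confusion`
#'   with rows = true clusters, `per_cluster_sensitivity`,
#'   `per_cluster_specificity`, `run_id`, `small_clusters`)
#' @export
crossval_classifier <- function(fm, labels, n_folds = 10, seed = 1L,
                                hyperparams = list(), run_id = 1L) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("labels define a single cluster")
  n <- nrow(X)
  K <- max(y) + 1L
  hp <- utils::modifyList(list(n_trees = 200, depth = 4,
                               learning_rate = 0.1, min_leaf = 10),
                          hyperparams)
  counts <- tabulate(y + 1L, K)
  small <- which(counts > 0 & counts < n_folds) - 1L
  fold <- integer(n)
  local_seed(seed, {
    for (k in seq_len(K) - 1L) {
      idx <- which(y == k)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  pred <- integer(n)
  fold_acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold == f
    fit <- gbt_fit(X[!te, , drop = FALSE], y[!te],
                   n_trees = hp$n_trees, depth = hp$depth,
                   learning_rate = hp$learning_rate,
                   min_leaf = hp$min_leaf, n_classes = K)
    pred[te] <- predict(fit, X[te, , drop = FALSE], type = "class")
    fold_acc[f] <- mean(pred[te] == y[te])
  }
  confusion <- matrix(0L, K, K,
                      dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (i in seq_len(n)) confusion[y[i] + 1L, pred[i] + 1L] <-
    confusion[y[i] + 1L, pred[i] + 1L] + 1L
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- n - tp - fn - fp
  report <- structure(list(
    fold_accuracies = fold_acc,
    mean_accuracy = sum(tp) / n,
    confusion = confusion,
    per_cluster_sensitivity = unname(ifelse(tp + fn > 0, tp / (tp + fn),
                                            NA_real_)),
    per_cluster_specificity = unname(ifelse(tn + fp > 0, tn / (tn + fp),
                                            NA_real_)),
    run_id = run_id, small_clusters = small), class = "classifier_report")
  full <- gbt_fit(X, y, n_trees = hp$n_trees, depth = hp$depth,
                  learning_rate = hp$learning_rate, min_leaf = hp$min_leaf,
                  n_classes = K)
  list(model = full, report = report)
}

#' Pick the classifier run with the highest accuracy
#' @param reports list of `classifier_report`s
#' @return the `run_id` of the best report (ties: lowest run_id)
#' @export
select_best_run <- function(reports) {
  if (length(reports) == 0) stop("empty report list")
  ids <- vapply(seq_along(reports), function(i) {
    rid <- reports[[i]]$run_id
    if (is.null(rid)) i else as.integer(rid)
  }, integer(1))
  acc <- vapply(reports, `[[`, numeric(1), "mean_accuracy")
  ids[order(-acc, ids)][1]
}

#' Exact interventional Shapley attributions for a tree-ensemble classifier
#'
#' Per class, each sample's margin score is split exactly among features
#' with the marginal-expectation (interventional) value function over a
#' background sample of the training matrix: summing a row's attributions
#' plus the class base value reproduces the model margin to numerical
#' precision. For non-tree models use [shapley_sampling()].
#'
#' @param model a `gbt_model`
#' @param fm `feature_matrix` (or matrix) of rows to explain
#' @param background matrix of background rows; defaults to a seeded
#'   subsample of `fm` of at most `max_background` rows
#' @param max_background background cap
#' @param seed integer seed for the background subsample
#' @return object of class `attribution_matrix`: `phi` (list of n x p
#'   matrices per class), `base_values`, `feature_names`, `patient_ids`,
#'   and `max_local_accuracy_error`
#' @export
shapley_attributions <- function(model, fm, background = NULL,
                                 max_background = 100, seed = 1L) {
  if (!inherits(model, "gbt_model"))
    stop("exact attributions need a gbt_model; see shapley_sampling()")
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  fn <- if (inherits(fm, "feature_matrix")) fm$feature_names
        else colnames(X)
  ids <- if (inherits(fm, "feature_matrix")) fm$patient_ids else NULL
  if (is.null(background)) {
    background <- if (nrow(X) <= max_background) X else
      X[local_seed(seed, sample.int(nrow(X), max_background)), ,
        drop = FALSE]
  }
  background <- as.matrix(background)
  K <- model$n_classes
  margins_x <- predict(model, X, type = "margin")
  margins_b <- predict(model, background, type = "margin")
  base <- colMeans(margins_b)
  phi <- vector("list", K)
  max_err <- 0
  for (k in seq_len(K)) {
    phi[[k]] <- shap_trees_cpp(model$trees[[k]], X, background)
    colnames(phi[[k]]) <- fn
    err <- max(abs(rowSums(phi[[k]]) + base[k] - margins_x[, k]))
    max_err <- max(max_err, err)
  }
  structure(list(phi = phi, base_values = base, feature_names = fn,
                 patient_ids = ids, method = "tree_exact",
                 max_local_accuracy_error = max_err),
            class = "attribution_matrix")
}

#' Permutation-sampling Shapley attributions for an arbitrary model
#'
#' Monte-Carlo Shapley: for each of `n_perm` random feature orderings,
#' features are switched from the background to the explicand one at a time
#' and the increment of the background-averaged score is credited to the
#' switched feature. The telescoping sum makes local accuracy exact for
#' every permutation (attributions sum to `f(x) - mean_bg f`); sampling
#' error only affects the split between features.
#'
#' @param predict_fun function `(matrix) -> numeric` score
#' @param X rows to explain
#' @param background background rows
#' @param n_perm permutations per sample
#' @param seed integer seed
#' @return n x p attribution matrix
#' @export
shapley_sampling <- function(predict_fun, X, background, n_perm = 64,
                             seed = 1L) {
  X <- as.matrix(X)
  background <- as.matrix(background)
  n <- nrow(X)
  p <- ncol(X)
  phi <- matrix(0, n, p)
  local_seed(seed, {
    for (i in seq_len(n)) {
      for (r in seq_len(n_perm)) {
        ord <- sample.int(p)
        cur <- background
        prev <- mean(predict_fun(cur))
        for (j in ord) {
          cur[, j] <- X[i, j]
          val <- mean(predict_fun(cur))
          phi[i, j] <- phi[i, j] + (val - prev) / n_perm
          prev <- val
        }
      }
    }
  })
  colnames(phi) <- colnames(X)
  phi
}

#' Rank the features driving membership of one cluster
#'
#' Orders features by mean absolute attribution for the class; the reported
#' direction is the sign of the correlation between feature value and
#' attribution (positive: high values drive membership). Features with zero
#' attribution everywhere are dropped.
#'
#' @param attr an `attribution_matrix`
#' @param cluster 0-based cluster index
#' @param top_m how many features to keep (default all)
#' @param fm optional `feature_matrix` supplying feature values for the
#'   direction; defaults to signless `NA` direction when absent
#' @return data.frame with `feature`, `mean_abs_phi`, `direction`
#' @export
rank_features <- function(attr, cluster, top_m = Inf, fm = NULL) {
  stopifnot(inherits(attr, "attribution_matrix"))
  P <- attr$phi[[cluster + 1L]]
  mabs <- colMeans(abs(P))
  keep <- which(mabs > 0)
  keep <- keep[order(-mabs[keep], keep)]
  if (is.finite(top_m)) keep <- utils::head(keep, top_m)
  dir <- rep(NA_real_, length(keep))
  if (!is.null(fm)) {
    V <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
    for (ii in seq_along(keep)) {
      j <- keep[ii]
      if (stats::sd(V[, j]) > 0 && stats::sd(P[, j]) > 0)
        dir[ii] <- sign(stats::cor(V[, j], P[, j]))
    }
  }
  data.frame(feature = attr$feature_names[keep],
             mean_abs_phi = unname(mabs[keep]),
             direction = dir, stringsAsFactors = FALSE)
}
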