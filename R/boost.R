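# Multiclass gradient-boosted trees (Friedman's multinomial deviance
# boosting). Depth-limited exact-greedy regression trees (src/trees.cpp) are
# fit to the class residuals y_ik - p_ik each round; leaf values use the
# standard (K-1)/K * sum(r) / sum(|r|(1-|r|)) Newton step, shrunk by the
# learning rate and stored inside the tree so prediction is a plain sum.

softmax_rows <- function(F) {
  m <- apply(F, 1, max)
  E <- exp(F - m)
  E / rowSums(E)
}

#' Fit a gradient-boosted decision-tree multiclass classifier
#'
#' @param X numeric matrix (n x p)
#' @param y 0-based integer class labels
#' @param n_trees boosting rounds (one tree per class per round)
#' @param depth maximum tree depth
#' @param learning_rate shrinkage
#' @param min_leaf minimum samples per leaf
#' @param n_classes number of classes (default `max(y) + 1`)
#' @param seed kept for interface stability (the fit is deterministic:
#'   exact greedy splits, no subsampling)
#' @return object of class `gbt_model`
#' @export
gbt_fit <- function(X, y, n_trees = 200, depth = 4, learning_rate = 0.1,
                    min_leaf = 10, n_classes = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (length(y) != n) stop("label length mismatch")
  K <- if (is.null(n_classes)) max(y) + 1L else as.integer(n_classes)
  if (K < 2) stop("need at least 2 classes")
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  F <- matrix(0, n, K)
  trees <- replicate(K, vector("list", n_trees), simplify = FALSE)
  for (m in seq_len(n_trees)) {
    P <- softmax_rows(F)
    for (k in seq_len(K)) {
      r <- Y[, k] - P[, k]
      tr <- build_tree_cpp(X, r, depth, min_leaf)
      leaf <- tr$leaf + 1L
      num <- tapply(r, leaf, sum)
      den <- tapply(abs(r) * (1 - abs(r)), leaf, sum)
      gamma <- (K - 1) / K * num / pmax(den, 1e-10)
      gamma <- pmin(pmax(gamma, -10), 10)
      tr$value[as.integer(names(num))] <- learning_rate * gamma
      tr$leaf <- NULL
      trees[[k]][[m]] <- tr
      F[, k] <- F[, k] + predict_tree_cpp(tr, X)
    }
  }
  structure(list(trees = trees, n_classes = K, n_trees = n_trees,
                 depth = depth, learning_rate = learning_rate,
                 min_leaf = min_leaf, p = ncol(X)),
            class = "gbt_model")
}

#' Predict from a gradient-boosted classifier
#' @param object a `gbt_model`
#' @param X matrix of rows to score
#' @param type `"class"` (0-based labels), `"prob"`, or `"margin"`
#' @param ... unused
#' @return vector of labels or n x K matrix
#' @export
predict.gbt_model <- function(object, X,
                              type = c("class", "prob", "margin"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  K <- object$n_classes
  F <- matrix(0, nrow(X), K)
  for (k in seq_len(K))
    for (tr in object$trees[[k]])
      F[, k] <- F[, k] + predict_tree_cpp(tr, X)
  switch(type,
         margin = F,
         prob = softmax_rows(F),
         class = max.col(F, ties.method = "first") - 1L)
}
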