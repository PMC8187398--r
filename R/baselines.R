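new_clustering_result <- function(labels, k, algorithm, seed = NULL,
                                  diagnostics = list()) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 algorithm = algorithm, seed = seed,
                 diagnostics = diagnostics), class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s, k=%d, n=%d\n", x$algorithm, x$k,
              length(x$labels)))
  invisible(x)
}

new_distance_matrix <- function(values, metric, patient_ids = NULL) {
  if (max(abs(values - t(values))) > 1e-10) stop("distance matrix asymmetric")
  if (any(diag(values) != 0)) stop("distance matrix diagonal must be 0")
  if (any(values < 0)) stop("negative distances")
  structure(list(values = values, metric = metric,
                 patient_ids = patient_ids), class = "distance_matrix")
}

#' Euclidean distance matrix of a feature matrix
#' @param fm a `feature_matrix`
#' @return a `distance_matrix` with metric tag `"euclidean"`
#' @export
euclidean_distances <- function(fm) {
  d <- as.matrix(stats::dist(fm$values))
  dimnames(d) <- NULL
  diag(d) <- 0
  new_distance_matrix((d + t(d)) / 2, "euclidean", fm$patient_ids)
}

# squared distances between rows of X and rows of C
row_dist2 <- function(X, C) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  pmax(d2, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ], "-")^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j + 1], ], "-")^2))
  }
  X[centers, , drop = FALSE]
}

lloyd <- function(X, C, max_iter = 100) {
  n <- nrow(X)
  trace <- numeric(0)
  assign_prev <- rep(-1L, n)
  for (it in seq_len(max_iter)) {
    d2 <- row_dist2(X, C)
    lab <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(n), lab)])
    trace <- c(trace, inertia)
    for (j in seq_len(nrow(C))) {
      members <- lab == j
      if (any(members)) {
        C[j, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        # re-seed an emptied cluster at the point worst served by its center
        far <- which.max(d2[cbind(seq_len(n), lab)])
        C[j, ] <- X[far, ]
        lab[far] <- j
      }
    }
    if (identical(lab, assign_prev)) break
    assign_prev <- lab
  }
  d2 <- row_dist2(X, C)
  lab <- max.col(-d2, ties.method = "first")
  list(labels = lab, centers = C,
       inertia = sum(d2[cbind(seq_len(n), lab)]), trace = trace)
}

#' k-means clustering (k-means++ seeding, best of restarts)
#'
#' Lloyd iterations from k-means++ seeds, `n_init` restarts, keeping the run
#' with the lowest within-cluster sum of squares. Deterministic given
#' `seed`; distance ties break to the lowest cluster index.
#'
#' @param fm a `feature_matrix` (or bare numeric matrix)
#' @param k number of clusters, `2 <= k <= n` (k = n allowed, degenerate)
#' @param seed integer seed
#' @param n_init restarts
#' @param max_iter Lloyd iteration cap per restart
#' @return a `clustering_result`; diagnostics hold `inertia`, the
#'   non-increasing `inertia_trace` of the winning restart, and `centers`
#' @export
kmeans_cluster <- function(fm, k, seed = 1L, n_init = 10, max_iter = 100) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k out of range")
  local_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      fit <- lloyd(X, kmeanspp_init(X, k), max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    new_clustering_result(best$labels - 1L, k, "kmeans", seed,
                          list(inertia = best$inertia,
                               inertia_trace = best$trace,
                               centers = best$centers))
  })
}

#' Agglomerative hierarchical clustering
#'
#' Builds the merge tree with [stats::hclust()] and cuts it at `k` clusters.
#' Ward linkage requires Euclidean feature input (it operates on squared
#' Euclidean geometry); `average` and `complete` accept any distance matrix.
#'
#' @param x a `feature_matrix` or a `distance_matrix`
#' @param k number of clusters
#' @param linkage one of `"ward"`, `"average"`, `"complete"`
#' @return a `clustering_result`; diagnostics hold the merge `heights` and
#'   `merge` table
#' @export
hier_cluster <- function(x, k, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(x, "feature_matrix")) {
    d <- stats::dist(x$values)
    n <- nrow(x$values)
  } else if (inherits(x, "distance_matrix")) {
    if (linkage == "ward" && !identical(x$metric, "euclidean"))
      stop("ward linkage requires euclidean distances")
    d <- stats::as.dist(x$values)
    n <- nrow(x$values)
  } else stop("x must be a feature_matrix or distance_matrix")
  if (k < 1 || k > n) stop("k out of range")
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  hc <- stats::hclust(d, method = method)
  lab <- stats::cutree(hc, k = k)
  new_clustering_result(lab - 1L, k, paste0("hc_", linkage), NULL,
                        list(heights = hc$height, merge = hc$merge))
}

#' Dynamic time warping distance between two value sequences
#'
#' Unconstrained DTW with absolute-difference local cost:
#' `D(i,j) = |a_i - b_j| + min(D(i-1,j), D(i,j-1), D(i-1,j-1))`, anchored at
#' `D(1,1) = |a_1 - b_1|`. Symmetric in its arguments.
#'
#' @param a,b nonempty numeric vectors
#' @return nonnegative warping cost
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sequence")
  dtw_cost_cpp(as.numeric(a), as.numeric(b))
}

#' Patient-by-patient DTW distance matrix
#'
#' Distance between two patients is the (weighted) mean over lab variables
#' of the univariate DTW cost between their series for that variable. Run
#' on an imputed cohort: every series must be nonempty.
#'
#' @param cohort an imputed `phenodec_cohort`
#' @param variable_weights optional nonnegative weights over the roster
#'   (default equal)
#' @return a `distance_matrix` with metric tag `"dtw"`
#' @export
dtw_distance_matrix <- function(cohort, variable_weights = NULL) {
  stopifnot(inherits(cohort, "phenodec_cohort"))
  roster <- cohort$variable_names
  if (is.null(variable_weights)) variable_weights <- rep(1, length(roster))
  series <- lapply(cohort$patients, function(p)
    lapply(roster, function(v) p$labs[[v]]$values))
  d <- dtw_distmat_cpp(series, as.numeric(variable_weights))
  ids <- vapply(cohort$patients, `[[`, character(1), "patient_id")
  new_distance_matrix(d, "dtw", ids)
}

#' Hierarchical clustering on DTW distances (HC-DTW)
#'
#' Composes [dtw_distance_matrix()] with [hier_cluster()]; Ward linkage is
#' rejected (invalid on non-Euclidean DTW distances).
#'
#' @param cohort an imputed `phenodec_cohort`
#' @param k number of clusters
#' @param variable_weights optional roster weights
#' @param linkage `"average"` (default) or `"complete"`
#' @return a `clustering_result` (algorithm tag `"hcdtw"`)
#' @export
hc_dtw_cluster <- function(cohort, k, variable_weights = NULL,
                           linkage = "average") {
  if (identical(linkage, "ward"))
    stop("ward linkage is not valid on DTW distances")
  dm <- dtw_distance_matrix(cohort, variable_weights)
  res <- hier_cluster(dm, k, linkage)
  res$algorithm <- "hcdtw"
  res
}

#' Write a distance matrix as a square CSV with patient-id headers
#' @param dm a `distance_matrix`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  ids <- dm$patient_ids
  if (is.null(ids)) ids <- sprintf("row%04d", seq_len(nrow(dm$values)))
  df <- data.frame(patient_id = ids, dm$values, check.names = FALSE)
  colnames(df) <- c("patient_id", ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
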