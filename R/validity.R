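#' Silhouette values from a precomputed distance matrix
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean distance to
#' the point's own cluster (excluding itself) and `b(i)` the smallest mean
#' distance to any other cluster. Singleton clusters get `s(i) = 0` by
#' convention.
#'
#' @param dm a `distance_matrix` (or bare symmetric matrix)
#' @param labels integer cluster labels (any coding)
#' @return list with `per_sample` and `mean`
#' @export
silhouette_score <- function(dm, labels) {
  d <- if (inherits(dm, "distance_matrix")) dm$values else as.matrix(dm)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("silhouette needs at least 2 clusters")
  n <- length(labels)
  counts <- tabulate(labels, k)
  ind <- matrix(0, n, k)
  ind[cbind(seq_len(n), labels)] <- 1
  sums <- d %*% ind                        # n x k total distance to cluster
  meanother <- sweep(sums, 2, counts, "/")
  own <- counts[labels]
  a <- sums[cbind(seq_len(n), labels)] / pmax(own - 1, 1)
  meanother[cbind(seq_len(n), labels)] <- Inf
  b <- apply(meanother, 1, min)
  s <- (b - a) / pmax(a, b)
  s[own == 1] <- 0
  list(per_sample = as.numeric(s), mean = mean(s))
}

#' Cluster size distribution
#' @param labels nonempty label vector
#' @return list with descending `proportions` and `largest_share`
#' @export
size_distribution <- function(labels) {
  if (length(labels) == 0) stop("empty labels")
  p <- sort(as.numeric(table(labels)) / length(labels), decreasing = TRUE)
  list(proportions = p, largest_share = p[1])
}

#' Shannon entropy of the cluster size distribution (natural log)
#' @param labels nonempty label vector
#' @return value in `[0, log k]`
#' @export
entropy_score <- function(labels) {
  p <- size_distribution(labels)$proportions
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Jaccard similarity of two id sets
#' @param a,b vectors treated as sets; not both empty
#' @return `|intersect| / |union|` in `[0, 1]`
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("both sets empty")
  length(intersect(a, b)) / u
}

#' Adjusted Rand index between two partitions
#' @param a,b equal-length label vectors
#' @return chance-corrected agreement (1 = identical up to relabeling)
#' @export
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Bootstrap cluster-wise Jaccard stability
#'
#' Hennig-style protocol: draw `B` n-of-n resamples with replacement,
#' recluster each, and score every reference cluster by its best Jaccard
#' overlap with any cluster of the resample clustering, restricted to the
#' resampled ids (duplicates counted once). Failed resamples are skipped
#' and counted.
#'
#' @param fm a `feature_matrix`
#' @param reference a `clustering_result` on the full data
#' @param clusterer function `(fm, seed) -> clustering_result` (or a bare
#'   label vector), deterministic given its seed
#' @param B number of resamples
#' @param seed integer seed
#' @return object of class `stability_report`: `per_cluster_jaccard`,
#'   `mean_jaccard`, `B`, `k`, `n_failed`
#' @export
bootstrap_stability <- function(fm, reference, clusterer, B = 100,
                                seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(reference, "clustering_result"))
  n <- nrow(fm$values)
  k <- reference$k
  ref_sets <- lapply(sort(unique(reference$labels)),
                     function(c) which(reference$labels == c))
  acc <- matrix(NA_real_, length(ref_sets), B)
  n_failed <- 0L
  # pre-draw resamples so a clusterer that touches the global RNG cannot
  # perturb the resampling stream
  idx_list <- local_seed(seed, lapply(seq_len(B), function(b)
    sample.int(n, n, replace = TRUE)))
  {
    for (b in seq_len(B)) {
      idx <- idx_list[[b]]
      res <- tryCatch({
        out <- clusterer(fm_subset(fm, idx), child_seed(seed, b))
        if (inherits(out, "clustering_result")) out$labels else out
      }, error = function(e) NULL)
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      uniq <- unique(idx)
      first_pos <- match(uniq, idx)   # one label per distinct patient
      lab_u <- res[first_pos]
      new_sets <- split(uniq, lab_u)
      for (ci in seq_along(ref_sets)) {
        ref_in <- intersect(ref_sets[[ci]], uniq)
        best <- 0
        for (ns in new_sets) {
          u <- length(union(ref_in, ns))
          if (u > 0) best <- max(best, length(intersect(ref_in, ns)) / u)
        }
        acc[ci, b] <- best
      }
    }
  }
  per_cluster <- rowMeans(acc, na.rm = TRUE)
  structure(list(per_cluster_jaccard = per_cluster,
                 mean_jaccard = mean(per_cluster), B = B, k = k,
                 n_failed = n_failed), class = "stability_report")
}

#' Select the number of clusters by bootstrap stability
#'
#' Runs [bootstrap_stability()] for every k in `k_range`; the selected
#' `k_star` maximizes mean Jaccard, ties going to the smaller k.
#'
#' @param fm a `feature_matrix`
#' @param clusterer_factory function `(k) -> clusterer(fm, seed)`
#' @param k_range candidate cluster counts
#' @param B resamples per k
#' @param seed integer seed
#' @return list with `k_star` and `reports` (named per k)
#' @export
select_k <- function(fm, clusterer_factory, k_range, B = 100, seed = 1L) {
  if (length(k_range) == 0) stop("empty k_range")
  reports <- list()
  for (k in sort(k_range)) {
    cl <- clusterer_factory(k)
    reference <- cl(fm, child_seed(seed, 1000L + k))
    if (!inherits(reference, "clustering_result"))
      reference <- new_clustering_result(reference, k, "custom")
    reports[[as.character(k)]] <-
      bootstrap_stability(fm, reference, cl, B = B,
                          seed = child_seed(seed, 2000L + k))
  }
  means <- vapply(reports, `[[`, numeric(1), "mean_jaccard")
  k_star <- as.integer(names(reports)[which.max(means)])  # first max = smallest k
  list(k_star = k_star, reports = reports)
}
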