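test_that("kmeans_cluster recovers separable blobs and degenerate k", {
  b <- make_blobs(n_per = 15, k = 2, p = 2, gap = 10, seed = 1)
  km <- kmeans_cluster(b$fm, 2, seed = 1)
  expect_equal(adjusted_rand(km$labels, b$labels), 1)
  kn <- kmeans_cluster(b$fm, nrow(b$fm$values), seed = 1)
  expect_equal(kn$diagnostics$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_cluster(b$fm, 31, seed = 1), "k out of range")
  expect_identical(kmeans_cluster(b$fm, 3, seed = 5),
                   kmeans_cluster(b$fm, 3, seed = 5))
})

test_that("kmeans inertia matches the exhaustive 6-point partition oracle", {
  set.seed(3)
  X <- matrix(rnorm(12), 6, 2)
  fm <- phenodec:::new_feature_matrix(X, c("x", "y"), paste0("p", 1:6))
  best <- Inf
  for (mask in 1:(2^6 - 2)) {     # all non-trivial 2-part splits
    g <- as.logical(bitwAnd(mask, 2^(0:5)))
    w <- 0
    for (side in list(g, !g)) {
      c_m <- colMeans(X[side, , drop = FALSE])
      w <- w + sum(sweep(X[side, , drop = FALSE], 2, c_m, "-")^2)
    }
    best <- min(best, w)
  }
  km <- kmeans_cluster(fm, 2, seed = 2, n_init = 30)
  expect_equal(km$diagnostics$inertia, best, tolerance = 1e-10)
})

test_that("kmeans inertia trace is non-increasing", {
  b <- make_blobs(n_per = 20, k = 3, p = 4, gap = 2, seed = 5)
  km <- kmeans_cluster(b$fm, 3, seed = 1)
  expect_true(all(diff(km$diagnostics$inertia_trace) <= 1e-8))
})

test_that("hier_cluster groups pairs, handles k=1, rejects bad ward input", {
  X <- rbind(c(0, 0), c(0, 0.1), c(10, 0), c(10, 0.1))
  fm <- phenodec:::new_feature_matrix(X, c("x", "y"), paste0("p", 1:4))
  hc <- hier_cluster(fm, 2, "ward")
  expect_equal(hc$labels[1], hc$labels[2])
  expect_equal(hc$labels[3], hc$labels[4])
  expect_false(hc$labels[1] == hc$labels[3])
  expect_length(unique(hier_cluster(fm, 1, "average")$labels), 1)
  dm_fake <- phenodec:::new_distance_matrix(
    as.matrix(dist(X))^0.5, "dtw", paste0("p", 1:4))
  expect_error(hier_cluster(dm_fake, 2, "ward"), "ward")
})

test_that("average-linkage heights match the naive agglomeration oracle", {
  set.seed(9)
  X <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(X))
  fm <- phenodec:::new_feature_matrix(X, c("x", "y"), paste0("p", 1:5))
  hc <- hier_cluster(fm, 2, "average")
  expect_equal(hc$diagnostics$heights, average_linkage_heights(d),
               tolerance = 1e-10)
})

test_that("dtw_distance satisfies identity, base case, and enumeration", {
  set.seed(4)
  x <- rnorm(6)
  expect_equal(dtw_distance(x, x), 0)
  expect_equal(dtw_distance(0, 3), 3)
  expect_error(dtw_distance(numeric(0), 1), "empty")
  for (r in 1:100) {
    a <- rnorm(sample(1:6, 1))
    b <- rnorm(sample(1:6, 1))
    expect_equal(dtw_distance(a, b), dtw_enumerate(a, b),
                 tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a),
                 tolerance = 1e-12)
  }
})

test_that("hc_dtw_cluster composes per-variable DTW and average linkage", {
  roster <- c("v1", "v2")
  same <- lapply(1:3, function(i) list(
    v1 = list(times = 1:3, values = c(1, 2, 3)),
    v2 = list(times = 1:2, values = c(5, 5))))
  co_same <- make_cohort(same, roster)
  dm <- dtw_distance_matrix(co_same)
  expect_true(all(dm$values == 0))
  # two groups at constant levels 0 and 10 separate perfectly
  mk <- function(level) list(
    v1 = list(times = 1:3, values = rep(level, 3)),
    v2 = list(times = 1:3, values = rep(level, 3)))
  co2 <- make_cohort(c(lapply(1:3, function(i) mk(0)),
                       lapply(1:3, function(i) mk(10))), roster)
  res <- hc_dtw_cluster(co2, 2)
  expect_equal(adjusted_rand(res$labels, rep(0:1, each = 3)), 1)
  expect_error(hc_dtw_cluster(co2, 2, linkage = "ward"), "ward")
  # 5-patient distance matrix equals the per-pair enumeration oracle
  set.seed(11)
  spec5 <- lapply(1:5, function(i) list(
    v1 = list(times = sort(runif(4, 0, 50)), values = rnorm(4)),
    v2 = list(times = sort(runif(3, 0, 50)), values = rnorm(3))))
  co5 <- make_cohort(spec5, roster)
  dm5 <- dtw_distance_matrix(co5)
  for (i in 1:4) for (j in (i + 1):5) {
    o <- mean(c(dtw_enumerate(spec5[[i]]$v1$values, spec5[[j]]$v1$values),
                dtw_enumerate(spec5[[i]]$v2$values, spec5[[j]]$v2$values)))
    expect_equal(dm5$values[i, j], o, tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric, nonnegative, zero-diagonal", {
  b <- make_blobs(n_per = 8, k = 2, p = 3, seed = 6)
  dm <- euclidean_distances(b$fm)
  expect_lt(max(abs(dm$values - t(dm$values))), 1e-10)
  expect_true(all(diag(dm$values) == 0))
  expect_true(all(dm$values >= 0))
})

test_that("relabeling clusters leaves ARI against truth unchanged", {
  b <- make_blobs(n_per = 12, k = 3, p = 3, gap = 2, seed = 2)
  km <- kmeans_cluster(b$fm, 3, seed = 1)
  perm <- c(2L, 0L, 1L)
  expect_equal(adjusted_rand(km$labels, b$labels),
               adjusted_rand(perm[km$labels + 1L], b$labels))
})
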