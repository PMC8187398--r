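roster8 <- paste0("v", 1:8)

test_that("missingness screen applies strict 10% boundary arithmetic", {
  roster40 <- paste0("v", 1:40)
  mk <- function(n_empty) {
    s <- stats::setNames(lapply(seq_len(40 - n_empty), function(i)
      list(times = c(1, 25), values = c(1, 2))), roster40[seq_len(40 - n_empty)])
    list(s)
  }
  co <- make_cohort(c(mk(5), mk(3)), roster40)
  out <- screen_patients(co, threshold = 0.10)
  # 5/40 = 0.125 excluded; 3/40 = 0.075 retained
  expect_identical(out$report$excluded_ids, "pt001")
  expect_identical(out$report$included_ids, "pt002")
  expect_equal(unname(out$report$missing_fraction), c(0.125, 0.075))
  expect_length(screen_patients(co, threshold = 1)$report$excluded_ids, 0)
  # strict inequality: one empty variable at threshold 0 excludes
  co1 <- make_cohort(mk(1), roster40)
  expect_identical(screen_patients(co1, 0)$report$excluded_ids, "pt001")
  co0 <- make_cohort(mk(0), roster40)
  expect_length(screen_patients(co0, 0)$report$excluded_ids, 0)
  expect_error(screen_patients(co, 1.2), "threshold")
})

test_that("rolling_mean_impute matches the hand oracle and conventions", {
  grid <- c(0, 24, 48, 72)
  s <- phenodec:::lab_series("x", c(1, 30, 73), c(1, 2, 4))
  out <- rolling_mean_impute(s, grid, window = 2, population_mean = 0)
  expect_equal(out$values, c(1, 2, 1.5, 4))  # gap = mean(1, 2)
  full <- phenodec:::lab_series("x", c(1, 30, 50, 73), c(1, 2, 3, 4))
  expect_equal(rolling_mean_impute(full, grid, 3, 0)$values, c(1, 2, 3, 4))
  empty <- phenodec:::lab_series("x")
  expect_equal(rolling_mean_impute(empty, grid, 3, 7)$values, rep(7, 4))
  expect_error(rolling_mean_impute(empty, grid, 3, NA_real_), "non-finite")
  # leading gaps use the population mean, which then enters the window
  late <- phenodec:::lab_series("x", 50, 5)
  expect_equal(rolling_mean_impute(late, grid, 2, 9)$values,
               c(9, 9, 5, mean(c(9, 5))))
})

test_that("iterative_impute recovers exact linear structure", {
  x <- cbind(a = as.numeric(1:6), b = 2 * (1:6))
  expect_identical(iterative_impute(x), x)  # no missing cells
  x[3, "b"] <- NA
  out <- iterative_impute(x, n_iter = 10)
  expect_equal(unname(out[3, "b"]), 6, tolerance = 1e-6)
  expect_error(iterative_impute(cbind(x[, 1], NA)), "all-missing")
})

test_that("iterative_impute stabilizes by 10 sweeps on MCAR data", {
  set.seed(42)
  n <- 60
  z <- matrix(rnorm(n * 4), n, 4)
  x <- z %*% matrix(runif(16, -1, 1), 4) + 0.1 * rnorm(n * 4)
  miss <- matrix(runif(length(x)) < 0.05, n)
  x[miss] <- NA
  a <- iterative_impute(x, n_iter = 10)
  b <- iterative_impute(x, n_iter = 11)
  expect_lt(max(abs(a - b)), 1e-4)
  expect_true(all(is.finite(a)))
})

test_that("extract_features computes mean and n-1 variance per series", {
  co <- make_cohort(list(list(
    v1 = list(times = c(1, 2, 3), values = c(2, 4, 6)),
    v2 = list(times = c(1, 2), values = c(5, 5)),
    v3 = list(times = 10, values = 5))), paste0("v", 1:3))
  fm <- extract_features(co)
  expect_equal(fm$values[1, "v1_mean"], 4)
  expect_equal(fm$values[1, "v1_var"], 4)     # divisor n-1
  expect_equal(fm$values[1, "v2_var"], 0)     # constant series
  expect_equal(fm$values[1, "v3_mean"], 5)
  expect_equal(fm$values[1, "v3_var"], 0)     # single measurement
  expect_identical(fm$feature_names,
                   c("age", "v1_mean", "v1_var", "v2_mean", "v2_var",
                     "v3_mean", "v3_var"))
})

test_that("screen -> impute -> extract is a no-op composition on complete data", {
  set.seed(21)
  roster <- paste0("v", 1:4)
  # one observation on every day of a 3-day stay: nothing to impute
  mk <- function() stats::setNames(lapply(roster, function(v)
    list(times = c(2, 20, 30, 50, 65), values = rnorm(5))), roster)
  co <- make_cohort(lapply(1:6, function(i) mk()), roster)
  direct <- extract_features(co)
  piped <- extract_features(impute_cohort(screen_patients(co)$cohort))
  expect_equal(piped$values, direct$values)
})

test_that("extracted features are finite with nonnegative variances", {
  for (seed in 1:3) {
    co <- generate_cohort(cohort_config(n_patients = 50,
                                        n_lab_variables = 8,
                                        missing_variable_rate = 0.1,
                                        seed = seed))
    fm <- extract_features(impute_cohort(screen_patients(co)$cohort))
    expect_true(all(is.finite(fm$values)))
    expect_true(all(fm$values[, grepl("_var$", fm$feature_names)] >= 0))
  }
})

test_that("standardize centres to population SD and is idempotent", {
  fm <- phenodec:::new_feature_matrix(
    cbind(a = c(0, 10), b = c(3, 3)), c("a", "b"), c("p1", "p2"))
  z <- standardize(fm)
  expect_equal(unname(z$values[, "a"]), c(-1, 1))  # population SD divisor
  expect_equal(unname(z$values[, "b"]), c(0, 0))   # constant -> zeros
  expect_equal(standardize(z)$values, z$values, tolerance = 1e-12)
  expect_identical(z$scaling, "standardized")
})

test_that("reduce_pca fixes signs and matches the eigen oracle", {
  set.seed(7)
  b <- make_blobs(n_per = 10, k = 2, p = 4, gap = 3, seed = 7)
  # rank-1 data reconstructs exactly from one component
  u <- rnorm(12)
  fm1 <- phenodec:::new_feature_matrix(outer(u, c(1, 2, 3)),
                                       c("a", "b", "c"),
                                       sprintf("q%02d", 1:12))
  z1 <- standardize(fm1)$values
  pc1 <- reduce_pca(fm1, 1)
  recon <- pc1$values %*% qr.solve(pc1$values, z1)
  expect_lt(max(abs(recon - z1)), 1e-8)
  # full-rank projection preserves pairwise distances
  pall <- reduce_pca(b$fm, 4)
  expect_equal(as.matrix(dist(pall$values)),
               as.matrix(dist(standardize(b$fm)$values)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # explained variance equals covariance eigenvalues on a 10 x 4 matrix
  set.seed(8)
  m <- matrix(rnorm(40), 10, 4)
  fm <- phenodec:::new_feature_matrix(m, paste0("f", 1:4),
                                      sprintf("r%02d", 1:10))
  z <- standardize(fm)$values
  ev <- eigen(crossprod(z) / (10 - 1), symmetric = TRUE)$values
  scores <- reduce_pca(fm, 4)$values
  expect_equal(apply(scores, 2, var), ev, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(reduce_pca(fm, 9), "out of range")
})
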