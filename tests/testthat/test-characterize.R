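test_that("cross-validated classifier separates blobs and nulls correctly", {
  b <- make_blobs(n_per = 40, k = 3, p = 4, gap = 4, seed = 1)
  cv <- crossval_classifier(b$fm, b$labels, n_folds = 5, seed = 1,
                            hyperparams = list(n_trees = 40))
  expect_gte(cv$report$mean_accuracy, 0.95)
  expect_equal(sum(cv$report$confusion), 120)
  expect_equal(rowSums(cv$report$confusion), table(b$labels),
               ignore_attr = TRUE)   # pooled OOF rows = true counts
  # shuffled labels: accuracy near the largest class share
  set.seed(2)
  null_lab <- sample(rep(0:2, each = 40))
  cvn <- crossval_classifier(b$fm, null_lab, n_folds = 5, seed = 1,
                             hyperparams = list(n_trees = 40))
  expect_lt(abs(cvn$report$mean_accuracy - 1 / 3), 0.12)
  expect_error(crossval_classifier(b$fm, rep(0L, 120)), "single cluster")
})

test_that("reported sensitivity/specificity agree with a counting oracle", {
  # a deliberately noisy 3-class problem so the confusion matrix is full
  set.seed(7)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  lab <- rep(0:2, each = n / 3)
  X[, 1] <- X[, 1] + 1.2 * lab          # weak signal -> misclassifications
  fm <- phenodec:::new_feature_matrix(X, colnames(X), sprintf("p%03d", 1:n))
  cv <- crossval_classifier(fm, lab, n_folds = 5, seed = 2,
                            hyperparams = list(n_trees = 30))
  conf <- cv$report$confusion
  for (j in 1:3) {
    tp <- conf[j, j]
    fn <- sum(conf[j, -j])
    fp <- sum(conf[-j, j])
    tn <- sum(conf) - tp - fn - fp
    expect_equal(cv$report$per_cluster_sensitivity[j],
                 unname(tp / (tp + fn)))
    expect_equal(cv$report$per_cluster_specificity[j],
                 unname(tn / (tn + fp)))
  }
  expect_equal(cv$report$mean_accuracy, sum(diag(conf)) / sum(conf))
})

test_that("select_best_run maximizes accuracy with lowest-id ties", {
  mk <- function(acc, id) structure(list(mean_accuracy = acc, run_id = id),
                                    class = "classifier_report")
  expect_equal(select_best_run(list(mk(0.5, 1))), 1L)
  expect_equal(select_best_run(list(mk(0.7, 1), mk(0.9, 2), mk(0.9, 3))), 2L)
  expect_equal(select_best_run(list(mk(0.9, 3), mk(0.9, 2), mk(0.7, 1))), 2L)
  expect_error(select_best_run(list()), "empty")
})

test_that("tree attributions are exact Shapley values", {
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0)
  model <- gbt_fit(X, y, n_trees = 15, depth = 3, min_leaf = 5)
  bg <- X[1:20, ]
  attr_m <- shapley_attributions(model, X[1:8, , drop = FALSE],
                                 background = bg)
  expect_lt(attr_m$max_local_accuracy_error, 1e-8)
  # brute force over all 2^3 coalitions, class-1 margin
  f1 <- function(row) predict(model, matrix(row, 1), type = "margin")[1, 2]
  for (i in 1:4) {
    phi_b <- shapley_brute(f1, X[i, ], bg)
    expect_equal(unname(attr_m$phi[[2]][i, ]), phi_b, tolerance = 1e-6)
  }
})

test_that("a single stump splits its score gap by the two-player formula", {
  # one binary feature decides the score; a second feature is inert
  X <- cbind(x = rep(c(0, 1), each = 20), z = 0)
  y <- as.integer(X[, "x"])
  model <- gbt_fit(X, y, n_trees = 10, depth = 1, min_leaf = 5)
  m <- predict(model, rbind(c(0, 0), c(1, 0)), type = "margin")[, 2]
  gap <- m[2] - m[1]
  attr_m <- shapley_attributions(model, rbind(c(1, 0)), background = X)
  # balanced background: phi_x = gap * P(bg disagrees) = gap / 2
  expect_equal(unname(attr_m$phi[[2]][1, 1]), gap / 2, tolerance = 1e-8)
  expect_equal(unname(attr_m$phi[[2]][1, 2]), 0)
})

test_that("constant models attribute nothing", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  model <- gbt_fit(X, rep(c(0L, 1L), 10), n_trees = 5, depth = 2,
                   min_leaf = 25)  # min_leaf > n: no splits possible
  attr_m <- shapley_attributions(model, X, background = X)
  expect_true(all(vapply(attr_m$phi, function(m) all(m == 0), logical(1))))
  expect_equal(nrow(rank_features(attr_m, 0)), 0)  # empty ranking
})

test_that("rank_features finds the elevated driver with positive direction", {
  set.seed(4)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  lab <- rep(0:2, each = n / 3)
  X[lab == 1, 3] <- X[lab == 1, 3] + 4   # cluster 1 defined by high f3
  fm <- phenodec:::new_feature_matrix(X, colnames(X),
                                      sprintf("p%03d", 1:n))
  model <- gbt_fit(X, lab, n_trees = 40, depth = 3)
  attr_m <- shapley_attributions(model, fm, seed = 1)
  rk <- rank_features(attr_m, 1, fm = fm)
  expect_equal(rk$feature[1], "f3")
  expect_equal(rk$direction[1], 1)
  # invariance to feature column order
  ord <- c(3, 1, 5, 2, 4)
  fm2 <- phenodec:::new_feature_matrix(X[, ord], colnames(X)[ord],
                                       sprintf("p%03d", 1:n))
  model2 <- gbt_fit(X[, ord], lab, n_trees = 40, depth = 3)
  rk2 <- rank_features(shapley_attributions(model2, fm2, seed = 1), 1,
                       fm = fm2)
  expect_equal(rk2$feature[1], "f3")
})

test_that("sampling Shapley satisfies local accuracy approximately", {
  set.seed(5)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  f <- function(M) M[, 1] * 2 + pmax(M[, 2], 0)
  bg <- X[1:10, ]
  phi <- shapley_sampling(function(M) f(M), X[1:3, , drop = FALSE], bg,
                          n_perm = 200, seed = 1)
  for (i in 1:3) {
    total <- f(X[i, , drop = FALSE]) - mean(f(bg))
    expect_lt(abs(sum(phi[i, ]) - total), 0.05)
  }
})
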