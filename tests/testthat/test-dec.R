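test_that("pretraining recovers a linear subspace and beats the mean", {
  set.seed(2)
  # rank-2 data, linear activations, no corruption: near-exact reconstruction
  Z <- matrix(rnorm(120 * 2), 120, 2)
  X <- Z %*% matrix(rnorm(10), 2, 5)
  fm <- phenodec:::new_feature_matrix(X, paste0("f", 1:5),
                                      sprintf("p%03d", 1:120))
  z <- standardize(fm)
  sp <- autoencoder_spec(hidden_widths = c(4, 2), activation = "linear",
                         pretrain_epochs = 400, denoise_sd = 0, seed = 1)
  ae <- pretrain_autoencoder(z, sp)
  expect_lt(utils::tail(ae$loss_trace, 1), 1e-3)
  expect_lt(utils::tail(ae$loss_trace, 1), ae$loss_trace[1])
  # determinism: identical loss traces for identical seeds
  ae2 <- pretrain_autoencoder(z, sp)
  expect_identical(ae$loss_trace, ae2$loss_trace)
  # random data: beats the constant column-mean decoder (MSE < 1)
  set.seed(3)
  R <- matrix(rnorm(80 * 6), 80, 6)
  fr <- standardize(phenodec:::new_feature_matrix(
    R, paste0("g", 1:6), sprintf("q%03d", 1:80)))
  aer <- pretrain_autoencoder(fr, autoencoder_spec(
    hidden_widths = c(8, 4), pretrain_epochs = 100, denoise_sd = 0,
    seed = 4))
  mse <- mean((reconstruct(aer, fr) - fr$values)^2)
  expect_lt(mse, mean(fr$values^2))  # column means are 0 after standardize
})

test_that("init_centroids delegates to k-means and recovers point masses", {
  Z <- rbind(matrix(1, 5, 2), matrix(9, 5, 2))
  cent <- init_centroids(Z, 2, seed = 1)
  expect_equal(sort(cent[, 1]), c(1, 9))
  expect_identical(init_centroids(Z, 2, seed = 7),
                   init_centroids(Z, 2, seed = 7))
  expect_equal(sort_rows <- cent,
               kmeans_cluster(Z, 2, seed = 1)$diagnostics$centers)
  expect_error(init_centroids(Z, 11, seed = 1), "fewer points")
})

test_that("soft_assign implements the Student's-t kernel", {
  Z <- matrix(c(0, 0), 1, 2)
  expect_equal(soft_assign(Z, matrix(c(5, 5), 1, 2))[1, 1], 1)  # k = 1
  mu2 <- rbind(c(1, 0), c(-1, 0))
  expect_equal(soft_assign(Z, mu2)[1, ], c(0.5, 0.5))  # equidistant
  # alpha = 1, squared distances (0, 1): unnormalized (1, 0.5) -> (2/3, 1/3)
  mu3 <- rbind(c(0, 0), c(1, 0))
  expect_equal(soft_assign(Z, mu3)[1, ], c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("target_distribution sharpens and matches the hand formula", {
  Q1 <- rbind(c(1, 0), c(0, 1))
  expect_equal(target_distribution(Q1), Q1)           # one-hot fixed point
  Qu <- matrix(0.5, 3, 2)
  expect_equal(target_distribution(Qu), Qu)           # uniform stays uniform
  Q <- rbind(c(0.8, 0.2), c(0.6, 0.4))
  f <- c(1.4, 0.6)
  raw <- sweep(Q^2, 2, f, "/")
  expect_equal(target_distribution(Q), raw / rowSums(raw),
               tolerance = 1e-12)
  # sharpening property on random row-stochastic matrices
  set.seed(5)
  for (r in 1:20) {
    Qr <- matrix(runif(40, 0.01, 1), 8, 5)
    Qr <- Qr / rowSums(Qr)
    P <- target_distribution(Qr)
    expect_true(all(abs(rowSums(P) - 1) < 1e-12))
    expect_true(all(apply(P, 1, max) >= apply(Qr, 1, max) - 1e-12))
  }
})

test_that("kl_loss is a valid divergence", {
  Q <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  expect_equal(kl_loss(Q, Q), 0)
  expect_equal(kl_loss(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)), log(2))
  expect_error(kl_loss(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), "q_ij = 0")
  set.seed(6)
  for (r in 1:20) {
    P <- matrix(runif(12, 0.01, 1), 4, 3)
    P <- P / rowSums(P)
    Q2 <- matrix(runif(12, 0.01, 1), 4, 3)
    Q2 <- Q2 / rowSums(Q2)
    direct <- sum(vapply(1:4, function(i)
      sum(P[i, ] * log(P[i, ] / Q2[i, ])), numeric(1)))
    expect_equal(kl_loss(P, Q2), direct, tolerance = 1e-12)
    expect_gte(kl_loss(P, Q2), 0)
  }
})

test_that("train_dec stops, descends, and respects vacuous tolerance", {
  b <- make_blobs(n_per = 25, k = 3, p = 6, gap = 6, seed = 9)
  z <- standardize(b$fm)
  sp <- autoencoder_spec(hidden_widths = c(16, 4), pretrain_epochs = 40,
                         seed = 2)
  fit <- train_dec(z, 3, spec = sp, max_iter = 600, update_interval = 60)
  expect_equal(adjusted_rand(fit$result$labels, b$labels), 1)
  tr <- fit$trace
  expect_lte(utils::tail(tr$kl_loss, 1), tr$kl_loss[1] + 1e-9)  # descent
  # vacuous tolerance stops at the first target refresh
  quick <- train_dec(z, 3, spec = sp, max_iter = 600, tol = 1,
                     update_interval = 60)
  expect_equal(max(quick$trace$iteration), 60)
  # reproducibility of the full run
  fit2 <- train_dec(z, 3, spec = sp, max_iter = 600, update_interval = 60)
  expect_identical(fit$result$labels, fit2$result$labels)
  expect_equal(fit$trace, fit2$trace)
})

test_that("run_dec_ensemble is order-stable and agrees on separable data", {
  b <- make_blobs(n_per = 20, k = 3, p = 6, gap = 6, seed = 10)
  z <- standardize(b$fm)
  sp <- autoencoder_spec(hidden_widths = c(16, 4), pretrain_epochs = 40)
  runs <- run_dec_ensemble(z, 3, n_runs = 3, base_seed = 5, spec = sp,
                           max_iter = 400, update_interval = 50)
  single <- train_dec(z, 3, spec = {s <- sp; s$seed <- 5L; s},
                      max_iter = 400, update_interval = 50)
  expect_identical(runs[[1]]$result$labels, single$result$labels)
  agree <- outer(seq_along(runs), seq_along(runs), Vectorize(function(i, j)
    adjusted_rand(runs[[i]]$result$labels, runs[[j]]$result$labels)))
  expect_true(all(agree >= 0.8))
})
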