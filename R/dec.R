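# ---- minimal MLP machinery (vectorised base R) ------------------------------
# A network is a list of layers, each list(W, b), with a parallel vector of
# activation tags ("relu" or "linear"). Gradients are summed over the batch;
# callers divide by the batch size.

mlp_init <- function(widths, acts, seed) {
  local_seed(seed, {
    lapply(seq_len(length(widths) - 1), function(l) {
      fan_in <- widths[l]
      sc <- if (acts[l] == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
      list(W = matrix(rnorm(fan_in * widths[l + 1], 0, sc), fan_in,
                      widths[l + 1]),
           b = rep(0, widths[l + 1]))
    })
  })
}

mlp_forward <- function(layers, acts, X) {
  A <- list(X)
  Z <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    Zl <- A[[l]] %*% layers[[l]]$W
    Zl <- sweep(Zl, 2, layers[[l]]$b, "+")
    Z[[l]] <- Zl
    A[[l + 1]] <- if (acts[l] == "relu") pmax(Zl, 0) else Zl
  }
  list(A = A, Z = Z)
}

mlp_backward <- function(layers, acts, cache, dOut) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (l in rev(seq_along(layers))) {
    dZ <- if (acts[l] == "relu") dA * (cache$Z[[l]] > 0) else dA
    grads[[l]] <- list(W = crossprod(cache$A[[l]], dZ), b = colSums(dZ))
    dA <- dZ %*% t(layers[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

# optimizer state: momentum velocity (sgd) or first/second moments (adam)
opt_zero_state <- function(layers) {
  lapply(layers, function(ly) list(W = ly$W * 0, b = ly$b * 0,
                                   W2 = ly$W * 0, b2 = ly$b * 0, t = 0L))
}

opt_step <- function(layers, grads, state, spec) {
  lr <- spec$learning_rate
  if (identical(spec$optimizer, "sgd")) {
    mom <- spec$momentum
    for (l in seq_along(layers)) {
      state[[l]]$W <- mom * state[[l]]$W - lr * grads[[l]]$W
      state[[l]]$b <- mom * state[[l]]$b - lr * grads[[l]]$b
      layers[[l]]$W <- layers[[l]]$W + state[[l]]$W
      layers[[l]]$b <- layers[[l]]$b + state[[l]]$b
    }
  } else {  # adam
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (l in seq_along(layers)) {
      st <- state[[l]]
      st$t <- st$t + 1L
      st$W <- b1 * st$W + (1 - b1) * grads[[l]]$W
      st$b <- b1 * st$b + (1 - b1) * grads[[l]]$b
      st$W2 <- b2 * st$W2 + (1 - b2) * grads[[l]]$W^2
      st$b2 <- b2 * st$b2 + (1 - b2) * grads[[l]]$b^2
      c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
      layers[[l]]$W <- layers[[l]]$W - lr * (st$W / c1) /
        (sqrt(st$W2 / c2) + eps)
      layers[[l]]$b <- layers[[l]]$b - lr * (st$b / c1) /
        (sqrt(st$b2 / c2) + eps)
      state[[l]] <- st
    }
  }
  list(layers = layers, state = state)
}

#' Autoencoder architecture and training hyper-parameters
#'
#' @param hidden_widths encoder hidden widths ending at the embedding
#'   dimension (default `c(64, 32, 10)`, i.e. input -> 64 -> 32 -> 10)
#' @param activation hidden activation (`"relu"`); bottleneck and output
#'   are linear
#' @param pretrain_epochs reconstruction-training epochs
#' @param learning_rate step size (Adam default 0.002; use ~0.01 for SGD)
#' @param momentum SGD momentum (ignored by Adam)
#' @param optimizer `"adam"` (default: reaches a usable representation
#'   within desk-scale epoch budgets) or `"sgd"` (fixed rate + momentum)
#' @param batch_size minibatch size
#' @param denoise_sd SD of the Gaussian input corruption during pretraining
#'   (denoising autoencoder; reconstruction targets stay clean). Corruption
#'   makes the encoder prefer structure that is redundant across features —
#'   the cluster signal — over feature-specific noise; 0 disables it
#' @param seed integer seed driving init and shuffling
#' @return object of class `autoencoder_spec`
#' @export
autoencoder_spec <- function(hidden_widths = c(64, 32, 10),
                             activation = "relu",
                             pretrain_epochs = 100,
                             learning_rate = 0.002,
                             momentum = 0.9,
                             optimizer = c("adam", "sgd"),
                             batch_size = 64,
                             denoise_sd = 1,
                             seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(denoise_sd >= 0)
  stopifnot(length(hidden_widths) >= 1, all(hidden_widths >= 1),
            utils::tail(hidden_widths, 1) >= 2,
            pretrain_epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(hidden_widths = as.integer(hidden_widths),
                 activation = activation,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 learning_rate = learning_rate, momentum = momentum,
                 optimizer = optimizer,
                 batch_size = as.integer(batch_size),
                 denoise_sd = denoise_sd,
                 seed = as.integer(seed)),
            class = "autoencoder_spec")
}

#' Pretrain an MLP autoencoder on reconstruction error
#'
#' Symmetric encoder/decoder with ReLU hidden layers and linear bottleneck
#' and output, trained by minibatch SGD with momentum on mean squared
#' reconstruction error. Deterministic given the spec's seed.
#'
#' @param fm a standardized `feature_matrix` (or bare matrix)
#' @param spec an [autoencoder_spec()]
#' @return object of class `autoencoder` with `encoder_layers`,
#'   `decoder_layers`, activation tags and the per-epoch `loss_trace`
#' @export
pretrain_autoencoder <- function(fm, spec = autoencoder_spec()) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (any(!is.finite(X))) stop("non-finite inputs")
  p <- ncol(X)
  n <- nrow(X)
  enc_w <- c(p, spec$hidden_widths)
  dec_w <- rev(enc_w)
  ne <- length(enc_w) - 1
  nd <- length(dec_w) - 1
  acts <- c(rep(spec$activation, ne - 1), "linear",   # encoder, linear bottleneck
            rep(spec$activation, nd - 1), "linear")   # decoder, linear output
  widths <- c(enc_w, dec_w[-1])
  layers <- mlp_init(widths, acts, spec$seed)
  state <- opt_zero_state(layers)
  bs <- min(spec$batch_size, n)
  loss_trace <- numeric(spec$pretrain_epochs)
  local_seed(child_seed(spec$seed, 1L), {
    for (ep in seq_len(spec$pretrain_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        xb <- X[idx, , drop = FALSE]
        xin <- if (spec$denoise_sd > 0)
          xb + matrix(rnorm(length(xb), 0, spec$denoise_sd), nrow(xb))
        else xb
        cache <- mlp_forward(layers, acts, xin)
        xhat <- cache$A[[length(cache$A)]]
        err <- xhat - xb
        ep_loss <- ep_loss + mean(err^2)
        nb <- nb + 1
        bw <- mlp_backward(layers, acts, cache,
                           2 * err / (length(idx) * p))
        up <- opt_step(layers, bw$grads, state, spec)
        layers <- up$layers
        state <- up$state
      }
      loss_trace[ep] <- ep_loss / nb
    }
  })
  structure(list(encoder_layers = layers[seq_len(ne)],
                 encoder_acts = acts[seq_len(ne)],
                 decoder_layers = layers[(ne + 1):(ne + nd)],
                 decoder_acts = acts[(ne + 1):(ne + nd)],
                 spec = spec, loss_trace = loss_trace),
            class = "autoencoder")
}

#' Encode data into the autoencoder's latent space
#' @param model an `autoencoder` or `dec_model`
#' @param X matrix or `feature_matrix`
#' @return n x d_z embedding matrix
#' @export
encode <- function(model, X) {
  if (inherits(X, "feature_matrix")) X <- X$values
  mlp_forward(model$encoder_layers, model$encoder_acts, X)$A[[
    length(model$encoder_layers) + 1]]
}

#' Reconstruct data through the full autoencoder
#' @param model an `autoencoder`
#' @param X matrix or `feature_matrix`
#' @return reconstruction matrix of the same shape
#' @export
reconstruct <- function(model, X) {
  if (inherits(X, "feature_matrix")) X <- X$values
  Z <- encode(model, X)
  mlp_forward(model$decoder_layers, model$decoder_acts, Z)$A[[
    length(model$decoder_layers) + 1]]
}

#' Initialize cluster centroids by k-means in the latent space
#' @param Z n x d_z embedding matrix
#' @param k number of centroids
#' @param seed integer seed (delegates to [kmeans_cluster()])
#' @return k x d_z centroid matrix
#' @export
init_centroids <- function(Z, k, seed = 1L) {
  if (nrow(Z) < k) stop("fewer points than centroids")
  kmeans_cluster(Z, k, seed = seed)$diagnostics$centers
}

#' Student's-t soft assignment of embeddings to centroids
#'
#' `q_ij = (1 + ||z_i - mu_j||^2 / alpha)^(-(alpha+1)/2)`, normalized over
#' clusters so each row sums to 1.
#'
#' @param Z n x d_z embeddings
#' @param centroids k x d_z centroid matrix
#' @param alpha Student's-t degrees of freedom (default 1)
#' @return n x k row-stochastic matrix Q
#' @export
soft_assign <- function(Z, centroids, alpha = 1) {
  d2 <- row_dist2(Z, centroids)
  num <- (1 + d2 / alpha)^(-(alpha + 1) / 2)
  num / rowSums(num)
}

#' Self-training target distribution
#'
#' `p_ij` proportional to `q_ij^2 / f_j` with cluster frequencies
#' `f_j = sum_i q_ij`, renormalized per row. Sharpens confident assignments
#' while down-weighting large clusters.
#'
#' @param Q row-stochastic soft-assignment matrix
#' @return row-stochastic matrix P with `max_j p_ij >= max_j q_ij` per row
#' @export
target_distribution <- function(Q) {
  f <- colSums(Q)
  W <- sweep(Q^2, 2, f, "/")
  W / rowSums(W)
}

#' Kullback-Leibler divergence loss between target and assignment
#'
#' `sum_ij p_ij log(p_ij / q_ij)` with `0 log 0 := 0`. Errors if some
#' `q_ij = 0` where `p_ij > 0`.
#'
#' @param P,Q matched row-stochastic matrices
#' @return nonnegative scalar, 0 iff `P == Q`
#' @export
kl_loss <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop("shape mismatch")
  pos <- P > 0
  if (any(Q[pos] == 0)) stop("q_ij = 0 where p_ij > 0")
  sum(P[pos] * log(P[pos] / Q[pos]))
}

#' Train a deep embedded clustering model
#'
#' Pretrains the autoencoder, initializes k centroids by k-means on the
#' embeddings, then alternates: every `update_interval` gradient batches the
#' target distribution P is recomputed from the full-data soft assignment Q,
#' and training stops when the fraction of points whose hard label changed
#' since the previous update falls below `tol` (or at `max_iter` batches).
#' Gradient steps update the encoder and the centroids against the KL loss.
#'
#' @param fm standardized `feature_matrix`
#' @param k number of clusters (>= 2)
#' @param spec an [autoencoder_spec()]; its seed drives the whole run
#' @param max_iter maximum gradient batches (default 8000)
#' @param tol stopping threshold on the label-change fraction (default 0.01)
#' @param record_assignments keep the full soft-assignment matrix Q at
#'   every target refresh (in `$q_record`; memory scales with n x k x
#'   updates — diagnostics/testing only)
#' @param update_interval batches between target-distribution refreshes
#' @param alpha Student's-t degrees of freedom
#' @return list with `model` (class `dec_model`: encoder + `centroids` +
#'   `alpha` + `k`), `result` (a `clustering_result`, hard labels =
#'   `argmax_j q_ij`) and `trace` (data.frame: iteration, kl_loss,
#'   label_change_fraction)
#' @export
train_dec <- function(fm, k, spec = autoencoder_spec(), max_iter = 8000,
                      record_assignments = FALSE,
                      tol = 0.01, update_interval = 140, alpha = 1) {
  if (k < 2) stop("k must be >= 2")
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  n <- nrow(X)
  ae <- pretrain_autoencoder(fm, spec)
  enc <- ae$encoder_layers
  acts <- ae$encoder_acts
  Z <- mlp_forward(enc, acts, X)$A[[length(enc) + 1]]
  mu <- init_centroids(Z, k, seed = child_seed(spec$seed, 2L))

  # fine-tuning uses plain SGD with momentum: gentler than Adam, it
  # polishes the k-means initialisation instead of overriding it
  ft_spec <- spec
  ft_spec$optimizer <- "sgd"
  ft_spec$learning_rate <- 0.01
  state <- opt_zero_state(enc)
  mu_layer <- list(list(W = mu, b = numeric(nrow(mu))))
  mu_state <- opt_zero_state(mu_layer)
  bs <- min(spec$batch_size, n)

  Q <- soft_assign(Z, mu, alpha)
  stopifnot(max(abs(rowSums(Q) - 1)) < 1e-8)
  P <- target_distribution(Q)
  labels_prev <- max.col(Q, ties.method = "first")
  trace <- data.frame(iteration = 0L, kl_loss = kl_loss(P, Q),
                      label_change_fraction = NA_real_)
  q_record <- if (record_assignments) list(Q) else NULL

  local_seed(child_seed(spec$seed, 3L), {
    ord <- sample.int(n)
    pos <- 1L
    it <- 0L
    converged <- FALSE
    while (it < max_iter && !converged) {
      it <- it + 1L
      if (pos + bs - 1L > n) {
        ord <- sample.int(n)
        pos <- 1L
      }
      idx <- ord[pos:(pos + bs - 1L)]
      pos <- pos + bs
      xb <- X[idx, , drop = FALSE]
      cache <- mlp_forward(enc, acts, xb)
      zb <- cache$A[[length(enc) + 1]]
      d2 <- row_dist2(zb, mu)
      base <- (1 + d2 / alpha)
      qb <- base^(-(alpha + 1) / 2)
      qb <- qb / rowSums(qb)
      pb <- P[idx, , drop = FALSE]
      w <- (pb - qb) / base                       # (p - q) * (1 + d2/a)^-1
      coef <- (alpha + 1) / alpha / length(idx)
      dZ <- coef * (rowSums(w) * zb - w %*% mu)
      dMu <- -coef * (crossprod(w, zb) - colSums(w) * mu)
      bw <- mlp_backward(enc, acts, cache, dZ)
      up <- opt_step(enc, bw$grads, state, ft_spec)
      enc <- up$layers
      state <- up$state
      upmu <- opt_step(mu_layer, list(list(W = dMu, b = numeric(nrow(mu)))),
                       mu_state, ft_spec)
      mu_layer <- upmu$layers
      mu_state <- upmu$state
      mu <- mu_layer[[1]]$W

      if (it %% update_interval == 0L || it == max_iter) {
        Z <- mlp_forward(enc, acts, X)$A[[length(enc) + 1]]
        Q <- soft_assign(Z, mu, alpha)
        if (any(!is.finite(Q)))
          stop(sprintf("non-finite soft assignment at iteration %d", it))
        stopifnot(max(abs(rowSums(Q) - 1)) < 1e-8)
        labels <- max.col(Q, ties.method = "first")
        delta <- mean(labels != labels_prev)
        P <- target_distribution(Q)
        stopifnot(max(abs(rowSums(P) - 1)) < 1e-8)
        kl <- kl_loss(P, Q)
        if (!is.finite(kl))
          stop(sprintf("non-finite loss at iteration %d", it))
        trace <- rbind(trace, data.frame(iteration = it, kl_loss = kl,
                                         label_change_fraction = delta))
        if (record_assignments) q_record[[length(q_record) + 1L]] <- Q
        labels_prev <- labels
        if (delta < tol) converged <- TRUE
      }
    }
  })
  labels <- max.col(Q, ties.method = "first") - 1L
  model <- structure(list(encoder_layers = enc, encoder_acts = acts,
                          centroids = mu, alpha = alpha, k = as.integer(k),
                          spec = spec), class = "dec_model")
  used <- length(unique(labels))
  result <- new_clustering_result(
    labels, k, "dec", spec$seed,
    list(kl_trace = trace, converged = trace$label_change_fraction[
      nrow(trace)] < tol, n_label_ids_used = used))
  out <- list(model = model, result = result, trace = trace)
  if (record_assignments) out$q_record <- q_record
  out
}

#' Predict DEC soft assignments / labels for (new) data
#' @param model a `dec_model`
#' @param fm `feature_matrix` or matrix on the training scale
#' @return list with `Q` and 0-based hard `labels`
#' @export
predict_dec <- function(model, fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  Z <- mlp_forward(model$encoder_layers, model$encoder_acts, X)$A[[
    length(model$encoder_layers) + 1]]
  Q <- soft_assign(Z, model$centroids, model$alpha)
  list(Q = Q, labels = max.col(Q, ties.method = "first") - 1L)
}

#' Run an ensemble of independent DEC trainings
#'
#' `n_runs` calls of [train_dec()] with seeds `base_seed, base_seed + 1,
#' ...`; order-stable and reproducible per seed.
#'
#' @param fm standardized `feature_matrix`
#' @param k number of clusters
#' @param n_runs ensemble size (full-scale default 100; scale down for
#'   desk runs)
#' @param base_seed first seed
#' @param spec template [autoencoder_spec()] (its seed field is overridden)
#' @param ... passed to [train_dec()]
#' @return list of `train_dec` results
#' @export
run_dec_ensemble <- function(fm, k, n_runs = 100, base_seed = 1L,
                             spec = autoencoder_spec(), ...) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(r) {
    sp <- spec
    sp$seed <- as.integer(base_seed + r - 1L)
    tryCatch(train_dec(fm, k, spec = sp, ...),
             error = function(e) stop(sprintf("DEC run %d failed: %s", r,
                                              conditionMessage(e))))
  })
}

#' Save / load a DEC model checkpoint
#'
#' Serializes encoder weights, centroids, alpha and the training spec into
#' a single JSON file (text-only, portable); `load_dec_model()` restores a
#' model whose predictions are bit-identical to the original.
#'
#' @param model a `dec_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
save_dec_model <- function(model, path) {
  stopifnot(inherits(model, "dec_model"))
  payload <- list(
    layers = lapply(model$encoder_layers, function(l)
      list(W = l$W, b = l$b)),
    acts = model$encoder_acts,
    centroids = model$centroids,
    alpha = model$alpha, k = model$k,
    spec = unclass(model$spec))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_dec_model
#' @export
load_dec_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  as_mat <- function(x)
    if (is.matrix(x)) x else matrix(unlist(x), nrow = length(x),
                                    byrow = TRUE)
  layers <- lapply(p$layers, function(l)
    list(W = as_mat(l$W), b = as.numeric(l$b)))
  spec <- as.list(p$spec)
  spec$hidden_widths <- as.integer(spec$hidden_widths)
  class(spec) <- "autoencoder_spec"
  structure(list(encoder_layers = layers, encoder_acts = p$acts,
                 centroids = as_mat(p$centroids),
                 alpha = p$alpha, k = as.integer(p$k), spec = spec),
            class = "dec_model")
}
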