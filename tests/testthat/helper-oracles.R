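# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms (recursions instead of dynamic
# programs, explicit loops instead of vectorised identities).

# DTW by explicit enumeration of every monotone warping path
dtw_enumerate <- function(a, b) {
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (i == length(a) && j == length(b)) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < length(a)) walk(i + 1, j, acc)
    if (j < length(b)) walk(i, j + 1, acc)
    if (i < length(a) && j < length(b)) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# silhouette by direct per-point loops
silhouette_brute <- function(d, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == cl]))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# naive O(n^3) average-linkage agglomeration, returns merge heights
average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  heights
}

# exact Shapley over all coalitions with the marginal-expectation value
# function: v(S) = mean over background rows of f(x_S, b_notS)
shapley_brute <- function(f, x, background, p = length(x)) {
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  vs <- apply(subsets, 1, function(S) {
    X <- background
    X[, S] <- matrix(x[S], nrow(background), sum(S), byrow = TRUE)
    mean(apply(X, 1, f))
  })
  key <- function(S) sum(2^(which(S) - 1)) + 1
  for (i in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- as.logical(subsets[r, ])
      if (S[i]) next
      Si <- S
      Si[i] <- TRUE
      w <- factorial(sum(S)) * factorial(p - sum(S) - 1) / factorial(p)
      phi[i] <- phi[i] + w * (vs[key(Si)] - vs[key(S)])
    }
  }
  phi
}

# hand log-rank tabulation over event times (explicit loop, two groups)
logrank_brute <- function(times, events, g1) {
  et <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in et) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# small separable gaussian feature matrix with known labels
make_blobs <- function(n_per = 20, k = 3, p = 5, gap = 8, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(c)
    matrix(rnorm(n_per * p, mean = gap * c), n_per, p)))
  labels <- rep(seq_len(k) - 1L, each = n_per)
  list(fm = phenodec:::new_feature_matrix(
    X, paste0("f", seq_len(p)), sprintf("pt%03d", seq_len(n_per * k))),
    labels = labels)
}

# tiny handmade cohort: `spec_list` is a list per patient of named lists
# variable -> list(times, values); roster fixed
make_cohort <- function(spec_list, roster, outcomes = NULL) {
  patients <- lapply(seq_along(spec_list), function(i) {
    labs <- lapply(roster, function(v) {
      s <- spec_list[[i]][[v]]
      if (is.null(s)) phenodec:::lab_series(v)
      else phenodec:::lab_series(v, s$times, s$values)
    })
    names(labs) <- roster
    o <- if (is.null(outcomes)) list(time_to_event_days = 90, event = 0L,
                                     icu_death = 0L, death_30d = 0L,
                                     death_90d = 0L, aki_stage = 0L,
                                     icu_los_days = 3, rrt = 0L, shock = 0L,
                                     vasoactive = 0L) else outcomes[[i]]
    list(patient_id = sprintf("pt%03d", i), statics = c(age = 60),
         labs = labs, outcome = o, true_cluster = NULL)
  })
  structure(list(patients = patients, variable_names = roster,
                 config = NULL), class = "phenodec_cohort")
}

# fresh scratch directory under the session tempdir (cleaned up with it)
withr_local_tempdir <- function() {
  d <- tempfile("phenodec")
  dir.create(d, recursive = TRUE)
  d
}
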