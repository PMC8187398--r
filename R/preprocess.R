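#' Screen patients by variable-level missingness
#'
#' A patient's missing fraction is the share of roster lab variables for
#' which no measurement was registered at any moment during the stay.
#' Patients with a fraction strictly greater than `threshold` (default 10%)
#' are excluded. Partial gaps inside a measured series do not count.
#'
#' @param cohort a `phenodec_cohort`
#' @param threshold exclusion threshold in \[0, 1\]
#' @return list with the filtered `cohort` and a `report` (class
#'   `screen_report`) holding `included_ids`, `excluded_ids` and the
#'   per-patient `missing_fraction`
#' @export
screen_patients <- function(cohort, threshold = 0.10) {
  stopifnot(inherits(cohort, "phenodec_cohort"))
  if (length(cohort$patients) == 0) stop("empty cohort")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  roster <- cohort$variable_names
  frac <- vapply(cohort$patients, function(p) {
    empty <- vapply(roster, function(v) {
      s <- p$labs[[v]]
      is.null(s) || length(s$values) == 0
    }, logical(1))
    mean(empty)
  }, numeric(1))
  ids <- vapply(cohort$patients, `[[`, character(1), "patient_id")
  names(frac) <- ids
  keep <- frac <= threshold
  out <- cohort
  out$patients <- cohort$patients[keep]
  report <- structure(list(included_ids = ids[keep],
                           excluded_ids = ids[!keep],
                           missing_fraction = frac,
                           threshold = threshold),
                      class = "screen_report")
  list(cohort = out, report = report)
}

#' Rolling-mean imputation of a lab series onto a daily grid
#'
#' Observations are first aligned to the daily grid (slot value = mean of the
#' observations falling in that day). Empty slots after the first observed
#' slot are filled with the mean of up to `window` most recent slot values
#' (observed or previously imputed); slots before the first observation fall
#' back to `population_mean`, the ICU-level mean of the variable.
#'
#' @param series a lab series (list with `variable`, `times` in hours,
#'   `values`)
#' @param grid vector of slot start times in hours (e.g. `seq(0, 96, 24)`);
#'   slot i covers `[grid[i], grid[i+1])`, the last slot is unbounded
#' @param window number of recent values averaged into a gap (>= 1)
#' @param population_mean fallback for leading gaps / fully empty series
#' @return lab series with `times = grid` and fully imputed `values`
#' @export
rolling_mean_impute <- function(series, grid, window = 3,
                                population_mean = NA_real_) {
  if (window < 1) stop("window must be >= 1")
  ng <- length(grid)
  if (ng == 0) stop("empty grid")
  slot <- findInterval(series$times, grid)
  vals <- rep(NA_real_, ng)
  for (s in unique(slot[slot >= 1]))
    vals[s] <- mean(series$values[slot == s])
  if (all(is.na(vals)) && !is.finite(population_mean))
    stop("fully empty series with non-finite population_mean")
  first_obs <- which(!is.na(vals))[1]
  if (is.na(first_obs)) first_obs <- ng + 1L
  for (i in seq_len(ng)) {
    if (!is.na(vals[i])) next
    if (i < first_obs) {
      vals[i] <- population_mean
    } else {
      recent <- vals[max(1, i - window):(i - 1)]
      recent <- recent[!is.na(recent)]
      vals[i] <- mean(utils::tail(recent, window))
    }
  }
  lab_series(series$variable, grid, vals)
}

#' Fill measurement gaps in all lab series of a cohort
#'
#' Daily-grid gap filling that leaves observed measurements untouched: for
#' each patient and variable, days of the stay without any observation get
#' one imputed point (at the day's start time) from [rolling_mean_impute()],
#' with the cohort mean of the variable as the cold-start fallback. Series
#' with at least one observation every day pass through unchanged, so
#' imputation is a no-op on complete cohorts.
#'
#' @param cohort a screened `phenodec_cohort`
#' @param window rolling window (day values)
#' @return cohort with gap-free series
#' @export
impute_cohort <- function(cohort, window = 3) {
  stopifnot(inherits(cohort, "phenodec_cohort"))
  roster <- cohort$variable_names
  pop_mean <- vapply(roster, function(v) {
    allv <- unlist(lapply(cohort$patients, function(p) p$labs[[v]]$values))
    if (length(allv)) mean(allv) else NA_real_
  }, numeric(1))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    stay_h <- max(24, p$outcome$icu_los_days * 24,
                  unlist(lapply(p$labs, function(s) {
                    if (length(s$times)) max(s$times) else 0
                  })))
    grid <- 24 * (seq_len(ceiling(stay_h / 24)) - 1)
    for (v in roster) {
      s <- p$labs[[v]]
      day_vals <- rolling_mean_impute(s, grid, window, pop_mean[[v]])
      observed_day <- unique(findInterval(s$times, grid))
      gap_days <- setdiff(seq_along(grid), observed_day)
      if (length(gap_days) == 0) next
      tt <- c(s$times, grid[gap_days])
      vv <- c(s$values, day_vals$values[gap_days])
      o <- order(tt)
      cohort$patients[[i]]$labs[[v]] <- lab_series(v, tt[o], vv[o])
    }
  }
  cohort
}

#' Iterative (chained-equations style) imputation of a static matrix
#'
#' Missing cells are initialized with the column mean (continuous) or mode
#' (binary), then `n_iter` sweeps regress each incomplete column on all
#' others by ordinary least squares over its observed rows and replace its
#' missing cells with the fitted values. Deterministic; the `seed` argument
#' is accepted for interface stability.
#'
#' @param x numeric matrix with `NA` cells; every column needs at least one
#'   observed value
#' @param n_iter number of sweeps
#' @param seed unused (kept for call-site compatibility)
#' @return completed matrix with no non-finite entries
#' @export
iterative_impute <- function(x, n_iter = 10, seed = NULL) {
  x <- as.matrix(x)
  if (any(colSums(!is.na(x)) == 0)) stop("all-missing column")
  miss <- is.na(x)
  if (!any(miss)) return(x)
  is_bin <- apply(x, 2, function(col) {
    obs <- col[!is.na(col)]
    all(obs %in% c(0, 1))
  })
  for (j in seq_len(ncol(x))) {
    mj <- miss[, j]
    if (!any(mj)) next
    obs <- x[!mj, j]
    x[mj, j] <- if (is_bin[j]) {
      as.numeric(names(which.max(table(obs))))
    } else mean(obs)
  }
  incomplete <- which(colSums(miss) > 0)
  for (it in seq_len(n_iter)) {
    for (j in incomplete) {
      mj <- miss[, j]
      X <- cbind(1, x[, -j, drop = FALSE])
      fit <- stats::lm.fit(X[!mj, , drop = FALSE], x[!mj, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0  # rank-deficient predictors contribute nothing
      x[mj, j] <- X[mj, , drop = FALSE] %*% beta
    }
  }
  if (any(!is.finite(x))) stop("imputation produced non-finite values")
  x
}

new_feature_matrix <- function(values, feature_names, patient_ids,
                               scaling = "raw") {
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  dimnames(values) <- list(patient_ids, feature_names)
  structure(list(values = values, feature_names = feature_names,
                 patient_ids = patient_ids, scaling = scaling),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s)\n", nrow(x$values),
              ncol(x$values), x$scaling))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# row-subset a feature matrix (bootstrap resampling)
fm_subset <- function(fm, idx) {
  new_feature_matrix(fm$values[idx, , drop = FALSE], fm$feature_names,
                     fm$patient_ids[idx], fm$scaling)
}

#' Extract the fixed-length feature vector of every patient
#'
#' Features are the static variables followed, per lab variable in roster
#' order, by the sample mean and sample variance (divisor n-1; variance 0
#' for a single measurement) of the full-stay series. Run after screening
#' and imputation; empty series are an error here.
#'
#' @param cohort a screened, imputed `phenodec_cohort`
#' @return a `feature_matrix` with `scaling = "raw"`
#' @export
extract_features <- function(cohort) {
  stopifnot(inherits(cohort, "phenodec_cohort"))
  roster <- cohort$variable_names
  if (length(roster) == 0) stop("empty variable roster")
  pts <- cohort$patients
  static_names <- names(pts[[1]]$statics)
  p <- length(static_names) + 2L * length(roster)
  values <- matrix(NA_real_, length(pts), p)
  for (i in seq_along(pts)) {
    pt <- pts[[i]]
    row <- as.numeric(pt$statics[static_names])
    for (v in roster) {
      s <- pt$labs[[v]]
      if (is.null(s) || length(s$values) == 0)
        stop(sprintf("empty series for %s in %s: impute before extracting",
                     v, pt$patient_id))
      m <- mean(s$values)
      vv <- if (length(s$values) > 1) stats::var(s$values) else 0
      row <- c(row, m, vv)
    }
    values[i, ] <- row
  }
  fn <- c(static_names,
          as.vector(rbind(paste0(roster, "_mean"), paste0(roster, "_var"))))
  ids <- vapply(pts, `[[`, character(1), "patient_id")
  new_feature_matrix(values, fn, ids, "raw")
}

#' Standardize feature columns
#'
#' Rescales each column to mean 0 and SD 1 using the population SD (divisor
#' n). Zero-variance columns map to all-zeros rather than NaN. Idempotent.
#'
#' @param fm a `feature_matrix`
#' @return standardized `feature_matrix` (`scaling = "standardized"`)
#' @export
standardize <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  n <- nrow(x)
  if (n < 2) stop("need at least 2 rows to standardize")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(x^2) - mu^2)
  sdv <- pmax(sdv, 0)
  z <- sweep(x, 2, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0
  new_feature_matrix(z, fm$feature_names, fm$patient_ids, "standardized")
}

#' Project features onto principal components
#'
#' PCA of the standardized matrix; each component's sign is fixed so that
#' its largest-absolute loading is positive.
#'
#' @param fm a `feature_matrix`
#' @param n_components number of components, in `[1, min(n, p)]`
#' @param seed unused (deterministic); kept for interface symmetry
#' @return `feature_matrix` of scores (`scaling = "pca"`)
#' @export
reduce_pca <- function(fm, n_components, seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  z <- standardize(fm)$values
  if (n_components < 1 || n_components > min(dim(z)))
    stop("n_components out of range")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- z %*% rot
  new_feature_matrix(scores, paste0("PC", seq_len(n_components)),
                     fm$patient_ids, "pca")
}
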