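#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_j <= t} (1 - d_j / n_j)` over distinct event times, with
#' deaths preceding censorings at tied times (subjects censored at t are
#' still at risk for events at t).
#'
#' @param times nonnegative follow-up times (days)
#' @param events 0/1 event flags
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `survival` (rows at distinct event times)
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("no subjects")
  if (any(times < 0)) stop("negative times")
  if (length(events) != length(times)) stop("length mismatch")
  et <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), n_risk = integer(0),
                    n_event = integer(0), survival = numeric(0))
  for (t in et) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, n_risk = n_risk, n_event = d,
                                 survival = s))
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' Chi-square statistic `(sum(O1 - E1))^2 / sum(V)` over the pooled distinct
#' event times, 1 degree of freedom, with the hypergeometric variance at
#' each event time. Zero total events makes the statistic undefined
#' (returned as `NA` with `p = NA`).
#'
#' @param times follow-up times
#' @param events 0/1 event flags
#' @param groups two-level group labels
#' @return list with `statistic`, `df`, `p`, `observed`, `expected` (length
#'   2, group order = sorted unique labels)
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2) stop("logrank_test needs exactly 2 groups")
  if (any(tabulate(g) == 0)) stop("empty group")
  in1 <- g == levels(g)[1]
  et <- sort(unique(times[events == 1]))
  if (length(et) == 0)
    return(list(statistic = NA_real_, df = 1L, p = NA_real_,
                observed = c(0, 0), expected = c(0, 0),
                note = "zero events"))
  # counts at each event time (vectorised over event times)
  n_tot <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_1 <- vapply(et, function(t) sum(times >= t & in1), numeric(1))
  d_tot <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  d_1 <- vapply(et, function(t) sum(times == t & events == 1 & in1),
                numeric(1))
  E1 <- d_tot * n_1 / n_tot
  V <- ifelse(n_tot > 1,
              d_tot * (n_1 / n_tot) * (1 - n_1 / n_tot) *
                (n_tot - d_tot) / (n_tot - 1), 0)
  O1 <- sum(d_1)
  stat <- (O1 - sum(E1))^2 / sum(V)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = c(O1, sum(d_tot) - O1),
       expected = c(sum(E1), sum(d_tot) - sum(E1)))
}

#' Per-cluster hazard ratios from log-rank O/E counts
#'
#' Each cluster is contrasted against its complement (the default; see
#' below for the pooled-cohort variant), truncating follow-up at `horizon`
#' days. The hazard ratio is `(O_in/E_in) / (O_out/E_out)` with a 95% CI of
#' `exp(log HR +- 1.96 sqrt(1/O_in + 1/O_out))` and the p-value from the
#' two-group log-rank test. A cluster with zero events is flagged
#' (`HR = NA`) without affecting the others.
#'
#' `reference = "cohort"` uses the full cohort's Nelson-Aalen expected
#' counts as the denominator (a literal full-cohort reference; statistically
#' improper because the cluster is part of its own reference, retained only
#' for comparability).
#'
#' @param times follow-up times (days)
#' @param events 0/1 event flags
#' @param labels cluster labels (0-based)
#' @param horizon optional truncation in days
#' @param reference `"complement"` (default) or `"cohort"`
#' @return data.frame with one row per cluster: `cluster`, `n`, `pct_event`,
#'   `O_in`, `E_in`, `O_out`, `E_out`, `HR`, `ci_lo`, `ci_hi`, `p`, `note`
#' @export
cluster_hazard_ratios <- function(times, events, labels, horizon = NULL,
                                  reference = c("complement", "cohort")) {
  reference <- match.arg(reference)
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  if (!is.null(horizon)) {
    events <- ifelse(times > horizon, 0L, events)
    times <- pmin(times, horizon)
  }
  rows <- lapply(sort(unique(labels)), function(cl) {
    inc <- labels == cl
    lr <- logrank_test(times, events, ifelse(inc, "in", "out"))
    # logrank_test orders groups alphabetically: "in" first
    O_in <- lr$observed[1]; E_in <- lr$expected[1]
    O_out <- lr$observed[2]; E_out <- lr$expected[2]
    if (reference == "cohort") {
      # expected events under the pooled-cohort cumulative hazard
      km_all <- km_estimate(times, events)
      ch <- stats::stepfun(km_all$time,
                           c(0, cumsum(km_all$n_event / km_all$n_risk)))
      E_in <- sum(ch(times[inc]))
      E_out <- sum(ch(times[!inc]))
      O_out <- sum(events[!inc])
    }
    if (O_in == 0 || O_out == 0 || E_in == 0 || E_out == 0) {
      data.frame(cluster = cl, n = sum(inc),
                 pct_event = 100 * mean(events[inc]),
                 O_in = O_in, E_in = E_in, O_out = O_out, E_out = E_out,
                 HR = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 p = lr$p, note = "degenerate: too few events")
    } else {
      hr <- (O_in / E_in) / (O_out / E_out)
      se <- sqrt(1 / O_in + 1 / O_out)
      data.frame(cluster = cl, n = sum(inc),
                 pct_event = 100 * mean(events[inc]),
                 O_in = O_in, E_in = E_in, O_out = O_out, E_out = E_out,
                 HR = hr, ci_lo = hr * exp(-1.96 * se),
                 ci_hi = hr * exp(1.96 * se), p = lr$p, note = "")
    }
  })
  do.call(rbind, rows)
}

#' Between-cluster feature and outcome tests
#'
#' One-way ANOVA (F test) for continuous features and Pearson chi-squared
#' (no continuity correction, expected counts from the margins) for binary
#' features. Zero-variance continuous features are skipped with a reason.
#' Raw p-values; no multiplicity correction.
#'
#' @param fm `feature_matrix`, matrix or data.frame of features/outcomes
#' @param labels cluster labels
#' @return data.frame: `feature`, `test`, `statistic`, `p`, `note`
#' @export
between_cluster_tests <- function(fm, labels) {
  X <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  g <- factor(labels)
  rows <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    nm <- colnames(X)[j]
    if (is.null(nm)) nm <- paste0("f", j)
    if (all(x %in% c(0, 1))) {
      tab <- table(factor(x, levels = c(0, 1)), g)
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(E == 0))
        return(data.frame(feature = nm, test = "chisq",
                          statistic = NA_real_, p = NA_real_,
                          note = "empty margin"))
      stat <- sum((tab - E)^2 / E)
      df <- (nrow(tab) - 1) * (ncol(tab) - 1)
      data.frame(feature = nm, test = "chisq", statistic = stat,
                 p = stats::pchisq(stat, df, lower.tail = FALSE), note = "")
    } else {
      if (stats::sd(x) == 0)
        return(data.frame(feature = nm, test = "anova",
                          statistic = NA_real_, p = NA_real_,
                          note = "zero variance"))
      fit <- stats::oneway.test(x ~ g, var.equal = TRUE)
      data.frame(feature = nm, test = "anova",
                 statistic = unname(fit$statistic), p = fit$p.value,
                 note = "")
    }
  })
  do.call(rbind, rows)
}

#' Collect survival data from a cohort
#' @param cohort a `phenodec_cohort`
#' @param horizon one of `"icu"`, `30`, `90` selecting the event flag and
#'   time scale; default overall (90-day) follow-up
#' @return data.frame with `patient_id`, `time`, `event`
#' @export
cohort_survival <- function(cohort, horizon = 90) {
  stopifnot(inherits(cohort, "phenodec_cohort"))
  rows <- lapply(cohort$patients, function(p) {
    o <- p$outcome
    if (identical(horizon, "icu")) {
      data.frame(patient_id = p$patient_id,
                 time = min(o$time_to_event_days, o$icu_los_days),
                 event = o$icu_death)
    } else {
      h <- as.numeric(horizon)
      data.frame(patient_id = p$patient_id,
                 time = pmin(o$time_to_event_days, h),
                 event = as.integer(o$event == 1 & o$time_to_event_days <= h))
    }
  })
  do.call(rbind, rows)
}
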