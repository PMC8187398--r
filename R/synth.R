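#' Default laboratory-variable roster
#'
#' Forty lab names typical of a general ICU panel (routine chemistry,
#' haematology and arterial point-of-care values). Purely cosmetic: the
#' generator treats variables identically up to their cluster effects.
#'
#' @return character vector of length 40
#' @export
default_lab_names <- function() {
  c("alat", "asat", "albumin", "amylase", "alp", "bilirubin", "gamma_gt",
    "ck", "crp", "calcium", "chloride", "magnesium", "mcv", "sodium",
    "phosphate", "potassium", "fibrinogen", "hemoglobin", "hematocrit",
    "creatinine", "ldh", "leukocytes", "thrombocytes", "troponin_t",
    "total_protein", "urea", "poc_ca_ion", "poc_glucose", "poc_hemoglobin",
    "poc_potassium", "poc_lactate", "poc_sodium", "poc_hco3", "poc_pco2",
    "poc_ph", "poc_po2", "poc_saturation", "poc_methb", "poc_hbco", "poc_be")
}

default_static_names <- function(n_cont, n_bin) {
  cont <- c("age", "apache_iv", "saps_ii", "bmi", "heart_rate", "map",
            "urine_output", "emv_score", "resp_rate", "cvp")
  bin <- c("surgical", "prev_icu", "hist_cvd", "hist_ckd", "hist_cirrhosis",
           "hist_copd", "hist_diabetes", "hist_hemat_malig", "hist_metastatic",
           "hist_mi", "hist_resp_insuff", "prev_dialysis")
  list(cont = c(cont, sprintf("static_c%02d", seq_len(max(0, n_cont - length(cont)))))[seq_len(n_cont)],
       bin = c(bin, sprintf("static_b%02d", seq_len(max(0, n_bin - length(bin)))))[seq_len(n_bin)])
}

#' Configuration of a synthetic ICU cohort
#'
#' Describes the statistical world the pipeline assumes: latent clusters with
#' unequal sizes, cluster-specific lab means/variances on a subset of
#' informative variables, irregular within-stay sampling, per-patient
#' variable-level missingness, and cluster-conditional event hazards.
#'
#' Defaults mirror a single-centre general-ICU cohort: 40 lab variables with
#' on average 21 measurements each, 90-day follow-up horizons, and six
#' latent clusters with sizes proportional to (68, 100, 46, 144, 290, 95).
#'
#' @param n_patients number of patients
#' @param n_clusters number of latent clusters
#' @param cluster_proportions simplex vector of length `n_clusters`
#' @param n_lab_variables number of laboratory variables
#' @param mean_measurements_per_variable Poisson mean of per-variable
#'   measurement counts (zero-truncated)
#' @param n_static_continuous,n_static_binary static feature counts
#' @param cluster_mean_shift separation of informative-feature cluster means,
#'   in SD units
#' @param n_informative_features how many lab variables carry cluster signal
#' @param missing_variable_rate per-patient probability a lab variable is
#'   entirely unmeasured
#' @param hazard_ratios per-cluster event-hazard multipliers (length
#'   `n_clusters`, all positive)
#' @param baseline_hazard baseline death hazard per day
#' @param followup_horizons mortality horizons in days
#' @param aki_probs per-cluster probability of severe (stage 2-3) AKI
#' @param mean_los_days mean ICU length of stay (exponential)
#' @param patient_effect_sd between-patient within-cluster spread of each
#'   lab's set-point, in base-SD units (log-SD units for lognormal labs).
#'   Patients have individual levels around their cluster mean; this is the
#'   SD that `cluster_mean_shift` is measured against
#' @param outlier_rate fraction of patients given heavy-tailed lab excursions
#' @param outlier_scale excursion magnitude in SD units (Cauchy-tailed)
#' @param lab_log_sd when > 0, lab values are lognormal with this sdlog and
#'   cluster effects act on the log scale — the skewed, heavy-tailed
#'   marginals typical of ICU chemistry (CK, bilirubin, CRP); 0 keeps
#'   Gaussian labs
#' @param seed integer seed; the cohort is a pure function of the config
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_patients = 600,
                          n_clusters = 6,
                          cluster_proportions = c(68, 100, 46, 144, 290, 95) / 743,
                          n_lab_variables = 40,
                          mean_measurements_per_variable = 21,
                          n_static_continuous = 7,
                          n_static_binary = 7,
                          cluster_mean_shift = 3,
                          n_informative_features = min(10, n_lab_variables),
                          missing_variable_rate = 0.02,
                          hazard_ratios = c(1, 1.55, 1.8, 0.57, 0.92, 0.87),
                          baseline_hazard = 0.004,
                          followup_horizons = c(30, 90),
                          aki_probs = c(0.5, 0.56, 0.74, 0.19, 0.45, 0.48),
                          mean_los_days = 6,
                          patient_effect_sd = 1,
                          outlier_rate = 0,
                          outlier_scale = 0,
                          lab_log_sd = 0,
                          seed = 1L) {
  stopifnot(n_patients >= 1, n_clusters >= 1,
            n_lab_variables >= 1, mean_measurements_per_variable > 0,
            n_static_continuous >= 0, n_static_binary >= 0,
            cluster_mean_shift >= 0,
            n_informative_features >= 0,
            n_informative_features <= n_lab_variables,
            baseline_hazard > 0, mean_los_days > 0,
            outlier_rate >= 0, outlier_rate <= 1, outlier_scale >= 0,
            lab_log_sd >= 0, patient_effect_sd >= 0)
  if (length(cluster_proportions) != n_clusters)
    stop("cluster_proportions must have length n_clusters")
  if (abs(sum(cluster_proportions) - 1) > 1e-12)
    stop("cluster_proportions must sum to 1")
  if (any(cluster_proportions < 0)) stop("cluster_proportions must be >= 0")
  if (n_clusters > n_patients) stop("n_clusters > n_patients")
  if (missing_variable_rate < 0 || missing_variable_rate > 1)
    stop("missing_variable_rate must be in [0, 1]")
  if (length(hazard_ratios) != n_clusters || any(hazard_ratios <= 0))
    stop("hazard_ratios must be positive, length n_clusters")
  if (length(aki_probs) != n_clusters || any(aki_probs < 0 | aki_probs > 1))
    stop("aki_probs must be in [0, 1], length n_clusters")
  structure(list(
    n_patients = as.integer(n_patients), n_clusters = as.integer(n_clusters),
    cluster_proportions = cluster_proportions,
    n_lab_variables = as.integer(n_lab_variables),
    mean_measurements_per_variable = mean_measurements_per_variable,
    n_static_continuous = as.integer(n_static_continuous),
    n_static_binary = as.integer(n_static_binary),
    cluster_mean_shift = cluster_mean_shift,
    n_informative_features = as.integer(n_informative_features),
    missing_variable_rate = missing_variable_rate,
    hazard_ratios = hazard_ratios, baseline_hazard = baseline_hazard,
    followup_horizons = followup_horizons, aki_probs = aki_probs,
    mean_los_days = mean_los_days, patient_effect_sd = patient_effect_sd,
    outlier_rate = outlier_rate, outlier_scale = outlier_scale,
    lab_log_sd = lab_log_sd,
    seed = as.integer(seed)), class = "cohort_config")
}

lab_series <- function(variable, times = numeric(0), values = numeric(0)) {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  list(variable = variable, times = as.numeric(times),
       values = as.numeric(values))
}

# zero-truncated Poisson draws via inverse CDF
rtpois <- function(n, lambda) {
  u <- runif(n, ppois(0, lambda), 1)
  qpois(u, lambda)
}

#' Generate a synthetic ICU cohort
#'
#' Draws each patient's latent cluster from `cluster_proportions`, then
#' simulates static features (cluster-shifted Gaussians, cluster-rate
#' Bernoullis), irregular lab time-series with cluster-specific means and
#' variances on the informative variables, variable-level missingness, and
#' cluster-conditional exponential survival censored administratively at 90
#' days. The informative lab variables are the first
#' `n_informative_features` of the roster. All effect sizes scale with
#' `cluster_mean_shift`, so a zero shift gives a signal-free cohort.
#'
#' @param config a [cohort_config()]
#' @return object of class `phenodec_cohort`: list with `patients`,
#'   `variable_names` and the `config`; each patient carries its latent
#'   `true_cluster` (0-based)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  cf <- config
  local_seed(cf$seed, {
    K <- cf$n_clusters
    V <- cf$n_lab_variables
    roster <- c(default_lab_names(),
                sprintf("lab_%02d", seq_len(max(0, V - 40))))[seq_len(V)]
    sn <- default_static_names(cf$n_static_continuous, cf$n_static_binary)

    # per-variable base scale and per-cluster effects
    base_mean <- runif(V, 1, 100)
    base_sd <- 0.15 * base_mean + 1
    shift <- matrix(0, K, V)
    ninf <- cf$n_informative_features
    if (ninf > 0)
      shift[, seq_len(ninf)] <- matrix(rnorm(K * ninf), K, ninf) *
        cf$cluster_mean_shift
    sd_mult <- matrix(1, K, V)
    if (ninf > 0 && cf$cluster_mean_shift > 0)
      sd_mult[, seq_len(ninf)] <- matrix(runif(K * ninf, 0.7, 1.5), K, ninf)

    nc <- cf$n_static_continuous
    nb <- cf$n_static_binary
    stat_mean <- if (nc) runif(nc, 10, 90) else numeric(0)
    stat_sd <- 0.15 * stat_mean + 1
    stat_shift <- if (nc) matrix(rnorm(K * nc), K, nc) *
      (0.5 * cf$cluster_mean_shift) else matrix(0, K, 0)
    bin_base <- if (nb) runif(nb, 0.05, 0.5) else numeric(0)
    bin_logit_shift <- if (nb) matrix(rnorm(K * nb), K, nb) *
      (0.5 * cf$cluster_mean_shift) else matrix(0, K, 0)

    n <- cf$n_patients
    cl <- sample.int(K, n, replace = TRUE, prob = cf$cluster_proportions)
    los <- rexp(n, 1 / cf$mean_los_days)
    los <- pmax(los, 0.5)  # everybody stays at least half a day

    # survival: exponential with cluster hazard, administrative censor at 90 d
    haz <- cf$baseline_hazard * cf$hazard_ratios[cl]
    t_death <- rexp(n, haz)
    horizon <- max(cf$followup_horizons)
    event <- as.integer(t_death <= horizon)
    t_obs <- pmin(t_death, horizon)

    out_n <- sample.int(n, size = round(cf$outlier_rate * n))

    patients <- vector("list", n)
    for (i in seq_len(n)) {
      k <- cl[i]
      stay_h <- los[i] * 24
      statics <- numeric(0)
      if (nc) {
        statics <- rnorm(nc, stat_mean + stat_shift[k, ] * stat_sd, stat_sd)
        names(statics) <- sn$cont
      }
      if (nb) {
        pb <- plogis(qlogis(bin_base) + bin_logit_shift[k, ])
        bv <- rbinom(nb, 1, pb)
        names(bv) <- sn$bin
        statics <- c(statics, bv)
      }
      m <- rtpois(V, cf$mean_measurements_per_variable)
      labs <- vector("list", V)
      for (v in seq_len(V)) {
        tt <- sort(runif(m[v], 0, stay_h))
        while (anyDuplicated(tt)) tt <- sort(tt + runif(m[v], 0, 1e-6))
        vals <- if (cf$lab_log_sd > 0) {
          # lognormal labs: cluster shift and patient set-point act on the
          # log scale; within-patient noise is half the between-patient SD
          setpt <- log(base_mean[v]) + shift[k, v] * cf$lab_log_sd +
            rnorm(1, 0, cf$patient_effect_sd * cf$lab_log_sd)
          exp(rnorm(m[v], setpt, 0.5 * cf$lab_log_sd * sd_mult[k, v]))
        } else {
          setpt <- base_mean[v] + shift[k, v] * base_sd[v] +
            rnorm(1, 0, cf$patient_effect_sd * base_sd[v])
          rnorm(m[v], setpt, base_sd[v] * sd_mult[k, v])
        }
        labs[[v]] <- lab_series(roster[v], tt, vals)
      }
      names(labs) <- roster
      if (i %in% out_n && cf$outlier_scale > 0) {
        # heavy-tailed excursions: a stay-long shift in a few labs whose
        # magnitude has Cauchy tails, emulating variables like CK or
        # bilirubin that span orders of magnitude in a handful of patients
        hit <- sample.int(V, min(5L, V))
        for (v in hit) {
          mag <- cf$outlier_scale * base_sd[v] * stats::rcauchy(1)
          labs[[v]]$values <- labs[[v]]$values + mag
        }
      }
      sev <- rbinom(1, 1, cf$aki_probs[k])
      aki <- if (sev) sample(2:3, 1) else sample(0:1, 1, prob = c(0.7, 0.3))
      icu_death <- as.integer(event[i] == 1 && t_death[i] <= los[i])
      los_i <- if (icu_death) min(los[i], t_death[i]) else los[i]
      outcome <- list(
        time_to_event_days = t_obs[i], event = event[i],
        icu_death = icu_death,
        death_30d = as.integer(event[i] == 1 && t_death[i] <= 30),
        death_90d = as.integer(event[i] == 1 && t_death[i] <= 90),
        aki_stage = aki, icu_los_days = los_i,
        rrt = rbinom(1, 1, 0.05 + 0.25 * sev),
        shock = rbinom(1, 1, plogis(qlogis(0.45) +
                                      0.5 * log(cf$hazard_ratios[k]))),
        vasoactive = rbinom(1, 1, plogis(qlogis(0.48) +
                                           0.5 * log(cf$hazard_ratios[k]))))
      patients[[i]] <- list(patient_id = sprintf("pt%05d", i),
                            statics = statics, labs = labs,
                            outcome = outcome, true_cluster = k - 1L)
    }
    cohort <- structure(list(patients = patients, variable_names = roster,
                             config = cf), class = "phenodec_cohort")
    if (cf$missing_variable_rate > 0)
      cohort <- inject_missingness(cohort, cf$missing_variable_rate,
                                   seed = child_seed(cf$seed, 777L))
    cohort
  })
}

#' @export
print.phenodec_cohort <- function(x, ...) {
  cat(sprintf("<phenodec_cohort> %d patients, %d lab variables\n",
              length(x$patients), length(x$variable_names)))
  invisible(x)
}

#' Empty out lab series at random (variable-level missingness)
#'
#' Each patient-by-variable pair is independently emptied (all measurements
#' removed) with probability `rate`. The input cohort is not modified.
#'
#' @param cohort a `phenodec_cohort`
#' @param rate probability in \[0, 1\]
#' @param seed integer seed
#' @return a new cohort
#' @export
inject_missingness <- function(cohort, rate, seed) {
  stopifnot(inherits(cohort, "phenodec_cohort"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0) return(cohort)
  local_seed(seed, {
    for (i in seq_along(cohort$patients)) {
      drop <- runif(length(cohort$variable_names)) < rate
      for (v in which(drop)) {
        nm <- cohort$variable_names[v]
        cohort$patients[[i]]$labs[[nm]] <- lab_series(nm)
      }
    }
    cohort
  })
}

#' True latent cluster labels of a synthetic cohort
#' @param cohort a `phenodec_cohort` produced by [generate_cohort()]
#' @return 0-based integer labels
#' @export
true_clusters <- function(cohort) {
  vapply(cohort$patients, function(p)
    if (is.null(p$true_cluster)) NA_integer_ else p$true_cluster, integer(1))
}
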