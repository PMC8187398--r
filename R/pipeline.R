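#' Write a cohort to the three-CSV layout
#'
#' Emits `statics.csv` (patient_id + static columns), `labs.csv`
#' (long format: patient_id, variable, time_hours, value), `outcomes.csv`
#' and, when latent truth is present, `truth.csv` (patient_id,
#' true_cluster). Comma-separated, UTF-8, header row, "." decimal; empty
#' cell = missing.
#'
#' @param cohort a `phenodec_cohort`
#' @param dir output directory (created if needed)
#' @return invisibly, the written file paths
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phenodec_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pts <- cohort$patients
  ids <- vapply(pts, `[[`, character(1), "patient_id")
  statics <- do.call(rbind, lapply(pts, function(p) as.data.frame(
    as.list(p$statics), check.names = FALSE)))
  statics <- cbind(patient_id = ids, statics)
  labs <- do.call(rbind, lapply(pts, function(p) {
    do.call(rbind, lapply(p$labs, function(s) {
      if (length(s$times) == 0) return(NULL)
      data.frame(patient_id = p$patient_id, variable = s$variable,
                 time_hours = s$times, value = s$values)
    }))
  }))
  if (is.null(labs))
    labs <- data.frame(patient_id = character(0), variable = character(0),
                       time_hours = numeric(0), value = numeric(0))
  outcomes <- do.call(rbind, lapply(pts, function(p)
    cbind(data.frame(patient_id = p$patient_id),
          as.data.frame(p$outcome))))
  paths <- file.path(dir, c("statics.csv", "labs.csv", "outcomes.csv"))
  utils::write.csv(statics, paths[1], row.names = FALSE)
  utils::write.csv(labs, paths[2], row.names = FALSE)
  utils::write.csv(outcomes, paths[3], row.names = FALSE)
  tc <- true_clusters(cohort)
  if (!all(is.na(tc))) {
    tp <- file.path(dir, "truth.csv")
    utils::write.csv(data.frame(patient_id = ids, true_cluster = tc), tp,
                     row.names = FALSE)
    paths <- c(paths, tp)
  }
  # variable roster, so empty-lab cohorts round-trip
  vp <- file.path(dir, "variables.csv")
  utils::write.csv(data.frame(variable = cohort$variable_names), vp,
                   row.names = FALSE)
  invisible(c(paths, vp))
}

#' Load a cohort from the three-CSV layout
#'
#' Validates the schema (named columns, row numbers in errors), checks ids
#' across files, sorts each series by time, and rejects duplicate
#' timestamps within a series and lab rows referencing unknown patients.
#'
#' @param statics_path,labs_path,outcomes_path CSV paths
#' @param variable_names lab roster; defaults to `variables.csv` next to
#'   the labs file, else the distinct variables present
#' @return a `phenodec_cohort`
#' @export
load_cohort <- function(statics_path, labs_path, outcomes_path,
                        variable_names = NULL) {
  for (p in c(statics_path, labs_path, outcomes_path))
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  statics <- utils::read.csv(statics_path, check.names = FALSE)
  labs <- utils::read.csv(labs_path)
  outcomes <- utils::read.csv(outcomes_path)
  need <- c("patient_id", "variable", "time_hours", "value")
  miss <- setdiff(need, names(labs))
  if (length(miss))
    stop(sprintf("labs file missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (!"patient_id" %in% names(statics)) stop("statics missing patient_id")
  if (!"patient_id" %in% names(outcomes)) stop("outcomes missing patient_id")
  ids <- statics$patient_id
  if (anyDuplicated(ids)) stop("duplicate patient_id in statics")
  if (!setequal(ids, outcomes$patient_id))
    stop("patient ids differ between statics and outcomes")
  bad <- which(!(labs$patient_id %in% ids))
  if (length(bad))
    stop(sprintf("labs row %d references unknown patient '%s'",
                 bad[1], labs$patient_id[bad[1]]))
  if (is.null(variable_names)) {
    vp <- file.path(dirname(labs_path), "variables.csv")
    variable_names <- if (file.exists(vp))
      utils::read.csv(vp)$variable else sort(unique(labs$variable))
  }
  unknown <- setdiff(unique(labs$variable), variable_names)
  if (length(unknown))
    stop(sprintf("unknown lab variable(s): %s",
                 paste(unknown, collapse = ", ")))
  out_by_id <- split(outcomes, outcomes$patient_id)
  labs_by_id <- split(labs, labs$patient_id)
  static_cols <- setdiff(names(statics), "patient_id")
  patients <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    sv <- as.numeric(statics[i, static_cols])
    names(sv) <- static_cols
    li <- labs_by_id[[id]]
    series <- lapply(variable_names, function(v) {
      if (is.null(li)) return(lab_series(v))
      rows <- li[li$variable == v, , drop = FALSE]
      if (nrow(rows) == 0) return(lab_series(v))
      rows <- rows[order(rows$time_hours), , drop = FALSE]
      if (anyDuplicated(rows$time_hours))
        stop(sprintf("duplicate timestamp for %s / %s", id, v))
      lab_series(v, rows$time_hours, rows$value)
    })
    names(series) <- variable_names
    o <- as.list(out_by_id[[id]][1, setdiff(names(outcomes), "patient_id")])
    list(patient_id = id, statics = sv, labs = series, outcome = o,
         true_cluster = NULL)
  })
  structure(list(patients = patients,
                 variable_names = as.character(variable_names),
                 config = NULL), class = "phenodec_cohort")
}

#' Pipeline run configuration
#'
#' @param synth_config a [cohort_config()] (or NULL when reading CSVs)
#' @param input_dir directory with statics/labs/outcomes CSVs (used when
#'   `synth_config` is NULL)
#' @param algorithms subset of `c("kmeans", "hc", "hcdtw", "dec")`
#' @param k_range candidate cluster counts for stability selection
#' @param k fixed cluster count (skips selection when not NULL)
#' @param B stability resamples
#' @param n_runs DEC ensemble size
#' @param n_folds classifier CV folds
#' @param seed master seed; every stage seed derives from it
#' @param out_dir output directory
#' @param fast_mode reduced epochs/iterations for desk-scale runs
#' @return list of class `run_config`
#' @export
run_config <- function(synth_config = cohort_config(),
                       input_dir = NULL,
                       algorithms = c("kmeans", "hc", "hcdtw", "dec"),
                       k_range = 3:8, k = NULL, B = 100, n_runs = 100,
                       n_folds = 10, seed = 1L, out_dir = "phenodec_run",
                       fast_mode = FALSE) {
  algorithms <- match.arg(algorithms, c("kmeans", "hc", "hcdtw", "dec"),
                          several.ok = TRUE)
  if (length(algorithms) == 0) stop("empty algorithm set")
  structure(list(synth_config = synth_config, input_dir = input_dir,
                 algorithms = algorithms, k_range = k_range, k = k,
                 B = as.integer(B), n_runs = as.integer(n_runs),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 out_dir = out_dir, fast_mode = isTRUE(fast_mode)),
            class = "run_config")
}

fast_spec <- function(config, seed) {
  if (config$fast_mode)
    autoencoder_spec(pretrain_epochs = 10, seed = seed)
  else autoencoder_spec(seed = seed)
}

dec_iter_opts <- function(config) {
  if (config$fast_mode) list(max_iter = 1500, update_interval = 100)
  else list(max_iter = 8000, update_interval = 140)
}

#' Run the end-to-end sub-phenotyping pipeline
#'
#' Screen -> rolling-mean impute -> feature extraction -> standardize ->
#' clustering per requested algorithm -> validity and stability -> k
#' selection (DEC-based, unless `k` is fixed) -> DEC ensemble -> classifier
#' cross-validation per run -> best run -> Shapley attributions and feature
#' rankings -> per-cluster survival and feature contrasts. All artifacts
#' are written under `config$out_dir` and listed, with md5 checksums, in
#' `manifest.json`. A single master seed fans out deterministically.
#'
#' @param config a [run_config()]
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  manifest <- list(config = config[setdiff(names(config), "synth_config")],
                   stages = list(), files = list())
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
    path
  }
  done <- function(s) manifest$stages[[s]] <<- "ok"
  tryCatch({
    cohort <- if (!is.null(config$input_dir)) {
      load_cohort(file.path(config$input_dir, "statics.csv"),
                  file.path(config$input_dir, "labs.csv"),
                  file.path(config$input_dir, "outcomes.csv"))
    } else generate_cohort(config$synth_config)
    done("load")

    stage <- "screen"
    sc <- screen_patients(cohort)
    cohort <- sc$cohort
    emit("screen_report.json", function(p) jsonlite::write_json(
      list(included = sc$report$included_ids,
           excluded = sc$report$excluded_ids,
           missing_fraction = as.list(sc$report$missing_fraction)),
      p, auto_unbox = TRUE, digits = NA))
    done("screen")

    stage <- "impute"
    cohort <- impute_cohort(cohort)
    done("impute")

    stage <- "features"
    fm_raw <- extract_features(cohort)
    # statics may carry NA when read from CSV; chain-impute them
    if (any(is.na(fm_raw$values)))
      fm_raw$values <- iterative_impute(fm_raw$values)
    fm <- standardize(fm_raw)
    emit("features.csv", function(p) utils::write.csv(
      data.frame(patient_id = fm_raw$patient_ids, fm_raw$values,
                 check.names = FALSE), p, row.names = FALSE))
    done("features")

    stage <- "cluster"
    k0 <- if (is.null(config$k)) max(3L, min(6L, nrow(fm$values) - 1L))
          else config$k
    results <- list()
    if ("kmeans" %in% config$algorithms)
      results$kmeans <- kmeans_cluster(fm, k0,
                                       seed = child_seed(config$seed, 11L))
    if ("hc" %in% config$algorithms)
      results$hc <- hier_cluster(fm, k0, "ward")
    if ("hcdtw" %in% config$algorithms)
      results$hcdtw <- hc_dtw_cluster(cohort, k0)
    done("cluster")

    stage <- "validity"
    dm <- euclidean_distances(fm)
    validity <- lapply(results, function(r) {
      sil <- silhouette_score(dm, r$labels)
      sz <- size_distribution(r$labels)
      list(algorithm = r$algorithm, silhouette_mean = sil$mean,
           size_proportions = sz$proportions,
           largest_share = sz$largest_share,
           entropy = entropy_score(r$labels))
    })
    done("validity")

    stage <- "select_k"
    it <- dec_iter_opts(config)
    dec_clusterer <- function(kk) function(fmx, seed)
      train_dec(fmx, kk, spec = fast_spec(config, seed),
                max_iter = it$max_iter,
                update_interval = it$update_interval)$result
    if (is.null(config$k) && "dec" %in% config$algorithms) {
      sel <- select_k(fm, dec_clusterer, config$k_range, B = config$B,
                      seed = child_seed(config$seed, 21L))
      k_star <- sel$k_star
      emit("stability_report.json", function(p) jsonlite::write_json(
        lapply(sel$reports, function(r) r[c("per_cluster_jaccard",
                                            "mean_jaccard", "B", "k")]),
        p, auto_unbox = TRUE, digits = NA))
    } else k_star <- k0
    done("select_k")

    stage <- "dec"
    dec_runs <- NULL
    if ("dec" %in% config$algorithms) {
      dec_runs <- run_dec_ensemble(
        fm, k_star, n_runs = config$n_runs,
        base_seed = child_seed(config$seed, 31L),
        spec = fast_spec(config, 0L),
        max_iter = it$max_iter, update_interval = it$update_interval)
      results$dec <- dec_runs[[1]]$result
      validity$dec <- local({
        r <- results$dec
        sz <- size_distribution(r$labels)
        list(algorithm = "dec",
             silhouette_mean = silhouette_score(dm, r$labels)$mean,
             size_proportions = sz$proportions,
             largest_share = sz$largest_share,
             entropy = entropy_score(r$labels))
      })
      emit("train_trace.csv", function(p)
        utils::write.csv(dec_runs[[1]]$trace, p, row.names = FALSE))
    }
    emit("validity_report.json", function(p) jsonlite::write_json(
      validity, p, auto_unbox = TRUE, digits = NA))
    for (nm in names(results)) {
      r <- results[[nm]]
      emit(paste0("clusters_", nm, ".csv"), function(p) utils::write.csv(
        data.frame(patient_id = fm$patient_ids, label = r$labels), p,
        row.names = FALSE))
    }
    done("dec")

    stage <- "characterize"
    characterization <- NULL
    if ("dec" %in% config$algorithms) {
      hp <- if (config$fast_mode) list(n_trees = 60) else list()
      cvs <- lapply(seq_along(dec_runs), function(i)
        crossval_classifier(fm, dec_runs[[i]]$result$labels,
                            n_folds = config$n_folds,
                            seed = child_seed(config$seed, 41L + i),
                            hyperparams = hp, run_id = i))
      best <- select_best_run(lapply(cvs, `[[`, "report"))
      attr_m <- shapley_attributions(cvs[[best]]$model, fm,
                                     seed = child_seed(config$seed, 51L))
      rankings <- lapply(seq_len(dec_runs[[best]]$result$k) - 1L,
                         function(cl) rank_features(attr_m, cl, top_m = 15,
                                                    fm = fm))
      names(rankings) <- paste0("cluster_", seq_along(rankings) - 1L)
      emit("classifier_report.json", function(p) jsonlite::write_json(
        list(best_run = best,
             reports = lapply(cvs, function(x) list(
               run_id = x$report$run_id,
               mean_accuracy = x$report$mean_accuracy,
               fold_accuracies = x$report$fold_accuracies,
               sensitivity = x$report$per_cluster_sensitivity,
               specificity = x$report$per_cluster_specificity))),
        p, auto_unbox = TRUE, digits = NA))
      emit("rankings.json", function(p) jsonlite::write_json(
        rankings, p, auto_unbox = TRUE, digits = NA))
      characterization <- list(best = best, cvs = cvs,
                               labels = dec_runs[[best]]$result$labels)
    }
    done("characterize")

    stage <- "outcomes"
    final_labels <- if (!is.null(characterization))
      characterization$labels else results[[1]]$labels
    surv <- cohort_survival(cohort, horizon = 90)
    km_rows <- do.call(rbind, lapply(sort(unique(final_labels)),
      function(cl) {
        i <- final_labels == cl
        km <- km_estimate(surv$time[i], surv$event[i])
        if (nrow(km) == 0) return(NULL)
        cbind(cluster = cl, km)
      }))
    emit("km_curves.csv", function(p)
      utils::write.csv(km_rows, p, row.names = FALSE))
    hz <- do.call(rbind, lapply(c(30, 90), function(h)
      cbind(horizon = h,
            cluster_hazard_ratios(surv$time, surv$event, final_labels,
                                  horizon = h))))
    emit("hazard_table.csv", function(p)
      utils::write.csv(hz, p, row.names = FALSE))
    emit("tests.csv", function(p) utils::write.csv(
      between_cluster_tests(fm_raw, final_labels), p, row.names = FALSE))
    done("outcomes")

    manifest$status <- "success"
  }, error = function(e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (identical(manifest$status, "failed"))
    stop(sprintf("pipeline failed at stage '%s': %s",
                 manifest$failed_stage, manifest$error))
  invisible(manifest)
}
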