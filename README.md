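# phenodec

Deep-embedded-clustering sub-phenotyping of heterogeneous ICU cohorts, as a
tested, reusable R pipeline.

Critically ill patients are clinically heterogeneous: admission diagnoses
neither predict trajectories nor group similar patients. `phenodec`
discovers *sub-phenotypes* — data-derived patient subgroups with shared
laboratory/clinical structure and outcome risk — from routinely collected
ICU data, and characterizes them all the way to survival contrasts:

1. **Synthetic cohorts** (`cohort_config()`, `generate_cohort()`): seeded
   patient records with latent clusters of unequal size, ~40 irregular lab
   time-series per patient (≈21 measurements each), per-patient set-point
   variability, variable-level missingness, optional heavy-tailed
   (lognormal / Cauchy-outlier) regimes, and cluster-conditional
   exponential survival with 30/90-day and AKI outcomes. Real registries
   of this kind are not publicly distributable; the generator makes every
   downstream stage testable offline.
2. **Preprocessing** (`screen_patients()`, `impute_cohort()`,
   `iterative_impute()`, `extract_features()`, `standardize()`,
   `reduce_pca()`): patients missing >10% of lab variables entirely are
   excluded (strict inequality); daily-grid rolling-mean gap filling;
   chained OLS imputation for statics; per-lab mean + variance features.
3. **Four clustering methodologies**: k-means (k-means++, best-of-restarts
   Lloyd), Ward/average hierarchical clustering, hierarchical clustering on
   dynamic-time-warping distances (`hc_dtw_cluster()`), and deep embedded
   clustering (`train_dec()`, `run_dec_ensemble()`).
4. **Validity and stability** (`silhouette_score()`, `entropy_score()`,
   `bootstrap_stability()`, `select_k()`): bootstrap Jaccard cluster-wise
   stability with full retraining per resample selects the number of
   clusters.
5. **Classifier validation + attribution** (`crossval_classifier()`,
   `shapley_attributions()`, `rank_features()`): a cross-validated
   gradient-boosted tree classifier predicts cluster membership; exact
   interventional Shapley values give signed per-feature drivers per
   cluster.
6. **Outcomes** (`km_estimate()`, `logrank_test()`,
   `cluster_hazard_ratios()`, `between_cluster_tests()`): Kaplan–Meier
   curves, log-rank tests, O/E hazard ratios with 95% CIs per cluster, and
   ANOVA/chi-squared feature contrasts.

The core of DEC: an MLP autoencoder embeds each patient's feature vector
$x_i$ as $z_i$; soft assignments to centroids $\mu_j$ use a Student's-$t$
kernel, $q_{ij} \propto (1 + \lVert z_i-\mu_j\rVert^2)^{-1}$; training
minimizes $\mathrm{KL}(P\Vert Q)$ against the self-training target
$p_{ij} \propto q_{ij}^2 / \sum_i q_{ij}$, which sharpens assignments while
resisting the one-giant-cluster collapse that k-means and HC exhibit on
heavy-tailed ICU laboratory marginals. See the methods vignette
(`vignettes/phenodec-methods.Rmd`) for the full model, parameter meanings,
and design rationale.

## Worked example

```r
library(phenodec)

cohort  <- generate_cohort(cohort_config(n_patients = 300, seed = 7))
screened <- screen_patients(cohort)                 # 10% missingness screen
fm <- standardize(extract_features(impute_cohort(screened$cohort)))

fit <- train_dec(fm, k = 6, spec = autoencoder_spec(seed = 1),
                 max_iter = 2000, update_interval = 140)
adjusted_rand(fit$result$labels, true_clusters(screened$cohort))
#> [1] 0.9914624
size_distribution(fit$result$labels)$proportions
#> [1] 0.407 0.220 0.130 0.110 0.077 0.057
entropy_score(fit$result$labels)        # max for k = 6 is log 6 = 1.792
#> [1] 1.567

surv <- cohort_survival(screened$cohort, horizon = 90)
cluster_hazard_ratios(surv$time, surv$event, fit$result$labels,
                      horizon = 90)[, c("cluster", "n", "pct_event",
                                        "HR", "ci_lo", "ci_hi", "p")]
#>   cluster   n pct_event    HR ci_lo ci_hi     p
#> 1       0  17      35.3 1.739 0.753 4.015 0.189
#> 2       1 122      22.1 0.887 0.548 1.436 0.626
#> 3       2  39      25.6 1.206 0.617 2.355 0.583
#> 4       3  23      34.8 1.567 0.750 3.272 0.228
#> 5       4  33      33.3 1.713 0.900 3.261 0.097
#> 6       5  66      12.1 0.411 0.197 0.859 0.015
```

The DEC labels recover the generator's six latent clusters almost exactly
(adjusted Rand index 0.99); cluster sizes stay spread out (entropy 1.57 of
a possible 1.79); and the per-cluster hazard ratios contrast each cluster
against its complement — here cluster 5 is a low-risk group (HR 0.41,
p = 0.015 by log-rank) mirroring the generator's hazard gradient.

The full pipeline — screening through stability-based `k` selection, the
DEC ensemble, classifier validation, Shapley rankings, and outcome tables,
with a checksummed manifest — is one call:

```r
run_pipeline(run_config(synth_config = cohort_config(n_patients = 300),
                        seed = 1, out_dir = "run1", fast_mode = TRUE))
```

A command-line interface wraps the same stages:

```sh
Rscript inst/cli/phenodec synth --n 300 --seed 7 --out cohort_dir
Rscript inst/cli/phenodec run --input cohort_dir --fast --out run_dir
```

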