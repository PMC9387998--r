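#' Run the full synthetic saccadometry study end-to-end
#'
#' Orchestrates the pipeline: simulate a cohort, write the trajectory
#' files, label and QC-filter the trials, fit the second-order model to
#' every saccade, filter fits by damping-ratio precision, build the
#' participant feature table, run the univariate mixed-model analyses
#' (damping ratio, latency, amplitude) and the error-rate comparison,
#' and evaluate both classifiers by TLPO-CV and the 5x2cv combined
#' F-test. Every stage's outputs are written under `dir`, and a JSON
#' manifest records the stage sequence, seeds and files; re-running with
#' the same configuration and seed reproduces identical outputs. Stage
#' seeds are derived deterministically from the master seed so stages
#' can be re-run in isolation.
#'
#' @param config a [simulation_config()].
#' @param qc a [qc_config()].
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param stages character vector of stages to run after simulation;
#'   subset of `c("stats", "classify")` — damping fitting, QC and
#'   features always run.
#' @param n_trees forest size for the classification stage.
#' @return (invisibly) a list with the per-stage results: `cohort`,
#'   `kept`, `rejected`, `fits`, `kept_fits`, `features`, `stats`,
#'   `error_rate_test`, `tlpo`, `f_test`, `manifest`.
#' @export
run_pipeline <- function(config = simulation_config(), qc = qc_config(),
                         dir = tempfile("saccadom_run_"), seed = 1L,
                         stages = c("stats", "classify"),
                         n_trees = 400) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list())
  t_start <- Sys.time()
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, dir)
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)), class = "saccadom_pipeline_error")
    })
    manifest$stages[[name]] <<- list(status = "completed",
                                     seed = derive_seed(seed, length(manifest$stages) + 1))
    res
  }

  cohort <- stage("simulate", simulate_cohort(config, seed = derive_seed(seed, 1)))
  stage("write", write_trajectories(cohort,
                                    file.path(dir, "samples.csv"),
                                    file.path(dir, "trials.csv")))

  pre <- stage("preprocess", preprocess_trials(cohort$trials, qc))
  readr::write_csv(pre$kept, file.path(dir, "trials_kept.csv"))
  readr::write_csv(pre$rejected, file.path(dir, "trials_rejected.csv"))

  fits <- stage("fit_damping", fit_saccades(pre$kept, cohort$samples))
  readr::write_csv(fits, file.path(dir, "damping_fits.csv"))
  kept_fits <- filter_by_sigma_se(fits, qc$sigma_se_max)

  features <- stage("features", build_feature_table(pre$kept, kept_fits))
  write_feature_table(features, file.path(dir, "features.csv"))

  stats_res <- NULL; err_test <- NULL
  if ("stats" %in% stages) {
    stats_res <- stage("stats", {
      metric_tbl <- pre$kept %>%
        left_join(kept_fits %>%
                    select("participant_id", "task", "trial_index",
                           "sigma", "fit_mse"),
                  by = c("participant_id", "task", "trial_index"))
      list(
        damping = fit_metric_model(
          metric_tbl %>% filter(is.finite(.data$sigma)), "sigma"),
        latency = fit_metric_model(metric_tbl, "latency_ms"),
        amplitude = fit_metric_model(metric_tbl, "amplitude_deg",
                                     transform = "sqrt"))
    })
    err_test <- stage("error_rate", {
      rates <- features %>% filter(is.finite(.data$as_error_rate))
      mann_whitney_error_rate(rates$as_error_rate[rates$group == "pd"],
                              rates$as_error_rate[rates$group == "control"])
    })
    stats_json <- list(
      tests = purrr::map(stats_res, ~ as.data.frame(.x$tests)),
      error_rate = as.data.frame(err_test))
    jsonlite::write_json(stats_json, file.path(dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  tlpo <- NULL; ftest <- NULL
  if ("classify" %in% stages) {
    tlpo <- stage("classify", {
      list(logistic = tlpo_cv(features, logistic_trainer(),
                              seed = derive_seed(seed, 20)),
           forest = tlpo_cv(features, forest_trainer(n_trees = n_trees),
                            seed = derive_seed(seed, 21)))
    })
    ftest <- stage("evaluate", five_by_two_f_test(
      features, logistic_trainer(), forest_trainer(n_trees = n_trees),
      seed = derive_seed(seed, 22)))
    readr::write_csv(tlpo$logistic$roc, file.path(dir, "roc_logistic.csv"))
    readr::write_csv(tlpo$forest$roc, file.path(dir, "roc_forest.csv"))
    jsonlite::write_json(
      list(auc_logistic = tlpo$logistic$auc, auc_forest = tlpo$forest$auc,
           n_fits = tlpo$logistic$n_fits,
           f_statistic = ftest$statistic, f_p_value = ftest$p.value),
      file.path(dir, "classification.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  write_manifest(manifest, dir)
  invisible(list(cohort = cohort, kept = pre$kept, rejected = pre$rejected,
                 fits = fits, kept_fits = kept_fits, features = features,
                 stats = stats_res, error_rate_test = err_test,
                 tlpo = tlpo, f_test = ftest, manifest = manifest,
                 dir = dir))
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
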