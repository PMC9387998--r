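#' Read and write saccade trajectory files
#'
#' Trajectories are stored as two UTF-8 comma-separated files with `.`
#' decimal marks:
#'
#' * a long-format samples file with columns `participant_id`, `task`,
#'   `trial_index`, `t_ms`, `position_deg` (one row per position sample,
#'   times strictly increasing with constant spacing within a trial);
#' * a trials file with one row per trial: `participant_id`, `group`,
#'   `task`, `trial_index`, `target_side`, `foreperiod_s`,
#'   `response_type`, `direction`, `direction_error`, `latency_ms`,
#'   `amplitude_deg`, `peak_velocity_deg_s` and any additional columns
#'   (extra columns round-trip unchanged).
#'
#' `write_trajectories()` accepts a `saccade_cohort` or a
#' `list(trials =, samples =)`; `read_trajectories()` validates the schema
#' and the within-trial time grid and returns the same structure.
#'
#' @param cohort a `saccade_cohort` or list with `trials` and `samples`
#'   tibbles.
#' @param samples_path,trials_path file paths.
#' @return `read_trajectories()` returns a list with `trials` and
#'   `samples` tibbles; `write_trajectories()` returns the paths,
#'   invisibly.
#' @export
write_trajectories <- function(cohort, samples_path, trials_path) {
  stopifnot(is.list(cohort), !is.null(cohort$trials), !is.null(cohort$samples))
  readr::write_csv(cohort$samples, samples_path)
  readr::write_csv(cohort$trials, trials_path)
  invisible(c(samples = samples_path, trials = trials_path))
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(samples_path, trials_path) {
  samples <- readr::read_csv(samples_path, show_col_types = FALSE,
                             progress = FALSE)
  trials <- readr::read_csv(trials_path, show_col_types = FALSE,
                            progress = FALSE)
  need_s <- c("participant_id", "task", "trial_index", "t_ms", "position_deg")
  miss <- setdiff(need_s, names(samples))
  if (length(miss))
    abort(paste0("samples file is missing columns: ",
                 paste(miss, collapse = ", ")), class = "saccadom_schema_error")
  need_t <- c("participant_id", "group", "task", "trial_index", "target_side",
              "latency_ms", "amplitude_deg", "peak_velocity_deg_s")
  miss <- setdiff(need_t, names(trials))
  if (length(miss))
    abort(paste0("trials file is missing columns: ",
                 paste(miss, collapse = ", ")), class = "saccadom_schema_error")
  validate_sample_grid(samples)
  list(trials = trials, samples = samples)
}

# Within every trial, sample times must be strictly increasing on a
# constant grid; violations are reported with the offending trial.
validate_sample_grid <- function(samples) {
  if (!nrow(samples)) return(invisible(TRUE))
  bad <- samples %>%
    group_by(.data$participant_id, .data$task, .data$trial_index) %>%
    summarise(ok = {
      d <- diff(.data$t_ms)
      length(d) == 0 || (all(d > 0) && max(d) - min(d) < 1e-9)
    }, .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad)) {
    first <- bad[1, ]
    abort(sprintf(
      "non-constant or non-increasing sample times in trial %s/%s/%s (%d trial(s) affected)",
      first$participant_id, first$task, first$trial_index, nrow(bad)),
      class = "saccadom_validation_error")
  }
  invisible(TRUE)
}

# Fixed feature-column order of the participant feature table.
feature_vocabulary <- function() {
  stats_ <- c("median", "q1", "q3", "iqr", "skewness", "kurtosis")
  metrics <- c("fit_mse", "damping_ratio", "latency", "amplitude",
               "peak_velocity")
  c(as.vector(outer(stats_, metrics,
                    function(s, m) paste("ps", m, s, sep = "_"))),
    as.vector(outer(stats_, metrics,
                    function(s, m) paste("as", m, s, sep = "_"))),
    "as_error_rate")
}

#' Read and write participant feature tables
#'
#' One row per participant: `participant_id`, `group`, then the 61 named
#' feature columns (`{task}_{metric}_{stat}` for task `ps`/`as`, metric
#' `fit_mse`/`damping_ratio`/`latency`/`amplitude`/`peak_velocity`, stat
#' `median`/`q1`/`q3`/`iqr`/`skewness`/`kurtosis`, plus `as_error_rate`)
#' in a fixed documented order. Missing features are written as empty
#' cells.
#'
#' @param features tibble with `participant_id`, `group` and feature
#'   columns.
#' @param path file path.
#' @return `read_feature_table()` returns a tibble;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (anyDuplicated(features$participant_id))
    abort("duplicate participant_id in feature table.",
          class = "saccadom_validation_error")
  vocab <- feature_vocabulary()
  extra <- setdiff(names(features), c("participant_id", "group", vocab))
  if (length(extra))
    abort(paste0("unknown feature columns: ", paste(extra, collapse = ", ")),
          class = "saccadom_schema_error")
  ordered <- c("participant_id", "group", intersect(vocab, names(features)))
  readr::write_csv(features[ordered], path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"),
                        col_types = readr::cols(
                          participant_id = readr::col_character(),
                          group = readr::col_character(),
                          .default = readr::col_double()))
  if (!all(c("participant_id", "group") %in% names(ft)))
    abort("feature table must have participant_id and group columns.",
          class = "saccadom_schema_error")
  if (anyDuplicated(ft$participant_id))
    abort("duplicate participant_id in feature table.",
          class = "saccadom_validation_error")
  ft
}
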