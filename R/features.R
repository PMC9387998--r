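#' Six-number distributional summary
#'
#' Median, lower and upper quartile, interquartile range, skewness and
#' excess kurtosis of a sample. Quantiles use linear interpolation between
#' order statistics (R type 7); skewness is the adjusted Fisher-Pearson
#' standardised third moment and kurtosis the adjusted excess kurtosis
#' (both as in `e1071`, type 2). Shape statistics require enough distinct
#' values (3 for skewness, 4 for kurtosis) and positive variance;
#' otherwise they are `NA` — insufficient data is reported as missing,
#' never as a fabricated zero.
#'
#' @param values numeric vector (NAs dropped).
#' @return named numeric vector: `median`, `q1`, `q3`, `iqr`, `skewness`,
#'   `kurtosis`.
#' @examples
#' summarize_distribution(c(1, 2, 3, 4, 5))
#' @export
summarize_distribution <- function(values) {
  x <- values[is.finite(values)]
  out <- c(median = NA_real_, q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
           skewness = NA_real_, kurtosis = NA_real_)
  if (!length(x)) return(out)
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  out["median"] <- q[2]; out["q1"] <- q[1]; out["q3"] <- q[3]
  out["iqr"] <- q[3] - q[1]
  if (length(unique(x)) >= 3 && length(x) >= 3 && sd(x) > 0)
    out["skewness"] <- e1071::skewness(x, type = 2)
  if (length(unique(x)) >= 3 && length(x) >= 4 && sd(x) > 0)
    out["kurtosis"] <- e1071::kurtosis(x, type = 2)
  out
}

#' Build one participant's feature vector
#'
#' Reduces a participant's QC-passed, response-typed saccades (with their
#' damping fits) to the fixed 61-feature vector: for each task
#' (prosaccade; correct antisaccades only) and each metric (second-order
#' fit MSE, damping ratio, latency, amplitude, peak velocity), the six
#' summary statistics of [summarize_distribution()]; plus the antisaccade
#' directional error rate. Erroneous prosaccades made during the
#' antisaccade task contribute only to the error rate, whose denominator
#' is the number of directional AS responses (correct + error). Damping
#' and fit-MSE features use only saccades whose fits survived the
#' damping-precision filter.
#'
#' @param trials one participant's kept trials (columns `response_type`,
#'   `latency_ms`, `amplitude_deg`, `peak_velocity_deg_s`).
#' @param fits that participant's retained damping fits (columns `task`,
#'   `trial_index`, `sigma`, `fit_mse`), already filtered by
#'   [filter_by_sigma_se()]; may be `NULL` when damping features are
#'   unavailable.
#' @return a 1-row tibble of 61 named features (missing markers where a
#'   statistic is not computable).
#' @export
build_feature_vector <- function(trials, fits = NULL) {
  vocab <- feature_vocabulary()
  out <- setNames(as.list(rep(NA_real_, length(vocab))), vocab)

  for (tk in c("ps", "as")) {
    resp <- if (tk == "ps") "ps_correct" else "as_correct"
    tt <- trials[trials$response_type == resp, , drop = FALSE]
    metrics <- list(latency = tt$latency_ms,
                    amplitude = tt$amplitude_deg,
                    peak_velocity = tt$peak_velocity_deg_s)
    if (!is.null(fits) && nrow(tt)) {
      ff <- dplyr::semi_join(
        fits[fits$task == tk, , drop = FALSE],
        tt, by = c("participant_id", "task", "trial_index"))
      metrics$damping_ratio <- ff$sigma
      metrics$fit_mse <- ff$fit_mse
    }
    for (m in names(metrics)) {
      s <- summarize_distribution(metrics[[m]])
      for (st in names(s)) out[[paste(tk, m, st, sep = "_")]] <- unname(s[st])
    }
  }

  n_err <- sum(trials$response_type == "as_error")
  n_corr <- sum(trials$response_type == "as_correct")
  if (n_err + n_corr > 0) out[["as_error_rate"]] <- n_err / (n_err + n_corr)
  as_tibble(out)
}

#' Build the participant-by-feature table for a cohort
#'
#' Applies [build_feature_vector()] per participant and returns the
#' feature table used by the classifiers (one row per participant,
#' `participant_id`, `group`, then the 61 features).
#'
#' @param trials kept trials for the whole cohort (after
#'   [preprocess_trials()]).
#' @param fits retained damping fits (after [filter_by_sigma_se()]), or
#'   `NULL` to leave damping-derived features missing.
#' @return tibble with one row per participant.
#' @export
build_feature_table <- function(trials, fits = NULL) {
  parts <- trials %>% distinct(.data$participant_id, .data$group) %>%
    arrange(.data$participant_id)
  rows <- purrr::map(seq_len(nrow(parts)), function(i) {
    pid <- parts$participant_id[i]
    fv <- build_feature_vector(
      trials[trials$participant_id == pid, , drop = FALSE],
      if (is.null(fits)) NULL else fits[fits$participant_id == pid, , drop = FALSE])
    dplyr::bind_cols(tibble(participant_id = pid, group = parts$group[i]), fv)
  })
  bind_rows(rows)
}
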