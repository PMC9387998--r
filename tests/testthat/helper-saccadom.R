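# Shared fixtures and oracles, built in code at test time.

# Small simulated cohort, cached per session (trajectories included).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_pd = 4, n_control = 4, trials_per_task = 12)
      cache <<- simulate_cohort(cfg, seed = 101)
    }
    cache
  }
})

# Feature table derived from the generator's true per-trial parameters
# (no trajectory fitting): damping features use sigma_true; fit-error
# features stay missing. Used where classifier machinery, not the damping
# estimator, is under test.
features_from_true <- function(trials) {
  pseudo_fits <- tibble::tibble(
    participant_id = trials$participant_id, task = trials$task,
    trial_index = trials$trial_index,
    sigma = trials$sigma_true, fit_mse = NA_real_,
    sigma_se = 0, converged = TRUE)
  build_feature_table(trials, pseudo_fits)
}

# Feature-level synthetic cohort: iid standard-normal features with an
# optional mean shift on the first `n_inf` features for the pd group.
feature_cohort <- function(n_pd, n_control, p = 10, shift = 0, n_inf = 2,
                           seed = 1) {
  withr::with_seed(seed, {
    n <- n_pd + n_control
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, 0), c(n_pd, n_control))
    if (shift != 0 && n_inf > 0)
      x[y == 1, seq_len(n_inf)] <- x[y == 1, seq_len(n_inf)] + shift
    colnames(x) <- sprintf("f%02d", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("s%03d", seq_len(n)),
                     group = ifelse(y == 1, "pd", "control")),
      tibble::as_tibble(x))
  })
}

# Trainer that scores by the first feature; on datasets whose first
# feature equals the label it is a perfect oracle.
first_feature_trainer <- function() {
  function(x, y, seed = NULL) function(x_new) x_new[, 1]
}

# Trainer whose scores are pure noise, seeded per fit.
coin_trainer <- function() {
  function(x, y, seed = NULL) {
    calls <- 0L
    function(x_new) {
      calls <<- calls + 1L
      withr::with_seed(
        if (is.null(seed)) sample.int(1e6, 1) else seed + calls,
        runif(nrow(x_new)))
    }
  }
}

# Trainer that predicts by the (training-set) nearest centroid on the first
# feature; cheap and genuinely data-driven.
centroid_trainer <- function() {
  function(x, y, seed = NULL) {
    m1 <- mean(x[y == 1, 1]); m0 <- mean(x[y == 0, 1])
    function(x_new) {
      d1 <- abs(x_new[, 1] - m1); d0 <- abs(x_new[, 1] - m0)
      d0 / (d0 + d1 + 1e-12)
    }
  }
}

# Brute-force ROC-AUC oracle: concordant case-control pair counting.
auc_bruteforce <- function(scores, labels) {
  cases <- which(labels == 1); controls <- which(labels == 0)
  tot <- 0
  for (i in cases) for (j in controls) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(cases) * length(controls))
}

# Mean of an exponential(rate) truncated to [lo, hi] (closed form).
truncexp_mean <- function(rate, lo, hi) {
  (lo * exp(-rate * lo) - hi * exp(-rate * hi) +
     (exp(-rate * lo) - exp(-rate * hi)) / rate) /
    (exp(-rate * lo) - exp(-rate * hi))
}

# Balanced saccade-level dataset with configurable effects, used to probe
# the mixed-model stage without running the full simulator.
metric_data <- function(n_per_group = 10, n_trials = 20, group_eff = 0,
                        task_eff = 0, subj_sd = 0.1, noise_sd = 0.2,
                        seed = 1) {
  withr::with_seed(seed, {
    ids <- c(sprintf("pd_%02d", 1:n_per_group),
             sprintf("hc_%02d", 1:n_per_group))
    groups <- rep(c("pd", "control"), each = n_per_group)
    intercepts <- rnorm(2 * n_per_group, 0, subj_sd)
    out <- tidyr::expand_grid(
      i = seq_along(ids),
      response_type = c("ps_correct", "as_correct"),
      trial = seq_len(n_trials))
    out$participant_id <- ids[out$i]
    out$group <- groups[out$i]
    out$y <- 1 + intercepts[out$i] +
      group_eff * (out$group == "pd") +
      task_eff * (out$response_type == "as_correct") +
      rnorm(nrow(out), 0, noise_sd)
    out
  })
}

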