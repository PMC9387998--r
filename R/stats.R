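#' Mixed-model group/task analysis of one saccade metric
#'
#' Fits a mixed-effects model to saccade-level data with fixed effects of
#' disease group, response type (prosaccade correct / antisaccade error /
#' antisaccade correct) and their interaction, and a random intercept per
#' participant. Fixed effects are tested with likelihood-ratio tests
#' comparing nested maximum-likelihood fits (interaction: full vs. both
#' main effects; each main effect: both main effects vs. the model without
#' it). Estimated marginal means (EMMs) are computed on the REML fit over
#' the group x response-type grid, back-transformed to the response scale
#' when `transform = "sqrt"`; pairwise contrasts cover the 6 within-group
#' task comparisons and the 3 within-task group comparisons, with
#' Bonferroni correction over that family of 9.
#'
#' A Gamma GLMM with identity link (`family = "gamma"`) is available for
#' strictly positive, right-skewed responses such as latency; the Gaussian
#' linear mixed model is the default and is robust to moderate departures
#' from normality at these sample sizes. Singular random-effect fits are
#' flagged, not discarded. Residual skewness and excess kurtosis of the
#' Pearson residuals are reported as diagnostics.
#'
#' @param data saccade-level tibble with columns `participant_id`,
#'   `group`, `response_type` and the response.
#' @param response name of the response column (string).
#' @param transform `"identity"` or `"sqrt"` (sqrt requires a
#'   non-negative response).
#' @param family `"gaussian"` (linear mixed model) or `"gamma"`
#'   (Gamma GLMM, identity link; falls back to Gaussian with a warning
#'   flag if it fails to converge).
#' @param tests_only if `TRUE`, fit and test the fixed effects but skip
#'   the REML refit, marginal means, contrasts and diagnostics (used in
#'   simulation studies where only the tests are needed).
#' @return object of class `metric_model` with elements `fit`, `tests`
#'   (LRT table), `emmeans`, `contrasts` (Bonferroni-adjusted),
#'   `diagnostics`, `singular`, `family`.
#' @export
fit_metric_model <- function(data, response,
                             transform = c("identity", "sqrt"),
                             family = c("gaussian", "gamma"),
                             tests_only = FALSE) {
  transform <- match.arg(transform)
  family <- match.arg(family)
  need <- c("participant_id", "group", "response_type", response)
  miss <- setdiff(need, names(data))
  if (length(miss))
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")),
          class = "saccadom_schema_error")
  data <- data[is.finite(data[[response]]), , drop = FALSE]
  if (dplyr::n_distinct(data$participant_id[data$group == data$group[1]]) < 2)
    abort("at least 2 participants per group are required.",
          class = "saccadom_domain_error")
  if (transform == "sqrt" && any(data[[response]] < 0))
    abort("sqrt transform requires a non-negative response.",
          class = "saccadom_domain_error")

  data$group <- factor(data$group)
  data$response_type <- factor(data$response_type)
  resp_term <- if (transform == "sqrt") sprintf("sqrt(%s)", response) else response

  forms <- list(
    full = sprintf("%s ~ group * response_type + (1 | participant_id)", resp_term),
    main = sprintf("%s ~ group + response_type + (1 | participant_id)", resp_term),
    no_group = sprintf("%s ~ response_type + (1 | participant_id)", resp_term),
    no_task = sprintf("%s ~ group + (1 | participant_id)", resp_term)
  )

  gamma_failed <- FALSE
  fit_one <- function(f, reml) {
    if (family == "gamma") {
      g <- tryCatch(suppressWarnings(
        lme4::glmer(as.formula(f), data = data,
                    family = stats::Gamma(link = "identity"),
                    control = lme4::glmerControl(calc.derivs = FALSE))),
        error = function(e) NULL)
      if (!is.null(g)) return(g)
      gamma_failed <<- TRUE
    }
    suppressMessages(suppressWarnings(
      lme4::lmer(as.formula(f), data = data, REML = reml)))
  }

  ml <- lapply(forms, fit_one, reml = FALSE)
  lrt <- function(small, big, term) {
    a <- suppressMessages(anova(small, big))
    tibble(term = term,
           statistic = a$Chisq[2], df = a$Df[2],
           p.value = a$`Pr(>Chisq)`[2],
           delta_aic = a$AIC[1] - a$AIC[2])
  }
  tests <- bind_rows(
    lrt(ml$no_group, ml$main, "group"),
    lrt(ml$no_task, ml$main, "response_type"),
    lrt(ml$main, ml$full, "group:response_type")
  )

  if (tests_only) {
    return(structure(list(response = response, transform = transform,
                          family = family, fit = ml$full, tests = tests,
                          emmeans = NULL, contrasts = NULL,
                          diagnostics = NULL, singular = NA),
                     class = "metric_model"))
  }

  fit <- fit_one(forms$full, reml = TRUE)
  singular <- tryCatch(lme4::isSingular(fit), error = function(e) NA)
  if (isTRUE(singular))
    warn("singular random-effect fit; estimates are still reported.")

  # asymptotic (z) degrees of freedom: Kenward-Roger is deliberately not
  # used (heavy small-sample correction; LRTs above carry the testing)
  em <- emmeans::emmeans(fit, ~ group * response_type, type = "response",
                         lmer.df = "asymptotic")
  emm_tbl <- fix_ci_names(as_tibble(as.data.frame(em)))

  by_group <- emmeans::contrast(
    emmeans::emmeans(fit, ~ response_type | group, lmer.df = "asymptotic"),
    method = "pairwise", adjust = "none")
  by_task <- emmeans::contrast(
    emmeans::emmeans(fit, ~ group | response_type, lmer.df = "asymptotic"),
    method = "pairwise", adjust = "none")
  ctr <- bind_rows(
    fix_ci_names(as_tibble(as.data.frame(summary(by_group, infer = TRUE)))),
    fix_ci_names(as_tibble(as.data.frame(summary(by_task, infer = TRUE))))
  )
  ctr$p.adjusted <- pmin(ctr$p.value * nrow(ctr), 1)

  pres <- stats::residuals(fit, type = "pearson")
  diagnostics <- tibble(
    residual_skewness = e1071::skewness(pres, type = 2),
    residual_kurtosis = e1071::kurtosis(pres, type = 2))

  structure(list(response = response, transform = transform,
                 family = if (gamma_failed) "gaussian (gamma fallback)" else family,
                 fit = fit, tests = tests, emmeans = emm_tbl,
                 contrasts = ctr, diagnostics = diagnostics,
                 singular = singular),
            class = "metric_model")
}

# emmeans labels asymptotic confidence limits asymp.LCL/asymp.UCL; use one
# canonical pair of names.
fix_ci_names <- function(d) {
  names(d)[names(d) == "asymp.LCL"] <- "lower.CL"
  names(d)[names(d) == "asymp.UCL"] <- "upper.CL"
  d
}

#' @export
print.metric_model <- function(x, ...) {
  cat("<metric_model> response:", x$response,
      " transform:", x$transform, " family:", x$family, "\n")
  cat("Fixed-effect likelihood-ratio tests:\n")
  print(as.data.frame(x$tests), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname fit_metric_model
#' @param x a `metric_model`.
#' @param ... unused.
#' @export
tidy.metric_model <- function(x, ...) {
  x$contrasts
}

#' @rdname fit_metric_model
#' @export
glance.metric_model <- function(x, ...) {
  dplyr::bind_cols(
    tidyr::pivot_wider(x$tests[, c("term", "p.value")], names_from = "term",
                       values_from = "p.value",
                       names_prefix = "p_"),
    x$diagnostics,
    tibble(singular = isTRUE(x$singular)))
}

#' Mann-Whitney comparison of antisaccade error rates
#'
#' Compares per-participant antisaccade directional error rates between
#' the two groups with the Mann-Whitney U test. The U statistic is
#' computed from midranks (ties share rank), and the two-tailed p-value
#' uses the normal approximation with tie correction; for small samples
#' without ties the exact distribution is used. U counts pairs in which
#' the first group's rate exceeds the second's (ties count one half), so
#' identical groups give U near `n1*n2/2` and complete separation with
#' the first group lower gives U = 0.
#'
#' @param rates_a,rates_b per-participant error rates for the two groups.
#' @return tibble with `U`, `p.value`, `n_a`, `n_b`.
#' @export
mann_whitney_error_rate <- function(rates_a, rates_b) {
  if (!length(rates_a) || !length(rates_b))
    abort("both groups must be non-empty.", class = "saccadom_domain_error")
  n1 <- length(rates_a); n2 <- length(rates_b)
  r <- rank(c(rates_a, rates_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pooled <- c(rates_a, rates_b)
  has_ties <- anyDuplicated(pooled) > 0
  p <- if (!has_ties && max(n1, n2) <= 20) {
    stats::wilcox.test(rates_a, rates_b, exact = TRUE)$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(rates_a, rates_b, exact = FALSE,
                         correct = FALSE)$p.value)
  }
  tibble(U = U, p.value = p, n_a = n1, n_b = n2)
}
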