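#' Plot a saccade trajectory with its fitted step response
#'
#' Overlays the fitted second-order step response on the sampled
#' post-initiation positions (both in normalised units when the fit was
#' normalised).
#'
#' @param t_ms sample times from initiation (ms).
#' @param position_deg sampled positions.
#' @param fit a [fit_second_order()] result.
#' @param amplitude_deg normalisation used for the fit (default: net
#'   displacement).
#' @return a ggplot object.
#' @export
plot_trajectory_fit <- function(t_ms, position_deg, fit,
                                amplitude_deg = NULL) {
  if (is.null(amplitude_deg))
    amplitude_deg <- abs(position_deg[length(position_deg)])
  obs <- tibble(t_ms = t_ms,
                position = sign(position_deg[length(position_deg)]) *
                  position_deg / amplitude_deg)
  grid <- seq(min(t_ms), max(t_ms), length.out = 200)
  mod <- tibble(t_ms = grid,
                position = so_model(grid - fit$delta_t, fit$A, fit$sigma,
                                    fit$omega0))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t_ms, y = .data$position)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::geom_line(data = mod, colour = "#2166ac") +
    ggplot2::labs(x = "time from initiation (ms)",
                  y = "normalised displacement",
                  title = sprintf("sigma = %.2f, omega0 = %.0f rad/s",
                                  fit$sigma, fit$omega0)) +
    ggplot2::theme_minimal()
}

#' @rdname tlpo_cv
#' @param object a `tlpo_result`.
#' @export
autoplot.tlpo_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("TLPO-CV ROC (AUC = %.2f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname rank_features
#' @param object a `feature_ranking`.
#' @param top_n number of features to display.
#' @export
autoplot.feature_ranking <- function(object, top_n = 10, ...) {
  d <- utils::head(as_tibble(object), top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ylab <- if (attr(object, "model") == "logistic")
    "selection proportion" else "mean decrease in impurity (normalised)"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = ylab, y = NULL,
                  title = sprintf("Top %d features (%s)", nrow(d),
                                  attr(object, "model"))) +
    ggplot2::theme_minimal()
}

#' @rdname fit_metric_model
#' @param object a `metric_model`.
#' @export
autoplot.metric_model <- function(object, ...) {
  emm <- object$emmeans
  est_col <- intersect(c("emmean", "response"), names(emm))[1]
  emm$estimate <- emm[[est_col]]
  ggplot2::ggplot(emm, ggplot2::aes(x = .data$response_type,
                                    y = .data$estimate,
                                    colour = .data$group,
                                    group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower.CL,
                                        ymax = .data$upper.CL),
                           width = 0.1,
                           position = ggplot2::position_dodge(0.2)) +
    ggplot2::labs(x = NULL, y = object$response,
                  title = "Estimated marginal means (95% CI)") +
    ggplot2::theme_minimal()
}
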