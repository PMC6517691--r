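#' Scatter plot of a diversity metric against age, by sex
#'
#' Points per sample with independent loess smooths for women and men — the
#' standard visual check for a nonlinear age trend that differs by sex.
#'
#' @param data alpha diversity joined to metadata (columns `age`, `sex` and
#'   the metric).
#' @param metric column to plot.
#' @param span,degree loess settings passed to [loess_curve()].
#' @return a ggplot object.
#' @export
plot_diversity_age <- function(data, metric = "richness", span = 0.75,
                               degree = 2) {
  assert_metric(metric, data)
  curves <- purrr::map_dfr(unique(data$sex), function(sx) {
    d <- data[data$sex == sx, ]
    if (nrow(d) < 10) return(NULL)
    cv <- loess_curve(d, metric, span = span, degree = degree)
    tibble::tibble(sex = sx, age = cv$age, fitted = cv$fitted)
  })
  ggplot2::ggplot(data, ggplot2::aes(x = .data$age, y = .data[[metric]],
                                     colour = .data$sex)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$fitted), linewidth = 1) +
    ggplot2::labs(x = "age (years)", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Box plot of relative microbiota age by sex
#'
#' @param results a [predict_microbiota_age()] tibble (optionally from
#'   several strata; facets by `stratum` if present).
#' @return a ggplot object.
#' @export
plot_relative_age <- function(results) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$sex,
                                    y = .data$relative_microbiota_age,
                                    fill = .data$sex)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative microbiota age (years)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if ("stratum" %in% names(results)) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' @export
autoplot.cv_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_svs,
                                       y = .data$mean_cv_error)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_cv_error - .data$sd_cv_error,
                   ymax = .data$mean_cv_error + .data$sd_cv_error)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "number of SVs", y = "10-fold CV error (years²)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.age_trend_fit <- function(object, ...) {
  d <- object$fit$model
  d$fitted <- object$fit$fitted.values
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linewidth = 1) +
    ggplot2::labs(x = "age (years)", y = object$metric,
                  title = sprintf("%s model (%s stratum)",
                                  object$model_kind, object$stratum)) +
    ggplot2::theme_minimal()
}
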