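#' Fit an age trend to an alpha-diversity metric
#'
#' Fits either a simple linear model `metric ~ age` or a linear-spline model
#' with one knot, using the change-of-slope basis `{1, age, (age - knot)+}`.
#' The spline allows the age slope to differ between the segments below and
#' above the knot; the reported segment slopes are `slope_young = b_age` and
#' `slope_middle = b_age + b_after_knot`. AIC is the full Gaussian
#' log-likelihood criterion (as returned by [stats::AIC()], counting the
#' error variance as a parameter), so nested AIC differences obey
#' `n * log(RSS_simple / RSS_spline) - 2` exactly.
#'
#' @param data a data frame with an `age` column and the metric column;
#'   typically `alpha_diversity()` joined to metadata.
#' @param metric name of the response column, e.g. `"richness"`.
#' @param model `"simple"` or `"spline"`.
#' @param knot knot age in years (default 45); ignored for `"simple"`.
#' @param stratum free-text label recorded in the result.
#' @return an object of class `age_trend_fit`; see [tidy.age_trend_fit()]
#'   and [glance.age_trend_fit()].
#' @examples
#' d <- tibble::tibble(age = 20:69, richness = 100 + 2 * (20:69))
#' glance(fit_age_trend(d, "richness"))
#' @export
fit_age_trend <- function(data, metric = "richness",
                          model = c("simple", "spline"), knot = 45,
                          stratum = "all") {
  model <- match.arg(model)
  assert_metric(metric, data)
  if (!"age" %in% names(data)) abort("data must contain an 'age' column")
  d <- data.frame(age = as.numeric(data$age), y = as.numeric(data[[metric]]))
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) abort("need at least 3 complete cases")
  if (length(unique(d$age)) < 2) {
    abort("age is constant in this stratum; fit is rank-deficient")
  }
  if (model == "spline") {
    if (!any(d$age <= knot) || !any(d$age > knot)) {
      abort("spline fit needs data on both sides of the knot")
    }
    d$age_after_knot <- pmax(d$age - knot, 0)
    fit <- lm(y ~ age + age_after_knot, data = d)
    V <- vcov(fit)
    slopes <- tibble::tibble(
      segment = c("young", "middle"),
      estimate = c(coef(fit)[["age"]],
                   coef(fit)[["age"]] + coef(fit)[["age_after_knot"]]),
      std.error = c(sqrt(V["age", "age"]),
                    sqrt(V["age", "age"] + V["age_after_knot", "age_after_knot"] +
                           2 * V["age", "age_after_knot"]))
    )
  } else {
    fit <- lm(y ~ age, data = d)
    se <- sqrt(vcov(fit)["age", "age"])
    slopes <- tibble::tibble(segment = c("young", "middle"),
                             estimate = rep(coef(fit)[["age"]], 2),
                             std.error = rep(se, 2))
  }
  new_age_trend_fit(fit, model_kind = model, metric = metric, knot = knot,
                    stratum = stratum, slopes = slopes)
}

new_age_trend_fit <- function(fit, model_kind, metric, knot, stratum,
                              slopes = NULL, delta_sex = NULL) {
  sm <- summary(fit)
  r2 <- sm$r.squared
  # constant response: no variance to explain (summary.lm's ratio of
  # floating-point residues is meaningless there)
  resp <- stats::model.response(stats::model.frame(fit))
  if (!is.finite(r2) || sd(resp) < 1e-12 * (1 + abs(mean(resp)))) r2 <- 0
  structure(
    list(fit = fit, model_kind = model_kind, metric = metric, knot = knot,
         stratum = stratum, slopes = slopes, delta_sex = delta_sex,
         n = length(resid(fit)), r_squared = r2,
         aic = AIC(fit), rss = sum(resid(fit)^2)),
    class = "age_trend_fit"
  )
}

#' @export
print.age_trend_fit <- function(x, ...) {
  cat(sprintf("<age_trend_fit> %s model of %s (stratum %s): n=%d, R2=%.3f, AIC=%.1f\n",
              x$model_kind, x$metric, x$stratum, x$n, x$r_squared, x$aic))
  if (!is.null(x$slopes)) {
    cat("  slopes:",
        paste(sprintf("%s %.3f (SE %.3f)", x$slopes$segment,
                      x$slopes$estimate, x$slopes$std.error),
              collapse = ", "), "\n")
  }
  if (!is.null(x$delta_sex)) {
    cat(sprintf("  delta men - women: %.3f (SE %.3f)\n",
                x$delta_sex[["estimate"]], x$delta_sex[["std.error"]]))
  }
  invisible(x)
}

#' Tidy an age-trend fit
#'
#' @param x an `age_trend_fit`.
#' @param ... unused.
#' @return a tibble of model terms with estimate, standard error, t statistic
#'   and p value.
#' @export
tidy.age_trend_fit <- function(x, ...) {
  ct <- summary(x$fit)$coefficients
  tibble::tibble(
    stratum = x$stratum, metric = x$metric, model_kind = x$model_kind,
    term = rownames(ct), estimate = ct[, 1], std.error = ct[, 2],
    statistic = ct[, 3], p.value = ct[, 4]
  )
}

#' One-line summary of an age-trend fit
#'
#' @param x an `age_trend_fit`.
#' @param ... unused.
#' @return a one-row tibble with R-squared, AIC and sample size.
#' @export
glance.age_trend_fit <- function(x, ...) {
  tibble::tibble(stratum = x$stratum, metric = x$metric,
                 model_kind = x$model_kind, r.squared = x$r_squared,
                 aic = x$aic, n = x$n)
}

#' Choose between simple and spline age-trend fits by AIC
#'
#' Returns the fit with the strictly lower AIC; on an exact tie the simple
#' model wins on parsimony. The fits must be on identical observations.
#'
#' @param simple,spline `age_trend_fit` objects of the respective kinds.
#' @return the selected `age_trend_fit`, with the choice in attribute
#'   `"selected"`.
#' @export
select_model <- function(simple, spline) {
  stopifnot(inherits(simple, "age_trend_fit"),
            inherits(spline, "age_trend_fit"))
  if (simple$model_kind != "simple" || spline$model_kind != "spline") {
    abort("arguments must be a simple fit and a spline fit, in that order")
  }
  if (simple$n != spline$n) {
    abort("fits are on different numbers of observations; AIC not comparable")
  }
  pick <- if (spline$aic < simple$aic) spline else simple
  attr(pick, "selected") <- pick$model_kind
  pick
}

#' Age-group-stratified regression of diversity on age and sex
#'
#' Within one age group (young adults, ages 20-45, or middle-aged adults,
#' 46-69), fits `metric ~ age + sex` by OLS, optionally with an age-by-sex
#' interaction and/or additional adjustment covariates. The male-indicator
#' coefficient is reported as `delta_sex`, the adjusted men-minus-women
#' difference in metric units.
#'
#' @param data a data frame with `age`, `sex` ("female"/"male"),
#'   `age_group`, and the metric column.
#' @param metric response column name.
#' @param group `"young"` or `"middle"`.
#' @param interaction include the age-by-sex interaction term?
#' @param covariates optional character vector of extra adjustment columns
#'   (e.g. a cardiometabolic risk score).
#' @return an `age_trend_fit` with the `delta_sex` element populated (unless
#'   the stratum is single-sex, in which case the sex term is dropped with a
#'   warning).
#' @export
fit_stratified <- function(data, metric = "richness",
                           group = c("young", "middle"),
                           interaction = FALSE, covariates = NULL) {
  group <- match.arg(group)
  assert_metric(metric, data)
  need <- c("age", "sex", "age_group")
  if (!all(need %in% names(data))) {
    abort("data must contain 'age', 'sex' and 'age_group' columns")
  }
  d <- data[!is.na(data$age_group) & data$age_group == group, , drop = FALSE]
  d <- as.data.frame(d)
  d$y <- as.numeric(d[[metric]])
  d$sex <- factor(d$sex, levels = c("female", "male"))
  keep <- complete.cases(d[, c("age", "sex", "y", covariates)])
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3) abort(sprintf("fewer than 3 usable samples in the %s group", group))
  two_sex <- length(unique(d$sex)) == 2
  if (!two_sex) {
    warn(sprintf("single-sex %s stratum: sex term dropped", group))
  }
  rhs <- c("age", if (two_sex) "sex", if (two_sex && interaction) "age:sex",
           covariates)
  fit <- lm(stats::reformulate(rhs, response = "y"), data = d)
  delta <- NULL
  if (two_sex) {
    ct <- summary(fit)$coefficients
    delta <- c(estimate = ct["sexmale", 1], std.error = ct["sexmale", 2],
               p.value = ct["sexmale", 4])
  }
  sl_se <- summary(fit)$coefficients["age", 2]
  slopes <- tibble::tibble(segment = group, estimate = coef(fit)[["age"]],
                           std.error = sl_se)
  new_age_trend_fit(fit, model_kind = "stratified", metric = metric,
                    knot = NA_real_, stratum = group, slopes = slopes,
                    delta_sex = delta)
}

#' Benjamini-Hochberg adjustment of a batch of p values
#'
#' Step-up false-discovery-rate adjustment. P values should be adjusted
#' jointly within one analysis batch (one cohort, one metric, the set of
#' reported terms).
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return adjusted p values, order-matched to the input.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p values must lie in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Loess smooth of a metric against age
#'
#' Locally weighted polynomial regression (tricube weights) evaluated on an
#' evenly spaced age grid, for visualising nonlinear age trends, typically
#' per sex.
#'
#' @param data data frame with `age` and the metric column.
#' @param metric response column name.
#' @param span loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param n_grid number of grid points.
#' @return a tibble of class `loess_curve` with columns `age`, `fitted`.
#' @export
loess_curve <- function(data, metric = "richness", span = 0.75, degree = 2,
                        n_grid = 100) {
  assert_metric(metric, data)
  d <- data.frame(age = as.numeric(data$age), y = as.numeric(data[[metric]]))
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10) abort("loess_curve needs at least 10 points")
  fit <- tryCatch(
    loess(y ~ age, data = d, span = span, degree = degree,
          family = "gaussian"),
    error = function(e) abort(paste0(
      "loess fit failed (span may be too small for local neighbourhoods; ",
      "try a larger span): ", conditionMessage(e)))
  )
  grid <- seq(min(d$age), max(d$age), length.out = n_grid)
  out <- tibble::tibble(age = grid, fitted = as.numeric(predict(fit, grid)))
  if (any(!is.finite(out$fitted))) abort("loess produced non-finite values")
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  class(out) <- c("loess_curve", class(out))
  out
}
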