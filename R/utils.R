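#' @importFrom methods as
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats AIC coef lm loess median pnorm predict quantile resid
#'   rbinom rmultinom rnorm runif sd setNames smooth.spline vcov wilcox.test
#'   p.adjust complete.cases
NULL

# Convert a feature-table tibble (sample_id + one column per SV) to an
# integer matrix with sample_id rownames. Validates on the way in.
ft_matrix <- function(features) {
  stopifnot(is.data.frame(features))
  if (!"sample_id" %in% names(features)) {
    abort("feature table must have a 'sample_id' column")
  }
  ids <- as.character(features$sample_id)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sv_cols <- setdiff(names(features), "sample_id")
  if (anyDuplicated(sv_cols)) abort("duplicate SV ids in feature table")
  m <- as.matrix(features[sv_cols])
  if (!is.numeric(m)) abort("feature counts must be numeric")
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("negative count at sample '%s', SV '%s'",
                  ids[bad[1, 1]], sv_cols[bad[1, 2]]))
  }
  if (any(m != round(m))) abort("feature counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

ft_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "sample_id")
}

#' Derive age group from integer age
#'
#' Adults aged 20-45 (inclusive) are "young", 46-69 are "middle"; ages
#' outside 20-69 get `NA` and are excluded from stratified analyses.
#'
#' @param age numeric vector of ages in years.
#' @param bounds length-2 numeric, inclusive adult age range.
#' @param knot age (years) at which the young/middle boundary sits; the
#'   young group is `[bounds[1], knot]`, the middle group `(knot, bounds[2]]`.
#' @return character vector with values "young", "middle" or `NA`.
#' @export
derive_age_group <- function(age, bounds = c(20, 69), knot = 45) {
  dplyr::case_when(
    age >= bounds[1] & age <= knot ~ "young",
    age > knot & age <= bounds[2] ~ "middle",
    TRUE ~ NA_character_
  )
}

# Deterministic fan-out of a top-level seed into named per-stage seeds,
# kept below 2^31 so they are valid R integer seeds.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("'%s' must be a single value in [0, 1]", name))
  }
}

assert_metric <- function(metric, data) {
  if (!metric %in% names(data)) {
    abort(sprintf("metric column '%s' not found in data", metric))
  }
}
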