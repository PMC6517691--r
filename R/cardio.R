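risk_covariates <- c("waist_cm", "triglycerides_mg_dl", "insulin_uu_ml",
                     "dbp_mmhg", "hscrp_mg_l")

#' Composite cardiometabolic risk scale
#'
#' The risk scale is the sum of the within-cohort z-scores of the
#' natural-log-transformed five covariates: waist circumference,
#' triglycerides, insulin, diastolic blood pressure and high-sensitivity
#' C-reactive protein. Higher raw covariate values give a higher score, so
#' positive scores indicate increased cardiometabolic risk. Samples with a
#' missing or non-positive covariate are excluded and reported. A covariate
#' that is constant within the cohort (SD 0) contributes a z-score of 0 for
#' every subject rather than failing.
#'
#' Because each covariate is logged then standardised, rescaling any raw
#' covariate column by a positive constant leaves all scores unchanged.
#'
#' @param metadata a data frame with `sample_id` and the five covariate
#'   columns (`waist_cm`, `triglycerides_mg_dl`, `insulin_uu_ml`,
#'   `dbp_mmhg`, `hscrp_mg_l`).
#' @param by_sex standardise within sex strata instead of the whole cohort?
#' @return a tibble with `sample_id`, one `z_*` column per covariate, and
#'   `score` (their sum); excluded samples are listed in the `"excluded"`
#'   attribute with reasons.
#' @export
risk_scale <- function(metadata, by_sex = FALSE) {
  missing_cols <- setdiff(risk_covariates, names(metadata))
  if (length(missing_cols) > 0) {
    abort(paste0("missing covariate column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (by_sex && !"sex" %in% names(metadata)) {
    abort("by_sex = TRUE requires a 'sex' column")
  }
  cov <- as.data.frame(metadata[risk_covariates])
  bad_na <- !complete.cases(cov)
  bad_nonpos <- apply(cov, 1, function(r) any(!is.na(r) & r <= 0))
  excluded <- tibble::tibble(
    sample_id = metadata$sample_id[bad_na | bad_nonpos],
    reason = ifelse(bad_na[bad_na | bad_nonpos],
                    "missing covariate", "non-positive covariate")
  )
  if (nrow(excluded) > 0) {
    inform(sprintf("risk_scale: excluded %d sample(s) with missing or non-positive covariates",
                   nrow(excluded)))
  }
  keep <- !(bad_na | bad_nonpos)
  if (!any(keep)) abort("no samples with complete positive covariates")
  ids <- metadata$sample_id[keep]
  logs <- log(as.matrix(cov[keep, , drop = FALSE]))
  stratum <- if (by_sex) metadata$sex[keep] else rep("all", sum(keep))
  z <- logs
  for (g in unique(stratum)) {
    rows <- stratum == g
    for (j in seq_len(ncol(logs))) {
      s <- sd(logs[rows, j])
      z[rows, j] <- if (is.na(s) || s == 0) 0 else
        (logs[rows, j] - mean(logs[rows, j])) / s
    }
  }
  out <- tibble::as_tibble(as.data.frame(z))
  names(out) <- paste0("z_", risk_covariates)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = ids), out)
  out$score <- unname(rowSums(z))
  attr(out, "excluded") <- excluded
  out
}

#' Adjust alpha diversity for cardiometabolic risk
#'
#' Residualises each diversity metric on the risk score: per metric, the OLS
#' fit `metric ~ score` is computed on the samples common to both tables and
#' its residuals replace the metric. Downstream age/sex analyses can then be
#' rerun on the residual scale. (The alternative adjustment — adding the
#' score as a covariate to the stratified models — is available via the
#' `covariates` argument of [fit_stratified()].)
#'
#' @param diversity an alpha-diversity tibble (`sample_id`, metric columns).
#' @param risk a [risk_scale()] result.
#' @param metrics metric columns to residualise.
#' @return a tibble like `diversity` but on the residual scale, restricted
#'   to the matched samples.
#' @export
adjust_diversity <- function(diversity, risk,
                             metrics = intersect(c("richness", "shannon"),
                                                 names(diversity))) {
  d <- dplyr::inner_join(diversity, risk[, c("sample_id", "score")],
                         by = "sample_id")
  if (nrow(d) == 0) abort("no samples shared between diversity and risk tables")
  out <- tibble::tibble(sample_id = d$sample_id)
  for (m in metrics) {
    out[[m]] <- as.numeric(resid(lm(d[[m]] ~ d$score)))
  }
  out
}

#' Split inputs by antibiotic-use flag for the sensitivity analysis
#'
#' Returns the flagged (recent antibiotic consumers) subset of a
#' diversity-plus-metadata table together with its complement, so the age
#' and sex analyses can be rerun on each.
#'
#' @param data a data frame with a logical (or "true"/"false") column
#'   `antibiotic_use`.
#' @return a list with elements `flagged` and `unflagged`.
#' @export
antibiotic_subset <- function(data) {
  if (!"antibiotic_use" %in% names(data)) {
    abort("no 'antibiotic_use' column: antibiotic sensitivity analysis skipped")
  }
  flag <- data$antibiotic_use
  if (is.character(flag)) flag <- tolower(flag) %in% c("true", "yes", "1")
  flag[is.na(flag)] <- FALSE
  res <- list(flagged = dplyr::filter(data, flag),
              unflagged = dplyr::filter(data, !flag))
  if (nrow(res$flagged) == 0) {
    inform("antibiotic_subset: no flagged samples")
  }
  if (nrow(res$unflagged) == 0) {
    warn("antibiotic_subset: complement is empty (all samples flagged)")
  }
  res
}
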