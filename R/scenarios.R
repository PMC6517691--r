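#' Define a synthetic cohort scenario
#'
#' A scenario bundles the generative parameters of a cross-sectional
#' microbiome cohort: a piecewise-linear age trend in latent SV richness with
#' a knot (slope `beta1` before the knot, `beta2` after), an additive sex
#' offset on richness (`gamma_male`, negative means men lower), a set of
#' age-informative SVs whose relative abundances follow smooth monotone ramps
#' in age, an optional sex-specific shift of that compositional age signal
#' (`delta_female_shift`: women's composition resembles same-age men shifted
#' older by that many years), and an antibiotic-associated richness reduction.
#'
#' Defaults describe a cohort of 1000 adults aged 20-69 whose richness rises
#' by 0.9 SVs/year up to age 45 and then plateaus, with men about 10 SVs
#' below women, subject-level noise of 8 SVs, a 3-year female shift in the
#' compositional age signal, and 15% antibiotic consumers carrying a 12-SV
#' deficit — magnitudes in line with published adult-cohort summaries.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param prop_women fraction of women in `[0, 1]`.
#' @param age_range inclusive `[min, max]` age in years.
#' @param knot age (years) where the richness slope changes.
#' @param beta0 latent richness (SVs) at the minimum age for women.
#' @param beta1,beta2 richness slopes (SVs/year) before and after the knot.
#' @param gamma_male additive sex offset on latent richness (SVs).
#' @param sigma SD of subject-level richness noise (SVs).
#' @param n_informative number of age-informative SVs.
#' @param delta_female_shift sex-specific age shift of the compositional
#'   signal, in years.
#' @param antibiotic_prob fraction of subjects flagged as recent antibiotic
#'   consumers.
#' @param antibiotic_effect additive richness change (SVs) for flagged
#'   subjects.
#' @param library_depth reads per sample before rarefaction.
#' @param pool_size total SVs in the global pool (>= `n_informative`).
#' @param seed integer seed; identical scenario + seed gives byte-identical
#'   output.
#' @return an object of class `cohort_scenario`.
#' @seealso [simulate_cohort()]
#' @export
cohort_scenario <- function(n_subjects = 1000,
                            prop_women = 0.5,
                            age_range = c(20, 69),
                            knot = 45,
                            beta0 = 95,
                            beta1 = 0.9,
                            beta2 = 0,
                            gamma_male = -10,
                            sigma = 8,
                            n_informative = 200,
                            delta_female_shift = 3,
                            antibiotic_prob = 0.15,
                            antibiotic_effect = -12,
                            library_depth = 3000,
                            pool_size = 800,
                            seed = 1) {
  if (n_subjects < 4) abort("n_subjects must be at least 4")
  assert_prob(prop_women, "prop_women")
  assert_prob(antibiotic_prob, "antibiotic_prob")
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    abort("age_range must be [min, max] with min < max")
  }
  if (!(knot > age_range[1] && knot < age_range[2])) {
    abort("knot must lie strictly inside age_range")
  }
  if (pool_size < n_informative) abort("pool_size must be >= n_informative")
  if (library_depth < 1) abort("library_depth must be positive")
  if (sigma < 0) abort("sigma must be non-negative")
  structure(
    list(
      n_subjects = as.integer(n_subjects), prop_women = prop_women,
      age_range = as.numeric(age_range), knot = knot, beta0 = beta0,
      beta1 = beta1, beta2 = beta2, gamma_male = gamma_male, sigma = sigma,
      n_informative = as.integer(n_informative),
      delta_female_shift = delta_female_shift,
      antibiotic_prob = antibiotic_prob,
      antibiotic_effect = antibiotic_effect,
      library_depth = as.integer(library_depth),
      pool_size = as.integer(pool_size), seed = as.integer(seed)
    ),
    class = "cohort_scenario"
  )
}

#' @export
print.cohort_scenario <- function(x, ...) {
  cat("<cohort_scenario>\n")
  cat(sprintf("  %d subjects, %.0f%% women, ages %d-%d, knot %g y\n",
              x$n_subjects, 100 * x$prop_women, x$age_range[1],
              x$age_range[2], x$knot))
  cat(sprintf("  richness: %g + %g/y (young) + %g/y (middle), sex offset %g, sd %g\n",
              x$beta0, x$beta1, x$beta2, x$gamma_male, x$sigma))
  cat(sprintf("  pool %d SVs (%d age-informative), female shift %g y, depth %d\n",
              x$pool_size, x$n_informative, x$delta_female_shift,
              x$library_depth))
  invisible(x)
}

#' Define a cardiometabolic covariate scenario
#'
#' Log-normal generative settings for the five covariates entering the
#' cardiometabolic risk scale: waist circumference (cm), triglycerides
#' (mg/dL), insulin (uU/mL), diastolic blood pressure (mmHg) and
#' high-sensitivity C-reactive protein (mg/L). Each covariate is drawn as
#' `exp(meanlog + beta_age * z(age) + beta_male * I(male) + Normal(0, sdlog))`,
#' so draws are strictly positive; association coefficients default to 0
#' (covariates independent of age and sex).
#'
#' @param covariates a data frame with columns `covariate`, `meanlog`,
#'   `sdlog`, `beta_age`, `beta_male`; defaults approximate adult clinical
#'   distributions.
#' @param seed integer seed.
#' @return an object of class `covariate_scenario`.
#' @export
covariate_scenario <- function(covariates = NULL, seed = 1) {
  if (is.null(covariates)) {
    covariates <- tibble::tribble(
      ~covariate,            ~meanlog,  ~sdlog, ~beta_age, ~beta_male,
      "waist_cm",            log(85),   0.12,   0,         0,
      "triglycerides_mg_dl", log(130),  0.45,   0,         0,
      "insulin_uu_ml",       log(10),   0.50,   0,         0,
      "dbp_mmhg",            log(78),   0.12,   0,         0,
      "hscrp_mg_l",          log(2),    0.90,   0,         0
    )
  }
  covariates <- tibble::as_tibble(covariates)
  need <- c("covariate", "meanlog", "sdlog", "beta_age", "beta_male")
  if (!all(need %in% names(covariates))) {
    abort(paste0("covariate scenario needs columns: ",
                 paste(need, collapse = ", ")))
  }
  if (any(covariates$sdlog < 0)) abort("sdlog must be non-negative")
  structure(list(covariates = covariates, seed = as.integer(seed)),
            class = "covariate_scenario")
}

#' Read or write a scenario as a structured text config
#'
#' Scenarios round-trip losslessly through YAML (`.yml`/`.yaml`) or JSON
#' (`.json`), chosen by file extension.
#'
#' @param scenario a `cohort_scenario` or `covariate_scenario`.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scenario()` returns the scenario object; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, c("cohort_scenario", "covariate_scenario")))
  payload <- unclass(scenario)
  payload[[".class"]] <- class(scenario)[1]
  if (inherits(scenario, "covariate_scenario")) {
    payload$covariates <- as.data.frame(payload$covariates)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path, column.major = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    abort("scenario files must end in .yaml, .yml or .json")
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  payload <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("scenario files must end in .yaml, .yml or .json")
  }
  cls <- payload[[".class"]] %||% "cohort_scenario"
  payload[[".class"]] <- NULL
  if (cls == "covariate_scenario") {
    cov <- payload$covariates
    if (is.list(cov) && !is.data.frame(cov)) {
      cov <- dplyr::bind_rows(lapply(cov, tibble::as_tibble))
    }
    covariate_scenario(covariates = cov, seed = payload$seed)
  } else {
    payload$age_range <- unlist(payload$age_range)
    do.call(cohort_scenario, payload)
  }
}
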