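# Constants of the compositional age signal. Pool base abundances are
# log-normal with this sdlog; informative SVs multiply their base abundance
# by exp(+/- ramp_amplitude * (logistic((effective age - threshold) /
# ramp_width) - 1/2)), with ramp directions alternating so half the
# informative SVs rise and half fall with age. Centring the ramp at zero and
# alternating directions keep the within-sample abundance skew small and
# independent of age; otherwise samples at one end of the age range would
# lose more rare SVs at rarefaction and the realised richness trend would be
# biased relative to the latent one. Subject SV subsets are drawn by a
# Gumbel top-k race on log-weights divided by jitter_temperature, so
# inclusion probability rises smoothly with weight while keeping subsets
# subject-specific and pool coverage broad. With these values a sample
# rarefied to 1250 reads observes nearly all of its ~R_i SVs and a
# random-forest age model reaches moderate-to-high out-of-bag variance
# explained, so planted age and sex signals are recoverable at realistic
# cohort sizes.
.sim_const <- list(
  base_sdlog = 0.3,
  ramp_amplitude = 1.5,
  ramp_width = 4,
  jitter_temperature = 2
)

#' Simulate a cross-sectional microbiome cohort
#'
#' Draws a cohort under a [cohort_scenario()]: integer ages uniform on the
#' age range, sex and antibiotic flags Bernoulli, a latent target richness
#' `R_i = beta0 + beta1 * min(age - min_age, knot - min_age) +
#' beta2 * max(age - knot, 0) + gamma_male * I(male) +
#' antibiotic_effect * I(antibiotic) + Normal(0, sigma)` clamped to
#' `[1, pool_size]`, and per-subject counts as a multinomial draw of
#' `library_depth` reads over a subject-specific subset of `R_i` SVs from a
#' log-normally-abundant global pool. Each informative SV's expected relative
#' abundance follows a monotone logistic ramp in the subject's effective age
#' (`age + delta_female_shift * I(female)`), half the ramps rising and half
#' falling with age, so composition encodes age and the female shift while
#' richness encodes the piecewise trend.
#'
#' @param scenario a [cohort_scenario()].
#' @return a list of class `cohort_simulation` with elements `features` (a
#'   tibble: `sample_id` plus one integer count column per SV; every row sums
#'   to `library_depth`), `metadata` (a tibble with `sample_id`, `age`,
#'   `sex`, `age_group`, `antibiotic_use`, `latent_richness`) and
#'   `informative_svs` (ids of the planted age-informative SVs).
#' @examples
#' cohort <- simulate_cohort(cohort_scenario(n_subjects = 50, seed = 1))
#' dplyr::count(cohort$metadata, sex)
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  s <- scenario
  set.seed(s$seed)
  n <- s$n_subjects
  age <- pmin(floor(runif(n, s$age_range[1], s$age_range[2] + 1)),
              s$age_range[2])
  sex <- ifelse(rbinom(n, 1, s$prop_women) == 1, "female", "male")
  antibiotic <- rbinom(n, 1, s$antibiotic_prob) == 1

  latent <- s$beta0 +
    s$beta1 * pmin(age - s$age_range[1], s$knot - s$age_range[1]) +
    s$beta2 * pmax(age - s$knot, 0) +
    s$gamma_male * (sex == "male") +
    s$antibiotic_effect * antibiotic +
    rnorm(n, 0, s$sigma)
  target_richness <- pmin(pmax(round(latent), 1), s$pool_size)

  p <- s$pool_size
  sv_ids <- sprintf("SV%04d", seq_len(p))
  base_abund <- exp(rnorm(p, 0, .sim_const$base_sdlog))
  # informative SVs: the highest-base-abundance pool members, so they are
  # present in most subjects; ramp thresholds spread evenly over the ages
  informative <- order(base_abund, decreasing = TRUE)[seq_len(s$n_informative)]
  threshold <- rep(NA_real_, p)
  ramp_sign <- rep(NA_real_, p)
  threshold[informative] <- seq(s$age_range[1], s$age_range[2],
                                length.out = max(s$n_informative, 2L))[
                                  seq_len(s$n_informative)]
  ramp_sign[informative] <- rep_len(c(1, -1), s$n_informative)

  eff_age <- age + s$delta_female_shift * (sex == "female")
  log_base <- log(base_abund)
  counts <- matrix(0L, nrow = n, ncol = p)
  for (i in seq_len(n)) {
    eta <- numeric(p)
    if (s$n_informative > 0) {
      eta[informative] <- .sim_const$ramp_amplitude * ramp_sign[informative] *
        (stats::plogis((eff_age[i] - threshold[informative]) /
                         .sim_const$ramp_width) - 0.5)
    }
    logw <- log_base + eta
    gumbel <- -log(-log(runif(p)))
    sel <- order(logw / .sim_const$jitter_temperature + gumbel,
                 decreasing = TRUE)[seq_len(target_richness[i])]
    pr <- exp(logw[sel] - max(logw[sel]))
    counts[i, sel] <- rmultinom(1, s$library_depth, pr / sum(pr))[, 1]
  }
  sample_id <- sprintf("S%05d", seq_len(n))
  colnames(counts) <- sv_ids
  rownames(counts) <- sample_id

  metadata <- tibble::tibble(
    sample_id = sample_id,
    age = as.integer(age),
    sex = sex,
    age_group = derive_age_group(age, s$age_range, s$knot),
    antibiotic_use = antibiotic,
    latent_richness = target_richness
  )
  structure(list(features = ft_tibble(counts), metadata = metadata,
                 scenario = s,
                 informative_svs = sv_ids[sort(informative)]),
            class = "cohort_simulation")
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat(sprintf("<cohort_simulation> %d samples x %d SVs\n",
              nrow(x$metadata), ncol(x$features) - 1L))
  invisible(x)
}

#' Append simulated cardiometabolic covariates to cohort metadata
#'
#' Draws the five risk-scale covariates per subject from the log-normal
#' models of a [covariate_scenario()] and appends them as columns. With all
#' association coefficients zero (the default) the covariates are independent
#' of age and sex.
#'
#' @param metadata a metadata tibble with at least `sample_id`, `age`, `sex`.
#' @param scenario a [covariate_scenario()].
#' @return the metadata tibble with one strictly positive column per
#'   covariate appended.
#' @export
simulate_covariates <- function(metadata, scenario = covariate_scenario()) {
  stopifnot(inherits(scenario, "covariate_scenario"))
  if (nrow(metadata) == 0) abort("metadata is empty")
  set.seed(scenario$seed)
  z_age <- as.numeric(scale(metadata$age))
  if (all(is.na(z_age))) z_age <- rep(0, nrow(metadata))
  male <- as.numeric(metadata$sex == "male")
  out <- metadata
  for (k in seq_len(nrow(scenario$covariates))) {
    row <- scenario$covariates[k, ]
    out[[row$covariate]] <- exp(
      row$meanlog + row$beta_age * z_age + row$beta_male * male +
        rnorm(nrow(metadata), 0, row$sdlog)
    )
  }
  out
}
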