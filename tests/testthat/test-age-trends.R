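test_that("noiseless lines are recovered exactly by both model kinds", {
  d <- tibble::tibble(age = seq(20, 69, length.out = 10),
                      richness = 2 * seq(20, 69, length.out = 10))
  fs <- fit_age_trend(d, "richness", "simple")
  expect_equal(fs$slopes$estimate, c(2, 2), tolerance = 1e-10)
  expect_equal(fs$r_squared, 1, tolerance = 1e-10)
  fp <- fit_age_trend(d, "richness", "spline")
  expect_equal(fp$slopes$estimate, c(2, 2), tolerance = 1e-8)
  # constant response: zero slopes, zero R-squared
  d2 <- tibble::tibble(age = 20:40, richness = rep(7, 21))
  f2 <- fit_age_trend(d2, "richness", "simple")
  expect_equal(f2$slopes$estimate[1], 0, tolerance = 1e-12)
  expect_equal(f2$r_squared, 0)
})

test_that("simple fit recovers a noisy generating slope within 2 SE", {
  set.seed(11)
  age <- runif(500, 20, 69)
  d <- tibble::tibble(age = age, richness = age + rnorm(500))
  f <- fit_age_trend(d, "richness", "simple")
  expect_lt(abs(f$slopes$estimate[1] - 1), 2 * f$slopes$std.error[1])
})

test_that("spline fit recovers piecewise generating slopes within 2 SE", {
  sim <- simulate_cohort(cohort_scenario(n_subjects = 1000, beta1 = 0.9,
                                         beta2 = 0, sigma = 8,
                                         antibiotic_prob = 0, seed = 5))
  rare <- rarefy(sim$features, 1250, seed = 6, quiet = TRUE)
  d <- dplyr::inner_join(alpha_diversity(rare), sim$metadata, by = "sample_id")
  f <- fit_age_trend(d, "richness", "spline")
  expect_lt(abs(f$slopes$estimate[1] - 0.9), 2 * f$slopes$std.error[1])
  expect_lt(abs(f$slopes$estimate[2] - 0.0), 2 * f$slopes$std.error[2])
})

test_that("fit preconditions are enforced", {
  expect_error(fit_age_trend(tibble::tibble(age = c(1, 2), richness = c(1, 2)),
                             "richness"), "at least 3")
  expect_error(fit_age_trend(tibble::tibble(age = rep(30, 5),
                                            richness = rnorm(5)), "richness"),
               "rank-deficient")
  expect_error(fit_age_trend(tibble::tibble(age = 20:30, richness = rnorm(11)),
                             "richness", "spline", knot = 45),
               "both sides of the knot")
})

test_that("nesting and the Gaussian AIC identity hold on random data", {
  set.seed(8)
  for (rep in 1:5) {
    d <- tibble::tibble(age = runif(80, 20, 69),
                        richness = rnorm(80, 100, 10))
    fs <- fit_age_trend(d, "richness", "simple")
    fp <- fit_age_trend(d, "richness", "spline")
    expect_lte(fp$rss, fs$rss + 1e-10)
    n <- fs$n
    expect_equal(fs$aic - fp$aic, n * log(fs$rss / fp$rss) - 2,
                 tolerance = 1e-8)
  }
})

test_that("AIC model selection prefers lower AIC and breaks ties simply", {
  cohort <- quick_cohort(n = 500, seed = 15)
  fs <- fit_age_trend(cohort$data, "richness", "simple")
  fp <- fit_age_trend(cohort$data, "richness", "spline")
  # a strongly piecewise cohort: the spline must win
  expect_equal(select_model(fs, fp)$model_kind, "spline")
  tied <- fp
  tied$aic <- fs$aic
  expect_equal(select_model(fs, tied)$model_kind, "simple")
  expect_error(select_model(fp, fs), "in that order")
  short <- fit_age_trend(cohort$data[1:100, ], "richness", "spline")
  expect_error(select_model(fs, short), "not comparable")
})

test_that("AIC false-selection rate under a linear truth is near theory", {
  # truth simple-linear: AIC picks the extra-parameter spline with
  # probability ~ P(chisq_1 > 2) ~ 0.157
  picks <- vapply(1:100, function(seed) {
    set.seed(seed)
    age <- runif(200, 20, 69)
    d <- tibble::tibble(age = age, richness = 100 + 0.5 * age + rnorm(200, 0, 8))
    fs <- fit_age_trend(d, "richness", "simple")
    fp <- fit_age_trend(d, "richness", "spline")
    select_model(fs, fp)$model_kind
  }, character(1))
  expect_gte(mean(picks == "simple"), 0.7)
})

test_that("stratified regression recovers the planted sex offset", {
  sim <- simulate_cohort(cohort_scenario(n_subjects = 1600, gamma_male = -10,
                                         antibiotic_prob = 0, seed = 2))
  rare <- rarefy(sim$features, 1250, seed = 3, quiet = TRUE)
  d <- dplyr::inner_join(alpha_diversity(rare), sim$metadata, by = "sample_id")
  fy <- fit_stratified(d, "richness", "young")
  expect_lt(abs(fy$delta_sex[["estimate"]] - (-10)),
            2 * fy$delta_sex[["std.error"]])
  # constant response: slopes exactly zero and R-squared zero
  d$flat <- 5
  ff <- fit_stratified(d, "flat", "young")
  expect_equal(ff$slopes$estimate, 0, tolerance = 1e-12)
  expect_equal(ff$r_squared, 0)
  # single-sex stratum drops the sex term with a warning
  expect_warning(fit_stratified(d[d$sex == "female", ], "richness", "young"),
                 "single-sex")
})

test_that("interaction tests hold their type-I error without an interaction", {
  hits <- vapply(1:50, function(seed) {
    sim <- simulate_cohort(cohort_scenario(n_subjects = 300,
                                           antibiotic_prob = 0,
                                           seed = 700 + seed))
    rare <- rarefy(sim$features, 1250, seed = seed, quiet = TRUE)
    d <- dplyr::inner_join(alpha_diversity(rare), sim$metadata,
                           by = "sample_id")
    fi <- fit_stratified(d, "richness", "young", interaction = TRUE)
    tt <- tidy(fi)
    tt$p.value[tt$term == "age:sexmale"] < 0.05
  }, logical(1))
  expect_lte(sum(hits), 10)
})

test_that("BH adjustment matches hand and brute-force step-up", {
  expect_equal(adjust_bh(0.05), 0.05)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(c(0.03, 0.01)), c(0.03, 0.02))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:8, 1))
    expect_equal(adjust_bh(p), bh_hand(p), tolerance = 1e-12)
  }
})

test_that("loess curves reproduce lines and flatten after a plateau knot", {
  d <- tibble::tibble(age = seq(20, 69, length.out = 40),
                      richness = 3 + 0.5 * seq(20, 69, length.out = 40))
  cv <- loess_curve(d, "richness")
  expect_lt(max(abs(cv$fitted - (3 + 0.5 * cv$age))), 1e-6)
  d2 <- tibble::tibble(age = seq(20, 69, length.out = 40), richness = rep(4, 40))
  cv2 <- loess_curve(d2, "richness")
  expect_lt(max(abs(cv2$fitted - 4)), 1e-8)
  expect_error(loess_curve(d[1:5, ], "richness"), "at least 10")
  # piecewise cohort: late-age loess slope is well under a third of early
  set.seed(31)
  age <- sample(20:69, 1000, replace = TRUE)
  y <- 95 + 0.9 * pmin(age - 20, 25) + rnorm(1000, 0, 8)
  cv3 <- loess_curve(tibble::tibble(age = age, richness = y), "richness")
  seg_slope <- function(lo, hi) {
    seg <- cv3[cv3$age >= lo & cv3$age <= hi, ]
    coef(lm(fitted ~ age, seg))[["age"]]
  }
  expect_lt(abs(seg_slope(50, 65)), abs(seg_slope(25, 40)) / 3)
})
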