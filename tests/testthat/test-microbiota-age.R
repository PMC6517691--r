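test_that("shared SVs equal the brute-force per-sex intersection", {
  ft <- tibble::tibble(
    sample_id = c("w1", "w2", "m1", "m2"),
    only_w = c(3L, 1L, 0L, 0L),
    only_m = c(0L, 0L, 2L, 0L),
    both = c(1L, 0L, 1L, 0L),
    neither = c(0L, 0L, 0L, 0L)
  )
  meta <- tibble::tibble(sample_id = c("w1", "w2", "m1", "m2"),
                         sex = c("female", "female", "male", "male"))
  expect_equal(shared_svs(ft, meta), "both")

  set.seed(9)
  m <- matrix(rbinom(600, 3, 0.25), nrow = 20,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("v%02d", 1:30)))
  ft2 <- tibble::as_tibble(as.data.frame(m), rownames = "sample_id")
  meta2 <- tibble::tibble(sample_id = rownames(m),
                          sex = rep(c("female", "male"), each = 10))
  oracle <- sort(intersect(
    colnames(m)[colSums(m[1:10, ] > 0) > 0],
    colnames(m)[colSums(m[11:20, ] > 0) > 0]
  ))
  expect_equal(shared_svs(ft2, meta2), oracle)
})

test_that("relative abundances row-sum to one over the shared set", {
  cohort <- quick_cohort(n = 60, seed = 3)
  sh <- shared_svs(cohort$rare, cohort$sim$metadata)
  ra <- microage:::relative_abundances(cohort$rare, sh)
  expect_equal(unname(rowSums(ra)), rep(1, nrow(ra)), tolerance = 1e-10)
})

test_that("a fully informative SV gives high out-of-bag accuracy; permuted ages give none", {
  toy <- monotone_table(n = 300, seed = 1)
  fit <- fit_microbiota_age(toy$features, toy$metadata, "female",
                            n_trees = 300, seed = 2)
  expect_gt(fit$training_r_squared, 0.8)

  r2 <- vapply(1:20, function(i) {
    meta <- toy$metadata
    set.seed(1000 + i)
    meta$age <- sample(meta$age)
    f <- fit_microbiota_age(toy$features, meta, "female",
                            n_trees = 100, seed = i)
    f$training_r_squared
  }, numeric(1))
  expect_lte(mean(r2), 0.05)
})

test_that("model training is deterministic under a fixed seed", {
  toy <- monotone_table(n = 120, seed = 5)
  f1 <- fit_microbiota_age(toy$features, toy$metadata, "male",
                           n_trees = 100, seed = 7)
  f2 <- fit_microbiota_age(toy$features, toy$metadata, "male",
                           n_trees = 100, seed = 7)
  p1 <- predict_microbiota_age(f1, toy$features, toy$metadata)
  p2 <- predict_microbiota_age(f2, toy$features, toy$metadata)
  expect_identical(p1, p2)
  expect_equal(f1$mtry, max(1, floor(length(f1$shared_sv_ids) / 3)))
})

test_that("relative age is measured against the calibration spline", {
  cohort <- quick_cohort(n = 400, seed = 12, gamma_male = 0,
                         antibiotic_prob = 0)
  fit <- fit_microbiota_age(cohort$rare, cohort$sim$metadata, "female",
                            n_trees = 150, seed = 4)
  pred <- predict_microbiota_age(fit, cohort$rare, cohort$sim$metadata)
  # definitional identity
  expect_equal(pred$relative_microbiota_age,
               pred$microbiota_age - pred$expected_microbiota_age,
               tolerance = 1e-12)
  # the training sex evaluated against its own spline centres near zero
  own <- pred[pred$sex == "female", ]
  expect_lt(abs(mean(own$relative_microbiota_age)), 0.5)
  expect_true(all(pred$prediction_type[pred$sex == "female"] == "out_of_bag"))
  expect_true(all(pred$prediction_type[pred$sex == "male"] == "test"))
  expect_false(any(pred$extrapolated))
})

test_that("a planted female age shift surfaces as a positive median shift", {
  cohort <- quick_cohort(n = 600, seed = 4, gamma_male = 0,
                         antibiotic_prob = 0, delta_female_shift = 3)
  fit <- fit_microbiota_age(cohort$rare, cohort$sim$metadata, "male",
                            n_trees = 200, seed = 5)
  pred <- predict_microbiota_age(fit, cohort$rare, cohort$sim$metadata)
  women <- pred[pred$sex == "female", ]
  expect_gt(median(women$relative_microbiota_age), 0)
  cmp <- compare_sexes(pred)
  expect_equal(cmp$direction, "women_higher")
  expect_lt(cmp$p.value, 0.05)
})

test_that("sex comparison matches exact enumeration of rank assignments", {
  cmp <- compare_sexes(tibble::tibble(
    sex = rep(c("female", "male"), each = 3),
    relative_microbiota_age = c(1, 2, 3, 4, 5, 6)
  ))
  expect_equal(cmp$p.value, 0.1)
  expect_equal(cmp$direction, "men_higher")

  same <- compare_sexes(tibble::tibble(
    sex = rep(c("female", "male"), each = 4),
    relative_microbiota_age = rep(c(1, 2, 3, 4), 2)
  ))
  expect_equal(same$delta_women_minus_men, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$direction, "null")

  expect_warning(
    tiny <- compare_sexes(tibble::tibble(
      sex = c("female", "female", "male", "male", "male"),
      relative_microbiota_age = rnorm(5))),
    "fewer than 3")
  expect_true(is.na(tiny$p.value))

  null_w <- wilcox_enum_null(8, 8)
  set.seed(77)
  for (i in 1:500) {
    x <- rnorm(8)
    y <- rnorm(8)
    cmp <- compare_sexes(tibble::tibble(
      sex = rep(c("female", "male"), each = 8),
      relative_microbiota_age = c(x, y)))
    expect_equal(cmp$p.value, wilcox_enum_p(x, y, null_w), tolerance = 1e-12)
  }
})

test_that("the CV profile has the requested grid and flags informative features", {
  toy <- monotone_table(n = 200, seed = 6)
  prof <- cv_error_profile(toy$features, toy$metadata, "female",
                           grid = c(1, 2), n_trees = 100, seed = 3)
  expect_s3_class(prof, "cv_profile")
  expect_equal(prof$n_svs, c(1L, 2L))
  expect_true(all(prof$mean_cv_error >= 0))
  # the single informative SV beats an intercept-only predictor
  ages <- toy$metadata$age[toy$metadata$sex == "female"]
  expect_lt(prof$mean_cv_error[1], mean((ages - mean(ages))^2))
  expect_error(cv_error_profile(toy$features, toy$metadata, "female",
                                grid = c(0, 2)), "at least 1")
  expect_error(cv_error_profile(toy$features, toy$metadata, "female",
                                grid = 99), "must not exceed")
})

test_that("importance ranking recovers planted informative SVs", {
  sim <- simulate_cohort(cohort_scenario(n_subjects = 300, gamma_male = 0,
                                         antibiotic_prob = 0,
                                         n_informative = 200, seed = 8))
  rare <- rarefy(sim$features, 1250, seed = 9, quiet = TRUE)
  fit <- fit_microbiota_age(rare, sim$metadata, "female", n_trees = 300,
                            seed = 10)
  imp <- tidy(fit)
  top50 <- imp$sv_id[imp$rank <= 50]
  expect_gte(mean(top50 %in% sim$informative_svs), 0.7)

  tab1 <- importance_table(fit, top_n = 10)
  expect_equal(nrow(tab1), 10)
  fit2 <- fit_microbiota_age(rare, sim$metadata, "male", n_trees = 100,
                             seed = 11)
  tab2 <- importance_table(list(fit, fit2), top_n = 5)
  expect_true(all(c("importance_female", "rank_female",
                    "importance_male", "rank_male") %in% names(tab2)))
  expect_gte(nrow(tab2), 5)
  expect_lte(nrow(tab2), 10)
  tax <- tibble::tibble(sv_id = tab2$sv_id,
                        taxonomy = paste0("f__Fam", seq_len(nrow(tab2))))
  tab3 <- importance_table(list(fit, fit2), top_n = 5, taxonomy = tax)
  expect_equal(names(tab3)[2], "taxonomy")
})
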