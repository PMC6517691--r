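cov_cols <- c("waist_cm", "triglycerides_mg_dl", "insulin_uu_ml",
              "dbp_mmhg", "hscrp_mg_l")

make_cov_table <- function(values) {
  # values: matrix-like with five columns
  out <- tibble::as_tibble(as.data.frame(values))
  names(out) <- cov_cols
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("p%02d", seq_len(nrow(out)))),
                   out)
}

test_that("risk scores equal hand-computed z-score sums", {
  set.seed(4)
  raw <- matrix(exp(rnorm(40)), nrow = 8)
  meta <- make_cov_table(raw)
  rs <- risk_scale(meta)
  hand <- rowSums(apply(log(raw), 2, function(v) (v - mean(v)) / sd(v)))
  expect_equal(rs$score, hand, tolerance = 1e-10)
  # components have mean 0 and SD 1 within the cohort
  z <- as.matrix(rs[paste0("z_", cov_cols)])
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-8)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-8)
  # two subjects mirrored about the log means score +c and -c
  two <- make_cov_table(rbind(exp(c(1, 1, 1, 1, 1)), exp(c(3, 3, 3, 3, 3))))
  rs2 <- risk_scale(two)
  expect_equal(rs2$score[1], -rs2$score[2], tolerance = 1e-10)
})

test_that("constant covariates contribute zero rather than failing", {
  raw <- cbind(c(80, 90, 100), matrix(5, nrow = 3, ncol = 4))
  rs <- risk_scale(make_cov_table(raw))
  expect_equal(as.numeric(as.matrix(rs[paste0("z_", cov_cols[2:5])])),
               rep(0, 12))
  expect_equal(rs$score, (log(c(80, 90, 100)) - mean(log(c(80, 90, 100)))) /
                 sd(log(c(80, 90, 100))), tolerance = 1e-10)
})

test_that("risk scores are invariant to rescaling raw covariates", {
  set.seed(5)
  raw <- matrix(exp(rnorm(60)), nrow = 12)
  rs1 <- risk_scale(make_cov_table(raw))
  scaled <- sweep(raw, 2, c(2.5, 10, 0.3, 7, 100), "*")
  rs2 <- risk_scale(make_cov_table(scaled))
  expect_equal(rs1$score, rs2$score, tolerance = 1e-10)
})

test_that("samples with missing or non-positive covariates are excluded", {
  raw <- matrix(exp(rnorm(20)), nrow = 4)
  meta <- make_cov_table(raw)
  meta$waist_cm[2] <- NA
  meta$hscrp_mg_l[3] <- -1
  expect_message(rs <- risk_scale(meta), "excluded 2")
  expect_equal(nrow(rs), 2)
  exc <- attr(rs, "excluded")
  expect_setequal(exc$sample_id, c("p02", "p03"))
  expect_setequal(exc$reason, c("missing covariate", "non-positive covariate"))
  expect_error(risk_scale(meta[, -2]), "missing covariate column")
})

test_that("residual adjustment removes the score and only the score", {
  set.seed(6)
  n <- 60
  score <- rnorm(n)
  div <- tibble::tibble(sample_id = sprintf("p%02d", 1:n),
                        richness = 2 * score,
                        shannon = rnorm(n))
  risk <- tibble::tibble(sample_id = div$sample_id, score = score)
  adj <- adjust_diversity(div, risk)
  expect_equal(adj$richness, rep(0, n), tolerance = 1e-10)
  expect_lt(abs(cor(adj$shannon, score)), 1e-10)
  # a metric orthogonal to the score is only mean-centred
  ortho <- unname(resid(lm(rnorm(n) ~ score)))
  div2 <- tibble::tibble(sample_id = div$sample_id, richness = ortho + 5)
  adj2 <- adjust_diversity(div2, risk, metrics = "richness")
  expect_equal(adj2$richness, ortho + 5 - mean(ortho + 5), tolerance = 1e-10)
})

test_that("antibiotic subsetting splits correctly and recovers the effect", {
  d0 <- tibble::tibble(sample_id = c("a", "b"), antibiotic_use = c(FALSE, FALSE))
  sub0 <- antibiotic_subset(d0)
  expect_equal(nrow(sub0$flagged), 0)
  expect_equal(nrow(sub0$unflagged), 2)
  expect_warning(antibiotic_subset(tibble::tibble(antibiotic_use = c(TRUE, TRUE))),
                 "complement is empty")
  expect_error(antibiotic_subset(tibble::tibble(x = 1)), "skipped")

  sim <- simulate_cohort(cohort_scenario(n_subjects = 1500,
                                         antibiotic_prob = 0.2,
                                         antibiotic_effect = -12, seed = 6))
  rare <- rarefy(sim$features, 1250, seed = 7, quiet = TRUE)
  d <- dplyr::inner_join(alpha_diversity(rare), sim$metadata, by = "sample_id")
  halves <- antibiotic_subset(d)
  gap <- mean(halves$unflagged$richness) - mean(halves$flagged$richness)
  expect_lt(abs(gap - 12), 3)
})

test_that("adjusting for an independent risk score leaves age slopes alone", {
  cohort <- quick_cohort(n = 400, seed = 23, antibiotic_prob = 0)
  meta <- simulate_covariates(cohort$sim$metadata, covariate_scenario(seed = 8))
  risk <- risk_scale(meta)
  adj <- adjust_diversity(cohort$div, risk)
  adj_data <- dplyr::inner_join(adj, meta, by = "sample_id")
  for (g in c("young", "middle")) {
    f0 <- fit_stratified(cohort$data, "richness", g)
    f1 <- fit_stratified(adj_data, "richness", g)
    expect_lt(abs(f1$slopes$estimate - f0$slopes$estimate),
              2 * f0$slopes$std.error)
  }
})
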