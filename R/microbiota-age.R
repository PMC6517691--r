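#' SVs shared between the sexes
#'
#' Returns the SVs observed (count > 0) in at least one sample of each sex,
#' in lexicographic order — the feature set on which the cross-sex
#' microbiota-age models are trained.
#'
#' @param features a feature-table tibble.
#' @param metadata a metadata tibble with `sample_id` and `sex`.
#' @return character vector of shared SV ids.
#' @export
shared_svs <- function(features, metadata) {
  m <- ft_matrix(features)
  meta <- metadata[match(rownames(m), metadata$sample_id), ]
  if (any(is.na(meta$sample_id))) {
    abort("every feature-table sample must appear in the metadata")
  }
  sexes <- unique(meta$sex)
  if (!all(c("female", "male") %in% sexes)) {
    abort("both sexes must be present to compute shared SVs")
  }
  in_f <- colSums(m[meta$sex == "female", , drop = FALSE] > 0) > 0
  in_m <- colSums(m[meta$sex == "male", , drop = FALSE] > 0) > 0
  out <- sort(colnames(m)[in_f & in_m])
  if (length(out) == 0) abort("no SVs shared between the sexes")
  out
}

# Relative abundances over a fixed SV set, rows renormalised to sum to 1.
# Samples with zero reads over the set are dropped with a warning.
relative_abundances <- function(features, sv_ids) {
  m <- ft_matrix(features)
  missing_sv <- setdiff(sv_ids, colnames(m))
  if (length(missing_sv) > 0) {
    abort(sprintf("%d SV id(s) absent from the feature table", length(missing_sv)))
  }
  m <- m[, sv_ids, drop = FALSE]
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warn(sprintf("%d sample(s) with no reads over the SV set dropped", sum(tot == 0)))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(m, 1, tot, "/")
}

#' Train a microbiota-age random-forest model on one sex
#'
#' Regresses chronological age on the relative abundances of the SVs shared
#' between the sexes, using random-forest regression with `mtry = floor(p/3)`
#' where `p` is the number of shared SVs. A cubic smoothing spline
#' (smoothness chosen by generalised cross-validation) is then fitted to the
#' out-of-bag predictions against chronological age; this calibration curve
#' defines the expected microbiota age of the training sex at each
#' chronological age, the reference from which relative microbiota ages are
#' measured. The out-of-bag variance explained is reported as the training
#' R-squared.
#'
#' @param features a (rarefied) feature-table tibble containing both sexes.
#' @param metadata metadata tibble with `sample_id`, `age`, `sex`.
#' @param training_sex `"female"` or `"male"`.
#' @param n_trees number of trees (default 1000).
#' @param seed integer seed; identical data + seed give identical models.
#' @param shared optional precomputed [shared_svs()] result.
#' @param importance `"permutation"` (increase in MSE when a predictor is
#'   permuted) or `"impurity"`.
#' @return an object of class `microbiota_age_fit`.
#' @export
fit_microbiota_age <- function(features, metadata,
                               training_sex = c("female", "male"),
                               n_trees = 1000, seed = 1, shared = NULL,
                               importance = c("permutation", "impurity")) {
  training_sex <- match.arg(training_sex)
  importance <- match.arg(importance)
  if (is.null(shared)) shared <- shared_svs(features, metadata)
  p <- length(shared)
  ra <- relative_abundances(features, shared)
  meta <- metadata[match(rownames(ra), metadata$sample_id), ]
  train <- meta$sex == training_sex & !is.na(meta$age)
  if (sum(train) < 30) abort("need at least 30 training samples")
  x <- ra[train, , drop = FALSE]
  y <- as.numeric(meta$age[train])
  if (length(unique(y)) < 2) abort("training ages are constant")
  mtry <- max(1L, floor(p / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = mtry,
    importance = importance == "permutation"
  )
  oob <- tibble::tibble(sample_id = rownames(x), age = y,
                        oob_prediction = unname(rf$predicted))
  if (length(unique(y)) < 4) abort("need at least 4 unique training ages for the calibration spline")
  calib <- smooth.spline(y, oob$oob_prediction, cv = FALSE)
  structure(
    list(rf = rf, training_sex = training_sex, shared_sv_ids = shared,
         n_trees = as.integer(n_trees), mtry = as.integer(mtry),
         seed = as.integer(seed), calibration = calib,
         age_range = range(y), oob = oob,
         importance_type = importance,
         training_r_squared = rf$rsq[length(rf$rsq)]),
    class = "microbiota_age_fit"
  )
}

#' @export
print.microbiota_age_fit <- function(x, ...) {
  cat(sprintf("<microbiota_age_fit> trained on %ss: %d samples, %d shared SVs, %d trees (mtry %d)\n",
              x$training_sex, nrow(x$oob), length(x$shared_sv_ids),
              x$n_trees, x$mtry))
  cat(sprintf("  out-of-bag R2 = %.3f; calibration over ages %g-%g\n",
              x$training_r_squared, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' @rdname glance.microbiota_age_fit
#' @export
tidy.microbiota_age_fit <- function(x, ...) {
  imp <- randomForest::importance(
    x$rf, type = if (x$importance_type == "permutation") 1 else 2,
    scale = FALSE
  )
  tibble::tibble(sv_id = rownames(imp), importance = as.numeric(imp[, 1]),
                 rank = rank(-imp[, 1], ties.method = "first")) |>
    dplyr::arrange(.data$rank)
}

#' Summaries of a microbiota-age model
#'
#' `tidy()` returns the per-SV importance table (permutation importance:
#' mean increase in MSE, unscaled); `glance()` a one-row model summary.
#'
#' @param x a `microbiota_age_fit`.
#' @param ... unused.
#' @export
glance.microbiota_age_fit <- function(x, ...) {
  tibble::tibble(training_sex = x$training_sex,
                 n_train = nrow(x$oob), n_shared_svs = length(x$shared_sv_ids),
                 n_trees = x$n_trees, mtry = x$mtry,
                 oob_r_squared = x$training_r_squared)
}

#' Microbiota age and relative microbiota age per sample
#'
#' The microbiota age of a sample is the model's predicted chronological
#' age: the full-forest prediction for samples of the opposite (test) sex,
#' and the out-of-bag prediction for samples of the training sex (avoiding
#' resubstitution optimism). The relative microbiota age is the microbiota
#' age minus the calibration spline's expected microbiota age at the
#' sample's chronological age. The spline is interpolated only within the
#' training age range; outside it the nearest boundary value is used and the
#' sample is flagged `extrapolated`.
#'
#' @param model a [fit_microbiota_age()] model.
#' @param features feature-table tibble containing the target samples.
#' @param metadata metadata tibble (`sample_id`, `age`, `sex`, optionally
#'   `age_group`).
#' @param target_sex restrict to one sex; default both.
#' @return a tibble with `sample_id`, `sex`, `age_group`,
#'   `chronological_age`, `microbiota_age`, `expected_microbiota_age`,
#'   `relative_microbiota_age`, `extrapolated`, `prediction_type`.
#' @export
predict_microbiota_age <- function(model, features, metadata,
                                   target_sex = NULL) {
  stopifnot(inherits(model, "microbiota_age_fit"))
  ra <- relative_abundances(features, model$shared_sv_ids)
  meta <- metadata[match(rownames(ra), metadata$sample_id), ]
  keep <- !is.na(meta$age) & meta$sex %in% c("female", "male")
  if (!is.null(target_sex)) keep <- keep & meta$sex %in% target_sex
  if (!any(keep)) abort("no target samples")
  ra <- ra[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]

  pred <- as.numeric(predict(model$rf, ra))
  type <- rep("test", nrow(ra))
  is_train <- match(rownames(ra), model$oob$sample_id)
  hit <- !is.na(is_train)
  pred[hit] <- model$oob$oob_prediction[is_train[hit]]
  type[hit] <- "out_of_bag"

  age <- as.numeric(meta$age)
  clamped <- pmin(pmax(age, model$age_range[1]), model$age_range[2])
  expected <- predict(model$calibration, clamped)$y
  tibble::tibble(
    sample_id = rownames(ra),
    sex = meta$sex,
    age_group = if ("age_group" %in% names(meta)) meta$age_group
                else derive_age_group(age),
    chronological_age = age,
    microbiota_age = pred,
    expected_microbiota_age = expected,
    relative_microbiota_age = pred - expected,
    extrapolated = age < model$age_range[1] | age > model$age_range[2],
    prediction_type = type
  )
}

#' Compare relative microbiota age between women and men
#'
#' Two-sided Wilcoxon rank-sum test of the relative microbiota ages of
#' women versus men, exact when both groups have at most 25 observations
#' and no ties, otherwise the tie-corrected normal approximation. The
#' reported difference is the women-minus-men difference of group medians
#' (group means are also emitted).
#'
#' @param results a [predict_microbiota_age()] tibble containing both sexes
#'   (e.g. the row-bound results of the two cross-sex applications).
#' @param stratum label recorded in the output (e.g. "all", "young",
#'   "middle").
#' @param value column to compare (default `relative_microbiota_age`).
#' @return a one-row tibble: group sizes, medians and means,
#'   `delta_women_minus_men`, `wilcoxon_W`, `p.value`, `direction`.
#' @export
compare_sexes <- function(results, stratum = "all",
                          value = "relative_microbiota_age") {
  assert_metric(value, results)
  w <- results[[value]][results$sex == "female"]
  m <- results[[value]][results$sex == "male"]
  w <- w[!is.na(w)]; m <- m[!is.na(m)]
  delta <- median(w) - median(m)
  if (length(w) < 3 || length(m) < 3) {
    warn("a sex group has fewer than 3 samples; p value undefined")
    W <- NA_real_; pval <- NA_real_
  } else {
    exact <- length(w) <= 25 && length(m) <= 25 && !anyDuplicated(c(w, m))
    ht <- suppressWarnings(
      wilcox.test(w, m, alternative = "two.sided", exact = exact)
    )
    W <- unname(ht$statistic); pval <- ht$p.value
  }
  tibble::tibble(
    stratum = stratum,
    n_women = length(w), n_men = length(m),
    median_women = median(w), median_men = median(m),
    mean_women = mean(w), mean_men = mean(m),
    delta_women_minus_men = delta,
    wilcoxon_W = W, p.value = pval,
    direction = dplyr::case_when(delta > 0 ~ "women_higher",
                                 delta < 0 ~ "men_higher",
                                 TRUE ~ "null")
  )
}

# Seeded fold assignment stratified by age decile: within each decile bin,
# samples are shuffled and folds dealt cyclically.
stratified_folds <- function(age, k = 10, seed = 1) {
  set.seed(seed)
  bins <- cut(rank(age, ties.method = "first"),
              breaks = k, labels = FALSE)
  fold <- integer(length(age))
  for (b in unique(bins)) {
    idx <- sample(which(bins == b))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validation error versus number of SVs
#'
#' Ranks the shared SVs by the full model's importance, then for each
#' requested subset size `k` refits the random forest on the top-`k` SVs and
#' records the mean and SD over 10 folds of the cross-validated mean squared
#' error (years squared). Folds are stratified by age decile and fixed by
#' the seed. Used to ask how far the model can be simplified before the
#' error rises.
#'
#' @param features feature-table tibble (both sexes present, for shared-SV
#'   selection).
#' @param metadata metadata tibble.
#' @param training_sex sex whose samples are cross-validated.
#' @param grid ascending subset sizes, each between 1 and the number of
#'   shared SVs.
#' @param n_trees trees per CV fit (default 200).
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param model optional prefitted [fit_microbiota_age()] model to rank SVs
#'   with (saves refitting).
#' @return a tibble of class `cv_profile` with columns `n_svs`,
#'   `mean_cv_error`, `sd_cv_error`.
#' @export
cv_error_profile <- function(features, metadata,
                             training_sex = c("female", "male"),
                             grid, n_trees = 200, folds = 10, seed = 1,
                             model = NULL) {
  training_sex <- match.arg(training_sex)
  if (is.null(model)) {
    model <- fit_microbiota_age(features, metadata, training_sex,
                                n_trees = n_trees, seed = stage_seed(seed, "rank"))
  }
  p <- length(model$shared_sv_ids)
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1)) abort("grid values must be at least 1")
  if (any(grid > p)) abort(sprintf("grid values must not exceed the %d shared SVs", p))
  ranking <- tidy(model)$sv_id
  ra <- relative_abundances(features, model$shared_sv_ids)
  meta <- metadata[match(rownames(ra), metadata$sample_id), ]
  train <- meta$sex == training_sex & !is.na(meta$age)
  x_all <- ra[train, , drop = FALSE]
  y <- as.numeric(meta$age[train])
  fold <- stratified_folds(y, k = folds, seed = stage_seed(seed, "folds"))

  res <- purrr::map_dfr(grid, function(k) {
    x <- x_all[, ranking[seq_len(k)], drop = FALSE]
    mse <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      set.seed(stage_seed(seed, paste0("cv", k, "_", f)))
      rf <- randomForest::randomForest(
        x = x[tr, , drop = FALSE], y = y[tr],
        ntree = n_trees, mtry = max(1L, floor(k / 3))
      )
      mean((predict(rf, x[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    tibble::tibble(n_svs = k, mean_cv_error = mean(mse), sd_cv_error = sd(mse))
  })
  class(res) <- c("cv_profile", class(res))
  res
}

#' Combined importance table across models
#'
#' Takes the union of the top-`n` SVs by importance in at least one of the
#' supplied models and reports each model's importance score and rank for
#' those SVs, with taxonomy strings joined when supplied.
#'
#' @param models a list of [fit_microbiota_age()] models (e.g. the
#'   women-trained and men-trained models).
#' @param top_n SVs retained per model (default 500).
#' @param taxonomy optional tibble with `sv_id` and `taxonomy` columns.
#' @return a tibble with `sv_id`, optional `taxonomy`, and one
#'   `importance_*` / `rank_*` column pair per model, sorted by the best
#'   (minimum) rank across models.
#' @export
importance_table <- function(models, top_n = 500, taxonomy = NULL) {
  if (inherits(models, "microbiota_age_fit")) models <- list(models)
  if (length(models) == 0) abort("at least one trained model is required")
  labels <- vapply(models, function(m) m$training_sex, character(1))
  labels <- make.unique(labels, sep = "_")
  imps <- purrr::map(models, tidy)
  keep <- unique(unlist(purrr::map(imps, function(t) {
    t$sv_id[t$rank <= top_n]
  })))
  out <- tibble::tibble(sv_id = keep)
  for (i in seq_along(imps)) {
    t <- imps[[i]]
    idx <- match(keep, t$sv_id)
    out[[paste0("importance_", labels[i])]] <- t$importance[idx]
    out[[paste0("rank_", labels[i])]] <- t$rank[idx]
  }
  rank_cols <- as.matrix(out[grep("^rank_", names(out))])
  out <- out[order(apply(rank_cols, 1, min, na.rm = TRUE)), ]
  if (!is.null(taxonomy)) {
    out <- dplyr::left_join(out, taxonomy[, c("sv_id", "taxonomy")],
                            by = "sv_id") |>
      dplyr::relocate("taxonomy", .after = "sv_id")
  }
  out
}
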