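#' Configure an end-to-end analysis run
#'
#' A pipeline config names the inputs (either file paths or a simulation
#' scenario), the analysis constants — rarefaction depth 1250 reads, spline
#' knot at 45 years, adult age bounds 20-69, random-forest `mtry = p/3` —
#' and the stages to run. All randomness in a run flows from the single
#' `seed`, fanned out to named per-stage seeds recorded in the run log.
#'
#' @param feature_table,metadata input file paths (TSV or `.biom`), or
#'   `NULL` when simulating.
#' @param scenario a [cohort_scenario()] to simulate instead of reading
#'   files.
#' @param covariates a [covariate_scenario()] to append simulated
#'   cardiometabolic covariates (simulated inputs only).
#' @param depth rarefaction depth in reads (default 1250).
#' @param knot spline knot age in years (default 45).
#' @param age_bounds inclusive adult age range (default `c(20, 69)`).
#' @param metrics diversity metrics to analyse.
#' @param n_trees random-forest trees (default 1000).
#' @param cv_grid optional SV-subset sizes for the cross-validation error
#'   profile; `NULL` skips that stage.
#' @param importance_top_n SVs kept per model in the combined importance
#'   table.
#' @param stages stages to run, in order; `diversity` and `age_trends` are
#'   always needed by later stages.
#' @param stratified_microbiota also run the microbiota-age comparison
#'   within the young and middle age groups?
#' @param seed top-level integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(feature_table = NULL, metadata = NULL,
                            scenario = NULL, covariates = NULL,
                            depth = 1250, knot = 45,
                            age_bounds = c(20, 69),
                            metrics = c("richness", "shannon"),
                            n_trees = 1000, cv_grid = NULL,
                            importance_top_n = 500,
                            stages = c("diversity", "age_trends",
                                       "antibiotic", "cardiometabolic",
                                       "microbiota_age"),
                            stratified_microbiota = TRUE,
                            seed = 1) {
  if (is.null(scenario) && (is.null(feature_table) || is.null(metadata))) {
    abort("provide either input paths or a simulation scenario")
  }
  structure(
    list(feature_table = feature_table, metadata = metadata,
         scenario = scenario, covariates = covariates,
         depth = as.integer(depth), knot = knot,
         age_bounds = as.numeric(age_bounds), metrics = metrics,
         n_trees = as.integer(n_trees), cv_grid = cv_grid,
         importance_top_n = as.integer(importance_top_n),
         stages = stages, stratified_microbiota = stratified_microbiota,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read or write a pipeline config as YAML/JSON
#'
#' Configs (including any embedded scenarios) round-trip losslessly.
#'
#' @param config a [pipeline_config()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  payload <- unclass(config)
  if (!is.null(payload$scenario)) payload$scenario <- unclass(payload$scenario)
  if (!is.null(payload$covariates)) {
    payload$covariates <- unclass(payload$covariates)
    payload$covariates$covariates <-
      as.data.frame(payload$covariates$covariates)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path, column.major = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    abort("config files must end in .yaml, .yml or .json")
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  payload <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config files must end in .yaml, .yml or .json")
  }
  # YAML/JSON render absent fields as empty lists; restore NULLs
  for (f in c("feature_table", "metadata", "scenario", "covariates",
              "cv_grid")) {
    if (length(payload[[f]]) == 0) payload[f] <- list(NULL)
  }
  if (!is.null(payload$scenario)) {
    payload$scenario$age_range <- unlist(payload$scenario$age_range)
    payload$scenario <- do.call(cohort_scenario, payload$scenario)
  }
  if (!is.null(payload$covariates)) {
    cov <- payload$covariates$covariates
    if (is.list(cov) && !is.data.frame(cov)) {
      cov <- dplyr::bind_rows(lapply(cov, tibble::as_tibble))
    }
    payload$covariates <- covariate_scenario(cov, payload$covariates$seed)
  }
  payload$age_bounds <- unlist(payload$age_bounds)
  if (!is.null(payload$cv_grid)) payload$cv_grid <- unlist(payload$cv_grid)
  payload$metrics <- unlist(payload$metrics)
  payload$stages <- unlist(payload$stages)
  do.call(pipeline_config, payload)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

# Age-trend analysis batch for one metric: whole-range simple/spline fits
# with AIC selection, per-sex loess curves, stratified age+sex fits with
# interaction tests, and joint BH adjustment of the reported p values.
age_trend_batch <- function(data, metric, knot, label = "") {
  simple <- fit_age_trend(data, metric, model = "simple", stratum = "all")
  spline <- fit_age_trend(data, metric, model = "spline", knot = knot,
                          stratum = "all")
  chosen <- select_model(simple, spline)

  strat <- purrr::map(c(young = "young", middle = "middle"), function(g) {
    list(main = fit_stratified(data, metric, group = g),
         inter = fit_stratified(data, metric, group = g, interaction = TRUE))
  })

  rows <- dplyr::bind_rows(
    tidy(simple), tidy(spline),
    purrr::map_dfr(strat, function(s) tidy(s$main)),
    purrr::map_dfr(strat, function(s) {
      t <- tidy(s$inter)
      t$model_kind <- "interaction"
      t
    })
  )
  # one BH family per metric batch: the stratified age, sex and
  # age-by-sex terms actually reported
  fam <- (rows$model_kind == "stratified" & rows$term %in% c("age", "sexmale")) |
    (rows$model_kind == "interaction" & rows$term == "age:sexmale")
  rows$p.adjusted <- NA_real_
  rows$p.adjusted[fam] <- adjust_bh(rows$p.value[fam])
  rows$bh_batch <- ifelse(fam, paste0(label, metric), NA_character_)

  glances <- dplyr::bind_rows(
    glance(simple), glance(spline),
    purrr::map_dfr(strat, function(s) glance(s$main))
  )
  glances$selected <- glances$model_kind == chosen$model_kind &
    glances$model_kind %in% c("simple", "spline")

  curves <- purrr::map_dfr(c("female", "male"), function(sx) {
    d <- data[data$sex == sx, ]
    if (nrow(d) < 10) return(NULL)
    cv <- loess_curve(d, metric)
    tibble::tibble(metric = metric, sex = sx, age = cv$age,
                   fitted = cv$fitted)
  })

  list(terms = rows, fits = glances, curves = curves,
       selected_kind = chosen$model_kind,
       strat = strat, simple = simple, spline = spline)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading or simulation, metadata validation and
#' exclusions, rarefaction, alpha diversity, whole-range and stratified
#' age-trend modelling with AIC selection and BH adjustment, the optional
#' antibiotic-subset and cardiometabolic-adjustment sensitivity analyses,
#' and the cross-sex microbiota-age procedure in both training directions
#' (all ages plus, optionally, each age group). Writes tidy TSV outputs, a
#' run log (package version, seeds, exclusions) and a descriptive summary
#' table (n, mean and SD of age, richness and Shannon per sex and age
#' group) when `output_dir` is given. Fixed seeds make re-runs
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for TSV outputs and the run log; `NULL`
#'   returns results without writing.
#' @param quiet suppress progress messages.
#' @return an object of class `microage_run`: a list of tidy tibbles
#'   (`alpha_diversity`, `age_trends`, `model_fits`, `loess_curves`,
#'   `summary_table`, `exclusions`, and — stage permitting — `risk_scale`,
#'   `adjusted_trends`, `antibiotic_trends`, `microbiota_age`,
#'   `sex_comparisons`, `cv_profile`, `importance`, plus the trained
#'   `models` and the `log` lines).
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    if (!quiet) inform(line)
  }
  say("microage %s pipeline run, top-level seed %d",
      as.character(utils::packageVersion("microage")), config$seed)

  # --- inputs ---------------------------------------------------------
  excl <- tibble::tibble(sample_id = character(0), reason = character(0))
  inputs <- run_stage("input", {
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      sc$seed <- stage_seed(config$seed, "simulate")
      say("simulating cohort: n=%d, seed %d", sc$n_subjects, sc$seed)
      sim <- simulate_cohort(sc)
      meta <- sim$metadata
      if (!is.null(config$covariates)) {
        cs <- config$covariates
        cs$seed <- stage_seed(config$seed, "covariates")
        meta <- simulate_covariates(meta, cs)
      }
      list(features = sim$features, metadata = meta)
    } else {
      say("reading feature table %s and metadata %s",
          config$feature_table, config$metadata)
      meta <- read_metadata(config$metadata, config$age_bounds, config$knot)
      excl <- dplyr::bind_rows(excl, attr(meta, "excluded"))
      list(features = read_feature_table(config$feature_table),
           metadata = meta)
    }
  })
  features <- inputs$features
  metadata <- inputs$metadata
  n_input <- nrow(ft_matrix(features))

  # --- rarefaction + diversity ---------------------------------------
  res <- list(config = config)
  div_data <- run_stage("diversity", {
    rare <- rarefy(features, depth = config$depth,
                   seed = stage_seed(config$seed, "rarefy"), quiet = quiet)
    dropped <- attr(rare, "dropped")
    if (nrow(dropped) > 0) {
      excl <- dplyr::bind_rows(excl, tibble::tibble(
        sample_id = dropped$sample_id,
        reason = sprintf("below rarefaction depth (%d reads)", dropped$total)))
    }
    say("rarefied to %d reads: %d samples retained, %d dropped",
        config$depth, nrow(rare), nrow(dropped))
    div <- alpha_diversity(rare)
    list(rare = rare, div = div,
         data = dplyr::inner_join(div, metadata, by = "sample_id"),
         excl = excl)
  })
  excl <- div_data$excl
  res$features_rarefied <- div_data$rare
  res$alpha_diversity <- div_data$div
  data <- div_data$data

  # --- age trends -----------------------------------------------------
  at <- run_stage("age_trends", {
    purrr::map(setNames(config$metrics, config$metrics), function(m) {
      age_trend_batch(data, m, config$knot)
    })
  })
  res$age_trends <- purrr::map_dfr(at, "terms")
  res$model_fits <- purrr::map_dfr(at, "fits")
  res$loess_curves <- purrr::map_dfr(at, "curves")
  for (m in config$metrics) {
    say("age trends (%s): AIC selects the %s model", m, at[[m]]$selected_kind)
  }

  # --- antibiotic sensitivity ----------------------------------------
  if ("antibiotic" %in% config$stages &&
      "antibiotic_use" %in% names(metadata)) {
    ab <- run_stage("antibiotic", {
      halves <- antibiotic_subset(data)
      purrr::imap_dfr(halves, function(d, nm) {
        if (nrow(d) < 30 || length(unique(d$sex)) < 2) {
          say("antibiotic subset '%s' too small (%d samples); skipped",
              nm, nrow(d))
          return(NULL)
        }
        purrr::map_dfr(config$metrics, function(m) {
          b <- age_trend_batch(d, m, config$knot, label = paste0(nm, "_"))
          t <- b$terms
          t$subset <- nm
          t
        })
      })
    })
    res$antibiotic_trends <- ab
    say("antibiotic sensitivity analysis run on %d flagged samples",
        sum(data$antibiotic_use %in% TRUE))
  } else {
    say("antibiotic stage skipped (no antibiotic_use column or stage disabled)")
  }

  # --- cardiometabolic adjustment ------------------------------------
  if ("cardiometabolic" %in% config$stages &&
      all(risk_covariates %in% names(metadata))) {
    cardio <- run_stage("cardiometabolic", {
      risk <- risk_scale(metadata)
      adj <- adjust_diversity(res$alpha_diversity, risk)
      adj_data <- dplyr::inner_join(adj, metadata, by = "sample_id")
      trends <- purrr::map_dfr(config$metrics, function(m) {
        b <- age_trend_batch(adj_data, m, config$knot, label = "adjusted_")
        t <- b$terms
        t$subset <- "risk_adjusted"
        t
      })
      list(risk = risk, adjusted = adj, trends = trends)
    })
    res$risk_scale <- cardio$risk
    res$adjusted_diversity <- cardio$adjusted
    res$adjusted_trends <- cardio$trends
    say("cardiometabolic risk adjustment run on %d samples",
        nrow(cardio$risk))
  } else {
    say("cardiometabolic stage skipped (covariates absent or stage disabled)")
  }

  # --- microbiota age -------------------------------------------------
  if ("microbiota_age" %in% config$stages) {
    ma <- run_stage("microbiota_age", {
      strata <- list(all = data)
      if (isTRUE(config$stratified_microbiota)) {
        strata$young <- data[data$age_group %in% "young", ]
        strata$middle <- data[data$age_group %in% "middle", ]
      }
      models <- list()
      samples <- list()
      comparisons <- list()
      for (st in names(strata)) {
        d <- strata[[st]]
        meta_st <- metadata[metadata$sample_id %in% d$sample_id, ]
        feat_st <- res$features_rarefied[
          res$features_rarefied$sample_id %in% d$sample_id, ]
        for (tr_sex in c("female", "male")) {
          lab <- sprintf("%s_trained_%s", st, tr_sex)
          fit <- fit_microbiota_age(
            feat_st, meta_st, training_sex = tr_sex,
            n_trees = config$n_trees,
            seed = stage_seed(config$seed, lab))
          pred <- predict_microbiota_age(fit, feat_st, meta_st)
          pred$stratum <- st
          pred$training_sex <- tr_sex
          cmp <- compare_sexes(pred, stratum = st)
          cmp$training_sex <- tr_sex
          cmp$n_shared_svs <- length(fit$shared_sv_ids)
          models[[lab]] <- fit
          samples[[lab]] <- pred
          comparisons[[lab]] <- cmp
          say("microbiota age [%s, trained on %ss]: %d shared SVs, OOB R2 %.3f",
              st, tr_sex, length(fit$shared_sv_ids), fit$training_r_squared)
        }
      }
      cmp <- dplyr::bind_rows(comparisons)
      cmp$p.adjusted <- NA_real_
      ok <- !is.na(cmp$p.value)
      cmp$p.adjusted[ok] <- adjust_bh(cmp$p.value[ok])
      list(models = models, samples = dplyr::bind_rows(samples),
           comparisons = cmp)
    })
    res$models <- ma$models
    res$microbiota_age <- ma$samples
    res$sex_comparisons <- ma$comparisons
    res$importance <- run_stage("importance", {
      importance_table(ma$models[c("all_trained_female", "all_trained_male")],
                       top_n = config$importance_top_n)
    })
    if (!is.null(config$cv_grid)) {
      res$cv_profile <- run_stage("cv_profile", {
        cv_error_profile(res$features_rarefied, metadata,
                         training_sex = "female", grid = config$cv_grid,
                         n_trees = min(config$n_trees, 200),
                         seed = stage_seed(config$seed, "cv"),
                         model = ma$models$all_trained_female)
      })
    }
  } else {
    say("microbiota_age stage skipped")
  }

  # --- summary + bookkeeping -----------------------------------------
  res$summary_table <- data |>
    dplyr::filter(!is.na(.data$age_group)) |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mean(.data$age), age_sd = sd(.data$age),
      richness_mean = mean(.data$richness), richness_sd = sd(.data$richness),
      shannon_mean = mean(.data$shannon), shannon_sd = sd(.data$shannon),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$age_group, .data$sex)
  res$exclusions <- excl
  say("exclusions: %d sample(s) excluded, %d analysed (of %d in the feature table)",
      nrow(excl), nrow(data), n_input)
  res$log <- log
  res$data <- data
  class(res) <- "microage_run"

  if (!is.null(output_dir)) write_run(res, output_dir)
  invisible(res)
}

#' @export
print.microage_run <- function(x, ...) {
  cat("<microage_run>\n")
  cat(sprintf("  %d samples analysed; components: %s\n",
              nrow(x$data),
              paste(setdiff(names(x), c("config", "log", "models", "data")),
                    collapse = ", ")))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes every tabular result of a [run_pipeline()] run as TSV, plus the
#' run log. Numeric formatting is deterministic, so identical runs give
#' byte-identical files.
#'
#' @param run a `microage_run`.
#' @param output_dir directory, created if needed.
#' @return `output_dir`, invisibly.
#' @export
write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("alpha_diversity", "age_trends", "model_fits", "loess_curves",
              "antibiotic_trends", "risk_scale", "adjusted_diversity",
              "adjusted_trends", "microbiota_age", "sex_comparisons",
              "cv_profile", "importance", "summary_table", "exclusions")
  for (nm in tables) {
    if (!is.null(run[[nm]]) && nrow(run[[nm]]) >= 0) {
      readr::write_tsv(run[[nm]], file.path(output_dir, paste0(nm, ".tsv")))
    }
  }
  writeLines(run$log, file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}
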