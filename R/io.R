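#' Read a feature table from TSV or BIOM
#'
#' TSV tables have a `sample_id` first column and one integer column per SV;
#' BIOM files (HDF5 or JSON, `.biom` extension) are read via the biomformat
#' package (BIOM stores observations as rows, so the matrix is transposed to
#' samples-by-SVs on the way in). Duplicate ids and negative counts are
#' rejected with diagnostics naming the offender.
#'
#' @param path file path; format chosen by extension (`.biom` vs anything
#'   else as TSV).
#' @return a validated feature-table tibble.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (tolower(tools::file_ext(path)) == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- t(as(biomformat::biom_data(b), "matrix"))
    ft <- ft_tibble(m)
  } else {
    ft <- readr::read_tsv(path, show_col_types = FALSE)
    names(ft)[1] <- "sample_id"
  }
  ft_tibble(ft_matrix(ft)) # validate and canonicalise
}

#' Write a feature table to TSV or BIOM
#'
#' @param features a feature-table tibble.
#' @param path output path; `.biom` writes BIOM via biomformat, anything
#'   else a TSV with a `sample_id` column and an SV-id header row.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  m <- ft_matrix(features)
  if (tolower(tools::file_ext(path)) == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("writing BIOM files requires the biomformat package")
    }
    biomformat::write_biom(biomformat::make_biom(t(m)), path)
  } else {
    readr::write_tsv(ft_tibble(m), path)
  }
  invisible(path)
}

normalise_sex <- function(x) {
  key <- substr(tolower(trimws(as.character(x))), 1, 1)
  dplyr::case_when(key == "f" ~ "female", key == "m" ~ "male",
                   TRUE ~ NA_character_)
}

#' Read and validate sample metadata
#'
#' Requires columns `sample_id`, `age` and `sex`. Sex values are normalised
#' to "female"/"male" (case-insensitive, initial-letter match); ages are
#' parsed as numbers; adults outside the age bounds (by default 20-69, i.e.
#' subjects aged 70 and above, or below 20) are excluded, as are samples
#' with unrecognised sex. An `age_group` column ("young"/"middle") is
#' derived. An `antibiotic_use` column, if present, is normalised to
#' logical.
#'
#' @param path TSV file path.
#' @param age_bounds inclusive adult age range (default `c(20, 69)`).
#' @param knot young/middle boundary age (default 45).
#' @return the included samples as a tibble; exclusions (with reasons) in
#'   the `"excluded"` attribute.
#' @export
read_metadata <- function(path, age_bounds = c(20, 69), knot = 45) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("sample_id", "age", "sex")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(raw$sample_id)) abort("duplicate sample ids in metadata")
  age <- suppressWarnings(as.numeric(raw$age))
  if (any(is.na(age) & !is.na(raw$age) & raw$age != "")) {
    bad <- raw$sample_id[is.na(age) & !is.na(raw$age)][1]
    abort(sprintf("unparseable age for sample '%s'", bad))
  }
  sex <- normalise_sex(raw$sex)
  reason <- dplyr::case_when(
    is.na(age) ~ "missing age",
    age < age_bounds[1] ~ sprintf("age below %d", age_bounds[1]),
    age > age_bounds[2] ~ sprintf("age above %d", age_bounds[2]),
    is.na(sex) ~ "unrecognised sex value",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(sample_id = raw$sample_id, age = age, sex = sex)
  extra <- raw[setdiff(names(raw), c(names(out), "age_group"))]
  for (cn in risk_covariates) {
    if (cn %in% names(extra)) extra[[cn]] <- as.numeric(extra[[cn]])
  }
  if ("antibiotic_use" %in% names(extra)) {
    extra$antibiotic_use <-
      tolower(extra$antibiotic_use) %in% c("true", "t", "yes", "1")
  }
  out <- dplyr::bind_cols(out, extra)
  out$age_group <- derive_age_group(age, age_bounds, knot)
  excluded <- tibble::tibble(sample_id = out$sample_id[!is.na(reason)],
                             reason = reason[!is.na(reason)])
  if (nrow(excluded) > 0) {
    inform(sprintf("read_metadata: excluded %d sample(s)", nrow(excluded)))
  }
  res <- out[is.na(reason), , drop = FALSE]
  attr(res, "excluded") <- excluded
  res
}

#' Write cohort metadata as TSV
#'
#' Logical antibiotic flags are written as "true"/"false".
#'
#' @param metadata a metadata tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  if ("antibiotic_use" %in% names(out) && is.logical(out$antibiotic_use)) {
    out$antibiotic_use <- ifelse(out$antibiotic_use, "true", "false")
  }
  readr::write_tsv(out, path)
  invisible(path)
}
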