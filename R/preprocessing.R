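# Categorical grouping ("normalisation") of the five clinical inputs and the
# binary pathological target. The grouping tables are fixed by the study
# design; all bins are half-open [lower, upper) so the real line is covered.

CLINICAL_T_CODES <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")
PATHOLOGICAL_T_CODES <- c("T2", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")

PSA_BREAKS <- c(2.6, 4.1, 6.1, 10, 20)
AGE_BREAKS <- seq(25, 70, by = 5)

#' Group pre-treatment PSA into its six ordinal bins
#'
#' PSA (ng/mL) is mapped to groups 1..6 using half-open intervals
#' `[0, 2.6) -> 1`, `[2.6, 4.1) -> 2`, `[4.1, 6.1) -> 3`, `[6.1, 10) -> 4`,
#' `[10, 20) -> 5`, `[20, Inf) -> 6`.
#'
#' @param psa Numeric vector of positive PSA values in ng/mL.
#' @return Integer vector of PSA groups in 1..6.
#' @export
#' @examples
#' group_psa(c(1, 9.84, 20, 107))
group_psa <- function(psa) {
  if (!is.numeric(psa)) abort("`psa` must be numeric.", class = "fuzzystage_invalid_value")
  if (any(!is.finite(psa) | psa <= 0)) {
    abort("PSA values must be positive and finite.", class = "fuzzystage_invalid_value")
  }
  findInterval(psa, PSA_BREAKS) + 1L
}

#' Group age at diagnosis into its eleven ordinal bins
#'
#' Five-year bins: below 25 is group 1, `[25, 30)` group 2, ..., `[65, 70)`
#' group 10, and 70 or older group 11.
#'
#' @param age Numeric vector of positive ages in years.
#' @return Integer vector of age groups in 1..11.
#' @export
group_age <- function(age) {
  if (!is.numeric(age)) abort("`age` must be numeric.", class = "fuzzystage_invalid_value")
  if (any(!is.finite(age) | age <= 0)) {
    abort("Age values must be positive and finite.", class = "fuzzystage_invalid_value")
  }
  findInterval(age, AGE_BREAKS) + 1L
}

#' Group clinical T stage codes
#'
#' T1a/T1b/T1c map to group 1, T2a to 2, T2b to 3, T2c to 4, and the
#' extra-prostatic codes T3a/T3b/T4 to 5. A bare "T2" (laterality unknown) is
#' not part of the published grouping; it is mapped to the most conservative
#' T2 subgroup (2) with a warning.
#'
#' @param code Character vector of clinical T codes.
#' @return Integer vector of clinical T groups in 1..5.
#' @export
group_clinical_t <- function(code) {
  code <- as.character(code)
  map <- c(T1a = 1L, T1b = 1L, T1c = 1L, T2a = 2L, T2b = 3L, T2c = 4L,
           T3a = 5L, T3b = 5L, T4 = 5L)
  if (any(code == "T2", na.rm = TRUE)) {
    warn("Clinical code 'T2' (laterality unknown) mapped to group 2.")
    map <- c(map, T2 = 2L)
  }
  bad <- !code %in% names(map)
  if (any(bad)) {
    abort(paste0("Unknown clinical T code(s): ",
                 paste(unique(code[bad]), collapse = ", ")),
          class = "fuzzystage_vocabulary_error")
  }
  unname(map[code])
}

#' Group pathological T stage codes into the binary outcome
#'
#' Organ-confined disease (pT2 family) is coded 1 and extra-prostatic disease
#' (pT3a, pT3b, pT4) is coded 2. Codes may carry a leading "p"
#' (e.g. "pT2b"). There is no pT1 classification: T1-family codes are an
#' error.
#'
#' @param code Character vector of pathological T codes.
#' @return Integer vector with values 1 (OCD) or 2 (ED).
#' @export
group_pathological_t <- function(code) {
  code <- sub("^p", "", as.character(code))
  if (any(grepl("^T1", code))) {
    abort("There is no pT1 classification.", class = "fuzzystage_vocabulary_error")
  }
  bad <- !code %in% PATHOLOGICAL_T_CODES
  if (any(bad)) {
    abort(paste0("Unknown pathological T code(s): ",
                 paste(unique(code[bad]), collapse = ", ")),
          class = "fuzzystage_vocabulary_error")
  }
  ifelse(code %in% c("T2", "T2a", "T2b", "T2c"), 1L, 2L)
}

#' Normalize a raw cohort to the grouped ordinal scale
#'
#' Applies the four grouping rules to every record. Gleason patterns pass
#' through unchanged (they are already ordinal grades 3-5). The
#' `pathological_t` column is optional (prediction mode).
#'
#' @param data Data frame with columns `primary_gleason`, `secondary_gleason`,
#'   `psa`, `age`, `clinical_t` and optionally `pathological_t`.
#' @return A tibble with columns `primary_gleason`, `secondary_gleason`,
#'   `psa_group`, `age_group`, `clinical_t_group` and, when the input carries
#'   outcomes, `pt_group` (1 = OCD, 2 = ED).
#' @export
#' @examples
#' raw <- tibble::tibble(primary_gleason = 3, secondary_gleason = 3,
#'                       psa = 1.0, age = 51.6, clinical_t = "T2b",
#'                       pathological_t = "T2a")
#' normalize_cohort(raw)
normalize_cohort <- function(data) {
  required <- c("primary_gleason", "secondary_gleason", "psa", "age", "clinical_t")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "fuzzystage_schema_error")
  }
  check_gleason(data$primary_gleason, "primary_gleason")
  check_gleason(data$secondary_gleason, "secondary_gleason")
  out <- tibble(
    primary_gleason = as.integer(data$primary_gleason),
    secondary_gleason = as.integer(data$secondary_gleason),
    psa_group = group_psa(data$psa),
    age_group = group_age(data$age),
    clinical_t_group = group_clinical_t(data$clinical_t)
  )
  if ("pathological_t" %in% names(data) && !all(is.na(data$pathological_t))) {
    out$pt_group <- group_pathological_t(data$pathological_t)
  }
  out
}

check_gleason <- function(x, name) {
  if (!is.numeric(x) || any(!x %in% 3:5)) {
    abort(paste0("`", name, "` must contain Gleason pattern grades 3, 4 or 5."),
          class = "fuzzystage_invalid_value")
  }
  invisible(x)
}

#' Read a raw cohort CSV
#'
#' Expects a comma-separated UTF-8 file with a header naming (at least)
#' `primary_gleason`, `secondary_gleason`, `psa`, `age`, `clinical_t`;
#' `pathological_t` is optional. Column names can be remapped via `col_map`.
#'
#' @param path Path to the CSV file.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file,
#'   e.g. `c(psa = "psa_ng_ml", age = "age_years")`.
#' @return A tibble of raw patient records.
#' @export
read_cohort <- function(path, col_map = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_guess()))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(data)) {
        names(data)[names(data) == col_map[[canon]]] <- canon
      }
    }
  }
  required <- c("primary_gleason", "secondary_gleason", "psa", "age", "clinical_t")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fuzzystage_schema_error")
  }
  if (nrow(data) == 0) return(as_tibble(data))
  for (col in c("psa", "age")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(data[[col]]))))
    if (length(bad) > 0) {
      abort(paste0("Unparsable `", col, "` value(s) at data row(s): ",
                   paste(bad, collapse = ", "), " (file line(s) ",
                   paste(bad + 1L, collapse = ", "), ")"),
            class = "fuzzystage_parse_error")
    }
    data[[col]] <- as.numeric(data[[col]])
  }
  as_tibble(data)
}

#' Summarise a grouped cohort
#'
#' Per-variable minimum, maximum, mean and standard deviation on the grouped
#' ordinal scale, plus the clinical-vs-pathological discordance: the number
#' of extra-prostatic cases (pt_group 2) in excess of the records staged
#' extra-prostatic clinically (clinical T group 5), floored at zero.
#'
#' @param grouped A grouped cohort (see [normalize_cohort()]) carrying
#'   `pt_group`.
#' @return An object of class `cohort_summary` with elements `stats` (a
#'   tibble), `n`, `discordant_n` and `discordant_pct`.
#' @export
cohort_summary <- function(grouped) {
  if (nrow(grouped) == 0) abort("Cannot summarise an empty cohort.")
  if (!"pt_group" %in% names(grouped)) {
    abort("Cohort summary requires outcomes (`pt_group`).")
  }
  vars <- c("primary_gleason", "secondary_gleason", "psa_group",
            "age_group", "clinical_t_group", "pt_group")
  vars <- intersect(vars, names(grouped))
  stats <- purrr::map_dfr(vars, function(v) {
    x <- grouped[[v]]
    tibble(variable = v, min = min(x), max = max(x),
           mean = mean(x), sd = stats::sd(x))
  })
  n <- nrow(grouped)
  disc <- max(0L, sum(grouped$pt_group == 2L) - sum(grouped$clinical_t_group == 5L))
  structure(
    list(stats = stats, n = n, discordant_n = disc,
         discordant_pct = 100 * disc / n),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Grouped cohort summary (n = ", x$n, ")\n\n", sep = "")
  print(x$stats)
  cat(sprintf("\nClinically under-staged extra-prostatic disease: %d (%.2f%%)\n",
              x$discordant_n, x$discordant_pct))
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$stats

#' Write a grouped cohort CSV
#'
#' @param grouped Grouped cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grouped_cohort <- function(grouped, path) {
  readr::write_csv(grouped, path)
  invisible(path)
}
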