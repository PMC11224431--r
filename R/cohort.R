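#' Categorical levels used throughout the package
#'
#' Reference levels (the first element of each vector) follow the usual
#' conventions for lung-cancer profiling cohorts: adenocarcinoma for
#' histology, primary tumor for specimen site, female for sex.
#'
#' @name cohort-levels
#' @keywords internal
NULL

HISTOLOGY_LEVELS <- c("adenocarcinoma", "squamous", "large_cell_neuroendocrine",
                      "other_nos")
SITE_LEVELS      <- c("primary", "advanced", "metastatic")
SEX_LEVELS       <- c("female", "male")
STAGE_LEVELS     <- c("I", "II", "III", "IV", "unknown")
TREATMENT_LEVELS <- c("io_mono", "io_chemo", "none")
VARIANT_CLASSES  <- c("snv", "cnv", "fusion_skipping")

# pass flag gating each variant class
.pass_flag_for <- c(snv = "pass_snv", cnv = "pass_cnv",
                    fusion_skipping = "pass_fusion")

#' Sliding age-threshold scheme
#'
#' Defines how a cohort is split into an older reference group and a nested
#' series of younger groups. With the defaults, patients aged >= 65 form the
#' reference; younger patients belong to every group `<t` with age strictly
#' below the threshold `t`, so a 50-year-old is a member of the <65, <60 and
#' <55 groups but not <50 or <45. For quantitative trend tests, ages at or
#' above `winsor` are collapsed to `winsor` (winsorized age).
#'
#' @param reference Age (years) at and above which patients form the
#'   reference ("older") group. Default 65.
#' @param young Strictly decreasing vector of young-group thresholds, each
#'   no larger than `reference`. Default `c(65, 60, 55, 50, 45)`.
#' @param winsor Cap applied to age for trend tests. Default 65.
#' @return An object of class `age_scheme`.
#' @examples
#' sch <- age_scheme()
#' sch$young_thresholds
#' @export
age_scheme <- function(reference = 65, young = c(65, 60, 55, 50, 45),
                       winsor = 65) {
  if (length(young) < 1 || any(diff(young) >= 0)) {
    abort("`young` thresholds must be strictly decreasing.",
          class = "agiscreen_config_error")
  }
  if (any(young > reference)) {
    abort("all `young` thresholds must be <= `reference`.",
          class = "agiscreen_config_error")
  }
  structure(
    list(reference_threshold = reference,
         young_thresholds = as.numeric(young),
         winsor_cap = winsor),
    class = "age_scheme"
  )
}

#' @export
print.age_scheme <- function(x, ...) {
  cat("<age_scheme> reference >=", x$reference_threshold,
      "| young groups:", paste0("<", x$young_thresholds, collapse = ", "),
      "| winsor cap:", x$winsor_cap, "\n")
  invisible(x)
}

#' Apply cohort exclusion rules
#'
#' Removes patients with missing age and ultra-hypermutated tumors
#' (TMB strictly greater than 200 mutations/Mb). A TMB of exactly 200 is
#' retained; missing TMB with known age is retained (such patients are
#' dropped later only from TMB-based models).
#'
#' @param patients Patient tibble with at least `patient_id`, `age`, `tmb`.
#' @return The filtered tibble, with the removals recorded in the
#'   `"exclusion_log"` attribute (retrieve with [exclusion_log()]).
#' @examples
#' pts <- tibble::tibble(patient_id = c("a", "b", "c"),
#'                       age = c(70, NA, 55), tmb = c(10, 12, 300))
#' kept <- apply_exclusions(pts)
#' exclusion_log(kept)
#' @export
apply_exclusions <- function(patients) {
  patients <- as_tibble(patients)
  if (nrow(patients) == 0) {
    out <- patients
    attr(out, "exclusion_log") <-
      tibble(patient_id = character(), reason = character())
    return(out)
  }
  missing_age <- is.na(patients$age)
  hyper <- !is.na(patients$tmb) & patients$tmb > 200
  log <- bind_rows(
    tibble(patient_id = patients$patient_id[missing_age],
           reason = "missing_age"),
    tibble(patient_id = patients$patient_id[!missing_age & hyper],
           reason = "ultra_hypermutated")
  )
  out <- patients[!missing_age & !hyper, , drop = FALSE]
  attr(out, "exclusion_log") <- log
  out
}

#' Retrieve the exclusion log attached by [apply_exclusions()]
#' @param x A tibble returned by [apply_exclusions()].
#' @return Tibble with columns `patient_id`, `reason`.
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusion_log") %||%
    tibble(patient_id = character(), reason = character())
}

#' Assign sliding age-group memberships
#'
#' @param patients Patient tibble with `patient_id` and non-missing `age`.
#' @param scheme An [age_scheme()].
#' @return Tibble with one row per patient: `is_reference` (age >=
#'   reference threshold), `winsorized_age`, a list-column `memberships`
#'   holding the thresholds `t` with age < t, and one logical column
#'   `lt<t>` per young threshold.
#' @examples
#' pts <- tibble::tibble(patient_id = c("p1", "p2"), age = c(50, 80))
#' assign_age_groups(pts, age_scheme())
#' @export
assign_age_groups <- function(patients, scheme = age_scheme()) {
  stopifnot(inherits(scheme, "age_scheme"))
  if (anyNA(patients$age)) {
    abort("ages must be non-missing; run apply_exclusions() first.",
          class = "agiscreen_schema_error")
  }
  ths <- scheme$young_thresholds
  out <- tibble(
    patient_id = patients$patient_id,
    age = patients$age,
    is_reference = patients$age >= scheme$reference_threshold,
    winsorized_age = pmin(patients$age, scheme$winsor_cap),
    memberships = map(patients$age, ~ ths[.x < ths])
  )
  for (t in ths) {
    out[[paste0("lt", t)]] <- patients$age < t
  }
  out
}

#' Count patients passing each assay component
#'
#' Each variant class of the profiling assay (SNV, CNV, fusion/exon
#' skipping) has its own QC pass flag, and every prevalence denominator
#' must use the matching component count, never the total cohort size.
#'
#' @param patients Patient tibble with logical `pass_snv`, `pass_cnv`,
#'   `pass_fusion` columns.
#' @param ... Optional grouping columns (tidy-select), e.g. `sex`.
#' @return Tibble with `n_total`, `n_snv`, `n_cnv`, `n_fusion` (per group
#'   when grouping columns are given).
#' @examples
#' pts <- tibble::tibble(patient_id = 1:4, sex = c("f", "f", "m", "m"),
#'                       pass_snv = c(TRUE, TRUE, FALSE, TRUE),
#'                       pass_cnv = TRUE, pass_fusion = FALSE)
#' component_denominators(pts)
#' component_denominators(pts, sex)
#' @export
component_denominators <- function(patients, ...) {
  patients |>
    group_by(...) |>
    summarise(
      n_total = dplyr::n(),
      n_snv = sum(.data$pass_snv, na.rm = TRUE),
      n_cnv = sum(.data$pass_cnv, na.rm = TRUE),
      n_fusion = sum(.data$pass_fusion, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Read a patient table from TSV/CSV
#'
#' Expects one row per patient with the `PatientRecord` columns
#' (`patient_id`, `age`, `sex`, `histology`, `specimen_site`,
#' `clinical_stage`, `tmb`, `pass_snv`, `pass_cnv`, `pass_fusion`,
#' `treatment`, `os_time`, `pfs_time`, `os_event`, `pfs_event`); missing
#' values may be empty or "NA". Delimiter is sniffed from the extension.
#'
#' @param path File path.
#' @return Patient tibble.
#' @export
read_patient_table <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- reader(path, na = c("", "NA"), show_col_types = FALSE)
  required <- c("patient_id", "age", "sex")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("patient table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "agiscreen_schema_error")
  }
  x
}

# internal: drop rows missing any of the given covariates, count removals
.drop_incomplete <- function(data, cols) {
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  dropped <- sum(!keep)
  if (dropped > 0) {
    warn(sprintf("dropping %d record(s) with missing %s", dropped,
                 paste(cols, collapse = "/")))
  }
  data[keep, , drop = FALSE]
}
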