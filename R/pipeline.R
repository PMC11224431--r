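#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> exclusions -> expression normalization and
#' scoring -> genomic screen -> immune screens -> survival screen ->
#' report, writing each stage's tidy tables to `out_dir` together with a
#' run manifest (config hash, seed, package version, file list). Stages
#' can be restricted with `stages`; later stages require their inputs and
#' fail fast otherwise. With the same config and seed the output tree is
#' byte-identical across runs.
#'
#' @param config A [sim_config()] (or path to a YAML config).
#' @param out_dir Output directory, created if needed.
#' @param seed Optional seed overriding the config's.
#' @param stages Character subset of `c("simulate", "normalize", "score",
#'   "assoc_genomic", "assoc_immune", "survival", "report")`.
#' @param strata Strata for the screens. Default all three.
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         seed = NULL,
                         stages = c("simulate", "normalize", "score",
                                    "assoc_genomic", "assoc_immune",
                                    "survival", "report"),
                         strata = c("all", "male", "female")) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  outputs <- character()
  state <- list()

  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(tbl, path)
    outputs <<- c(outputs, name)
  }

  if ("simulate" %in% stages) {
    state$cohort <- simulate_cohort(config)
    state$patients <- apply_exclusions(state$cohort$patients)
    emit(state$patients, "patients.tsv")
    emit(state$cohort$alterations, "alterations.tsv")
    emit(exclusion_log(state$patients), "exclusion_log.tsv")
  }
  if ("normalize" %in% stages) {
    .require_stage(state, "cohort", "normalize", "simulate")
    ch <- state$cohort
    bsrc <- background_subtract(ch$raw_counts, ch$ntc)
    norm <- compute_nrpm(bsrc, ch$ref_profile)
    state$nrpm <- norm$nrpm
    emit(.matrix_tbl(norm$nrpm), "nrpm.tsv")
    emit(tibble(sample_id = names(norm$ratios), ratio = norm$ratios),
         "normalization_ratios.tsv")
  }
  if ("score" %in% stages) {
    .require_stage(state, "nrpm", "score", "normalize")
    ch <- state$cohort
    state$ranks <- rank_against_reference(state$nrpm, ch$reference_nrpm)
    scores <- tibble(sample_id = colnames(state$ranks))
    for (nm in names(ch$signatures)) {
      scores[[tolower(nm)]] <-
        unname(score_signature(state$ranks, ch$signatures[[nm]]))
    }
    state$patients <- left_join(state$patients, scores,
                                by = c(patient_id = "sample_id"))
    emit(.matrix_tbl(state$ranks), "ranks.tsv")
    emit(scores, "signature_scores.tsv")
  }
  if ("assoc_genomic" %in% stages) {
    .require_stage(state, "patients", "assoc_genomic", "simulate")
    state$genomic <- run_genomic_screen(state$patients,
                                        state$cohort$alterations,
                                        strata = strata)
    emit(state$genomic$trend, "genomic_trend.tsv")
    emit(state$genomic$groups, "genomic_groups.tsv")
  }
  if ("assoc_immune" %in% stages) {
    .require_stage(state, "ranks", "assoc_immune", "score")
    sig <- run_signature_screen(state$patients, strata = strata)
    state$signature_screen <- sig
    emit(sig$trend, "signature_trend.tsv")
    de <- run_de_screen(state$patients, state$nrpm, strata = strata[1])
    state$de <- de
    emit(de$results, "de_results.tsv")
  }
  if ("survival" %in% stages) {
    .require_stage(state, "patients", "survival", "simulate")
    if (any(state$patients$treatment %in% c("io_mono", "io_chemo") &
              !is.na(state$patients$os_time))) {
      state$survival <- run_survival_screen(state$patients)
      emit(state$survival$results, "survival_results.tsv")
      emit(state$survival$km, "km_curves.tsv")
      emit(state$survival$sex_contrasts, "survival_sex_contrasts.tsv")
    }
  }
  if ("report" %in% stages) {
    rep <- build_report(state)
    for (nm in names(rep$tables)) emit(rep$tables[[nm]], paste0(nm, ".tsv"))
    jsonlite::write_json(rep$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "summary.json")
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("agiscreen")),
    stages = stages,
    outputs = sort(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(state, list(manifest = manifest, out_dir = out_dir)))
}

.require_stage <- function(state, element, stage, needs) {
  if (is.null(state[[element]])) {
    abort(sprintf("stage '%s' requires stage '%s' to run first.",
                  stage, needs),
          class = "agiscreen_config_error")
  }
}

.matrix_tbl <- function(m) {
  df <- as.data.frame(m)
  as_tibble(cbind(gene = rownames(m), df))
}

#' Hash a simulation config, invariant to field order
#'
#' @param config A `sim_config`.
#' @return Character MD5 hash of the canonically ordered config.
#' @export
config_hash <- function(config) {
  canon <- .sort_fields(unclass(config))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(canon, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.sort_fields <- function(x) {
  if (is.data.frame(x)) return(x[, sort(names(x)), drop = FALSE])
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) x <- x[sort(names(x))]
    return(lapply(x, .sort_fields))
  }
  x
}

#' Assemble cohort-level summary tables from pipeline state
#'
#' Produces a demographics table (one row per characteristic per age
#' group, percentages to one decimal), the table of significant screen
#' hits, and the survival grid, from the in-memory outputs of
#' [run_pipeline()].
#'
#' @param state List of stage outputs (as assembled by [run_pipeline()]);
#'   must contain `patients`.
#' @return List: `tables` (named list of tibbles:
#'   `report_cohort_summary`, `report_screen_hits`, `report_survival`)
#'   and `summary` (list for JSON serialization).
#' @export
build_report <- function(state) {
  if (is.null(state$patients)) {
    abort("incomplete run: missing stage output 'patients' (simulate).",
          class = "agiscreen_config_error")
  }
  pts <- state$patients
  scheme <- age_scheme()
  groups <- c(list(all = rep(TRUE, nrow(pts)),
                   reference = pts$age >= scheme$reference_threshold),
              setNames(lapply(scheme$young_thresholds,
                              function(t) pts$age < t),
                       paste0("lt", scheme$young_thresholds)))
  summarize_group <- function(mask, label) {
    sub <- pts[mask, , drop = FALSE]
    n <- nrow(sub)
    chars <- bind_rows(
      tibble(characteristic = "n", category = "total",
             n = n, pct = NA_real_),
      sub |> count(category = .data$sex) |>
        mutate(characteristic = "sex"),
      sub |> count(category = .data$histology) |>
        mutate(characteristic = "histology"),
      sub |> count(category = .data$specimen_site) |>
        mutate(characteristic = "specimen_site")
    )
    chars |>
      mutate(age_group = label,
             pct = if_else(.data$characteristic == "n", NA_real_,
                           round(100 * .data$n / max(n, 1), 1)))
  }
  cohort_summary <- imap(groups, summarize_group) |> list_rbind() |>
    select("age_group", "characteristic", "category", "n", "pct")

  hits <- if (!is.null(state$genomic)) {
    h <- filter(state$genomic$trend, .data$significant)
    if (nrow(h) == 0) {
      tibble(stratum = "all", feature_id = "none",
             note = "no significant features")
    } else {
      mutate(h, pct = round(.data$pct, 1), note = NA_character_)
    }
  } else {
    tibble(stratum = character(), feature_id = character(),
           note = character())
  }

  surv <- if (!is.null(state$survival)) {
    state$survival$results
  } else {
    tibble(endpoint = character(), treatment = character(),
           stratum = character())
  }

  list(
    tables = list(report_cohort_summary = cohort_summary,
                  report_screen_hits = hits,
                  report_survival = surv),
    summary = list(
      n_patients = nrow(pts),
      pct_reference = round(100 * mean(pts$age >= 65), 1),
      n_significant_genomic =
        if (!is.null(state$genomic))
          sum(state$genomic$trend$significant, na.rm = TRUE) else NA,
      n_significant_genes =
        if (!is.null(state$de))
          sum(state$de$results$significant, na.rm = TRUE) else NA
    )
  )
}

#' Format a proportion the way cohort tables print it
#'
#' @param n Numerator(s).
#' @param total Denominator.
#' @return Character like `"27.8%"` (one decimal).
#' @export
format_pct <- function(n, total) {
  sprintf("%.1f%%", 100 * n / total)
}
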