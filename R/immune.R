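#' Transform and model-family routing for immune features
#'
#' TMB, the CP and CTAB signature scores, and per-gene nRPM expression are
#' shifted-log transformed (`log1p`) before linear modelling because they
#' are heavily skewed toward zero; TIGS (already a bounded mean of ranks)
#' is modelled on the identity scale; high-expressor status is binary and
#' uses Firth penalized logistic regression.
#'
#' @return Tibble with columns `feature`, `scale`, `family`.
#' @export
immune_feature_table <- function() {
  tibble::tribble(
    ~feature,          ~scale,     ~family,
    "tmb",             "log1p",    "linear",
    "tigs",            "identity", "linear",
    "cp",              "log1p",    "linear",
    "ctab",            "log1p",    "linear",
    "gene_nrpm",       "log1p",    "linear",
    "high_expressor",  "identity", "firth_logistic"
  )
}

.route_feature <- function(feature) {
  tab <- immune_feature_table()
  key <- if (feature %in% tab$feature) feature else "gene_nrpm"
  tab[tab$feature == key, ]
}

.apply_scale <- function(x, scale) {
  if (scale == "log1p") log1p_transform(x) else x
}

#' Test one immune feature for age association
#'
#' Runs the young-group-vs-reference comparisons and the winsorized-age
#' trend test on a patient-level quantitative or binary feature, with the
#' transform and model family routed by [immune_feature_table()].
#'
#' @param patients Patient tibble containing a column named `feature`
#'   plus `age` and the covariates.
#' @param feature Column name: `"tmb"`, `"tigs"`, `"cp"`, `"ctab"`, or any
#'   other column (treated as gene nRPM: log1p + linear).
#' @param scheme An [age_scheme()].
#' @param covariates Adjustment covariates.
#' @param group_tests Include per-age-group tests? Default TRUE.
#' @return List of tibbles `groups` (group, estimate, p_value) and `trend`
#'   (slope, statistic, p_value).
#' @export
test_immune_feature <- function(patients, feature, scheme = age_scheme(),
                                covariates = c("specimen_site", "histology"),
                                group_tests = TRUE) {
  route <- .route_feature(feature)
  vals <- patients[[feature]]
  if (is.null(vals)) {
    abort(paste0("no column `", feature, "` in patients."),
          class = "agiscreen_schema_error")
  }
  if (length(unique(stats::na.omit(vals))) < 2) {
    abort(paste0("feature `", feature, "` is constant; nothing to test."),
          class = "agiscreen_fit_error")
  }
  dat <- patients
  dat$.response <- .apply_scale(vals, route$scale)
  .assoc_feature(dat, route$family, scheme, covariates, group_tests)
}

#' Immune signature and TMB screen across strata
#'
#' Tests TMB and the TIGS/CP/CTAB signature scores for age association in
#' each stratum.
#'
#' @param patients Patient tibble carrying `tmb`, `tigs`, `cp`, `ctab`.
#' @param scheme An [age_scheme()].
#' @param strata Subset of `c("all", "male", "female")`.
#' @param covariates Adjustment covariates.
#' @return List: `trend` (stratum x feature trend results) and `groups`
#'   (stratum x feature x age-group estimates).
#' @export
run_signature_screen <- function(patients, scheme = age_scheme(),
                                 strata = c("all", "male", "female"),
                                 covariates = c("specimen_site",
                                                "histology")) {
  feats <- intersect(c("tmb", "tigs", "cp", "ctab"), names(patients))
  rows_t <- list(); rows_g <- list()
  for (st in strata) {
    pts <- switch(st, all = patients,
                  male = filter(patients, .data$sex == "male"),
                  female = filter(patients, .data$sex == "female"))
    for (ft in feats) {
      out <- test_immune_feature(pts, ft, scheme, covariates)
      rows_t[[length(rows_t) + 1]] <-
        bind_cols(tibble(stratum = st, feature = ft),
                  rename(out$trend, trend_slope = "slope",
                         trend_stat = "statistic", trend_p = "p_value"))
      rows_g[[length(rows_g) + 1]] <-
        bind_cols(tibble(stratum = st, feature = ft)[rep(1, nrow(out$groups)), ],
                  out$groups)
    }
  }
  list(trend = list_rbind(rows_t), groups = list_rbind(rows_g))
}

#' Per-gene differential expression screen
#'
#' Tests every gene's `log1p(nRPM)` for age association (linear model,
#' young groups vs >= 65 reference plus winsorized-age trend), applies BH
#' correction across the tested genes within each stratum, and summarizes
#' each gene's group coefficients into a single estimated fold change for
#' volcano plotting: the exponent of the mean of the per-group
#' coefficients (fold change > 1 means enriched in younger tumors).
#'
#' @param patients Patient tibble.
#' @param nrpm Genes x samples nRPM matrix; columns are patient ids.
#' @param scheme An [age_scheme()].
#' @param strata Subset of `c("all", "male", "female")`.
#' @param covariates Adjustment covariates (may include a driver-alteration
#'   indicator column added with [add_driver_covariate()]).
#' @param group_tests Include per-age-group tests (needed for the fold
#'   change)? Default TRUE.
#' @return Object of class `de_screen`: tibble `results` with one row per
#'   stratum x gene (trend slope/p/adjusted p, fold change, direction,
#'   significance at adjusted p < 0.25) and tibble `groups` with the
#'   per-age-group coefficients.
#' @export
run_de_screen <- function(patients, nrpm, scheme = age_scheme(),
                          strata = "all",
                          covariates = c("specimen_site", "histology"),
                          group_tests = TRUE) {
  ids <- intersect(patients$patient_id, colnames(nrpm))
  rows <- list(); rows_g <- list()
  for (st in strata) {
    pts <- switch(st, all = patients,
                  male = filter(patients, .data$sex == "male"),
                  female = filter(patients, .data$sex == "female"))
    pts <- pts[pts$patient_id %in% ids, , drop = FALSE]
    for (g in rownames(nrpm)) {
      dat <- pts
      dat$.response <- log1p_transform(nrpm[g, dat$patient_id])
      if (length(unique(dat$.response)) < 2) next
      out <- .assoc_feature(dat, "linear", scheme, covariates, group_tests)
      fc <- if (group_tests) {
        compute_volcano_foldchange(out$groups$estimate)
      } else {
        tibble(fold_change = NA_real_, direction = NA_character_)
      }
      rows[[length(rows) + 1]] <- bind_cols(
        tibble(stratum = st, gene = g),
        rename(out$trend, trend_slope = "slope", trend_stat = "statistic",
               trend_p = "p_value"),
        fc
      )
      if (group_tests) {
        rows_g[[length(rows_g) + 1]] <-
          bind_cols(tibble(stratum = st,
                           gene = g)[rep(1, nrow(out$groups)), ],
                    out$groups)
      }
    }
  }
  results <- list_rbind(rows) |>
    group_by(.data$stratum) |>
    mutate(trend_p_adj = bh_fdr(.data$trend_p)) |>
    ungroup() |>
    mutate(significant = !is.na(.data$trend_p_adj) &
             .data$trend_p_adj < ALPHA_FDR)
  structure(list(results = results,
                 groups = if (length(rows_g)) list_rbind(rows_g) else NULL),
            class = "de_screen")
}

#' @export
print.de_screen <- function(x, ...) {
  cat("<de_screen>", nrow(x$results), "stratum x gene tests;",
      sum(x$results$significant, na.rm = TRUE),
      "significant at adjusted p <", ALPHA_FDR, "\n")
  invisible(x)
}

#' @describeIn run_de_screen Tidy per-gene results.
#' @param x A `de_screen`.
#' @param ... Unused.
#' @export
tidy.de_screen <- function(x, ...) x$results

#' Volcano fold-change summary of per-group coefficients
#'
#' The single estimated fold change of a gene is the exponent of the mean
#' of its young-group-vs-reference coefficients (equal weight across the
#' age groups). Under the coding used here (young group = 1), a fold
#' change above 1 means expression enriched in younger tumors.
#'
#' @param coefs Numeric vector of per-group coefficients (log scale);
#'   `NA`s from non-converged groups are dropped.
#' @return One-row tibble: `fold_change`, `direction`
#'   (`"younger_enriched"` / `"older_enriched"`).
#' @examples
#' compute_volcano_foldchange(c(0.1, 0.2, 0.3, 0.4, 0.5))  # exp(0.3)
#' @export
compute_volcano_foldchange <- function(coefs) {
  coefs <- coefs[!is.na(coefs)]
  if (length(coefs) == 0) {
    return(tibble(fold_change = NA_real_, direction = NA_character_))
  }
  fc <- exp(mean(coefs))
  tibble(fold_change = fc,
         direction = if_else(fc > 1, "younger_enriched", "older_enriched"))
}

#' High-expressor prevalence screen over a marker panel
#'
#' For each marker gene, tests whether younger tumors are more or less
#' likely to be "high expressors" (rank >= 75) than the >= 65 reference
#' group, using Firth penalized logistic regression plus the penalized-LRT
#' age trend, with BH correction across the panel within each stratum.
#' Markers with no high expressors at all (or all high expressors) are
#' excluded with a log entry.
#'
#' @param patients Patient tibble.
#' @param ranks Genes x samples percentile-rank matrix.
#' @param markers Character vector of marker genes (default: all rows of
#'   `ranks`).
#' @inheritParams run_de_screen
#' @return List: `results` (stratum x gene trend + adjusted p), `groups`
#'   (per-age-group ORs), `excluded` (tibble of skipped markers).
#' @export
run_high_expressor_screen <- function(patients, ranks,
                                      markers = rownames(ranks),
                                      scheme = age_scheme(), strata = "all",
                                      covariates = c("specimen_site",
                                                     "histology"),
                                      group_tests = TRUE) {
  ids <- intersect(patients$patient_id, colnames(ranks))
  rows <- list(); rows_g <- list(); excluded <- list()
  for (st in strata) {
    pts <- switch(st, all = patients,
                  male = filter(patients, .data$sex == "male"),
                  female = filter(patients, .data$sex == "female"))
    pts <- pts[pts$patient_id %in% ids, , drop = FALSE]
    for (g in markers) {
      he <- as.numeric(call_high_expressor(ranks[g, pts$patient_id]))
      if (length(unique(he)) < 2) {
        excluded[[length(excluded) + 1]] <-
          tibble(stratum = st, gene = g,
                 reason = if (all(he == 0)) "no_high_expressors"
                          else "all_high_expressors")
        next
      }
      dat <- pts
      dat$.response <- he
      out <- .assoc_feature(dat, "firth_logistic", scheme, covariates,
                            group_tests)
      rows[[length(rows) + 1]] <- bind_cols(
        tibble(stratum = st, gene = g),
        rename(out$trend, trend_slope = "slope", trend_stat = "statistic",
               trend_p = "p_value")
      )
      if (group_tests) {
        rows_g[[length(rows_g) + 1]] <-
          bind_cols(tibble(stratum = st,
                           gene = g)[rep(1, nrow(out$groups)), ],
                    mutate(out$groups, or = exp(.data$estimate)))
      }
    }
  }
  results <- list_rbind(rows)
  if (nrow(results)) {
    results <- results |>
      group_by(.data$stratum) |>
      mutate(trend_p_adj = bh_fdr(.data$trend_p)) |>
      ungroup() |>
      mutate(significant = !is.na(.data$trend_p_adj) &
               .data$trend_p_adj < ALPHA_FDR)
  }
  list(results = results,
       groups = if (length(rows_g)) list_rbind(rows_g) else NULL,
       excluded = if (length(excluded)) list_rbind(excluded) else
         tibble(stratum = character(), gene = character(),
                reason = character()))
}

#' Add an ALK/EGFR driver-alteration covariate
#'
#' Flags patients carrying any alteration in the given driver genes, so
#' that immune analyses can be repeated with driver status as an extra
#' covariate (sensitivity analysis: are age associations merely driven by
#' the age-linked driver alterations?). If no patient (or every patient)
#' carries a driver alteration the column is constant and the modelling
#' engine drops it, making the adjusted run identical to the primary one;
#' a warning is issued.
#'
#' @param patients Patient tibble.
#' @param calls Long alteration-call tibble.
#' @param genes Driver genes. Default `c("ALK", "EGFR")`.
#' @param name Name of the new column. Default `"driver"`.
#' @return `patients` with the added 0/1 column.
#' @export
add_driver_covariate <- function(patients, calls, genes = c("ALK", "EGFR"),
                                 name = "driver") {
  carriers <- unique(calls$patient_id[calls$gene %in% genes])
  flag <- as.numeric(patients$patient_id %in% carriers)
  if (length(unique(flag)) < 2) {
    warn("driver covariate is constant; adjusted analyses will equal the primary run.")
  }
  patients[[name]] <- flag
  patients
}

#' Male-vs-female contrast for one feature
#'
#' Same model family and transform as the age analyses, but with sex as
#' the exposure (no age term), adjusted for the covariates. The
#' coefficient describes males relative to the female reference.
#'
#' @param patients Patient tibble containing the feature column and both
#'   sexes.
#' @param feature Feature column name (routed as in
#'   [test_immune_feature()]).
#' @param covariates Adjustment covariates.
#' @return One-row tibble: `estimate` (male coefficient), `statistic`,
#'   `p_value`, `n`.
#' @export
sex_contrast <- function(patients, feature,
                         covariates = c("specimen_site", "histology")) {
  if (length(unique(patients$sex)) < 2) {
    abort("both sexes must be present for a sex contrast.",
          class = "agiscreen_schema_error")
  }
  route <- .route_feature(feature)
  dat <- .covariate_factors(patients)
  dat$.response <- .apply_scale(dat[[feature]], route$scale)
  dat <- dat[!is.na(dat$.response), , drop = FALSE]
  keep <- stats::complete.cases(dat[, covariates, drop = FALSE])
  dat <- dat[keep, , drop = FALSE]
  out <- .nested_term_test(dat, route$family, "sex", covariates)
  if (is.null(out)) {
    abort("sex contrast did not converge.", class = "agiscreen_fit_error")
  }
  tibble(estimate = out$estimate, statistic = out$test$statistic,
         p_value = out$test$p_value, n = nrow(dat))
}
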