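#' Aggregate alteration calls into testable features
#'
#' Builds the feature set for the prevalence screen: one gene-level
#' feature per (gene, variant class) — a patient is a carrier if they have
#' at least one call of that class in that gene, duplicates counting once
#' — plus one variant-level feature per distinct (gene, variant class,
#' variant label). Aggregation stays within variant class: a patient with
#' only an ALK fusion is not a carrier of an ALK SNV feature. Tier
#' annotations are carried along as metadata and never gate testing.
#'
#' @param calls Long `AlterationCall` tibble (`patient_id`, `gene`,
#'   `variant_class`, `variant_label`, optional `tier`).
#' @return Feature tibble: `feature_id`, `level` ("gene"/"variant"),
#'   `gene`, `variant_class`, `variant_label` (`NA` at gene level),
#'   `tier`, and a list-column `carriers` of patient ids.
#' @export
aggregate_gene_level <- function(calls) {
  calls <- as_tibble(calls)
  if (!"tier" %in% names(calls)) calls$tier <- NA_character_
  gene_level <- calls |>
    group_by(.data$gene, .data$variant_class) |>
    summarise(carriers = list(unique(.data$patient_id)),
              tier = paste(sort(unique(stats::na.omit(.data$tier))),
                           collapse = "/"),
              .groups = "drop") |>
    mutate(level = "gene", variant_label = NA_character_,
           feature_id = paste("G", .data$gene, .data$variant_class,
                              sep = ":"))
  variant_level <- calls |>
    group_by(.data$gene, .data$variant_class, .data$variant_label) |>
    summarise(carriers = list(unique(.data$patient_id)),
              tier = paste(sort(unique(stats::na.omit(.data$tier))),
                           collapse = "/"),
              .groups = "drop") |>
    mutate(level = "variant",
           feature_id = paste("V", .data$gene, .data$variant_class,
                              .data$variant_label, sep = ":"))
  bind_rows(gene_level, variant_level) |>
    mutate(tier = if_else(.data$tier == "", NA_character_, .data$tier)) |>
    select("feature_id", "level", "gene", "variant_class", "variant_label",
           "tier", "carriers")
}

#' Keep features detected in at least `min_count` tumors
#'
#' @param features Feature tibble from [aggregate_gene_level()] with an
#'   `n_detected` column (see [run_genomic_screen()]), or with `carriers`
#'   from which counts are derived.
#' @param min_count Inclusion threshold; features seen in fewer tumors are
#'   dropped. Default 5 ("at least 5" is inclusive).
#' @return Filtered feature tibble.
#' @export
filter_min_detected <- function(features, min_count = 5) {
  if (!"n_detected" %in% names(features)) {
    features$n_detected <- map_dbl(features$carriers, length)
  }
  features[features$n_detected >= min_count, , drop = FALSE]
}

#' Prevalence of a feature within a denominator
#'
#' @param n_detected Number of carriers.
#' @param denominator Number of patients passing the matching assay
#'   component (never the total cohort size).
#' @return One-row tibble: `n_detected`, `denominator`, `prevalence`
#'   (fraction) and `pct` (percentage); a zero denominator gives `NA`
#'   prevalence with `degenerate = TRUE`.
#' @examples
#' compute_prevalence(1998, 7179)  # 27.8%
#' @export
compute_prevalence <- function(n_detected, denominator) {
  degenerate <- denominator == 0
  prev <- if_else(degenerate, NA_real_, n_detected / denominator)
  tibble(n_detected = n_detected, denominator = denominator,
         prevalence = prev, pct = 100 * prev, degenerate = degenerate)
}

#' Run the genomic alteration prevalence screen
#'
#' For each stratum (all patients, males, females): aggregates calls into
#' gene- and variant-level features, applies the minimum-detection filter
#' within the component-passing subcohort, tests each young age group
#' against the >= 65 reference with Firth penalized logistic regression
#' adjusted for the covariates, runs the winsorized-age penalized-LRT
#' trend test, and applies Benjamini-Hochberg correction across the
#' features of each (stratum, level) pool — group p-values additionally
#' pool within age group. Non-converged fits are flagged and excluded
#' from the FDR pools.
#'
#' @param patients Patient tibble (post-exclusion).
#' @param calls Long alteration-call tibble.
#' @param scheme An [age_scheme()].
#' @param strata Subset of `c("all", "male", "female")`.
#' @param covariates Adjustment covariates. Default specimen site and
#'   histology.
#' @param min_count Minimum tumors a feature must be detected in.
#' @param group_tests Run the per-age-group tests in addition to the trend
#'   test? Set FALSE to compute trend tests only (e.g. in simulation
#'   studies). Default TRUE.
#' @return Object of class `genomic_screen`: tibbles `trend` (one row per
#'   stratum x feature: prevalence, trend slope/p/adjusted p,
#'   `significant` at adjusted p < 0.25) and `groups` (one row per
#'   stratum x feature x age group: n, prevalence, OR, p, adjusted p).
#' @export
run_genomic_screen <- function(patients, calls, scheme = age_scheme(),
                               strata = c("all", "male", "female"),
                               covariates = c("specimen_site", "histology"),
                               min_count = 5, group_tests = TRUE) {
  features <- aggregate_gene_level(calls)
  res <- map(strata, function(st) {
    pts <- switch(st, all = patients,
                  male = filter(patients, .data$sex == "male"),
                  female = filter(patients, .data$sex == "female"))
    .screen_stratum(pts, features, scheme, covariates, min_count, st,
                    group_tests)
  })
  groups <- list_rbind(map(res, "groups"))
  trend <- list_rbind(map(res, "trend"))
  # FDR pools: trend within (stratum, level); group tests within
  # (stratum, level, group)
  trend <- trend |>
    group_by(.data$stratum, .data$level) |>
    mutate(trend_p_adj = bh_fdr(.data$trend_p)) |>
    ungroup() |>
    mutate(significant = !is.na(.data$trend_p_adj) &
             .data$trend_p_adj < ALPHA_FDR)
  groups <- groups |>
    group_by(.data$stratum, .data$level, .data$group) |>
    mutate(p_adj = bh_fdr(.data$p_value)) |>
    ungroup()
  structure(list(trend = trend, groups = groups, features = features),
            class = "genomic_screen")
}

.screen_stratum <- function(patients, features, scheme, covariates,
                            min_count, stratum_label, group_tests = TRUE) {
  rows_g <- list(); rows_t <- list()
  for (i in seq_len(nrow(features))) {
    ft <- features[i, ]
    passing <- patients[patients[[.pass_flag_for[[ft$variant_class]]]], ,
                        drop = FALSE]
    carriers <- intersect(ft$carriers[[1]], passing$patient_id)
    n_det <- length(carriers)
    if (n_det < min_count) next
    dat <- passing
    dat$.response <- as.numeric(dat$patient_id %in% carriers)
    out <- .assoc_feature(dat, "firth_logistic", scheme, covariates,
                          group_tests)
    meta <- select(ft, "feature_id", "level", "gene", "variant_class",
                   "variant_label", "tier")
    if (group_tests) {
      # per-group carrier counts/prevalence over the component denominator
      grp <- out$groups |>
        mutate(or = exp(.data$estimate))
      prev_rows <- map(scheme$young_thresholds, function(t) {
        sub <- passing[passing$age < t, , drop = FALSE]
        compute_prevalence(sum(sub$patient_id %in% carriers), nrow(sub)) |>
          mutate(group = paste0("lt", t))
      }) |> list_rbind()
      ref <- passing[passing$age >= scheme$reference_threshold, ,
                     drop = FALSE]
      ref_prev <- compute_prevalence(sum(ref$patient_id %in% carriers),
                                     nrow(ref)) |>
        mutate(group = "reference")
      grp <- left_join(grp, bind_rows(prev_rows, ref_prev), by = "group")
      grp_all <- bind_rows(grp,
                           mutate(ref_prev, estimate = NA_real_,
                                  or = NA_real_, p_value = NA_real_,
                                  converged = NA)) |>
        mutate(stratum = stratum_label)
      rows_g[[length(rows_g) + 1]] <-
        bind_cols(grp_all, meta[rep(1, nrow(grp_all)), ])
    }
    rows_t[[length(rows_t) + 1]] <- bind_cols(
      tibble(stratum = stratum_label), meta,
      compute_prevalence(n_det, nrow(passing)) |>
        select(-"degenerate"),
      rename(out$trend, trend_slope = "slope", trend_stat = "statistic",
             trend_p = "p_value", n_model = "n")
    )
  }
  list(
    groups = if (length(rows_g)) list_rbind(rows_g) else .empty_group_rows(),
    trend = if (length(rows_t)) list_rbind(rows_t) else .empty_trend_rows()
  )
}

.empty_group_rows <- function() {
  tibble(group = character(), estimate = numeric(), p_value = numeric(),
         n = integer(), converged = logical(), or = numeric(),
         n_detected = numeric(), denominator = numeric(),
         prevalence = numeric(), pct = numeric(), degenerate = logical(),
         stratum = character(), feature_id = character(), level = character(),
         gene = character(), variant_class = character(),
         variant_label = character(), tier = character())
}

.empty_trend_rows <- function() {
  tibble(stratum = character(), feature_id = character(), level = character(),
         gene = character(), variant_class = character(),
         variant_label = character(), tier = character(),
         n_detected = numeric(), denominator = numeric(),
         prevalence = numeric(), pct = numeric(), trend_slope = numeric(),
         trend_stat = numeric(), trend_p = numeric(), n_model = integer(),
         converged = logical())
}

#' @export
print.genomic_screen <- function(x, ...) {
  cat("<genomic_screen>", nrow(x$trend), "feature x stratum trend tests;",
      sum(x$trend$significant, na.rm = TRUE),
      "significant at adjusted p <", ALPHA_FDR, "\n")
  invisible(x)
}

#' @describeIn run_genomic_screen Tidy trend-level results.
#' @param x A `genomic_screen`.
#' @param ... Unused.
#' @export
tidy.genomic_screen <- function(x, ...) x$trend

#' Read a long alteration-call table from TSV/CSV
#' @param path File path with columns `patient_id`, `gene`,
#'   `variant_class`, `variant_label`, optional `tier`.
#' @return Tibble of calls.
#' @export
read_alteration_table <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- reader(path, na = c("", "NA"), show_col_types = FALSE)
  required <- c("patient_id", "gene", "variant_class")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(paste0("alteration table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "agiscreen_schema_error")
  }
  x
}
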