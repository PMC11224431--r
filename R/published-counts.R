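#' Published cohort summary counts shipped with the package
#'
#' Marginal counts from the demographic and alteration-prevalence summary
#' tables of the large real-world NSCLC profiling cohort that this
#' package's defaults emulate (8,230 patients; component denominators
#' SNV 7,179 / CNV 7,291 / fusion 6,304). These are used for worked
#' examples: reconstructing 2x2 tables for Fisher odds ratios and
#' verifying prevalence arithmetic. They are summary counts only — no
#' patient-level data.
#'
#' @param which `"age"` (demographics by age group) or `"alterations"`
#'   (alteration detection counts).
#' @return Tibble of counts.
#' @examples
#' counts <- published_cohort_counts("age")
#' head(counts)
#' @export
published_cohort_counts <- function(which = c("age", "alterations")) {
  which <- match.arg(which)
  file <- switch(which, age = "cohort_age_counts.tsv",
                 alterations = "alteration_prevalence_counts.tsv")
  readr::read_tsv(system.file("extdata", file, package = "agiscreen",
                              mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Build a young-vs-reference 2x2 table from published counts
#'
#' Rows are (young group, reference group), columns are (category yes,
#' category no), suitable for [fisher_exact_2x2()].
#'
#' @param counts Tibble from `published_cohort_counts("age")`.
#' @param category Category of interest (e.g. `"squamous"`).
#' @param young_group Age-group label (e.g. `"lt65"`).
#' @param characteristic Which characteristic the category belongs to.
#' @return 2x2 integer matrix.
#' @export
published_2x2 <- function(counts, category, young_group,
                          characteristic = "histology") {
  pick <- function(grp) {
    row <- counts[counts$age_group == grp &
                    counts$characteristic == characteristic &
                    counts$category == category, ]
    if (nrow(row) != 1) {
      abort(sprintf("no unique count row for %s/%s/%s", grp,
                    characteristic, category),
            class = "agiscreen_schema_error")
    }
    c(yes = row$n, total = row$group_total)
  }
  y <- pick(young_group); r <- pick("ge65")
  matrix(c(y["yes"], y["total"] - y["yes"],
           r["yes"], r["total"] - r["yes"]),
         nrow = 2, byrow = TRUE,
         dimnames = list(c(young_group, "ge65"), c("yes", "no")))
}
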