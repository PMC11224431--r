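#' Volcano plot of a differential-expression screen
#'
#' Estimated fold change (log2 axis) against -log10 adjusted trend p for
#' every tested gene, colored by enrichment direction.
#'
#' @param x A `de_screen` from [run_de_screen()].
#' @param stratum Which stratum to plot. Default `"all"`.
#' @param alpha Significance line on the adjusted p scale. Default 0.25.
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, stratum = "all", alpha = ALPHA_FDR) {
  stopifnot(inherits(x, "de_screen"))
  d <- filter(x$results, .data$stratum == .env$stratum,
              !is.na(.data$fold_change), !is.na(.data$trend_p_adj))
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$fold_change),
                                  y = -log10(.data$trend_p_adj),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(younger_enriched = "#2166ac",
                                            older_enriched = "#b2182b"),
                                 na.value = "grey60") +
    ggplot2::labs(x = "log2 estimated fold change (younger vs ≥65)",
                  y = "-log10 adjusted P for trend", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.de_screen <- function(object, ...) plot_volcano(object, ...)

#' Kaplan-Meier step plot
#'
#' @param km Tidy curve tibble from [km_curve()] (or the `km` element of a
#'   [run_survival_screen()] result filtered to one cell).
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  start <- km |>
    group_by(.data$group) |>
    summarise(time = 0, survival = 1, .groups = "drop")
  ggplot2::ggplot(bind_rows(start, select(km, "group", "time", "survival")),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Prevalence-by-age-group bars for screen hits
#'
#' Mirrors the usual presentation of age-associated alteration
#' prevalences: one bar per age group per significant feature.
#'
#' @param x A `genomic_screen` from [run_genomic_screen()].
#' @param stratum Stratum to plot. Default `"all"`.
#' @return A ggplot object.
#' @export
plot_prevalence <- function(x, stratum = "all") {
  stopifnot(inherits(x, "genomic_screen"))
  sig <- filter(x$trend, .data$stratum == .env$stratum, .data$significant)
  d <- filter(x$groups, .data$stratum == .env$stratum,
              .data$feature_id %in% sig$feature_id)
  d$group <- factor(d$group, levels = c("reference", "lt65", "lt60",
                                        "lt55", "lt50", "lt45"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$group)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::facet_wrap(~ .data$feature_id, scales = "free_x") +
    ggplot2::labs(x = "Prevalence (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.genomic_screen <- function(object, ...) plot_prevalence(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
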