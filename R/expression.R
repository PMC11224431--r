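#' Subtract no-template-control background from raw counts
#'
#' Subtracts a per-gene background count (from a sequenced no-template
#' control) from every sample, flooring at zero: negative pseudo-counts
#' have no meaning for the downstream ratio and log1p steps.
#'
#' @param raw Genes x samples matrix of raw read counts with rownames.
#' @param ntc Named per-gene background vector covering the same genes.
#' @return Background-subtracted (BSRC) matrix, same dimensions.
#' @examples
#' m <- matrix(c(5, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' background_subtract(m, c(g1 = 7, g2 = 1))
#' @export
background_subtract <- function(raw, ntc) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw)) || is.null(names(ntc)) ||
      !setequal(rownames(raw), names(ntc))) {
    abort("`ntc` must be named and cover exactly the genes of `raw`.",
          class = "agiscreen_schema_error")
  }
  pmax(raw - ntc[rownames(raw)], 0)
}

#' Housekeeping reference profile
#'
#' A pre-constructed RPM profile of the housekeeping genes from an
#' external, validated control sample, against which each sample's
#' normalization ratio is computed.
#'
#' @param rpm Named numeric vector of strictly positive RPM values, one per
#'   housekeeping gene.
#' @return Object of class `reference_profile`.
#' @export
reference_profile <- function(rpm) {
  if (is.null(names(rpm)) || anyDuplicated(names(rpm)) ||
      any(!is.finite(rpm)) || any(rpm <= 0)) {
    abort("`rpm` must be a uniquely named vector of positive values.",
          class = "agiscreen_config_error")
  }
  structure(list(housekeeping_ids = names(rpm), rpm = rpm),
            class = "reference_profile")
}

#' Median-ratio normalization to nRPM
#'
#' For each sample, the ratios of its housekeeping-gene BSRC values to the
#' reference profile's RPM values are formed and their median (even counts
#' use the midpoint average) is the sample's normalization ratio; every
#' gene's BSRC is then divided by that ratio to give normalized reads per
#' million (nRPM). The result is invariant to rescaling all of a sample's
#' counts by a common factor. Samples whose housekeeping BSRCs give a
#' non-positive median ratio cannot be normalized and are dropped with a
#' log entry.
#'
#' @param bsrc Genes x samples BSRC matrix (from [background_subtract()]).
#' @param ref A [reference_profile()]; its genes must be rows of `bsrc`.
#' @return List: `nrpm` (matrix over retained samples), `ratios` (named
#'   per-sample normalization ratios), `dropped` (tibble of removed
#'   samples with reasons).
#' @export
compute_nrpm <- function(bsrc, ref) {
  stopifnot(inherits(ref, "reference_profile"))
  bsrc <- as.matrix(bsrc)
  hk <- ref$housekeeping_ids
  missing <- setdiff(hk, rownames(bsrc))
  if (length(missing)) {
    abort(paste0("housekeeping gene(s) absent from matrix: ",
                 paste(missing, collapse = ", ")),
          class = "agiscreen_schema_error")
  }
  ratios <- apply(bsrc[hk, , drop = FALSE] / ref$rpm[hk], 2, median)
  ok <- is.finite(ratios) & ratios > 0
  dropped <- tibble(sample_id = colnames(bsrc)[!ok],
                    reason = "unnormalizable_zero_housekeeping")
  if (any(!ok)) {
    warn(sprintf("dropping %d sample(s) with zero housekeeping signal",
                 sum(!ok)))
  }
  nrpm <- sweep(bsrc[, ok, drop = FALSE], 2, ratios[ok], "/")
  list(nrpm = nrpm, ratios = ratios[ok], dropped = dropped)
}

#' Percentile rank against a reference population
#'
#' Maps a value onto the 1-100 percentile scale of a reference population
#' using the mid-rank convention
#' `100 * (#\{r < v\} + 0.5 * #\{r = v\}) / n`, clamped to \[1, 100\].
#' Monotone non-decreasing in the value; ties in the reference each
#' contribute half a count. Ranks are kept as reals.
#'
#' @param value Numeric vector of values to rank.
#' @param reference Non-empty numeric vector: the reference population's
#'   values for the same gene.
#' @return Ranks in \[1, 100\], same length as `value`.
#' @examples
#' percentile_rank(25, c(10, 20, 30, 40))  # 50
#' @export
percentile_rank <- function(value, reference) {
  if (length(reference) == 0) {
    abort("reference population is empty.", class = "agiscreen_config_error")
  }
  n <- length(reference)
  sr <- sort(reference)
  n_lt <- findInterval(value, sr, left.open = FALSE)   # r <= v
  n_le <- n_lt
  n_lt <- findInterval(value, sr, left.open = TRUE)    # r < v
  raw <- 100 * (n_lt + 0.5 * (n_le - n_lt)) / n
  pmin(pmax(raw, 1), 100)
}

#' Rank every gene of an nRPM matrix against a reference population
#'
#' @param nrpm Genes x samples nRPM matrix.
#' @param reference_nrpm Genes x reference-samples nRPM matrix of the
#'   reference population, same genes.
#' @return Matrix of percentile ranks in \[1, 100\], dimensions of `nrpm`.
#' @export
rank_against_reference <- function(nrpm, reference_nrpm) {
  nrpm <- as.matrix(nrpm); reference_nrpm <- as.matrix(reference_nrpm)
  if (!setequal(rownames(nrpm), rownames(reference_nrpm))) {
    abort("gene sets of sample and reference matrices differ.",
          class = "agiscreen_schema_error")
  }
  out <- nrpm
  for (g in rownames(nrpm)) {
    out[g, ] <- percentile_rank(nrpm[g, ], reference_nrpm[g, ])
  }
  out
}

#' High-expressor call from a percentile rank
#'
#' A tumor is a "high expressor" of a gene when its normalized expression
#' rank reaches 75 or above (the threshold is inclusive; the rule applies
#' to the real-valued rank).
#'
#' @param rank Numeric rank(s) in \[1, 100\].
#' @return Logical vector.
#' @export
call_high_expressor <- function(rank) {
  rank >= 75
}

#' Define an expression signature
#'
#' TIGS (tumor immunogenic score) and CP (cellular proliferation) average
#' the ranks of their gene sets; CTAB (cancer testis antigen burden) sums
#' them. Custom signatures choose either mode.
#'
#' @param name Signature name; `"TIGS"`/`"CP"` force mode `"mean"`,
#'   `"CTAB"` forces `"sum"`.
#' @param genes Non-empty character vector of gene ids.
#' @param mode `"mean"` or `"sum"`; only honoured for custom names.
#' @return Object of class `signature_def`.
#' @export
signature_def <- function(name, genes, mode = c("mean", "sum")) {
  if (length(genes) == 0) {
    abort("signature gene set is empty.", class = "agiscreen_config_error")
  }
  mode <- switch(toupper(name),
                 TIGS = "mean", CP = "mean", CTAB = "sum",
                 match.arg(mode))
  structure(list(name = name, genes = unique(genes), mode = mode),
            class = "signature_def")
}

#' Score one signature for every sample
#'
#' @param ranks Genes x samples rank matrix.
#' @param def A [signature_def()]. Every signature gene must be present in
#'   `ranks`; a missing gene is an error naming the gene, never silently
#'   skipped.
#' @return Named per-sample score vector.
#' @export
score_signature <- function(ranks, def) {
  stopifnot(inherits(def, "signature_def"))
  missing <- setdiff(def$genes, rownames(ranks))
  if (length(missing)) {
    abort(paste0("signature ", def$name, " gene(s) missing from matrix: ",
                 paste(missing, collapse = ", ")),
          class = "agiscreen_schema_error")
  }
  sub <- ranks[def$genes, , drop = FALSE]
  if (def$mode == "mean") colMeans(sub) else colSums(sub)
}

#' Run the full expression pipeline
#'
#' Background subtraction, median-ratio nRPM normalization, percentile
#' ranking against the reference population, high-expressor calls, and
#' signature scoring, in one call.
#'
#' @param raw Genes x samples raw count matrix.
#' @param ntc Named per-gene no-template-control counts.
#' @param ref A [reference_profile()] of housekeeping RPM values.
#' @param reference_nrpm Genes x samples nRPM matrix of the rank-calibration
#'   reference population.
#' @param signatures Named list of [signature_def()] objects.
#' @return List of class `expression_layers`: matrices `bsrc`, `nrpm`,
#'   `ranks`, logical `high_expressor`, per-sample `scores` tibble, the
#'   normalization `ratios`, and `dropped` samples.
#' @export
run_expression_pipeline <- function(raw, ntc, ref, reference_nrpm,
                                    signatures) {
  bsrc <- background_subtract(raw, ntc)
  norm <- compute_nrpm(bsrc, ref)
  ranks <- rank_against_reference(norm$nrpm, reference_nrpm)
  scores <- tibble(sample_id = colnames(ranks))
  for (nm in names(signatures)) {
    scores[[tolower(nm)]] <- unname(score_signature(ranks, signatures[[nm]]))
  }
  structure(
    list(bsrc = bsrc, nrpm = norm$nrpm, ranks = ranks,
         high_expressor = call_high_expressor(ranks),
         scores = scores, ratios = norm$ratios, dropped = norm$dropped),
    class = "expression_layers"
  )
}

#' @export
print.expression_layers <- function(x, ...) {
  cat("<expression_layers>", nrow(x$nrpm), "genes x", ncol(x$nrpm),
      "samples;", nrow(x$dropped), "sample(s) dropped\n")
  invisible(x)
}
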