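#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table with rows as exposure
#' groups and columns as outcome yes/no. The two-sided p-value sums the
#' probabilities of all tables (with the observed margins) whose
#' hypergeometric probability is at most that of the observed table — the
#' common exact-test convention. Two odds-ratio estimates are returned: the
#' sample OR `(a*d)/(b*c)` (with Haldane's 0.5 continuity correction added
#' to every cell only when some cell is zero) and the conditional maximum
#' likelihood OR that maximizes the noncentral hypergeometric likelihood.
#'
#' @param a,b,c,d Cell counts: row 1 = (a, b), row 2 = (c, d); column 1 is
#'   "outcome yes". A 2x2 matrix may be passed as `a`.
#' @return One-row tibble: `p_value`, `sample_or`, `cmle_or`, `degenerate`
#'   (TRUE when a margin is zero, in which case the OR is undefined and
#'   p = 1).
#' @examples
#' fisher_exact_2x2(379, 1732, 1464, 4655)  # squamous <65 vs >=65
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    abort("cells must be non-negative integers.",
          class = "agiscreen_schema_error")
  }
  if (sum(cells) == 0) {
    abort("table total must be positive.", class = "agiscreen_schema_error")
  }
  # degenerate margins: no information, flag and return p = 1
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(tibble(p_value = 1, sample_or = NA_real_, cmle_or = NA_real_,
                  degenerate = TRUE))
  }
  m <- a + c   # column-1 total
  n <- b + d
  k <- a + b   # row-1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p_value <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))

  or_cells <- if (any(cells == 0)) cells + 0.5 else cells
  sample_or <- (or_cells[1] * or_cells[4]) / (or_cells[2] * or_cells[3])

  tibble(p_value = p_value,
         sample_or = sample_or,
         cmle_or = .cmle_or(a, m, n, k, support),
         degenerate = FALSE)
}

# Conditional MLE of the odds ratio: psi maximizing the noncentral
# hypergeometric likelihood, found by solving E[X | psi] = a on log(psi).
.cmle_or <- function(a, m, n, k, support) {
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  logw0 <- lchoose(m, support) + lchoose(n, k - support)
  cond_mean <- function(logpsi) {
    logw <- logw0 + support * logpsi
    w <- exp(logw - max(logw))
    sum(support * w) / sum(w) - a
  }
  lo <- -1; hi <- 1
  while (cond_mean(lo) > 0) lo <- lo * 2
  while (cond_mean(hi) < 0) hi <- hi * 2
  exp(uniroot(cond_mean, c(lo, hi), tol = 1e-10)$root)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns FDR-adjusted p-values in the input order: sort ascending,
#' multiply the i-th by m/i, enforce monotonicity from the largest down,
#' cap at 1. `NA`s pass through and do not count toward m.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("p-values must lie in [0, 1].", class = "agiscreen_schema_error")
  }
  out <- rep(NA_real_, length(p))
  x <- p[ok]
  m <- length(x)
  if (m > 0) {
    o <- order(x, decreasing = TRUE)
    ro <- order(o)
    out[ok] <- pmin(1, cummin(m / (m:1) * x[o]))[ro]
  }
  out
}

#' Shifted-log transform for zero-heavy non-negative measures
#'
#' `log(1 + x)` (natural log), the transform applied to TMB, CP and CTAB
#' signature scores, and nRPM expression values before linear modelling.
#'
#' @param x Non-negative numeric vector (`NA` allowed).
#' @return `log1p(x)`.
#' @export
log1p_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("log1p_transform() requires non-negative input.",
          class = "agiscreen_schema_error")
  }
  log1p(x)
}
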