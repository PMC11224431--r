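#' Gaussian linear model fit with exact log-likelihood
#'
#' Ordinary least squares via the QR decomposition, returning the Gaussian
#' log-likelihood needed by [lrt()]. Rank-deficient designs are an error
#' that names the collinear columns rather than silently dropping them.
#'
#' @param formula Model formula (the response on the left).
#' @param data Data frame; rows with missing values in the model variables
#'   are dropped with a warning.
#' @return An `agi_fit` object (family `"linear"`) with `coefficients`,
#'   `std_errors`, `loglik`, `n_obs`, `converged` and the design term
#'   labels. Supports [tidy()] and [glance()].
#' @examples
#' fit <- fit_linear(mpg ~ wt + cyl, mtcars)
#' tidy(fit)
#' @export
fit_linear <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- model.matrix(stats::terms(mf), mf)
  .check_full_rank(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    abort(sprintf("need more observations (%d) than parameters (%d).", n, p),
          class = "agiscreen_fit_error")
  }
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  # maximized Gaussian loglik (sigma^2 profiled out at RSS/n)
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  .new_agi_fit(
    coefficients = setNames(as.numeric(beta), colnames(X)),
    std_errors = setNames(se, colnames(X)),
    loglik = loglik,
    n_obs = n, family = "linear", converged = TRUE,
    terms = attr(stats::terms(mf), "term.labels"),
    extra = list(rss = rss, sigma2 = sigma2)
  )
}

#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{\ell(\beta) + \tfrac12 \log\det I(\beta)} by Newton iterations with
#' the hat-value-adjusted score
#' \eqn{U^*_j = \sum_i (y_i - p_i + h_i(\tfrac12 - p_i))\,x_{ij}}, with
#' step-halving whenever a step would decrease the penalized likelihood.
#' The penalty keeps every estimate finite even under complete separation,
#' which the screens here rely on for rare alterations. Convergence is
#' declared when the modified score's max-norm falls below `tol`.
#'
#' @param formula Model formula with a logical/0-1 response.
#' @param data Data frame.
#' @param tol Convergence tolerance on the modified score (default 1e-6).
#' @param max_iter Maximum Newton iterations (default 100).
#' @return An `agi_fit` object (family `"firth_logistic"`); `loglik` is the
#'   penalized log-likelihood. `converged` is FALSE if `max_iter` was hit.
#' @examples
#' d <- data.frame(y = c(1, 1, 1, 0, 0, 0), x = c(1, 1, 1, 0, 0, 0))
#' coef(fit_firth(y ~ x, d))  # finite despite complete separation
#' @seealso [firth_plrt()] for the penalized likelihood-ratio test.
#' @export
fit_firth <- function(formula, data, tol = 1e-6, max_iter = 100) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (!all(y %in% c(0, 1))) {
    abort("response must be binary (logical or 0/1).",
          class = "agiscreen_schema_error")
  }
  X <- model.matrix(stats::terms(mf), mf)
  .check_full_rank(X)
  fit <- firth_logistic(y, X, tol = tol, max_iter = max_iter)
  fit$terms <- attr(stats::terms(mf), "term.labels")
  fit
}

#' Low-level Firth fit on a response vector and design matrix
#'
#' With `fixed`, the listed columns' coefficients are constrained to zero
#' while the Jeffreys penalty is still computed from the full design's
#' information — the constrained fit needed by the penalized
#' likelihood-ratio test (see [firth_plrt()]).
#'
#' @param y 0/1 response vector.
#' @param X Design matrix including the intercept column.
#' @param fixed Integer indices of columns whose coefficients are fixed at
#'   zero (must not include the intercept).
#' @inheritParams fit_firth
#' @return An `agi_fit` object, as [fit_firth()]; `df_free` counts the
#'   freely estimated parameters.
#' @export
firth_logistic <- function(y, X, tol = 1e-6, max_iter = 100,
                           fixed = integer(0)) {
  X_orig <- as.matrix(X)
  n <- nrow(X_orig); k <- ncol(X_orig)
  if (length(y) != n) {
    abort("length(y) must match nrow(X).", class = "agiscreen_schema_error")
  }
  # standardize non-constant columns for Newton conditioning; the fit is
  # mapped back to the original scale below (the Jeffreys penalty shifts
  # by an additive constant under this linear reparametrization, so the
  # maximizer is unchanged)
  ctr <- colMeans(X_orig)
  scl <- apply(X_orig, 2, stats::sd)
  const_col <- !is.finite(scl) | scl == 0
  if (!any(const_col)) ctr[] <- 0   # centering needs an intercept column
  ctr[const_col] <- 0
  scl[const_col] <- 1
  X <- sweep(sweep(X_orig, 2, ctr, "-"), 2, scl, "/")
  fixed <- as.integer(fixed)
  if (any(const_col[fixed])) {
    abort("cannot constrain the intercept column.",
          class = "agiscreen_config_error")
  }
  free <- setdiff(seq_len(k), fixed)
  beta <- numeric(k)
  pl_old <- .firth_penloglik(y, X, beta)
  converged <- FALSE
  info <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * w
    info <- crossprod(X, XW)                      # X' W X
    info_chol <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(info_chol)) {
      return(.firth_failed(X, beta, info))
    }
    info_inv <- chol2inv(info_chol)
    # hat values of the weighted design: h_i = w_i x_i' (X'WX)^-1 x_i
    # (full design, even for constrained fits: the penalty is always the
    # full-model Jeffreys penalty)
    h <- rowSums((X %*% info_inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (max(abs(score[free])) < tol) {
      converged <- TRUE
      break
    }
    delta <- numeric(k)
    delta[free] <- drop(solve(info[free, free, drop = FALSE], score[free]))
    # cap the Newton step (per coordinate) to avoid overshooting into the
    # flat tails on quasi-separated designs, then step-halve
    big <- max(abs(delta))
    if (big > 5) delta <- delta * 5 / big
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      pl_new <- .firth_penloglik(y, X, beta_new)
      if (is.finite(pl_new) && pl_new >= pl_old - 1e-10) break
      step <- step / 2
      if (step < 1e-6) break
    }
    beta <- beta + step * delta
    pl_old <- .firth_penloglik(y, X, beta)
  }
  if (!converged) {
    # Newton can stall in a tiny cycle near the optimum because the
    # penalty's curvature is absent from the Hessian approximation;
    # polish with BFGS (over the free coordinates) on the exact
    # penalized likelihood and re-check
    expand <- function(bf) { b <- numeric(k); b[free] <- bf; b }
    neg_pl <- function(bf) -.firth_penloglik(y, X, expand(bf))
    full_gr <- function(b) {
      p <- stats::plogis(drop(X %*% b))
      w <- pmax(p * (1 - p), 1e-12)
      inf <- crossprod(X, X * w)
      ic <- tryCatch(chol(inf), error = function(e) NULL)
      if (is.null(ic)) return(rep(0, length(b)))
      ii <- chol2inv(ic)
      h <- rowSums((X %*% ii) * (X * w))
      drop(crossprod(X, y - p + h * (0.5 - p)))
    }
    neg_gr <- function(bf) -full_gr(expand(bf))[free]
    opt <- tryCatch(
      stats::optim(beta[free], neg_pl, neg_gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && -opt$value >= pl_old) {
      beta <- expand(opt$par)
      pl_old <- -opt$value
    }
    converged <- max(abs(full_gr(beta)[free])) < tol
  }
  # map back to the original scale; loglik and SEs are reported there
  beta_orig <- beta / scl
  shift <- sum((ctr / scl) * beta)
  if (any(const_col) && shift != 0) {
    ic <- which(const_col)[1]
    beta_orig[ic] <- beta_orig[ic] - shift / X_orig[1, ic]
  }
  p <- stats::plogis(drop(X_orig %*% beta_orig))
  w <- pmax(p * (1 - p), 1e-12)
  info_orig <- crossprod(X_orig, X_orig * w)
  se <- sqrt(pmax(diag(chol2inv(chol(info_orig))), 0))
  .new_agi_fit(
    coefficients = setNames(beta_orig, colnames(X_orig)),
    std_errors = setNames(se, colnames(X_orig)),
    loglik = .firth_penloglik(y, X_orig, beta_orig),
    n_obs = n, family = "firth_logistic", converged = converged,
    terms = colnames(X_orig)[-1] %||% character(),
    extra = list(df_free = length(free), fixed = fixed)
  )
}

#' Penalized likelihood-ratio test for a Firth logistic model
#'
#' Tests one model term by comparing the full Firth fit against the
#' constrained fit in which that term's coefficients are fixed at zero
#' while the Jeffreys penalty is still evaluated on the full design —
#' the penalized likelihood-ratio test. The statistic
#' `2 * (pl_full - pl_constrained)` (floored at 0) is referred to a
#' chi-squared distribution with df equal to the number of constrained
#' coefficients.
#'
#' @param formula Full model formula with a binary response.
#' @param data Data frame.
#' @param test Term label (as it appears in the formula) to test.
#' @inheritParams fit_firth
#' @return List: `test` (one-row tibble `statistic`, `df`, `p_value`),
#'   `full` and `null` (`agi_fit` objects).
#' @examples
#' d <- data.frame(y = rbinom(50, 1, 0.3), x = rnorm(50))
#' firth_plrt(y ~ x, d, test = "x")$test
#' @export
firth_plrt <- function(formula, data, test, tol = 1e-6, max_iter = 100) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  trm <- stats::terms(mf)
  X <- model.matrix(trm, mf)
  .check_full_rank(X)
  labels <- attr(trm, "term.labels")
  if (!test %in% labels) {
    abort(paste0("term '", test, "' is not in the model."),
          class = "agiscreen_config_error")
  }
  cols <- which(attr(X, "assign") == match(test, labels))
  full <- firth_logistic(y, X, tol = tol, max_iter = max_iter)
  null <- firth_logistic(y, X, tol = tol, max_iter = max_iter,
                         fixed = cols)
  out <- lrt(full, null)
  list(test = out, full = full, null = null)
}

.firth_penloglik <- function(y, X, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
              (1 - y) * stats::plogis(-eta, log.p = TRUE))
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(X, X * w)
  det_chol <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(det_chol)) return(-Inf)
  ll + sum(log(diag(det_chol)))   # + 1/2 log det I
}

.firth_failed <- function(X, beta, info) {
  .new_agi_fit(
    coefficients = setNames(rep(NA_real_, ncol(X)), colnames(X)),
    std_errors = setNames(rep(NA_real_, ncol(X)), colnames(X)),
    loglik = NA_real_, n_obs = nrow(X), family = "firth_logistic",
    converged = FALSE, terms = colnames(X)[-1] %||% character()
  )
}

#' Likelihood-ratio test between nested fits
#'
#' For linear fits this is the standard LRT on the maximized Gaussian
#' log-likelihoods (equivalently `n * log(RSS_null / RSS_full)`). For
#' Firth fits it is the penalized likelihood-ratio test: the null must be
#' the constrained fit of the same design (tested coefficients fixed at
#' zero, penalty from the full-model information — see [firth_plrt()],
#' which builds the pair); two independently penalized fits of different
#' designs are not comparable because their Jeffreys penalties differ by
#' a design-dependent constant. The statistic is floored at zero and
#' referred to a chi-squared distribution with df equal to the free
#' parameter difference.
#'
#' @param full,null Nested `agi_fit` objects of the same family fitted on
#'   the same observations (the null's covariates must be a subset of the
#'   full's).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, null) {
  stopifnot(inherits(full, "agi_fit"), inherits(null, "agi_fit"))
  if (full$family != null$family) {
    abort("fits must share a family.", class = "agiscreen_schema_error")
  }
  if (full$n_obs != null$n_obs) {
    abort("fits must use the same observations.",
          class = "agiscreen_schema_error")
  }
  n_par <- function(f) f$df_free %||% length(f$coefficients)
  if (full$family == "firth_logistic" &&
      (length(full$coefficients) != length(null$coefficients) ||
         length(null$fixed %||% integer(0)) == 0)) {
    abort(paste0("the Firth penalized LRT needs a constrained null fit of ",
                 "the same design; use firth_plrt()."),
          class = "agiscreen_schema_error")
  }
  df <- n_par(full) - n_par(null)
  if (df < 1) {
    abort("`full` must have more parameters than `null`.",
          class = "agiscreen_schema_error")
  }
  if (!isTRUE(full$converged) || !isTRUE(null$converged)) {
    return(tibble(statistic = NA_real_, df = df, p_value = NA_real_))
  }
  stat <- max(0, 2 * (full$loglik - null$loglik))
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

# ---- agi_fit class ---------------------------------------------------------

.new_agi_fit <- function(coefficients, std_errors, loglik, n_obs, family,
                         converged, terms, extra = list()) {
  structure(
    c(list(coefficients = coefficients, std_errors = std_errors,
           loglik = loglik, n_obs = n_obs, family = family,
           converged = converged, terms = terms), extra),
    class = "agi_fit"
  )
}

#' @export
coef.agi_fit <- function(object, ...) object$coefficients

#' @export
logLik.agi_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.agi_fit <- function(x, ...) {
  cat("<agi_fit>", x$family, "| n =", x$n_obs,
      "| loglik =", format(x$loglik, digits = 6),
      if (!x$converged) "| NOT CONVERGED", "\n")
  print(x$coefficients)
  invisible(x)
}

#' Tidy an `agi_fit`
#'
#' @param x An `agi_fit` from [fit_linear()] or [fit_firth()].
#' @param exponentiate Return `exp(estimate)` (odds ratios for logistic
#'   fits)? Default FALSE.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic` (Wald z),
#'   `p.value`.
#' @export
tidy.agi_fit <- function(x, exponentiate = FALSE, ...) {
  z <- x$coefficients / x$std_errors
  est <- if (exponentiate) exp(x$coefficients) else x$coefficients
  tibble(term = names(x$coefficients),
         estimate = unname(est),
         std.error = unname(x$std_errors),
         statistic = unname(z),
         p.value = unname(2 * stats::pnorm(-abs(z))))
}

#' One-row model summary of an `agi_fit`
#' @param x An `agi_fit`.
#' @param ... Unused.
#' @return Tibble: `family`, `logLik`, `n_obs`, `n_param`, `converged`.
#' @export
glance.agi_fit <- function(x, ...) {
  tibble(family = x$family, logLik = x$loglik, n_obs = x$n_obs,
         n_param = length(x$coefficients), converged = x$converged)
}

.check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")),
          class = "agiscreen_fit_error")
  }
  invisible(TRUE)
}
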