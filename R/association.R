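# Shared engine for the age-group and age-trend association tests used by
# both the genomic and immune screens. Every comparison is young group vs
# the >= 65 reference, adjusted for the configured covariates; the trend
# test compares a model with winsorized age against an age-null model by a
# (penalized, for Firth fits) likelihood-ratio test.

# keep only covariates that actually vary in this subset; constants carry
# no information and would make the design rank-deficient
.usable_covariates <- function(data, covariates) {
  covariates[vapply(covariates, function(cv) {
    length(unique(data[[cv]][!is.na(data[[cv]])])) >= 2
  }, logical(1))]
}

.covariate_factors <- function(data) {
  if ("histology" %in% names(data)) {
    data$histology <- factor(data$histology,
                             levels = intersect(HISTOLOGY_LEVELS,
                                                unique(data$histology)))
  }
  if ("specimen_site" %in% names(data)) {
    data$specimen_site <- factor(data$specimen_site,
                                 levels = intersect(SITE_LEVELS,
                                                    unique(data$specimen_site)))
  }
  if ("sex" %in% names(data)) {
    data$sex <- factor(data$sex, levels = intersect(SEX_LEVELS,
                                                    unique(data$sex)))
  }
  data
}

.fit_family <- function(formula, data, family) {
  if (family == "firth_logistic") fit_firth(formula, data)
  else fit_linear(formula, data)
}

# Nested test of one term: linear fits use the standard LRT on two
# nested fits; Firth fits use the penalized LRT (constrained null of the
# full design, full-model penalty) via firth_plrt().
.nested_term_test <- function(data, family, term, covariates) {
  covs <- .usable_covariates(data, covariates)
  rhs_null <- if (length(covs)) paste(covs, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste(".response ~", term, "+", rhs_null))
  if (family == "firth_logistic") {
    out <- tryCatch(firth_plrt(f_full, data, test = term),
                    error = function(e) NULL)
    if (is.null(out) || !isTRUE(out$full$converged) ||
          !isTRUE(out$null$converged)) {
      return(NULL)
    }
    list(estimate = .term_coef(coef(out$full), term), test = out$test)
  } else {
    f_null <- stats::as.formula(paste(".response ~", rhs_null))
    fit_full <- tryCatch(.fit_family(f_full, data, family),
                         error = function(e) NULL)
    fit_null <- tryCatch(.fit_family(f_null, data, family),
                         error = function(e) NULL)
    if (is.null(fit_full) || is.null(fit_null) ||
          !isTRUE(fit_full$converged) || !isTRUE(fit_null$converged)) {
      return(NULL)
    }
    list(estimate = .term_coef(coef(fit_full), term),
         test = lrt(fit_full, fit_null))
  }
}

# coefficient for a (possibly factor) term: exact name or its single dummy
.term_coef <- function(coefs, term) {
  if (term %in% names(coefs)) return(unname(coefs[term]))
  hits <- which(startsWith(names(coefs), term))
  if (length(hits) == 0) return(NA_real_)
  unname(coefs[hits[1]])
}

# One young-group-vs-reference test. `data` must hold `.response`, `age`
# and the covariates; returns estimate (log-OR or linear coefficient) and
# the (penalized) LRT p-value for the group indicator.
.test_one_group <- function(data, threshold, reference, family, covariates) {
  sub <- data[data$age >= reference | data$age < threshold, , drop = FALSE]
  sub$.young <- as.numeric(sub$age < threshold)
  n_young <- sum(sub$.young == 1)
  if (n_young == 0 || n_young == nrow(sub)) {
    return(tibble(estimate = NA_real_, p_value = NA_real_,
                  n = nrow(sub), converged = FALSE))
  }
  out <- .nested_term_test(sub, family, ".young", covariates)
  if (is.null(out)) {
    return(tibble(estimate = NA_real_, p_value = NA_real_,
                  n = nrow(sub), converged = FALSE))
  }
  tibble(estimate = out$estimate, p_value = out$test$p_value,
         n = nrow(sub), converged = TRUE)
}

# Age-trend test over the whole analyzed set: winsorized age vs age-null.
.test_trend <- function(data, family, covariates, winsor = 65) {
  data$.wage <- pmin(data$age, winsor)
  if (length(unique(data$.wage)) < 2) {
    abort("age has no variation after winsorizing; trend test undefined.",
          class = "agiscreen_fit_error")
  }
  out <- .nested_term_test(data, family, ".wage", covariates)
  if (is.null(out)) {
    return(tibble(slope = NA_real_, statistic = NA_real_,
                  p_value = NA_real_, n = nrow(data), converged = FALSE))
  }
  tibble(slope = out$estimate, statistic = out$test$statistic,
         p_value = out$test$p_value, n = nrow(data), converged = TRUE)
}

# Full association of one response column: every young group vs the
# reference plus the trend test.
.assoc_feature <- function(data, family, scheme, covariates,
                           group_tests = TRUE) {
  data <- .covariate_factors(data)
  data <- data[!is.na(data$.response), , drop = FALSE]
  keep <- stats::complete.cases(data[, covariates, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  groups <- if (group_tests) {
    map(scheme$young_thresholds, function(t) {
      .test_one_group(data, t, scheme$reference_threshold, family,
                      covariates) |>
        mutate(group = paste0("lt", t), .before = 1)
    }) |> list_rbind()
  } else {
    tibble(group = character(), estimate = numeric(), p_value = numeric(),
           n = integer(), converged = logical())
  }
  trend <- .test_trend(data, family, covariates, scheme$winsor_cap)
  list(groups = groups, trend = trend)
}
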