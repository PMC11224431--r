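#' Build survival records for one endpoint
#'
#' Reshapes a patient table into the analysis records for overall or
#' progression-free survival: complete time/event pairs only, with the
#' binary age group (<65 vs >= 65) and winsorized age attached.
#'
#' @param patients Patient tibble with `os_time`/`os_event` or
#'   `pfs_time`/`pfs_event`, `treatment`, `age`, `sex`, `histology`.
#' @param endpoint `"os"` or `"pfs"`.
#' @param winsor Age cap for the trend exposure. Default 65.
#' @return Tibble: `patient_id`, `endpoint`, `time`, `event`, `treatment`,
#'   `sex`, `histology`, `age`, `age_group` (`"lt65"`/`"ge65"`),
#'   `winsorized_age`.
#' @export
survival_records <- function(patients, endpoint = c("os", "pfs"),
                             winsor = 65) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  ok <- !is.na(patients[[tcol]]) & !is.na(patients[[ecol]])
  pts <- patients[ok, , drop = FALSE]
  if (any(pts[[tcol]] <= 0)) {
    abort("survival times must be positive.",
          class = "agiscreen_schema_error")
  }
  tibble(patient_id = pts$patient_id, endpoint = endpoint,
         time = pts[[tcol]], event = as.logical(pts[[ecol]]),
         treatment = pts$treatment, sex = pts$sex,
         histology = pts$histology, age = pts$age,
         age_group = if_else(pts$age < 65, "lt65", "ge65"),
         winsorized_age = pmin(pts$age, winsor))
}

#' Cox proportional hazards fit for an age exposure
#'
#' Fits `Surv(time, event) ~ exposure + histology` by Cox partial
#' likelihood with Efron tie handling, where the exposure is either the
#' binary young-vs-old indicator (`age_group`: <65 vs the >= 65
#' reference) or winsorized age as a quantitative trend. The hazard ratio
#' and its Wald p-value are reported.
#'
#' @param records Tibble from [survival_records()].
#' @param exposure `"age_group"` or `"age_trend"`.
#' @param covariates Adjustment covariates. Default `"histology"`;
#'   covariates constant within `records` are dropped.
#' @return One-row tibble of class: `exposure`, `coefficient`,
#'   `hazard_ratio`, `std_error`, `p_value`, `n`, `n_events`,
#'   `ties_method`. The underlying `coxph` fit is kept in the `"fit"`
#'   attribute.
#' @export
fit_cox <- function(records, exposure = c("age_group", "age_trend"),
                    covariates = "histology") {
  exposure <- match.arg(exposure)
  if (sum(records$event) < 1) {
    abort("no events in records; Cox model undefined.",
          class = "agiscreen_fit_error")
  }
  dat <- .covariate_factors(as.data.frame(records))
  dat$.exposure <- if (exposure == "age_group") {
    as.numeric(dat$age_group == "lt65")
  } else {
    dat$winsorized_age
  }
  if (length(unique(dat$.exposure)) < 2) {
    abort("exposure has no variation in these records.",
          class = "agiscreen_fit_error")
  }
  covs <- .usable_covariates(dat, covariates)
  rhs <- paste(c(".exposure", covs), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  s <- summary(fit)
  co <- s$coefficients[".exposure", , drop = TRUE]
  out <- tibble(exposure = exposure,
                coefficient = unname(co["coef"]),
                hazard_ratio = unname(co["exp(coef)"]),
                std_error = unname(co["se(coef)"]),
                p_value = unname(co["Pr(>|z|)"]),
                n = s$n, n_events = unname(s$nevent),
                ties_method = "efron")
  attr(out, "fit") <- fit
  out
}

#' Kaplan-Meier curves by group
#'
#' Product-limit survival estimate within each level of a grouping
#' column; censored subjects leave the risk set after their time.
#'
#' @param records Tibble from [survival_records()].
#' @param group Name of the grouping column. Default `"age_group"`.
#' @return Tidy tibble: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (the step function value at `time`).
#' @export
km_curve <- function(records, group = "age_group") {
  if (nrow(records) == 0) {
    abort("no records.", class = "agiscreen_schema_error")
  }
  dat <- as.data.frame(records)
  dat$.group <- factor(dat[[group]])
  fit <- survival::survfit(survival::Surv(time, event) ~ .group, data = dat)
  strata <- if (is.null(fit$strata)) {
    rep(levels(dat$.group)[1], length(fit$time))
  } else {
    rep(sub("^\\.group=", "", names(fit$strata)), fit$strata)
  }
  tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
         n_event = fit$n.event, n_censor = fit$n.censor,
         survival = fit$surv)
}

#' Full immunotherapy survival screen
#'
#' Runs the Cox analyses over the grid endpoint x treatment arm x stratum
#' (all/male/female) x exposure (binary <65 vs >= 65, and winsorized-age
#' trend), each adjusted for histology, plus a male-vs-female contrast
#' per endpoint x arm. Kaplan-Meier curves are computed for every binary
#' cell. Cells without events are flagged, not fatal.
#'
#' @param patients Patient tibble with survival fields.
#' @param endpoints Endpoints to analyze. Default both.
#' @param treatments Treatment arms. Default io_mono and io_chemo.
#' @param covariates Adjustment covariates. Default `"histology"`.
#' @return Object of class `survival_screen`: tibble `results` (one row
#'   per grid cell with HR, p, n, n_events or an `error` note), tibble
#'   `sex_contrasts`, and tibble `km` of Kaplan-Meier curves for the
#'   binary cells.
#' @export
run_survival_screen <- function(patients, endpoints = c("os", "pfs"),
                                treatments = c("io_mono", "io_chemo"),
                                covariates = "histology") {
  rows <- list(); km_rows <- list(); sex_rows <- list()
  for (ep in endpoints) {
    recs <- survival_records(patients, ep)
    for (tr in treatments) {
      arm <- filter(recs, .data$treatment == tr)
      for (st in c("all", "male", "female")) {
        sub <- switch(st, all = arm,
                      male = filter(arm, .data$sex == "male"),
                      female = filter(arm, .data$sex == "female"))
        for (exposure in c("age_group", "age_trend")) {
          res <- tryCatch(
            fit_cox(sub, exposure, covariates) |>
              mutate(error = NA_character_),
            error = function(e) {
              tibble(exposure = exposure, coefficient = NA_real_,
                     hazard_ratio = NA_real_, std_error = NA_real_,
                     p_value = NA_real_, n = nrow(sub),
                     n_events = sum(sub$event), ties_method = "efron",
                     error = conditionMessage(e))
            })
          rows[[length(rows) + 1]] <-
            bind_cols(tibble(endpoint = ep, treatment = tr, stratum = st),
                      res)
        }
        if (nrow(sub) > 0) {
          km_rows[[length(km_rows) + 1]] <-
            bind_cols(tibble(endpoint = ep, treatment = tr,
                             stratum = st)[rep(1, nrow(km_curve(sub))), ],
                      km_curve(sub))
        }
      }
      # male vs female contrast (no age term), adjusted for histology
      sex_rows[[length(sex_rows) + 1]] <- tryCatch({
        dat <- .covariate_factors(as.data.frame(arm))
        covs <- .usable_covariates(dat, covariates)
        rhs <- paste(c("sex", covs), collapse = " + ")
        fit <- survival::coxph(
          stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
          data = dat, ties = "efron")
        s <- summary(fit)$coefficients["sexmale", , drop = TRUE]
        tibble(endpoint = ep, treatment = tr,
               hazard_ratio = unname(s["exp(coef)"]),
               p_value = unname(s["Pr(>|z|)"]), n = nrow(arm),
               error = NA_character_)
      }, error = function(e) {
        tibble(endpoint = ep, treatment = tr, hazard_ratio = NA_real_,
               p_value = NA_real_, n = nrow(arm),
               error = conditionMessage(e))
      })
    }
  }
  structure(list(results = list_rbind(rows),
                 sex_contrasts = list_rbind(sex_rows),
                 km = list_rbind(km_rows)),
            class = "survival_screen")
}

#' @export
print.survival_screen <- function(x, ...) {
  cat("<survival_screen>", nrow(x$results), "Cox cells;",
      sum(!is.na(x$results$error)), "degenerate\n")
  invisible(x)
}

#' @describeIn run_survival_screen Tidy Cox grid results.
#' @param x A `survival_screen`.
#' @param ... Unused.
#' @export
tidy.survival_screen <- function(x, ...) x$results
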