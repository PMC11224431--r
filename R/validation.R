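# Reusable validation studies: closed-form checks and simulation-based
# calibration/recovery experiments for the package's statistical engine.
# These back both the test suite and the reproducibility script.

#' Exhaustive closed-form check of the Firth estimator on 2x2 designs
#'
#' For an intercept + one binary covariate, the Firth fit equals ordinary
#' logistic regression on the table with 0.5 added to every cell, so the
#' slope has the closed form `log(((a+.5)(d+.5)) / ((b+.5)(c+.5)))`.
#' Sweeps every table with cell counts up to `max_cell` (both margins
#' non-empty), including completely separated ones, and records the worst
#' absolute deviation and whether every estimate stayed finite.
#'
#' @param max_cell Largest cell count in the sweep. Default 5.
#' @param tol Optimizer tolerance passed to [firth_logistic()].
#' @return One-row tibble: `n_tables`, `max_abs_err`, `all_finite`.
#' @export
validate_firth_closed_form <- function(max_cell = 5, tol = 1e-9) {
  worst <- 0; n_tables <- 0L; all_finite <- TRUE
  for (a in 0:max_cell) for (b in 0:max_cell) {
    if (a + b == 0) next
    for (cc in 0:max_cell) for (d in 0:max_cell) {
      if (cc + d == 0) next
      y <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
      x <- c(rep(1, a + b), rep(0, cc + d))
      fit <- firth_logistic(y, cbind(1, x), tol = tol)
      expected <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)))
      n_tables <- n_tables + 1L
      all_finite <- all_finite && all(is.finite(coef(fit)))
      worst <- max(worst, abs(unname(coef(fit)[2]) - expected))
    }
  }
  tibble(n_tables = n_tables, max_abs_err = worst, all_finite = all_finite)
}

#' Type-I error of the penalized-LRT age trend test under the null
#'
#' Replicates small synthetic cohorts (demographics from the default
#' generator) with a carrier status drawn independently of age, runs the
#' winsorized-age penalized likelihood-ratio trend test adjusted for
#' specimen site and histology, and reports the rejection rate at the
#' given level.
#'
#' @param reps Number of replicate cohorts. Default 1000.
#' @param n Cohort size per replicate. Default 200.
#' @param prevalence Null carrier probability. Default 0.2.
#' @param alpha Nominal level. Default 0.05.
#' @param seed Base seed.
#' @return One-row tibble: `reps`, `rejection_rate`, `mc_se` (binomial
#'   Monte-Carlo standard error at the nominal level).
#' @export
validate_trend_calibration <- function(reps = 1000, n = 200,
                                       prevalence = 0.2, alpha = 0.05,
                                       seed = 1) {
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_patients = n, seed = seed + r)
    pts <- simulate_patients(cfg)
    set.seed(seed + 500000L + r)
    pts$.response <- rbinom(n, 1, prevalence)
    out <- .test_trend(.covariate_factors(pts), "firth_logistic",
                       c("specimen_site", "histology"))
    rej[r] <- !is.na(out$p_value) && out$p_value < alpha
  }
  tibble(reps = reps, rejection_rate = mean(rej),
         mc_se = sqrt(alpha * (1 - alpha) / reps))
}

#' Recovery of one true age-associated feature among null features
#'
#' Each replicate simulates a cohort in which one alteration has a
#' configured negative log-odds-per-year age slope (prevalence rising as
#' age falls) and 50 alterations are age-independent, runs the gene-level
#' trend screen, and checks which features are flagged at BH-adjusted
#' p < 0.25. Reports the detection rate of the true feature and the mean
#' false discovery proportion among flags.
#'
#' @param reps Number of replicate cohorts. Default 100.
#' @param n Cohort size. Default 800.
#' @param beta_age True log-odds slope per year of age. Default -0.08.
#' @param n_null Number of null features. Default 50.
#' @param seed Base seed.
#' @return One-row tibble: `reps`, `sensitivity`, `mean_fdp`.
#' @export
validate_screen_recovery <- function(reps = 100, n = 800, beta_age = -0.08,
                                     n_null = 50, seed = 1) {
  models <- bind_rows(
    tibble(gene = "TRUE1", variant_class = "snv", variant_label = "V",
           tier = NA_character_, beta0 = stats::qlogis(0.12),
           beta_age = beta_age, beta_sex = 0),
    tibble(gene = sprintf("NULL%02d", seq_len(n_null)),
           variant_class = "snv", variant_label = "V",
           tier = NA_character_, beta0 = stats::qlogis(0.10),
           beta_age = 0, beta_sex = 0))
  hit <- logical(reps); fdp <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_patients = n, seed = seed + r,
                      alteration_models = models,
                      pass_rates = c(snv = 1, cnv = 1, fusion = 1))
    pts <- simulate_patients(cfg)
    calls <- simulate_alterations(pts, models, seed = seed + 300000L + r)
    gs <- run_genomic_screen(pts, calls, strata = "all",
                             covariates = character(0),
                             group_tests = FALSE)
    tr <- gs$trend[gs$trend$level == "gene", ]
    flags <- tr$gene[tr$significant]
    hit[r] <- "TRUE1" %in% flags
    fdp[r] <- if (length(flags)) sum(flags != "TRUE1") / length(flags) else 0
  }
  tibble(reps = reps, sensitivity = mean(hit), mean_fdp = mean(fdp))
}

#' Coverage of the Cox hazard-ratio confidence interval
#'
#' Replicates exponential survival data with a true hazard ratio for the
#' <65 age group, about 20% censoring, fits the Cox model, and reports
#' how often the 95% Wald interval covers the truth.
#'
#' @param reps Number of replicates. Default 200.
#' @param n Subjects per replicate. Default 300.
#' @param true_hr True hazard ratio for the young group. Default 2.
#' @param baseline Baseline monthly hazard. Default 0.05.
#' @param censor_rate Exponential censoring rate. Default 0.015.
#' @param seed Base seed.
#' @return One-row tibble: `reps`, `coverage`, `mean_hr`.
#' @export
validate_cox_recovery <- function(reps = 200, n = 300, true_hr = 2,
                                  baseline = 0.05, censor_rate = 0.015,
                                  seed = 1) {
  covered <- logical(reps); hrs <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    young <- rbinom(n, 1, 0.4)
    t_event <- rexp(n, baseline * true_hr^young)
    t_cens <- rexp(n, censor_rate)
    rec <- tibble(
      patient_id = seq_len(n), endpoint = "os",
      time = pmin(t_event, t_cens), event = t_event <= t_cens,
      treatment = "io_mono", sex = "female",
      histology = "adenocarcinoma",
      age = ifelse(young == 1, 55, 75),
      age_group = ifelse(young == 1, "lt65", "ge65"),
      winsorized_age = ifelse(young == 1, 55, 65))
    fit <- fit_cox(rec, "age_group", covariates = character(0))
    ci <- fit$coefficient + c(-1.96, 1.96) * fit$std_error
    covered[r] <- ci[1] <= log(true_hr) && log(true_hr) <= ci[2]
    hrs[r] <- fit$hazard_ratio
  }
  tibble(reps = reps, coverage = mean(covered), mean_hr = mean(hrs))
}
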