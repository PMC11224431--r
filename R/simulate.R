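#' Simulation configuration for synthetic CGIP cohorts
#'
#' Builds the full parameter set for [simulate_cohort()]. The defaults
#' emulate the marginal structure of a large real-world NSCLC profiling
#' cohort: a two-component age mixture with about 74% of patients aged
#' >= 65 (older component 74.8 +/- 6.5 years, younger 58 +/- 6.2), a
#' near-even sex split (50.2% female), histology and specimen-site
#' frequencies that shift with age (more adenocarcinoma and more
#' metastatic/advanced specimens at younger ages), logistic-in-age
#' alteration prevalences, negative-binomial immune-gene counts with
#' stable housekeeping genes, and exponential immunotherapy survival with
#' treatment x age x sex interactions. A rank-calibration reference
#' population of 735 tumors is generated from the same expression model
#' with all age/sex effects zeroed.
#'
#' Override any component by passing a replacement list; unnamed elements
#' of the default are kept (`modifyList` semantics).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed stored with the config.
#' @param ... Named overrides for the components documented above
#'   (`age_mixture`, `p_female`, `histology`, `site`, `stage_probs`,
#'   `pass_rates`, `tmb_model`, `alteration_models`, `expression_model`,
#'   `survival_model`, `treatment_probs`, `reference_population_size`).
#' @return Object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 7)
#' cfg$age_mixture$p_old
#' @export
sim_config <- function(n_patients = 1000, seed = 1, ...) {
  cfg <- list(
    n_patients = n_patients,
    seed = seed,
    age_mixture = list(p_old = 0.74, mean_old = 74.8, sd_old = 6.5,
                       mean_young = 58, sd_young = 6.2,
                       min_age = 18, max_age = 100, split_age = 65),
    p_female = 0.502,
    # multinomial-logit utilities: intercept anchored at age 75, per-year
    # slope; first level is the baseline with utility 0
    histology = list(
      levels = HISTOLOGY_LEVELS,
      intercepts = c(0, -0.911, -4.595, -1.306),
      slopes = c(0, 0.0393, -0.0103, -0.0059),
      anchor_age = 75
    ),
    site = list(
      levels = SITE_LEVELS,
      intercepts = c(0, -1.327, -1.876),
      slopes = c(0, -0.0201, -0.0206),
      anchor_age = 75
    ),
    stage_probs = c(I = 0.038, II = 0.022, III = 0.058, IV = 0.234,
                    unknown = 0.648),
    pass_rates = c(snv = 0.872, cnv = 0.886, fusion = 0.766),
    # log-normal TMB; meanlog anchored at age 65, rising slowly with age
    tmb_model = list(meanlog = 2.0, sdlog = 0.9, age_slope = 0.010,
                     anchor_age = 65),
    alteration_models = default_alteration_models(),
    expression_model = list(
      n_genes = 397, n_housekeeping = 10,
      baseline_meanlog = log(200), baseline_sdlog = 1.0,
      libsize_sdlog = 0.3, nb_dispersion = 10,
      prop_age_genes = 0.25, age_slope = 0.012,
      prop_sex_genes = 0.30, sex_effect = -0.30,
      ntc_mean = 5,
      signature_sizes = c(TIGS = 20, CP = 10, CTAB = 15),
      anchor_age = 65
    ),
    treatment_probs = c(io_mono = 102 / 250, io_chemo = 148 / 250, none = 0),
    survival_model = list(
      # monthly baseline hazards per (endpoint, arm); log-HR terms act on
      # the linear predictor exp(b_lt65*lt65 + b_male*male + b_int*both)
      os = list(io_mono = list(baseline = 0.040, lt65 = 0.00, male = 0.10,
                               lt65_male = 0.70),
                io_chemo = list(baseline = 0.035, lt65 = -0.50, male = 0.10,
                                lt65_male = 0.50)),
      pfs = list(io_mono = list(baseline = 0.072, lt65 = 0.00, male = 0.10,
                                lt65_male = 0.70),
                 io_chemo = list(baseline = 0.063, lt65 = -0.50, male = 0.10,
                                 lt65_male = 0.50)),
      censor_rate = 0.02
    ),
    reference_population_size = 735
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) {
    abort(paste0("unknown sim_config component(s): ",
                 paste(bad, collapse = ", ")),
          class = "agiscreen_config_error")
  }
  for (nm in names(overrides)) {
    plain_list <- function(x) is.list(x) && !is.data.frame(x)
    cfg[[nm]] <- if (plain_list(cfg[[nm]]) && plain_list(overrides[[nm]])) {
      modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      overrides[[nm]]
    }
  }
  validate_sim_config(structure(cfg, class = "sim_config"))
}

#' Default logistic prevalence models for synthetic alterations
#'
#' One row per simulated variant: log-odds intercept at the anchor age of
#' 65, per-year age slope (positive = more prevalent in older patients),
#' and a log-odds shift for males. The defaults mix age-enriched,
#' age-depleted and null features across all three variant classes.
#'
#' @return Tibble with columns `gene`, `variant_class`, `variant_label`,
#'   `tier`, `beta0`, `beta_age`, `beta_sex`.
#' @export
default_alteration_models <- function() {
  tibble::tribble(
    ~gene,    ~variant_class,    ~variant_label,       ~tier, ~beta0, ~beta_age, ~beta_sex,
    "KRAS",   "snv",             "G12C",               "1",   -1.00,   0.040,     0,
    "RBM10",  "snv",             "RBM10 SNV",          "2",   -2.40,   0.080,     0,
    "EGFR",   "snv",             "E746_A750del",       "1",   -3.60,  -0.060,     0,
    "TP53",   "snv",             "TP53 SNV",           "2",    0.00,   0.000,     0,
    "CREBBP", "snv",             "CREBBP SNV",         NA,    -4.40,  -0.030,     0,
    "CDKN2A", "cnv",             "CDKN2A Loss",        "2",   -2.20,   0.000,     0,
    "FGF3",   "cnv",             "FGF3 Amplification", "2",   -3.80,  -0.030,     0.40,
    "ALK",    "fusion_skipping", "EML4-ALK Fusion",    "1",   -4.60,  -0.120,     0,
    "MET",    "fusion_skipping", "Exon 14 Skipping",   "1",   -3.20,   0.090,     0,
    "ROS1",   "fusion_skipping", "ROS1 Fusion",        "1",   -5.20,  -0.090,     0
  )
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$age_mixture$p_old, cfg$p_female, cfg$pass_rates,
             cfg$treatment_probs, cfg$stage_probs)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1].",
          class = "agiscreen_config_error")
  }
  if (cfg$n_patients < 0 || cfg$n_patients != round(cfg$n_patients)) {
    abort("n_patients must be a non-negative integer.",
          class = "agiscreen_config_error")
  }
  em <- cfg$expression_model
  if (em$nb_dispersion <= 0) {
    abort("nb_dispersion must be positive.",
          class = "agiscreen_config_error")
  }
  if (em$n_housekeeping >= em$n_genes) {
    abort("n_housekeeping must be smaller than n_genes.",
          class = "agiscreen_config_error")
  }
  if (sum(em$signature_sizes) > em$n_genes - em$n_housekeeping) {
    abort("signature sets exceed available non-housekeeping genes.",
          class = "agiscreen_config_error")
  }
  bad_class <- setdiff(cfg$alteration_models$variant_class, VARIANT_CLASSES)
  if (length(bad_class)) {
    abort(paste0("unknown variant_class in alteration_models: ",
                 paste(bad_class, collapse = ", ")),
          class = "agiscreen_config_error")
  }
  cfg
}

#' Read/write a simulation config as YAML
#'
#' @param cfg A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- sim_config(n_patients = raw$n_patients %||% 1000,
                     seed = raw$seed %||% 1)
  raw$alteration_models <- if (!is.null(raw$alteration_models)) {
    as_tibble(raw$alteration_models)
  } else {
    base$alteration_models
  }
  for (nm in intersect(names(raw), names(base))) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(raw[[nm]]) &&
                        !tibble::is_tibble(base[[nm]])) {
      modifyList(base[[nm]], raw[[nm]])
    } else {
      raw[[nm]]
    }
  }
  validate_sim_config(base)
}

# truncated-normal draw by inverse CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, plo, phi), mean, sd)
}

.softmax_sample <- function(age, model) {
  util <- vapply(seq_along(model$levels), function(j) {
    model$intercepts[j] + model$slopes[j] * (age - model$anchor_age)
  }, numeric(length(age)))
  util <- matrix(util, nrow = length(age))
  p <- exp(util - apply(util, 1, max))
  p <- p / rowSums(p)
  idx <- vapply(seq_along(age),
                function(i) sample.int(length(model$levels), 1, prob = p[i, ]),
                integer(1))
  model$levels[idx]
}

#' Simulate patient demographics and clinical covariates
#'
#' Ages are drawn from the configured two-component mixture, each
#' component truncated to its side of the 65-year split so that `p_old`
#' is exactly the probability of the >= 65 group; histology and specimen
#' site follow multinomial-logit models in age; TMB is log-normal with an
#' age trend; assay pass flags and treatment arms are independent
#' Bernoulli/multinomial draws.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return Patient tibble in the `PatientRecord` schema (survival fields
#'   `NA` until [simulate_survival()]).
#' @export
simulate_patients <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_patients
  if (n == 0) return(.empty_patients())
  am <- config$age_mixture
  old <- runif(n) < am$p_old
  age <- numeric(n)
  age[old] <- .rtruncnorm(sum(old), am$mean_old, am$sd_old,
                          am$split_age, am$max_age)
  age[!old] <- .rtruncnorm(sum(!old), am$mean_young, am$sd_young,
                           am$min_age, am$split_age - 1e-9)
  sex <- if_else(runif(n) < config$p_female, "female", "male")
  tm <- config$tmb_model
  tmb <- rlnorm(n, tm$meanlog + tm$age_slope * (age - tm$anchor_age),
                tm$sdlog)
  tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age,
    sex = sex,
    histology = .softmax_sample(age, config$histology),
    specimen_site = .softmax_sample(age, config$site),
    clinical_stage = sample(names(config$stage_probs), n, replace = TRUE,
                            prob = config$stage_probs),
    tmb = pmin(tmb, 200),       # generator never produces excluded records
    pass_snv = runif(n) < config$pass_rates[["snv"]],
    pass_cnv = runif(n) < config$pass_rates[["cnv"]],
    pass_fusion = runif(n) < config$pass_rates[["fusion"]],
    treatment = sample(names(config$treatment_probs), n, replace = TRUE,
                       prob = config$treatment_probs),
    os_time = NA_real_, os_event = NA,
    pfs_time = NA_real_, pfs_event = NA
  )
}

.empty_patients <- function() {
  tibble(patient_id = character(), age = numeric(), sex = character(),
         histology = character(), specimen_site = character(),
         clinical_stage = character(), tmb = numeric(),
         pass_snv = logical(), pass_cnv = logical(), pass_fusion = logical(),
         treatment = character(), os_time = numeric(), os_event = logical(),
         pfs_time = numeric(), pfs_event = logical())
}

#' Simulate alteration calls from logistic prevalence models
#'
#' Each model row yields an independent per-patient Bernoulli draw with
#' `logit(p) = beta0 + beta_age * (age - 65) + beta_sex * male`; a call is
#' emitted only for patients who pass the assay component matching the
#' variant class.
#'
#' @param patients Patient tibble with ages, sex and pass flags.
#' @param models Tibble as [default_alteration_models()].
#' @param seed Integer seed.
#' @return Long `AlterationCall` tibble (`patient_id`, `gene`,
#'   `variant_class`, `variant_label`, `tier`).
#' @export
simulate_alterations <- function(patients, models, seed) {
  set.seed(seed)
  if (nrow(patients) == 0 || nrow(models) == 0) {
    return(tibble(patient_id = character(), gene = character(),
                  variant_class = character(), variant_label = character(),
                  tier = character()))
  }
  bad_class <- setdiff(models$variant_class, VARIANT_CLASSES)
  if (length(bad_class)) {
    abort(paste0("unknown variant_class: ",
                 paste(bad_class, collapse = ", ")),
          class = "agiscreen_config_error")
  }
  male <- as.numeric(patients$sex == "male")
  out <- pmap(models, function(gene, variant_class, variant_label, tier,
                               beta0, beta_age, beta_sex, ...) {
    eta <- beta0 + beta_age * (patients$age - 65) + beta_sex * male
    carrier <- runif(nrow(patients)) < stats::plogis(eta)
    passing <- patients[[.pass_flag_for[[variant_class]]]]
    idx <- which(carrier & passing)
    tibble(patient_id = patients$patient_id[idx], gene = gene,
           variant_class = variant_class, variant_label = variant_label,
           tier = if (is.na(tier)) NA_character_ else as.character(tier))
  })
  list_rbind(out)
}

#' Realize per-gene expression parameters
#'
#' Draws each gene's baseline log-mean and assigns age/sex effects and
#' signature membership. Housekeeping genes always have zero age and sex
#' effects; signature sets are disjoint from the housekeeping set.
#'
#' @param model The `expression_model` component of a [sim_config()].
#' @param seed Integer seed.
#' @return Tibble: `gene`, `housekeeping`, `baseline`, `age_slope`,
#'   `sex_effect`, `signature` (`NA`, "TIGS", "CP" or "CTAB").
#' @export
realize_expression_genes <- function(model, seed) {
  set.seed(seed)
  n <- model$n_genes
  nh <- model$n_housekeeping
  genes <- c(sprintf("HK%02d", seq_len(nh)),
             sprintf("IMM%03d", seq_len(n - nh)))
  hk <- c(rep(TRUE, nh), rep(FALSE, n - nh))
  baseline <- rnorm(n, model$baseline_meanlog, model$baseline_sdlog)
  age_slope <- sex_effect <- numeric(n)
  nonhk <- which(!hk)
  n_age <- round(model$prop_age_genes * length(nonhk))
  n_sex <- round(model$prop_sex_genes * length(nonhk))
  age_slope[sample(nonhk, n_age)] <- model$age_slope
  sex_effect[sample(nonhk, n_sex)] <- model$sex_effect
  signature <- rep(NA_character_, n)
  pool <- nonhk
  for (sig in names(model$signature_sizes)) {
    pick <- pool[seq_len(model$signature_sizes[[sig]])]
    signature[pick] <- sig
    pool <- setdiff(pool, pick)
  }
  tibble(gene = genes, housekeeping = hk, baseline = baseline,
         age_slope = age_slope, sex_effect = sex_effect,
         signature = signature)
}

#' Simulate raw immune-gene counts
#'
#' Negative-binomial counts with per-sample log-normal library factors:
#' `mu_gs = exp(baseline_g + age_slope_g * (age_s - 65) + sex_effect_g *
#' male_s) * lib_s`, plus a Poisson background shared with the returned
#' no-template-control vector. Setting `zero_effects = TRUE` zeroes every
#' age/sex effect (used to build the rank-calibration reference
#' population).
#'
#' @param patients Patient tibble (only `age` and `sex` are used).
#' @param model The `expression_model` component of a [sim_config()].
#' @param genes Gene parameter tibble from [realize_expression_genes()].
#' @param seed Integer seed.
#' @param zero_effects Zero all age/sex effects?
#' @return List: `raw` (genes x samples integer matrix), `ntc` (named
#'   per-gene background counts), `lib_factors`.
#' @export
simulate_expression <- function(patients, model, genes, seed,
                                zero_effects = FALSE) {
  set.seed(seed)
  n <- nrow(patients)
  g <- nrow(genes)
  ntc <- stats::rpois(g, model$ntc_mean)
  names(ntc) <- genes$gene
  if (n == 0) {
    return(list(raw = matrix(integer(), g, 0,
                             dimnames = list(genes$gene, NULL)),
                ntc = ntc, lib_factors = numeric()))
  }
  lib <- rlnorm(n, 0, model$libsize_sdlog)
  male <- as.numeric(patients$sex == "male")
  dage <- patients$age - model$anchor_age
  a_slope <- if (zero_effects) numeric(g) else genes$age_slope
  s_eff <- if (zero_effects) numeric(g) else genes$sex_effect
  logmu <- outer(genes$baseline, rep(1, n)) +
    outer(a_slope, dage) + outer(s_eff, male)
  mu <- exp(logmu) * rep(lib, each = g)
  signal <- matrix(rnbinom(g * n, size = model$nb_dispersion, mu = mu), g, n)
  bg <- matrix(stats::rpois(g * n, rep(ntc, n)), g, n)
  raw <- signal + bg
  dimnames(raw) <- list(genes$gene, patients$patient_id %||% NULL)
  if (is.null(colnames(raw)) && n > 0) colnames(raw) <- sprintf("S%04d", 1:n)
  list(raw = raw, ntc = ntc, lib_factors = setNames(lib, colnames(raw)))
}

#' Simulate exponential survival with treatment x age x sex interactions
#'
#' Event times are exponential with rate
#' `baseline[arm] * exp(b_lt65*lt65 + b_male*male + b_int*lt65*male)` per
#' endpoint; censoring is an independent exponential with the configured
#' rate, and the recorded event indicator is "event time <= censor time".
#' Patients with treatment `"none"` keep `NA` survival fields.
#'
#' @param patients Patient tibble with `age`, `sex`, `treatment`.
#' @param model The `survival_model` component of a [sim_config()].
#' @param seed Integer seed.
#' @return `patients` with `os_time`/`os_event`/`pfs_time`/`pfs_event`
#'   filled for treated patients.
#' @export
simulate_survival <- function(patients, model, seed) {
  set.seed(seed)
  n <- nrow(patients)
  if (n == 0) return(patients)
  lt65 <- as.numeric(patients$age < 65)
  male <- as.numeric(patients$sex == "male")
  for (endpoint in c("os", "pfs")) {
    time <- rep(NA_real_, n)
    event <- rep(NA, n)
    for (arm in c("io_mono", "io_chemo")) {
      par <- model[[endpoint]][[arm]]
      if (par$baseline <= 0) {
        abort("baseline hazard must be positive.",
              class = "agiscreen_config_error")
      }
      idx <- which(patients$treatment == arm)
      if (!length(idx)) next
      rate <- par$baseline *
        exp(par$lt65 * lt65[idx] + par$male * male[idx] +
              par$lt65_male * lt65[idx] * male[idx])
      t_event <- rexp(length(idx), rate)
      t_cens <- if (model$censor_rate > 0) {
        rexp(length(idx), model$censor_rate)
      } else {
        rep(Inf, length(idx))
      }
      time[idx] <- pmin(t_event, t_cens)
      event[idx] <- t_event <= t_cens
    }
    patients[[paste0(endpoint, "_time")]] <- time
    patients[[paste0(endpoint, "_event")]] <- event
  }
  patients
}

#' Generate a complete synthetic CGIP cohort
#'
#' Composes [simulate_patients()], [simulate_alterations()],
#' [simulate_expression()] (for the cohort and for the rank-calibration
#' reference population, the latter with all effects zeroed) and
#' [simulate_survival()], all deterministically derived from one seed.
#' The generating parameters are kept in the `truth` element for
#' parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return Object of class `synthetic_cohort`: `patients`, `alterations`,
#'   `raw_counts`, `ntc`, `ref_profile`, `reference_nrpm`, `signatures`
#'   (named list of [signature_def()]), `gene_params`, `truth`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  em <- config$expression_model
  genes <- realize_expression_genes(em, seed + 11L)
  patients <- simulate_patients(config, seed)
  patients <- simulate_survival(patients, config$survival_model, seed + 17L)
  alterations <- simulate_alterations(patients, config$alteration_models,
                                      seed + 13L)
  expr <- simulate_expression(patients, em, genes, seed + 19L)

  # housekeeping profile of the external control = the true baselines
  hk <- genes$gene[genes$housekeeping]
  ref_profile <- reference_profile(
    setNames(exp(genes$baseline[genes$housekeeping]), hk))

  # reference population: same gene model, effects zeroed
  n_ref <- config$reference_population_size
  ref_patients <- tibble(patient_id = sprintf("REF%04d", seq_len(n_ref)),
                         age = rep(65, n_ref), sex = "female")
  ref_expr <- simulate_expression(ref_patients, em, genes, seed + 23L,
                                  zero_effects = TRUE)
  ref_bsrc <- background_subtract(ref_expr$raw, ref_expr$ntc)
  ref_nrpm <- compute_nrpm(ref_bsrc, ref_profile)$nrpm

  signatures <- list()
  for (sig in names(em$signature_sizes)) {
    signatures[[sig]] <- signature_def(sig,
                                       genes$gene[!is.na(genes$signature) &
                                                    genes$signature == sig])
  }

  structure(
    list(patients = patients, alterations = alterations,
         raw_counts = expr$raw, ntc = expr$ntc,
         ref_profile = ref_profile, reference_nrpm = ref_nrpm,
         signatures = signatures, gene_params = genes,
         truth = list(config = config, seed = seed,
                      lib_factors = expr$lib_factors)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$patients), "patients,",
      nrow(x$alterations), "alteration calls,",
      nrow(x$raw_counts), "genes\n")
  invisible(x)
}

#' Write a synthetic cohort's tables to a directory
#'
#' Emits `patients.tsv`, `alterations.tsv`, `counts.tsv` (genes as rows),
#' `ntc.tsv`, `reference_nrpm.tsv` and `truth.json`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$patients, file.path(dir, "patients.tsv"))
  readr::write_tsv(cohort$alterations, file.path(dir, "alterations.tsv"))
  .write_matrix_tsv(cohort$raw_counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(tibble(gene = names(cohort$ntc), count = cohort$ntc),
                   file.path(dir, "ntc.tsv"))
  .write_matrix_tsv(cohort$reference_nrpm,
                    file.path(dir, "reference_nrpm.tsv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

.write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  df <- cbind(gene = rownames(m), df)
  readr::write_tsv(as_tibble(df), path)
}
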