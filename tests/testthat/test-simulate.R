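test_that("cohort generation is deterministic and respects n = 0", {
  cfg <- sim_config(n_patients = 60, seed = 5,
                    expression_model = list(n_genes = 20, n_housekeeping = 3,
                                            signature_sizes = c(TIGS = 3,
                                                                CP = 2,
                                                                CTAB = 2)),
                    reference_population_size = 30)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$alterations, b$alterations)
  expect_identical(a$raw_counts, b$raw_counts)
  expect_identical(a$reference_nrpm, b$reference_nrpm)

  empty <- simulate_cohort(sim_config(
    n_patients = 0, seed = 1,
    expression_model = list(n_genes = 20, n_housekeeping = 3,
                            signature_sizes = c(TIGS = 3, CP = 2, CTAB = 2)),
    reference_population_size = 30))
  expect_equal(nrow(empty$patients), 0)
  expect_equal(nrow(empty$alterations), 0)
  expect_equal(ncol(empty$raw_counts), 0)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(p_female = 1.5), class = "agiscreen_config_error")
  expect_error(sim_config(n_patients = -1), class = "agiscreen_config_error")
  expect_error(sim_config(expression_model = list(nb_dispersion = 0)),
               class = "agiscreen_config_error")
  expect_error(sim_config(expression_model = list(n_genes = 5,
                                                  n_housekeeping = 10)),
               class = "agiscreen_config_error")
  expect_error(sim_config(nonsense = 1), class = "agiscreen_config_error")
})

test_that("age mixture hits the configured old fraction", {
  cfg <- sim_config(n_patients = 20000, seed = 101)
  pts <- simulate_patients(cfg)
  p_old <- mean(pts$age >= 65)
  se <- sqrt(0.74 * 0.26 / 20000)
  expect_lt(abs(p_old - 0.74), 3 * se)
  expect_true(all(pts$age >= 18 & pts$age <= 100))
  # sex split
  expect_lt(abs(mean(pts$sex == "female") - 0.502),
            3 * sqrt(0.5 * 0.5 / 20000))
})

test_that("alteration prevalence follows the logistic model", {
  cfg <- sim_config(n_patients = 10000, seed = 7, pass_rates = c(
    snv = 1, cnv = 1, fusion = 1))
  pts <- simulate_patients(cfg)
  flat <- tibble::tibble(gene = "X", variant_class = "snv",
                         variant_label = "X1", tier = NA_character_,
                         beta0 = qlogis(0.1), beta_age = 0, beta_sex = 0)
  calls <- simulate_alterations(pts, flat, seed = 8)
  prev <- length(unique(calls$patient_id)) / nrow(pts)
  expect_lt(abs(prev - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))

  # prevalence 0 -> no calls
  none <- simulate_alterations(pts, dplyr::mutate(flat, beta0 = -Inf), 8)
  expect_equal(nrow(none), 0)

  # negative age slope -> younger group more often altered
  young_enr <- simulate_alterations(
    pts, dplyr::mutate(flat, beta0 = qlogis(0.1), beta_age = -0.1), 9)
  carrier <- pts$patient_id %in% young_enr$patient_id
  p_young <- mean(carrier[pts$age < 45])
  p_old <- mean(carrier[pts$age >= 65])
  expect_gt(p_young, p_old)

  expect_error(simulate_alterations(pts, dplyr::mutate(flat,
                                                       variant_class = "indel"),
                                    8),
               class = "agiscreen_config_error")
})

test_that("calls are gated by the matching component pass flag", {
  cfg <- sim_config(n_patients = 2000, seed = 12,
                    pass_rates = c(snv = 0.5, cnv = 1, fusion = 0))
  pts <- simulate_patients(cfg)
  models <- tibble::tibble(gene = c("A", "B"),
                           variant_class = c("snv", "fusion_skipping"),
                           variant_label = c("A1", "B1"),
                           tier = NA_character_,
                           beta0 = qlogis(0.9), beta_age = 0, beta_sex = 0)
  calls <- simulate_alterations(pts, models, 13)
  expect_true(all(calls$patient_id %in%
                    pts$patient_id[pts$pass_snv | pts$pass_fusion]))
  expect_equal(sum(calls$variant_class == "fusion_skipping"), 0)
  snv_callers <- calls$patient_id[calls$variant_class == "snv"]
  expect_true(all(pts$pass_snv[match(snv_callers, pts$patient_id)]))
})

test_that("expression model: null effects balance sexes, library scales counts", {
  em <- sim_config()$expression_model
  em$n_genes <- 30; em$n_housekeeping <- 4
  em$signature_sizes <- c(TIGS = 4, CP = 3, CTAB = 3)
  em$prop_age_genes <- 0; em$prop_sex_genes <- 0
  genes <- realize_expression_genes(em, 31)
  expect_true(all(genes$age_slope[genes$housekeeping] == 0))
  expect_true(all(is.na(genes$signature[genes$housekeeping])))

  pts <- tibble::tibble(patient_id = sprintf("q%d", 1:800),
                        age = runif(800, 40, 90),
                        sex = rep(c("male", "female"), 400))
  expr <- simulate_expression(pts, em, genes, 32)
  # with zero effects, per-gene means match across sexes (t-test)
  male <- pts$sex == "male"
  pvals <- vapply(1:5, function(i) {
    stats::t.test(expr$raw[i, male], expr$raw[i, !male])$p.value
  }, numeric(1))
  expect_gt(min(pvals), 0.001)

  # library factor scales expected counts: per-sample totals track it
  cors <- cor(log(expr$lib_factors), log(colSums(expr$raw)))
  expect_gt(cors, 0.8)
})

test_that("survival generator matches exponential theory", {
  cfg <- sim_config(n_patients = 8000, seed = 14,
                    treatment_probs = c(io_mono = 1, io_chemo = 0, none = 0))
  cfg$survival_model$os$io_mono[c("lt65", "male", "lt65_male")] <- list(0, 0, 0)
  cfg$survival_model$censor_rate <- 0
  pts <- simulate_patients(cfg)
  pts <- simulate_survival(pts, cfg$survival_model, 15)
  # no censoring: all events, median = ln 2 / h
  expect_true(all(pts$os_event))
  h <- cfg$survival_model$os$io_mono$baseline
  expect_equal(median(pts$os_time), log(2) / h, tolerance = 0.08)

  # with censoring: event fraction h / (h + c)
  cfg$survival_model$censor_rate <- 0.04
  pts2 <- simulate_survival(simulate_patients(cfg), cfg$survival_model, 16)
  expect_lt(abs(mean(pts2$os_event) - h / (h + 0.04)),
            3 * sqrt(0.5^2 / 8000) + 0.01)

  expect_error({
    bad <- cfg$survival_model; bad$os$io_mono$baseline <- 0
    simulate_survival(pts, bad, 17)
  }, class = "agiscreen_config_error")
})

test_that("a configured Cox log-HR is recovered downstream", {
  cfg <- sim_config(n_patients = 4000, seed = 18,
                    treatment_probs = c(io_mono = 1, io_chemo = 0, none = 0))
  cfg$survival_model$os$io_mono[c("lt65", "male", "lt65_male")] <-
    list(log(2), 0, 0)
  pts <- simulate_survival(simulate_patients(cfg), cfg$survival_model, 19)
  res <- fit_cox(survival_records(pts, "os"), "age_group")
  ci <- exp(res$coefficient + c(-1.96, 1.96) * res$std_error)
  expect_true(ci[1] <= 2 && 2 <= ci[2])
})

test_that("null cohorts give calibrated trend p-values", {
  # Kolmogorov-Smirnov uniformity of the penalized-LRT trend p under the
  # global null, over replicated small cohorts
  set.seed(20)
  reps <- 60
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 120
    age <- runif(n, 35, 90)
    y <- rbinom(n, 1, 0.25)
    d <- data.frame(.response = y, age = age)
    out <- agiscreen:::.test_trend(d, "firth_logistic", character(0))
    pvals[r] <- out$p_value
  }
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("config YAML round-trips", {
  cfg <- sim_config(n_patients = 77, seed = 4, p_female = 0.6)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_patients, 77)
  expect_equal(back$p_female, 0.6)
  expect_equal(back$age_mixture, cfg$age_mixture)
  expect_equal(as.data.frame(back$alteration_models),
               as.data.frame(cfg$alteration_models))
})
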