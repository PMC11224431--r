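test_that("transform routing matches the declared table exactly", {
  tab <- immune_feature_table()
  want <- tibble::tribble(
    ~feature,         ~scale,     ~family,
    "tmb",            "log1p",    "linear",
    "tigs",           "identity", "linear",
    "cp",             "log1p",    "linear",
    "ctab",           "log1p",    "linear",
    "gene_nrpm",      "log1p",    "linear",
    "high_expressor", "identity", "firth_logistic"
  )
  expect_equal(as.data.frame(tab), as.data.frame(want))
  # any unknown feature routes as gene nRPM
  expect_equal(agiscreen:::.route_feature("IMM042")$scale, "log1p")
})

test_that("tigs is modelled untransformed while ctab is log-transformed", {
  set.seed(50)
  n <- 400
  pts <- tibble::tibble(
    patient_id = sprintf("p%d", 1:n),
    age = runif(n, 40, 90),
    sex = sample(c("male", "female"), n, TRUE),
    tigs = runif(n, 1, 100),
    ctab = rexp(n, 0.01)
  )
  # same fixture; the identity-scale fit must equal a manual fit on raw
  # values, the log1p fit a manual fit on log1p values
  out_tigs <- test_immune_feature(pts, "tigs", covariates = character(0),
                                  group_tests = FALSE)
  man <- agiscreen:::.test_trend(
    within(as.data.frame(pts), .response <- tigs), "linear", character(0))
  expect_equal(out_tigs$trend$slope, man$slope, tolerance = 1e-12)

  out_ctab <- test_immune_feature(pts, "ctab", covariates = character(0),
                                  group_tests = FALSE)
  man2 <- agiscreen:::.test_trend(
    within(as.data.frame(pts), .response <- log1p(ctab)), "linear",
    character(0))
  expect_equal(out_ctab$trend$slope, man2$slope, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out_ctab$trend$slope, man$slope)))
})

test_that("a constant feature is rejected", {
  pts <- tibble::tibble(patient_id = c("a", "b"), age = c(50, 70),
                        tigs = c(10, 10))
  expect_error(test_immune_feature(pts, "tigs"),
               class = "agiscreen_fit_error")
})

test_that("volcano fold change is the exponent of the mean coefficient", {
  expect_equal(compute_volcano_foldchange(rep(log(2), 5))$fold_change, 2)
  expect_equal(compute_volcano_foldchange(rep(0, 5))$fold_change, 1)
  out <- compute_volcano_foldchange(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(out$fold_change, exp(0.3))
  expect_equal(out$direction, "younger_enriched")
  expect_equal(compute_volcano_foldchange(c(-0.5, -0.1))$direction,
               "older_enriched")
  expect_true(is.na(compute_volcano_foldchange(NA_real_)$fold_change))
})

test_that("DE screen recovers a configured expression-age trend", {
  ch <- small_cohort(n = 600, seed = 55,
                     expression_model = list(
                       n_genes = 30, n_housekeeping = 4,
                       signature_sizes = c(TIGS = 4, CP = 3, CTAB = 3),
                       prop_age_genes = 0.3, age_slope = 0.02))
  pts <- apply_exclusions(ch$patients)
  bsrc <- background_subtract(ch$raw_counts, ch$ntc)
  nrpm <- compute_nrpm(bsrc, ch$ref_profile)$nrpm
  de <- run_de_screen(pts, nrpm, strata = "all",
                      covariates = character(0), group_tests = FALSE)
  res <- dplyr::left_join(de$results,
                          ch$gene_params[, c("gene", "age_slope")],
                          by = "gene")
  true_pos <- res$age_slope > 0 & !res$gene %in%
    ch$gene_params$gene[ch$gene_params$housekeeping]
  # most truly age-affected genes flagged; positive slope recovered
  expect_gt(mean(res$significant[true_pos]), 0.6)
  expect_gt(mean(res$trend_slope[true_pos] > 0), 0.9)
  # determinism
  de2 <- run_de_screen(pts, nrpm, strata = "all",
                       covariates = character(0), group_tests = FALSE)
  expect_identical(de$results, de2$results)
})

test_that("high-expressor screen excludes degenerate markers", {
  ch <- small_cohort(n = 150, seed = 66)
  pts <- apply_exclusions(ch$patients)
  pipe <- run_expression_pipeline(ch$raw_counts, ch$ntc, ch$ref_profile,
                                  ch$reference_nrpm, ch$signatures)
  ranks <- pipe$ranks
  # force one marker to have no high expressors
  ranks["IMM001", ] <- 10
  out <- run_high_expressor_screen(pts, ranks,
                                   markers = c("IMM001", "IMM002", "IMM003"),
                                   covariates = character(0))
  expect_true("IMM001" %in% out$excluded$gene)
  expect_false("IMM001" %in% out$results$gene)
  expect_true(all(c("IMM002", "IMM003") %in% out$results$gene))
})

test_that("sex contrast flips sign under relabeling and needs both sexes", {
  set.seed(60)
  n <- 300
  pts <- tibble::tibble(
    patient_id = sprintf("p%d", 1:n),
    age = runif(n, 40, 90),
    sex = rep(c("male", "female"), n / 2),
    tigs = rnorm(n, 50, 10) + 5 * (rep(c(1, 0), n / 2))
  )
  out <- sex_contrast(pts, "tigs", covariates = character(0))
  flipped <- pts
  flipped$sex <- ifelse(pts$sex == "male", "female", "male")
  out2 <- sex_contrast(flipped, "tigs", covariates = character(0))
  expect_equal(out$estimate, -out2$estimate, tolerance = 1e-10)
  expect_equal(out$p_value, out2$p_value, tolerance = 1e-10)
  expect_gt(out$estimate, 0)   # males constructed higher

  single <- pts[pts$sex == "male", ]
  expect_error(sex_contrast(single, "tigs"),
               class = "agiscreen_schema_error")
})

test_that("driver covariate warns when constant and attaches carriers", {
  pts <- toy_patients()
  calls <- toy_calls()
  out <- add_driver_covariate(pts, calls)
  expect_equal(out$driver,
               as.numeric(pts$patient_id %in% c("p1", "p2", "p4")))
  expect_warning(add_driver_covariate(pts, calls[0, ]), "constant")
})

test_that("driver adjustment attenuates a driver-mediated age effect", {
  set.seed(70)
  n <- 800
  age <- runif(n, 40, 90)
  driver <- rbinom(n, 1, plogis(3 - 0.08 * age))   # young-enriched driver
  expr <- rnorm(n, 5 + 2 * driver, 1)              # effect only via driver
  pts <- tibble::tibble(patient_id = sprintf("p%d", 1:n), age = age,
                        sex = "female", g = expr, driver = driver)
  primary <- test_immune_feature(pts, "g", covariates = character(0),
                                 group_tests = FALSE)
  adjusted <- test_immune_feature(pts, "g", covariates = "driver",
                                  group_tests = FALSE)
  expect_lt(abs(adjusted$trend$slope), abs(primary$trend$slope))
  expect_gt(adjusted$trend$p_value, primary$trend$p_value)
})
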