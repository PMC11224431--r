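test_that("Kaplan-Meier matches hand product-limit computations", {
  # n = 4, one event at t = 1: S(1) = 3/4
  rec <- tibble::tibble(patient_id = 1:4, endpoint = "os",
                        time = c(1, 2, 3, 4),
                        event = c(TRUE, FALSE, FALSE, FALSE),
                        treatment = "io_mono", sex = "male",
                        histology = "adenocarcinoma", age = 70,
                        age_group = "ge65", winsorized_age = 65)
  km <- km_curve(rec)
  expect_equal(km$survival[km$time == 1], 0.75)

  # all censored -> S stays 1
  rec2 <- dplyr::mutate(rec, event = FALSE)
  expect_true(all(km_curve(rec2)$survival == 1))

  # textbook 10-subject table vs independent tally
  times <- c(1, 2, 2, 4, 5, 5, 7, 8, 9, 10)
  event <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  rec3 <- tibble::tibble(patient_id = 1:10, endpoint = "os", time = times,
                         event = event, treatment = "io_mono", sex = "male",
                         histology = "adenocarcinoma", age = 70,
                         age_group = "ge65", winsorized_age = 65)
  km3 <- km_curve(rec3)
  # hand product-limit: at each distinct event time multiply (1 - d/n)
  s <- 1; at_risk <- 10; hand <- c()
  for (t in sort(unique(times))) {
    d <- sum(times == t & event)
    if (d > 0) s <- s * (1 - d / at_risk)
    hand <- c(hand, s)
    at_risk <- at_risk - sum(times == t)
  }
  expect_equal(km3$survival[match(sort(unique(times)), km3$time)], hand)
})

test_that("Cox fit is symmetric, stationary, and scale-equivariant", {
  # identical event structure in both groups -> HR 1
  rec <- tibble::tibble(
    patient_id = 1:8, endpoint = "os",
    time = rep(c(2, 4, 6, 8), 2),
    event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
    treatment = "io_mono", sex = "male", histology = "adenocarcinoma",
    age = rep(c(50, 70), each = 4),
    age_group = rep(c("lt65", "ge65"), each = 4),
    winsorized_age = rep(c(50, 65), each = 4))
  res <- fit_cox(rec, "age_group", covariates = character(0))
  expect_equal(res$hazard_ratio, 1, tolerance = 1e-8)
  expect_equal(res$ties_method, "efron")

  # score stationarity at the optimum
  fit <- attr(res, "fit")
  score <- colSums(as.matrix(survival::coxph.detail(fit)$score))
  expect_lt(max(abs(score)), 1e-6)

  # multiplying all times by a constant leaves HR and p unchanged
  set.seed(80)
  rec2 <- tibble::tibble(
    patient_id = 1:60, endpoint = "os",
    time = rexp(60, 0.1), event = rbinom(60, 1, 0.8) == 1,
    treatment = "io_mono", sex = "male", histology = "adenocarcinoma",
    age = runif(60, 40, 90)) |>
    dplyr::mutate(age_group = ifelse(age < 65, "lt65", "ge65"),
                  winsorized_age = pmin(age, 65))
  a <- fit_cox(rec2, "age_group", covariates = character(0))
  b <- fit_cox(dplyr::mutate(rec2, time = time * 12), "age_group",
               covariates = character(0))
  expect_equal(a$hazard_ratio, b$hazard_ratio, tolerance = 1e-10)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-10)
})

test_that("Cox coefficient matches a grid-maximized Efron partial likelihood", {
  # 8 records with one tied event time
  time <- c(2, 2, 3, 4, 5, 6, 7, 8)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  # independent Efron partial loglik
  efron_pl <- function(beta) {
    ll <- 0
    for (t in unique(time[event])) {
      dead <- which(time == t & event)
      risk <- which(time >= t)
      d <- length(dead)
      s_risk <- sum(exp(beta * x[risk]))
      s_dead <- sum(exp(beta * x[dead]))
      ll <- ll + beta * sum(x[dead])
      for (l in seq_len(d) - 1) {
        ll <- ll - log(s_risk - (l / d) * s_dead)
      }
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_oracle <- grid[which.max(vapply(grid, efron_pl, numeric(1)))]
  rec <- tibble::tibble(patient_id = 1:8, endpoint = "os", time = time,
                        event = event, treatment = "io_mono", sex = "male",
                        histology = "adenocarcinoma", age = 70,
                        age_group = ifelse(x == 1, "lt65", "ge65"),
                        winsorized_age = 65)
  res <- fit_cox(rec, "age_group", covariates = character(0))
  expect_equal(res$coefficient, beta_oracle, tolerance = 1e-4)
})

test_that("degenerate Cox inputs raise explicit errors", {
  rec <- tibble::tibble(patient_id = 1:4, endpoint = "os",
                        time = 1:4, event = FALSE, treatment = "io_mono",
                        sex = "male", histology = "adenocarcinoma",
                        age = c(50, 55, 70, 75),
                        age_group = c("lt65", "lt65", "ge65", "ge65"),
                        winsorized_age = c(50, 55, 65, 65))
  expect_error(fit_cox(rec, "age_group"), class = "agiscreen_fit_error")
  rec$event <- TRUE
  rec$age_group <- "ge65"
  expect_error(fit_cox(rec, "age_group"), class = "agiscreen_fit_error")
})

test_that("survival records keep only endpoint-complete rows", {
  pts <- toy_patients()
  pts$os_time[2] <- NA
  rec <- survival_records(pts, "os")
  expect_equal(nrow(rec), 5)
  expect_true(all(rec$time > 0))
  expect_equal(rec$age_group, ifelse(rec$age < 65, "lt65", "ge65"))
  pts$os_time[1] <- -1
  expect_error(survival_records(pts, "os"), class = "agiscreen_schema_error")
})

test_that("the survival screen covers the grid and flags empty cells", {
  cfg <- sim_config(n_patients = 600, seed = 90)
  pts <- simulate_survival(simulate_patients(cfg), cfg$survival_model, 91)
  scr <- run_survival_screen(pts)
  expect_equal(nrow(scr$results), 2 * 2 * 3 * 2)  # endpoint x arm x stratum x exposure
  expect_true(all(c("os", "pfs") %in% scr$results$endpoint))
  expect_equal(nrow(scr$sex_contrasts), 4)
  # deterministic rerun
  scr2 <- run_survival_screen(pts)
  expect_identical(scr$results, scr2$results)
  # km curves present for binary cells
  expect_true(all(c("lt65", "ge65") %in% scr$km$group))

  # the constructed io_mono young-male excess hazard is visible
  big_cfg <- sim_config(n_patients = 4000, seed = 92)
  big <- simulate_survival(simulate_patients(big_cfg),
                           big_cfg$survival_model, 93)
  scr3 <- run_survival_screen(big)
  cell <- scr3$results[scr3$results$endpoint == "os" &
                         scr3$results$treatment == "io_mono" &
                         scr3$results$stratum == "male" &
                         scr3$results$exposure == "age_group", ]
  expect_gt(cell$hazard_ratio, 1.3)
  expect_lt(cell$p_value, 0.05)
})
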