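test_that("background subtraction floors at zero and matches the oracle", {
  m <- matrix(c(5, 10, 0, 3, 8, 2), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ntc <- c(g1 = 7, g2 = 1, g3 = 0)
  out <- background_subtract(m, ntc)
  # elementwise oracle
  for (g in rownames(m)) for (s in colnames(m)) {
    expect_equal(out[g, s], max(m[g, s] - ntc[[g]], 0))
  }
  expect_equal(out["g1", "s1"], 0)          # 5 - 7 floored
  # zero ntc is the identity
  expect_equal(background_subtract(m, c(g1 = 0, g2 = 0, g3 = 0)), m)
  expect_error(background_subtract(m, c(g1 = 1, g2 = 1)),
               class = "agiscreen_schema_error")
})

test_that("median-ratio normalization follows the stated formula", {
  ref <- reference_profile(c(h1 = 5, h2 = 10, h3 = 2))
  bsrc <- matrix(c(10, 20, 8, 5, 10, 2), nrow = 6,
                 dimnames = list(c("h1", "h2", "h3", "g1", "g2", "g3"),
                                 "s1"))
  # ratios: 10/5=2, 20/10=2, 8/2=4 -> median 2
  out <- compute_nrpm(bsrc, ref)
  expect_equal(unname(out$ratios["s1"]), 2)
  expect_equal(out$nrpm["g1", "s1"], 2.5)   # 5 / 2
  expect_equal(out$nrpm["g2", "s1"], 5)     # 10 / 2

  # housekeeping equal to the reference profile -> ratio 1, nRPM = BSRC
  b2 <- bsrc; b2[c("h1", "h2", "h3"), 1] <- c(5, 10, 2)
  out2 <- compute_nrpm(b2, ref)
  expect_equal(unname(out2$ratios["s1"]), 1)
  expect_equal(out2$nrpm, b2)
})

test_that("nRPM is invariant to rescaling a sample's counts", {
  set.seed(7)
  genes <- c(paste0("h", 1:4), paste0("g", 1:6))
  ref <- reference_profile(setNames(runif(4, 1, 20), paste0("h", 1:4)))
  bsrc <- matrix(rpois(30, 40), nrow = 10, dimnames = list(genes, c("a", "b", "c")))
  for (k in c(0.1, 10, 3.7)) {
    scaled <- bsrc; scaled[, "b"] <- k * bsrc[, "b"]
    expect_equal(compute_nrpm(scaled, ref)$nrpm[, "b"],
                 compute_nrpm(bsrc, ref)$nrpm[, "b"], tolerance = 1e-12)
  }
})

test_that("samples with zero housekeeping signal are dropped with a log", {
  ref <- reference_profile(c(h1 = 5, h2 = 10))
  bsrc <- matrix(c(10, 20, 5, 0, 0, 9), nrow = 3,
                 dimnames = list(c("h1", "h2", "g1"), c("ok", "dead")))
  expect_warning(out <- compute_nrpm(bsrc, ref), "zero housekeeping")
  expect_equal(colnames(out$nrpm), "ok")
  expect_equal(out$dropped$sample_id, "dead")
})

test_that("percentile rank uses the mid-rank convention with clamping", {
  ref <- c(10, 20, 30, 40)
  expect_equal(percentile_rank(25, ref), 50)
  expect_equal(percentile_rank(1000, ref), 100)  # above all -> clamp 100
  expect_equal(percentile_rank(-5, ref), 1)      # below all -> clamp 1
  expect_equal(percentile_rank(20, ref), 100 * (1 + 0.5) / 4)  # tie mid-rank
  expect_error(percentile_rank(5, numeric(0)),
               class = "agiscreen_config_error")
})

test_that("ranks match brute force and are monotone", {
  set.seed(8)
  for (rep in 1:5) {
    ref <- sample(0:50, 9, replace = TRUE)
    vals <- sort(c(sample(0:50, 8, replace = TRUE), ref[1]))
    got <- percentile_rank(vals, ref)
    want <- vapply(vals, brute_percentile, numeric(1), ref = ref)
    expect_equal(got, want)
    expect_true(all(diff(got) >= 0))   # monotone in the value
  }
  # matrix path vs brute force on a small matrix
  nr <- matrix(runif(20, 0, 100), 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  refm <- matrix(runif(24, 0, 100), 4,
                 dimnames = list(paste0("g", 1:4), paste0("r", 1:6)))
  rk <- rank_against_reference(nr, refm)
  for (g in rownames(nr)) for (s in colnames(nr)) {
    expect_equal(rk[g, s], brute_percentile(nr[g, s], refm[g, ]))
  }
})

test_that("high-expressor threshold is inclusive at 75", {
  expect_true(call_high_expressor(75))
  expect_false(call_high_expressor(74.9))
  expect_true(call_high_expressor(100))
})

test_that("signature scoring averages or sums ranks and checks genes", {
  ranks <- matrix(c(50, 60, 70, 10, 20, 90), nrow = 6,
                  dimnames = list(paste0("g", 1:6), "s1"))
  tigs <- signature_def("TIGS", c("g1", "g2", "g3"))
  ctab <- signature_def("CTAB", c("g1", "g2", "g3"))
  expect_equal(unname(score_signature(ranks, tigs)), 60)   # mean
  expect_equal(unname(score_signature(ranks, ctab)), 180)  # sum
  # CTAB lower bound: all ranks 1
  ones <- matrix(1, nrow = 6, dimnames = dimnames(ranks))
  expect_equal(unname(score_signature(ones, ctab)), 3)
  # missing gene errors by name
  bad <- signature_def("CP", c("g1", "nope"))
  err <- expect_error(score_signature(ranks, bad),
                      class = "agiscreen_schema_error")
  expect_match(conditionMessage(err), "nope")
  # mode is forced by signature name
  expect_equal(signature_def("TIGS", "g1", mode = "sum")$mode, "mean")
})

test_that("signature scores respect their theoretical bounds", {
  set.seed(9)
  ranks <- matrix(runif(60, 1, 100), nrow = 10,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  mean_sig <- signature_def("TIGS", paste0("g", 1:4))
  sum_sig <- signature_def("CTAB", paste0("g", 5:9))
  ms <- score_signature(ranks, mean_sig)
  ss <- score_signature(ranks, sum_sig)
  expect_true(all(ms >= 1 & ms <= 100))
  expect_true(all(ss >= 5 & ss <= 500))
})

test_that("the full expression pipeline composes the stages", {
  ch <- small_cohort(n = 50, seed = 21)
  out <- run_expression_pipeline(ch$raw_counts, ch$ntc, ch$ref_profile,
                                 ch$reference_nrpm, ch$signatures)
  expect_s3_class(out, "expression_layers")
  expect_true(all(out$ranks >= 1 & out$ranks <= 100))
  expect_equal(out$high_expressor, out$ranks >= 75)
  expect_named(out$scores, c("sample_id", "tigs", "cp", "ctab"))
  expect_true(all(out$scores$tigs >= 1 & out$scores$tigs <= 100))
})
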