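# Small in-code fixtures shared across test files.

toy_patients <- function() {
  tibble::tibble(
    patient_id = sprintf("p%d", 1:6),
    age = c(70, 50, 80, 44, 66, 58),
    sex = c("male", "female", "female", "male", "male", "female"),
    histology = c("adenocarcinoma", "squamous", "adenocarcinoma",
                  "other_nos", "squamous", "adenocarcinoma"),
    specimen_site = c("primary", "metastatic", "primary", "advanced",
                      "primary", "primary"),
    clinical_stage = c("IV", "III", "unknown", "IV", "I", "II"),
    tmb = c(10, 5, 80, 12, 3, 7),
    pass_snv = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    pass_cnv = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    pass_fusion = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    treatment = c("io_mono", "io_chemo", "io_mono", "io_chemo",
                  "io_mono", "io_chemo"),
    os_time = c(12, 20, 8, 30, 5, 16),
    os_event = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    pfs_time = c(6, 12, 4, 18, 3, 9),
    pfs_event = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
}

toy_calls <- function() {
  tibble::tribble(
    ~patient_id, ~gene,  ~variant_class,    ~variant_label,  ~tier,
    "p1",        "EGFR", "snv",             "E746_A750del",  "1",
    "p1",        "EGFR", "snv",             "A750P",         "2",
    "p2",        "ALK",  "fusion_skipping", "EML4-ALK",      "1",
    "p4",        "EGFR", "snv",             "E746_A750del",  "1",
    "p6",        "KRAS", "snv",             "G12C",          "1"
  )
}

# fast tiny cohort for integration-style tests
small_cohort <- function(n = 300, seed = 11, ...) {
  cfg <- sim_config(
    n_patients = n, seed = seed,
    expression_model = list(n_genes = 40, n_housekeeping = 4,
                            signature_sizes = c(TIGS = 6, CP = 4, CTAB = 5)),
    reference_population_size = 80, ...)
  simulate_cohort(cfg)
}

# brute-force mid-rank percentile, independent of the implementation
brute_percentile <- function(v, ref) {
  r <- 100 * (sum(ref < v) + 0.5 * sum(ref == v)) / length(ref)
  min(max(r, 1), 100)
}

# grid maximization of the Firth penalized log-likelihood for a design
# with intercept + one binary covariate (independent oracle)
grid_firth_1bin <- function(y, x, b0_range = c(-6, 6), b1_range = c(-10, 10),
                            n_grid = 241) {
  X <- cbind(1, x)
  pen <- function(b0, b1) {
    eta <- b0 + b1 * x
    p <- stats::plogis(eta)
    ll <- sum(y * log(p) + (1 - y) * log(1 - p))
    w <- p * (1 - p)
    i11 <- sum(w); i12 <- sum(w * x); i22 <- sum(w * x^2)
    det <- i11 * i22 - i12^2
    if (det <= 0) return(-Inf)
    ll + 0.5 * log(det)
  }
  b0s <- seq(b0_range[1], b0_range[2], length.out = n_grid)
  b1s <- seq(b1_range[1], b1_range[2], length.out = n_grid)
  vals <- outer(b0s, b1s, Vectorize(pen))
  idx <- arrayInd(which.max(vals), dim(vals))
  list(b0 = b0s[idx[1]], b1 = b1s[idx[2]], value = max(vals))
}
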