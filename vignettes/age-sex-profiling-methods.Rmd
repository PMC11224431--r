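---
title: "Methods: age- and sex-stratified genomic and immune profiling screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age- and sex-stratified genomic and immune profiling screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agiscreen)
```

## The problem

Large real-world comprehensive genomic and immune profiling (CGIP) cohorts
of non-small cell lung cancer (NSCLC) make it possible to ask whether the
tumors of younger patients differ systematically from those of older
patients — in which genes are altered, in how immunologically active the
tumor microenvironment is, and in how patients respond to immunotherapy.
`agiscreen` implements that analysis as a reusable pipeline:

1. **Cohort construction** — exclusion rules, a sliding age-threshold
   grouping, and per-assay-component denominators.
2. **Expression processing** — background subtraction, housekeeping
   median-ratio normalization, percentile ranking against a reference
   population, high-expressor calls, and the TIGS/CP/CTAB signature
   scores.
3. **Association screens** — Firth penalized logistic regression (binary
   features) and Gaussian linear models (quantitative features), with a
   penalized likelihood-ratio *trend* test on winsorized age,
   Benjamini–Hochberg control across features.
4. **Survival analysis** — Cox proportional hazards and Kaplan–Meier
   curves over an endpoint × treatment × sex × age-exposure grid.
5. **A synthetic cohort generator** that emulates the joint structure of
   such data, so every stage is testable without access to patient-level
   records.

## Age groups and the trend test

Patients aged ≥ 65 years form the reference ("older") group. Younger
patients are grouped by a sliding threshold: `<65, <60, <55, <50, <45`
years. Membership is *nested* — a 50-year-old belongs to the `<65`,
`<60` and `<55` groups. Group comparisons therefore reuse patients across
groups, and each group is always tested against the same ≥ 65 reference
(the model subset is that group plus the reference, never other young
groups). Boundaries are strict: age 65 is reference, ages use `<` for
group membership.

For the trend test, age enters as a quantitative covariate with every
value at or above 65 collapsed to 65 ("winsorized age"), so that the
test asks whether the feature changes across the younger range without
being driven by variation inside the reference group. Each patient is a
single data point in the trend test. Both tests adjust for tumor
specimen site (primary / advanced / metastatic) and histology
(adenocarcinoma reference), because both vary with age in cohorts like
this and would otherwise confound the comparisons.

## Firth regression and the penalized likelihood-ratio test

Many screened alterations are rare (a handful of carriers among
thousands), and rare binary outcomes regularly produce separated or
quasi-separated designs in subgroup models, where ordinary maximum
likelihood diverges. The package therefore fits logistic models by
Firth's penalized likelihood,
$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log \det I(\beta)$,
whose Jeffreys-prior penalty keeps every estimate finite. The
implementation is Newton iteration with the hat-adjusted score
$U^*_j = \sum_i (y_i - p_i + h_i(\tfrac12 - p_i)) x_{ij}$, step-halving
whenever a step would reduce $\ell^*$, and a per-iteration step cap.

Two numerical choices matter and are pinned by tests:

* **Column standardization.** Non-constant design columns are centered
  and scaled internally (the linear reparametrization changes the
  penalty only by an additive constant, so the maximizer is unchanged);
  without it, the intercept/age collinearity makes Newton crawl on
  quasi-separated subgroup fits. Estimates, standard errors and the
  reported penalized log-likelihood are mapped back to the original
  scale.
* **BFGS polish.** The Newton Hessian approximation omits the penalty's
  curvature, and near quasi-separated optima the iteration can stall in
  a tiny cycle. When the gradient criterion (max-norm < 1e-6, up to 100
  iterations) is not met, the optimizer re-polishes with BFGS on the
  exact penalized likelihood and re-checks the gradient.

**The trend test is a *constrained* penalized LRT.** The age-null model
is not an independent Firth fit of the smaller design: it is the full
design with the age coefficient fixed at zero and the Jeffreys penalty
still evaluated on the full-model information. This matters. The
penalty's $\tfrac12\log\det I$ term differs between designs of different
dimension by a large, design-dependent constant, so subtracting two
independently penalized log-likelihoods produces a statistic that is not
remotely $\chi^2$ — in null simulations it rejected essentially always.
With the constrained null (the convention of the reference
implementation of Firth regression), the test is well calibrated: in the
package's own validation study (1,000 replicate null cohorts of
n = 200), rejection at $\alpha = 0.05$ falls within Monte-Carlo error of
0.05. Linear models use the standard LRT on two nested fits, where this
issue does not arise.

Significance conventions: raw p < 0.05; BH-adjusted p < 0.25 for the
screens (the customary threshold when screening hundreds of features
with FDR control). FDR pools are per stratum × feature level for trend
tests, and additionally per age group for the group tests.

## Expression processing

Raw targeted RNA-seq counts (397 immune genes in the default
configuration) are processed as:

1. **BSRC** — subtract the no-template control's per-gene counts, floored
   at zero. The floor is a design decision: negative pseudo-counts are
   meaningless for the ratio and `log1p` steps downstream.
2. **nRPM** — per sample, divide all BSRCs by the median of the
   housekeeping-gene ratios against a fixed external housekeeping RPM
   profile (10 genes by default; even counts use the midpoint median).
   This makes nRPM invariant to per-sample sequencing depth, which tests
   assert exactly.
3. **Ranks** — each gene's nRPM is converted to a percentile rank from 1
   to 100 against a reference population (735 tumors by default) with
   the mid-rank convention
   $100\,(\#\{r < v\} + \tfrac12\#\{r = v\})/n$, clamped to [1, 100] and
   kept as a real number. The convention is isolated in one function;
   the proprietary pipeline's exact tie rule is not public, so the
   choice is declared rather than inferred.
4. **High expressors** — rank ≥ 75, inclusive.
5. **Signatures** — TIGS and CP are means of their gene sets' ranks,
   CTAB is a sum. The real assay's signature gene sets are not public;
   synthetic sets are explicit configuration, not a reconstruction.

Model routing for immune features is fixed and table-driven: TMB, CP,
CTAB and per-gene nRPM are `log1p`-transformed (they are zero-heavy and
right-skewed) and modelled linearly; TIGS — already a bounded mean of
ranks — is modelled untransformed; high-expressor status is binary and
uses Firth regression. The per-gene volcano summary is
$\exp(\mathrm{mean})$ of the five group coefficients, equal weight.

## Survival analysis

Cox proportional hazards with Efron tie handling (the ecosystem default,
pinned for reproducibility) via the `survival` package, adjusted for
histology, once with the binary <65 vs ≥65 exposure and once with
winsorized age; Wald p-values are reported. Kaplan–Meier curves cover
the binary cells. The screen runs the full endpoint (OS/PFS) ×
treatment (immunotherapy alone / with chemotherapy) × stratum
(all/male/female) grid and flags, rather than fails on, cells without
events.

## The synthetic generator

`sim_config()` holds every generating parameter; defaults emulate the
marginal structure of a large real-world NSCLC CGIP cohort:

* **Age** is a two-component normal mixture: with probability 0.74 the
  patient is "older" (N(74.8, 6.5²) truncated to [65, 100]), otherwise
  "younger" (N(58, 6.2²) truncated to [18, 65)). Truncating each
  component to its side of 65 makes `p_old` exactly the probability of
  the ≥65 group, so the group fraction is testable with a binomial
  standard error.
* **Sex** is Bernoulli (50.2% female). **Histology** and **specimen
  site** follow multinomial-logit models in age whose slopes reproduce
  the qualitative trends (more adenocarcinoma and more
  advanced/metastatic specimens at younger ages); the exact slopes are
  free parameters, not published quantities.
* **Alterations** are per-feature Bernoulli draws with
  `logit(p) = β₀ + β_age (age − 65) + β_sex·male`, emitted only for
  patients passing the matching assay component (pass rates default to
  the component denominators' share of the cohort: 0.872 SNV, 0.886
  CNV, 0.766 fusion).
* **Expression** counts are negative binomial (dispersion is a testable
  knob; a count model is not published) with log-normal library factors,
  per-gene age/sex log-mean effects (housekeeping genes always have
  none), and a shared Poisson background matching the no-template
  control. The rank-calibration reference population is generated from
  the same gene model with all effects zeroed, since the real assay's
  pan-cancer reference is proprietary.
* **Survival** is exponential per endpoint and treatment arm with
  log-hazard terms for age<65, male sex and their interaction, plus
  independent exponential censoring. The default interaction pattern
  makes younger males do worse on immunotherapy alone and younger
  females do better with added chemotherapy — the qualitative structure
  the survival screen is designed to resolve.

The `truth` element of a simulated cohort retains all generating
parameters for recovery tests.

### What passing tests do and do not show

The generator produces independent patients, exactly exponential
survival, exactly negative-binomial counts and logistic-in-age
prevalences. Real cohorts violate all of these in various ways
(correlated assay failures, batch effects, non-proportional hazards,
informative censoring). Green tests therefore demonstrate that the
*pipeline computes its declared quantities correctly and with the
declared operating characteristics under its model assumptions* — not
that those assumptions hold in any particular real data set.

## Validation studies and problem sizes

The simulation studies shipped as `validate_*()` functions (used by both
the test suite and `scripts/acceptance.R`) run, by choice, at sizes that
give stable Monte-Carlo estimates in minutes on one core:

* Firth closed form: every 2×2 design with cells ≤ 5 (1,225 tables),
  agreement to 1e-6 with the half-cell-corrected log odds ratio,
  finiteness under complete separation.
* Trend-test calibration: 1,000 null cohorts of n = 200, covariates
  included; rejection within 3 Monte-Carlo SEs of 0.05.
* Screen recovery: 100 cohorts of n = 800 with one true feature
  (β_age = −0.08 per year, baseline prevalence 0.12) among 50 null
  features; detection of the true feature at adjusted p < 0.25 in ≥ 90%
  of replicates and mean false-discovery proportion ≤ 0.25. These
  validation cohorts carry no confounding by construction, so the
  screen is run without covariate adjustment there; the screen's
  default for real analyses remains site + histology adjustment.
* Cox recovery: 200 replicates of n = 300 at true HR 2 with ~20%
  censoring; 95% Wald interval coverage ≥ 90%.

## Known limitations

* Gene-level aggregation stays within variant class (SNV genes separate
  from fusion genes); cross-class aggregation is intentionally not the
  default.
* Tier annotations are metadata only; they never gate testing.
* The trend test treats winsorized age as linear on the link scale;
  non-monotone age effects (the CP signature's plateau pattern, for
  instance) surface only through the group comparisons.
* No proportional-hazards diagnostics, time-varying covariates or
  competing risks; no gene-ontology enrichment (it depends on an
  external annotation service).
* Records missing a model covariate are dropped from that model only,
  with a logged count; TMB-missing records stay in expression and
  survival analyses.
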