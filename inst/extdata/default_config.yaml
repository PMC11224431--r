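n_patients: 1000.0
seed: 1.0
age_mixture:
  p_old: 0.74
  mean_old: 74.8
  sd_old: 6.5
  mean_young: 58.0
  sd_young: 6.2
  min_age: 18.0
  max_age: 100.0
  split_age: 65.0
p_female: 0.502
histology:
  levels:
  - adenocarcinoma
  - squamous
  - large_cell_neuroendocrine
  - other_nos
  intercepts:
  - 0.0
  - -0.911
  - -4.595
  - -1.306
  slopes:
  - 0.0
  - 0.0393
  - -0.0103
  - -0.0059
  anchor_age: 75.0
site:
  levels:
  - primary
  - advanced
  - metastatic
  intercepts:
  - 0.0
  - -1.327
  - -1.876
  slopes:
  - 0.0
  - -0.0201
  - -0.0206
  anchor_age: 75.0
stage_probs:
- 0.038
- 0.022
- 0.058
- 0.234
- 0.648
pass_rates:
- 0.872
- 0.886
- 0.766
tmb_model:
  meanlog: 2.0
  sdlog: 0.9
  age_slope: 0.01
  anchor_age: 65.0
alteration_models:
  gene:
  - KRAS
  - RBM10
  - EGFR
  - TP53
  - CREBBP
  - CDKN2A
  - FGF3
  - ALK
  - MET
  - ROS1
  variant_class:
  - snv
  - snv
  - snv
  - snv
  - snv
  - cnv
  - cnv
  - fusion_skipping
  - fusion_skipping
  - fusion_skipping
  variant_label:
  - G12C
  - RBM10 SNV
  - E746_A750del
  - TP53 SNV
  - CREBBP SNV
  - CDKN2A Loss
  - FGF3 Amplification
  - EML4-ALK Fusion
  - Exon 14 Skipping
  - ROS1 Fusion
  tier:
  - '1'
  - '2'
  - '1'
  - '2'
  - .na.character
  - '2'
  - '2'
  - '1'
  - '1'
  - '1'
  beta0:
  - -1.0
  - -2.4
  - -3.6
  - 0.0
  - -4.4
  - -2.2
  - -3.8
  - -4.6
  - -3.2
  - -5.2
  beta_age:
  - 0.04
  - 0.08
  - -0.06
  - 0.0
  - -0.03
  - 0.0
  - -0.03
  - -0.12
  - 0.09
  - -0.09
  beta_sex:
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.4
  - 0.0
  - 0.0
  - 0.0
expression_model:
  n_genes: 397.0
  n_housekeeping: 10.0
  baseline_meanlog: 5.2983174
  baseline_sdlog: 1.0
  libsize_sdlog: 0.3
  nb_dispersion: 10.0
  prop_age_genes: 0.25
  age_slope: 0.012
  prop_sex_genes: 0.3
  sex_effect: -0.3
  ntc_mean: 5.0
  signature_sizes:
  - 20.0
  - 10.0
  - 15.0
  anchor_age: 65.0
treatment_probs:
- 0.408
- 0.592
- 0.0
survival_model:
  os:
    io_mono:
      baseline: 0.04
      lt65: 0.0
      male: 0.1
      lt65_male: 0.7
    io_chemo:
      baseline: 0.035
      lt65: -0.5
      male: 0.1
      lt65_male: 0.5
  pfs:
    io_mono:
      baseline: 0.072
      lt65: 0.0
      male: 0.1
      lt65_male: 0.7
    io_chemo:
      baseline: 0.063
      lt65: -0.5
      male: 0.1
      lt65_male: 0.5
  censor_rate: 0.02
reference_population_size: 735.0
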