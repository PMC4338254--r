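seed: 20150223
simulate:
  n_transcripts: 1000
  class_proportions:
    autosomal: 0.86
    z_linked: 0.02
    w_linked: 0.02
    female_biased: 0.04
    male_biased: 0.04
    contaminant: 0.02
  length_range:
  - 501
  - 3000
  w_expected_reads_min: 20.0
  design:
    n_female_pools: 6
    n_male_pools: 6
    fish_per_pool: 2
    target_library_size: 1000000.0
    library_size_cv: 0.2
    dispersion_log_mean: -2.3026
    dispersion_log_sd: 0.5
screen:
  min_length_bp: 501
  posterior_threshold: 0.999999
  min_female_pools_present: 1
  max_male_reads_total: 0
  prior_de: 0.05
  exclusion_list: []
primers:
  tm_min: 59.0
  tm_opt: 60.0
  tm_max: 61.0
  tm_pair_max_diff: 1.0
  max_poly_x: 3
  gc_clamp: 1
  product_min: 480
  product_opt: 500
  product_max: 520
  n_templates: 3
  control_product_bp: 259
  min_separation_bp: 40
diagnostic:
  template_length: 1000
  substitution_rate: 0.05
  min_differences: 2
clock:
  loci:
  - locus: cytb
    n_differences: 41
    n_sites: 876
    rate_fast: 0.0076
    rate_slow: 0.0036
  - locus: control_region
    n_differences: 6
    n_sites: 396
    rate_fast: 0.044
    rate_slow: 0.004
cohort:
  groups:
  - population: Mexico
    phenotypic_sex: F
    'n': 25
  - population: Mexico
    phenotypic_sex: M
    'n': 19
  - population: NewZealand
    phenotypic_sex: F
    'n': 29
  - population: NewZealand
    phenotypic_sex: M
    'n': 42
  sex_reversal_rate: 0.01
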