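generator:
  n_patients: 800
  years:
  - 2007
  - 2008
  index_year: 2008
  gender_split:
    female: 0.6395
    male: 0.3605
  age_band_weights:
    40-50: 0.2476
    51-60: 0.287
    61-70: 0.2338
    71-80: 0.2316
  age_out_of_range_prob: 0.03
  premium_weights:
    low: 0.1888
    mid: 0.7316
    high: 0.0796
  cert_prob: 0.228
  chronic_prob: 0.9775
  in_county_prob: 0.95
  deceased_prob: 0.023094851331309
  reason_prevalence:
    mood_disorder: 0.308
    hypertension: 0.205
    other_emotional_disturbances: 0.129
    gastrointestinal_disease: 0.082
    coronary_heart_disease: 0.097
    degenerative_arthritis: 0.075
  default_reason_prevalence: 0.05
  coefficients:
    intercept: calibrate
    male: 0.285178942233662
    age_40-50: 0.488580014818671
    age_51-60: 0.207014169384326
    age_61-70: 0.039220713153281
    premium_low: 0.336472236621213
    premium_mid: -0.174353387144778
    cert: 0.732367893713227
    chronic: 1.451613827240533
    reason_mood_disorder: 1.36863942588117
    reason_hypertension: 0.27002713721306
    reason_other_emotional_disturbances: 0.570979546585738
    reason_gastrointestinal_disease: 0.494696241836107
    reason_coronary_heart_disease: 0.587786664902119
    reason_degenerative_arthritis: 0.444685821261446
  target_high_fraction: 0.2282
  institution_counts:
    regional: 3.0
    district: 5.0
    clinic: 40.0
    psychiatric_hospital: 2.0
  out_of_county_institution_frac: 0.1
  shopping_intensity:
    low: 2.0
    high: 4.0
  visit_rate:
    low: 6.0
    high: 12.0
  tablets_low_range:
  - 40
  - 360
  tablets_high_range:
  - 361
  - 1460
  high_exceed_prob: 1.0
  max_tablets_per_visit: 90
  psychiatrist_fraction: 0.15
  seed: 20080101
criteria:
  index_year: 2008
  age_min: 40.0
  age_max: 80.0
  min_rx_year1: 4
  min_rx_index: 1
  require_in_county: yes
  exclude_deceased: yes
threshold_tablets: 360.0
network_mode: precedence
normalized_betweenness: no
regression:
  covariates:
  - gender
  - age_band
  - catastrophic_cert
  - reason_mood_disorder
  selection: none
  entry_p: 0.05
  stay_p: 0.1
seed: 20080101
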