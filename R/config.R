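#' Configuration for the synthetic claims generator
#'
#' Bundles every parameter of the synthetic claims simulator: the cohort
#' structure (size, demographics, insurance, clinical flags), the latent
#' high-dose propensity model (log-odds per covariate), and the visit /
#' dispensing process (visit rates, distinct-institution "shopping"
#' intensity, annual tablet ranges, per-visit dispensing cap).
#'
#' The demographic marginals default to a county-level cohort of chronic
#' zolpidem users aged 40-80 (about 64% female; age bands roughly 25/29/23/23%;
#' monthly insurance premium bands 19/73/8%; 22.8% with a catastrophic illness
#' certification; 97.8% with chronic disease). The propensity coefficients
#' default to the adjusted odds ratios of high-dose membership this cohort
#' structure is meant to reproduce (e.g. male 1.33, age 40-50 vs 71-80 1.63,
#' chronic disease 4.27, mood disorder 3.93), entered as log-odds.
#'
#' @param n_patients number of patients to simulate (default 5290).
#' @param years calendar years covered by the visit stream (default 2006:2009).
#' @param index_year the analysis year (default 2008); the year before it is
#'   used for the prescription-frequency inclusion criterion.
#' @param gender_split named probabilities for `female`/`male` (sum to 1).
#' @param age_band_weights named weights for the four age bands.
#' @param age_out_of_range_prob probability a simulated person falls outside
#'   40-80 (they enter the raw stream and are removed by cohort selection).
#' @param premium_weights named weights for premium bands `low` (<= NTD
#'   20,000/month), `mid` (20,001-40,000) and `high` (> 40,000).
#' @param cert_prob probability of catastrophic illness certification.
#' @param chronic_prob probability of the chronic-disease flag.
#' @param in_county_prob probability a patient resides in the study county.
#' @param deceased_prob probability of the presumed-deceased flag.
#' @param reason_prevalence named probabilities (over [reason_categories()])
#'   that a patient ever visits for that reason; unlisted categories get
#'   `default_reason_prevalence`.
#' @param default_reason_prevalence fallback prevalence for reason categories
#'   not named in `reason_prevalence`.
#' @param coefficients named log-odds of latent high-dose membership; see
#'   Details. `intercept = NULL` calibrates the intercept so the expected
#'   high-dose fraction equals `target_high_fraction`.
#' @param target_high_fraction marginal high-dose fraction used to calibrate
#'   the intercept (default 0.2282).
#' @param institution_counts named counts of institutions per level
#'   (`regional`, `district`, `clinic`, `psychiatric_hospital`).
#' @param out_of_county_institution_frac fraction of institutions per level
#'   flagged as outside the study county (deterministic assignment).
#' @param shopping_intensity named means (`low`, `high`) of the number of
#'   distinct institutions a patient draws visits from; modelled as
#'   1 + Poisson(mean - 1).
#' @param visit_rate named Poisson means (`low`, `high`) of visits per year.
#' @param tablets_low_range integer range of annual tablets for latent
#'   low-dose patients (upper end is the 360-tablet threshold).
#' @param tablets_high_range integer range for latent high-dose patients;
#'   default ceiling 1460 tablets/year (4 of the 10 mg tablets per day).
#' @param high_exceed_prob probability a latent high-dose patient's annual
#'   total is drawn from `tablets_high_range` rather than the low range.
#' @param max_tablets_per_visit per-visit dispensing cap (default 90,
#'   mirroring the 90-day ceiling on refillable prescriptions).
#' @param psychiatrist_fraction probability that a visit outside a
#'   psychiatric hospital is prescribed by a psychiatrist (psychiatric
#'   hospital visits always are).
#' @param seed default integer seed used when a generator function is called
#'   without one.
#'
#' @return an object of class `zolnet_config` (a validated named list).
#' @seealso [generate_population()], [generate_visits()], [simulate_claims()]
#' @export
generator_config <- function(
    n_patients = 5290,
    years = 2006:2009,
    index_year = 2008,
    gender_split = c(female = 0.6395, male = 0.3605),
    age_band_weights = c("40-50" = 0.2476, "51-60" = 0.2870,
                         "61-70" = 0.2338, "71-80" = 0.2316),
    age_out_of_range_prob = 0.03,
    premium_weights = c(low = 0.1888, mid = 0.7316, high = 0.0796),
    cert_prob = 0.2280,
    chronic_prob = 0.9775,
    in_county_prob = 0.95,
    deceased_prob = 654 / 28318,
    reason_prevalence = c(
      mood_disorder = 0.308, hypertension = 0.205,
      other_emotional_disturbances = 0.129,
      gastrointestinal_disease = 0.082,
      coronary_heart_disease = 0.097, degenerative_arthritis = 0.075),
    default_reason_prevalence = 0.05,
    coefficients = default_propensity_coefficients(),
    target_high_fraction = 0.2282,
    institution_counts = c(regional = 3, district = 5, clinic = 40,
                           psychiatric_hospital = 2),
    out_of_county_institution_frac = 0.10,
    shopping_intensity = c(low = 2, high = 4),
    visit_rate = c(low = 6, high = 12),
    tablets_low_range = c(40L, 360L),
    tablets_high_range = c(361L, 1460L),
    high_exceed_prob = 1.0,
    max_tablets_per_visit = 90L,
    psychiatrist_fraction = 0.15,
    seed = 1L) {

  check_count(n_patients, "n_patients")
  if (!is.numeric(years) || length(years) < 1) {
    config_abort("years", "must be one or more calendar years")
  }
  if (!index_year %in% years || !(index_year - 1) %in% years) {
    config_abort("index_year", "and the preceding year must lie inside `years`")
  }
  check_prob(gender_split, "gender_split")
  if (!setequal(names(gender_split), c("female", "male")) ||
      abs(sum(gender_split) - 1) > 1e-8) {
    config_abort("gender_split", "must name `female` and `male` and sum to 1")
  }
  if (!setequal(names(age_band_weights), c("40-50", "51-60", "61-70", "71-80")) ||
      any(age_band_weights < 0)) {
    config_abort("age_band_weights", "must be non-negative weights for the four bands")
  }
  check_prob(age_out_of_range_prob, "age_out_of_range_prob")
  if (!setequal(names(premium_weights), c("low", "mid", "high")) ||
      any(premium_weights < 0)) {
    config_abort("premium_weights", "must be non-negative weights for low/mid/high")
  }
  check_prob(cert_prob, "cert_prob")
  check_prob(chronic_prob, "chronic_prob")
  check_prob(in_county_prob, "in_county_prob")
  check_prob(deceased_prob, "deceased_prob")
  check_prob(reason_prevalence, "reason_prevalence")
  if (!all(names(reason_prevalence) %in% reason_categories())) {
    config_abort("reason_prevalence",
                 "names must belong to reason_categories()")
  }
  check_prob(default_reason_prevalence, "default_reason_prevalence")
  if (!is.numeric(coefficients$intercept %||% 0)) {
    config_abort("coefficients$intercept", "must be numeric or NULL")
  }
  check_prob(target_high_fraction, "target_high_fraction")
  if (!setequal(names(institution_counts), institution_levels())) {
    config_abort("institution_counts",
                 "must name regional, district, clinic, psychiatric_hospital")
  }
  check_count(institution_counts, "institution_counts")
  if (sum(institution_counts) < 1) {
    config_abort("institution_counts", "must provide at least one institution")
  }
  check_prob(out_of_county_institution_frac, "out_of_county_institution_frac")
  if (!setequal(names(shopping_intensity), c("low", "high")) ||
      any(shopping_intensity < 1)) {
    config_abort("shopping_intensity", "must name low/high means >= 1")
  }
  if (!setequal(names(visit_rate), c("low", "high")) || any(visit_rate <= 0)) {
    config_abort("visit_rate", "must name positive low/high Poisson means")
  }
  if (length(tablets_low_range) != 2 || tablets_low_range[1] < 1 ||
      tablets_low_range[1] > tablets_low_range[2]) {
    config_abort("tablets_low_range", "must be an increasing positive range")
  }
  if (length(tablets_high_range) != 2 ||
      tablets_high_range[1] <= tablets_low_range[2] ||
      tablets_high_range[1] > tablets_high_range[2]) {
    config_abort("tablets_high_range",
                 "must be an increasing range starting above the low range")
  }
  check_prob(high_exceed_prob, "high_exceed_prob")
  check_count(max_tablets_per_visit, "max_tablets_per_visit", min = 1)
  check_prob(psychiatrist_fraction, "psychiatrist_fraction")
  check_count(seed, "seed")

  structure(list(
    n_patients = as.integer(n_patients),
    years = as.integer(years),
    index_year = as.integer(index_year),
    gender_split = gender_split,
    age_band_weights = age_band_weights / sum(age_band_weights),
    age_out_of_range_prob = age_out_of_range_prob,
    premium_weights = premium_weights / sum(premium_weights),
    cert_prob = cert_prob,
    chronic_prob = chronic_prob,
    in_county_prob = in_county_prob,
    deceased_prob = deceased_prob,
    reason_prevalence = reason_prevalence,
    default_reason_prevalence = default_reason_prevalence,
    coefficients = coefficients,
    target_high_fraction = target_high_fraction,
    institution_counts = institution_counts,
    out_of_county_institution_frac = out_of_county_institution_frac,
    shopping_intensity = shopping_intensity,
    visit_rate = visit_rate,
    tablets_low_range = as.integer(tablets_low_range),
    tablets_high_range = as.integer(tablets_high_range),
    high_exceed_prob = high_exceed_prob,
    max_tablets_per_visit = as.integer(max_tablets_per_visit),
    psychiatrist_fraction = psychiatrist_fraction,
    seed = as.integer(seed)
  ), class = "zolnet_config")
}

#' Default latent high-dose propensity coefficients
#'
#' Log-odds of latent high-dose membership per covariate, with reference
#' levels female, age 71-80, premium band `high`, no certification, no
#' chronic disease and no visit-reason flag. The defaults are the natural
#' logs of the adjusted odds ratios the generator is designed to make
#' recoverable by [fit_logistic()] (male 1.33; age 1.63/1.23/1.04; premium
#' low 1.40, mid 0.84; certification 2.08; chronic disease 4.27; mood
#' disorder 3.93; hypertension 1.31; other emotional disturbances 1.77;
#' gastrointestinal disease 1.64; coronary heart disease 1.80; degenerative
#' arthritis 1.56).
#'
#' @return named list: `intercept` (NULL = calibrated) plus one log-odds per
#'   non-reference covariate level.
#' @export
default_propensity_coefficients <- function() {
  list(
    intercept = NULL,
    male = log(1.33),
    `age_40-50` = log(1.63),
    `age_51-60` = log(1.23),
    `age_61-70` = log(1.04),
    premium_low = log(1.40),
    premium_mid = log(0.84),
    cert = log(2.08),
    chronic = log(4.27),
    reason_mood_disorder = log(3.93),
    reason_hypertension = log(1.31),
    reason_other_emotional_disturbances = log(1.77),
    reason_gastrointestinal_disease = log(1.64),
    reason_coronary_heart_disease = log(1.80),
    reason_degenerative_arthritis = log(1.56)
  )
}

#' @export
print.zolnet_config <- function(x, ...) {
  cat("<zolnet_config>\n")
  cat("  patients:", x$n_patients, " years:", paste(range(x$years), collapse = "-"),
      " index year:", x$index_year, "\n")
  cat("  institutions:", paste(names(x$institution_counts),
                               x$institution_counts, collapse = ", "), "\n")
  cat("  shopping intensity low/high:",
      paste(x$shopping_intensity, collapse = "/"),
      " visit rate low/high:", paste(x$visit_rate, collapse = "/"), "\n")
  invisible(x)
}

#' Institution roster implied by a generator configuration
#'
#' Builds the deterministic institution table (ids, level, in-county flag)
#' used by the visit simulator. Out-of-county institutions are the last
#' `out_of_county_institution_frac` share within each level, so the roster
#' depends only on the configuration, not on the RNG.
#'
#' @param config a [generator_config()].
#' @return tibble with columns `institution_id`, `institution_level`,
#'   `in_county`.
#' @export
institution_roster <- function(config) {
  stopifnot(inherits(config, "zolnet_config"))
  prefix <- c(regional = "R", district = "D", clinic = "C",
              psychiatric_hospital = "Y")
  purrr::map_dfr(institution_levels(), function(lv) {
    n <- config$institution_counts[[lv]]
    if (n == 0) return(tibble())
    n_out <- floor(n * config$out_of_county_institution_frac)
    tibble(
      institution_id = sprintf("%s%02d", prefix[[lv]], seq_len(n)),
      institution_level = lv,
      in_county = seq_len(n) <= (n - n_out)
    )
  })
}
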