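#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used by most clinical/epidemiological tables (and by SPSS),
#' unlike [base::round()] which rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 2).
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(22.825, 2) # 22.83, where round() gives 22.82
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # epsilon absorbs representation error in values such as x.xx5
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Percentage with table rounding
#'
#' @param n counts (numerator).
#' @param total denominator.
#' @param digits decimal places (default 2).
#' @return numeric percentages, half-up rounded; `NA` where `total` is 0.
#' @export
percent_of <- function(n, total, digits = 2) {
  total <- rep_len(total, length(n))
  out <- rep(NA_real_, length(n))
  ok <- !is.na(total) & total > 0
  out[ok] <- round_half_up(100 * n[ok] / total[ok], digits)
  out
}

# stop with a classed configuration error naming the offending field
config_abort <- function(field, msg) {
  abort(sprintf("invalid configuration: `%s` %s", field, msg),
        class = "zolnet_config_error", field = field)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    config_abort(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 0) {
  if (!is.numeric(x) || anyNA(x) || any(x < min) || any(x != floor(x))) {
    config_abort(field, sprintf("must be an integer >= %d", min))
  }
  invisible(x)
}

# derive a stream-specific 32-bit seed from a base seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

#' Age bands used throughout the analysis
#'
#' Cuts integer ages into the four decade-ish bands 40-50, 51-60, 61-70,
#' 71-80 used for the descriptive tables and the regression design.
#' Ages outside 40-80 yield `NA`.
#'
#' @param age integer vector of ages in years.
#' @return factor with levels `"40-50"`, `"51-60"`, `"61-70"`, `"71-80"`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(39, 50, 60, 70, 80),
      labels = c("40-50", "51-60", "61-70", "71-80"))
}

#' Reason-for-visit vocabulary
#'
#' The 19 named outpatient reason-for-visit categories plus `"other"`.
#'
#' @return character vector of 20 category labels.
#' @export
reason_categories <- function() {
  c("anxiety", "mood_disorder", "hypertension", "common_cold",
    "other_emotional_disturbances", "diabetes_mellitus", "dizziness",
    "hyperlipidemia", "musculoskeletal_disorders", "back_pain", "headache",
    "gastrointestinal_disease", "coronary_heart_disease",
    "degenerative_arthritis", "copd", "arrhythmia", "bronchitis",
    "other_gastric_diseases", "gastric_ulcer", "other")
}

reason_cols <- function() paste0("reason_", reason_categories())

institution_levels <- function() {
  c("regional", "district", "clinic", "psychiatric_hospital")
}
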