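# Synthetic claims simulator.
#
# Two-stage scheme: (1) a latent dose group is drawn per patient from a
# logistic model on the covariates, so the generating log-odds are
# recoverable by the downstream regression; (2) visits and dispensed
# tablets are drawn conditionally on the latent group, so that high-group
# patients consume more tablets and spread their visits over more distinct
# institutions ("doctor shopping"). The latent group itself is never
# written to the output tables.

#' Generate a synthetic patient attribute table
#'
#' Draws `config$n_patients` patients with independent demographic,
#' insurance and clinical covariates at the configured marginal
#' frequencies, plus residence (`in_county`), a presumed-deceased flag and
#' ever/never indicators for the reason-for-visit categories.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$seed`. Identical
#'   config + seed gives identical output.
#' @return tibble with one row per patient: `patient_id`, `gender`,
#'   `age_years`, `premium_band`, `catastrophic_cert`, `chronic_disease`,
#'   `in_county`, `deceased`, and one logical `reason_*` column per
#'   category in [reason_categories()].
#' @examples
#' pop <- generate_population(generator_config(n_patients = 100))
#' dplyr::count(pop, gender)
#' @export
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "zolnet_config"))
  n <- config$n_patients
  if (n == 0) return(empty_population())

  withr::with_seed(derive_seed(seed, 1L), {
    gender <- sample(c("female", "male"), n, replace = TRUE,
                     prob = config$gender_split[c("female", "male")])
    band <- sample(names(config$age_band_weights), n, replace = TRUE,
                   prob = config$age_band_weights)
    lo <- c("40-50" = 40, "51-60" = 51, "61-70" = 61, "71-80" = 71)[band]
    hi <- c("40-50" = 50, "51-60" = 60, "61-70" = 70, "71-80" = 80)[band]
    age <- lo + floor(runif(n) * (hi - lo + 1))
    # a small share falls outside the study window and is later filtered out
    oob <- runif(n) < config$age_out_of_range_prob
    age[oob] <- ifelse(runif(sum(oob)) < 0.5,
                       30 + floor(runif(sum(oob)) * 10),   # 30-39
                       81 + floor(runif(sum(oob)) * 10))   # 81-90

    prev <- setNames(rep(config$default_reason_prevalence,
                         length(reason_categories())),
                     reason_categories())
    prev[names(config$reason_prevalence)] <- config$reason_prevalence
    reasons <- purrr::map(reason_categories(),
                          ~ runif(n) < prev[[.x]])
    names(reasons) <- reason_cols()

    out <- tibble(
      patient_id = sprintf("P%06d", seq_len(n)),
      gender = factor(gender, levels = c("female", "male")),
      age_years = as.integer(age),
      premium_band = factor(
        sample(c("low", "mid", "high"), n, replace = TRUE,
               prob = config$premium_weights[c("low", "mid", "high")]),
        levels = c("low", "mid", "high")),
      catastrophic_cert = runif(n) < config$cert_prob,
      chronic_disease = runif(n) < config$chronic_prob,
      in_county = runif(n) < config$in_county_prob,
      deceased = runif(n) < config$deceased_prob
    )
    dplyr::bind_cols(out, tibble::as_tibble(reasons))
  })
}

empty_population <- function() {
  out <- tibble(
    patient_id = character(), gender = factor(levels = c("female", "male")),
    age_years = integer(),
    premium_band = factor(levels = c("low", "mid", "high")),
    catastrophic_cert = logical(), chronic_disease = logical(),
    in_county = logical(), deceased = logical()
  )
  for (col in reason_cols()) out[[col]] <- logical()
  out
}

# linear predictor of the latent high-dose logistic model, excluding the
# intercept; ages outside 40-80 contribute the reference (0)
propensity_linear_predictor <- function(population, config) {
  cf <- config$coefficients
  band <- age_band(population$age_years)
  lp <- rep(0, nrow(population))
  add <- function(lp, term, x) {
    if (!is.null(cf[[term]])) lp + cf[[term]] * x else lp
  }
  lp <- add(lp, "male", as.numeric(population$gender == "male"))
  for (b in c("40-50", "51-60", "61-70")) {
    lp <- add(lp, paste0("age_", b), as.numeric(!is.na(band) & band == b))
  }
  lp <- add(lp, "premium_low", as.numeric(population$premium_band == "low"))
  lp <- add(lp, "premium_mid", as.numeric(population$premium_band == "mid"))
  lp <- add(lp, "cert", as.numeric(population$catastrophic_cert))
  lp <- add(lp, "chronic", as.numeric(population$chronic_disease))
  for (col in intersect(names(cf), reason_cols())) {
    lp <- add(lp, col, as.numeric(population[[col]]))
  }
  lp
}

# probability a patient with Poisson visit rate `lambda` and annual
# tablet target uniform on `tablets_range` satisfies the standard
# inclusion rule (>= 4 prescription events in the pre-index year, >= 1 in
# the index year). The per-visit cap forces ceiling(target/cap) visits,
# so large targets guarantee the frequency rule; a zero-visit draw skips
# the year entirely.
retention_prob <- function(lambda, tablets_range, cap) {
  a <- tablets_range[1]; b <- tablets_range[2]
  # P(ceiling(T / cap) >= 4) = P(T > 3 * cap) for integer T uniform [a, b]
  pf4 <- min(1, max(0, (b - max(a - 1, 3 * cap)) / (b - a + 1)))
  p_ge1 <- stats::ppois(0, lambda, lower.tail = FALSE)
  p_ge4 <- stats::ppois(3, lambda, lower.tail = FALSE)
  (pf4 * p_ge1 + (1 - pf4) * p_ge4) * p_ge1
}

#' Latent high-dose propensity per patient
#'
#' Evaluates `P(high | covariates) = plogis(intercept + x'beta)` under the
#' configured coefficients. When `config$coefficients$intercept` is `NULL`
#' the intercept is calibrated by root finding so that the *cohort-level*
#' high-dose fraction — the published marginal refers to patients surviving
#' the prescription-frequency inclusion rule, which low-rate (mostly
#' low-dose) patients fail more often — equals
#' `config$target_high_fraction`. The calibration weights each group by
#' its probability of meeting the standard rule (at least 4 prescription
#' events in the pre-index year and 1 in the index year) under the
#' configured visit rates.
#'
#' @inheritParams generate_population
#' @param population tibble from [generate_population()].
#' @return numeric vector of probabilities, one per patient.
#' @export
dose_group_propensity <- function(population, config) {
  stopifnot(inherits(config, "zolnet_config"))
  if (nrow(population) == 0) return(numeric())
  lp <- propensity_linear_predictor(population, config)
  b0 <- config$coefficients$intercept
  if (is.null(b0)) {
    target <- config$target_high_fraction
    r_low <- retention_prob(config$visit_rate[["low"]],
                            config$tablets_low_range,
                            config$max_tablets_per_visit)
    r_high <- retention_prob(config$visit_rate[["high"]],
                             config$tablets_high_range,
                             config$max_tablets_per_visit)
    b0 <- uniroot(function(b) {
      pi <- plogis(b + lp)
      mean(pi * r_high) / mean(pi * r_high + (1 - pi) * r_low) - target
    }, interval = c(-20, 20), tol = 1e-10)$root
  }
  plogis(b0 + lp)
}

#' Draw latent dose groups
#'
#' Samples each patient's latent dose group from the logistic propensity
#' model. The latent group parameterises the visit and tablet process in
#' [generate_visits()]; it is not part of the emitted claims data (the
#' observable group is recovered from dispensed tablets by
#' [classify_dose()]).
#'
#' @inheritParams dose_group_propensity
#' @param seed integer seed (defaults to `config$seed`).
#' @return factor of `"low"`/`"high"`, one per patient.
#' @export
assign_dose_group_latent <- function(population, config, seed = config$seed) {
  p <- dose_group_propensity(population, config)
  withr::with_seed(derive_seed(seed, 2L), {
    factor(ifelse(runif(length(p)) < p, "high", "low"),
           levels = c("low", "high"))
  })
}

#' Generate a synthetic visit/prescription stream
#'
#' For each patient and calendar year, draws the number of zolpidem
#' outpatient visits (Poisson with a group-dependent mean), an annual
#' tablet total (uniform on the group's configured range), and spreads the
#' tablets over the visits subject to the per-visit dispensing cap; each
#' visit is placed at one of the patient's personal set of institutions
#' (larger for latent high-dose patients: the doctor-shopping contrast).
#' Rows are returned in the package-wide deterministic order
#' (`patient_id`, `visit_date`, `institution_id`, draw ordinal), and
#' `record_id` fixes that total order for downstream precedence logic.
#'
#' The drawn per-patient-year tablet totals are attached as attribute
#' `"annual_targets"`; within a year with at least one visit the dispensed
#' tablets sum exactly to the drawn total.
#'
#' @inheritParams dose_group_propensity
#' @param seed integer seed (defaults to `config$seed`).
#' @param latent optional factor of latent groups (as from
#'   [assign_dose_group_latent()]); computed internally from the same seed
#'   when omitted.
#' @return tibble with columns `record_id`, `patient_id`, `visit_date`
#'   (Date), `institution_id`, `institution_level`, `in_county` (of the
#'   institution), `prescriber_is_psychiatrist`, `tablets_dispensed`,
#'   `reason`.
#' @export
generate_visits <- function(population, config, seed = config$seed,
                            latent = NULL) {
  stopifnot(inherits(config, "zolnet_config"))
  roster <- institution_roster(config)
  if (nrow(roster) == 0) {
    config_abort("institution_counts", "produced an empty institution pool")
  }
  if (nrow(population) == 0) return(empty_visits())
  if (is.null(latent)) {
    latent <- assign_dose_group_latent(population, config, seed)
  }
  stopifnot(length(latent) == nrow(population))

  n <- nrow(population)
  cap <- config$max_tablets_per_visit

  withr::with_seed(derive_seed(seed, 3L), {
    # personal institution pool per patient: 1 + Poisson(mean - 1) distinct
    # institutions, capped by the roster size
    m <- 1L + rpois(n, config$shopping_intensity[as.character(latent)] - 1)
    m <- pmin(m, nrow(roster))
    pool_idx <- purrr::map(m, ~ sample.int(nrow(roster), .x))

    # patient-year grid
    py <- tidyr::expand_grid(pi = seq_len(n), year = config$years)
    py$group <- as.character(latent)[py$pi]
    py$n_visits <- rpois(nrow(py), config$visit_rate[py$group])

    lo <- config$tablets_low_range
    hi <- config$tablets_high_range
    u <- runif(nrow(py))
    target_low <- lo[1] + floor(u * (lo[2] - lo[1] + 1L))
    target_high <- hi[1] + floor(runif(nrow(py)) * (hi[2] - hi[1] + 1L))
    use_high <- py$group == "high" & runif(nrow(py)) < config$high_exceed_prob
    py$target <- as.integer(ifelse(use_high, target_high, target_low))

    # enough visits to respect the dispensing cap; at least one tablet per visit
    keep <- py$n_visits > 0L
    py <- py[keep, ]
    py$n_visits <- pmax(py$n_visits, ceiling(py$target / cap))
    py$n_visits <- pmin(py$n_visits, py$target)

    total <- sum(py$n_visits)
    rep_py <- rep.int(seq_len(nrow(py)), py$n_visits)
    ord <- sequence(py$n_visits)                 # visit ordinal within year
    pi <- py$pi[rep_py]

    # split the annual target into n_visits near-equal integer parts
    q <- py$target %/% py$n_visits
    r <- py$target %% py$n_visits
    tablets <- q[rep_py] + as.integer(ord <= r[rep_py])

    # institution choice within the personal pool
    m_rep <- m[pi]
    offsets <- cumsum(c(0L, lengths(pool_idx)))[pi]
    pick <- 1L + floor(runif(total) * m_rep)
    inst <- unlist(pool_idx)[offsets + pick]

    year_start <- as.Date(paste0(py$year, "-01-01"))
    ndays <- as.integer(as.Date(paste0(py$year, "-12-31")) - year_start) + 1L
    date <- year_start[rep_py] + floor(runif(total) * ndays[rep_py])

    # reason drawn among the patient's ever-reasons ("other" if none)
    reason_mat <- as.matrix(population[reason_cols()])
    colnames(reason_mat) <- reason_categories()
    reason_sets <- apply(reason_mat, 1L, function(z) {
      s <- colnames(reason_mat)[z]
      if (length(s) == 0) "other" else s
    }, simplify = FALSE)
    n_reasons <- lengths(reason_sets)[pi]
    ridx <- 1L + floor(runif(total) * n_reasons)
    reason_offsets <- cumsum(c(0L, lengths(reason_sets)))[pi]
    reason <- unlist(reason_sets)[reason_offsets + ridx]

    lv <- roster$institution_level[inst]
    psy <- lv == "psychiatric_hospital" |
      runif(total) < config$psychiatrist_fraction

    visits <- tibble(
      patient_id = population$patient_id[pi],
      visit_date = date,
      institution_id = roster$institution_id[inst],
      institution_level = lv,
      in_county = roster$in_county[inst],
      prescriber_is_psychiatrist = psy,
      tablets_dispensed = as.integer(tablets),
      reason = reason,
      .draw = seq_len(total)
    )
    visits <- dplyr::arrange(visits, .data$patient_id, .data$visit_date,
                             .data$institution_id, .data$.draw)
    visits$.draw <- NULL
    visits <- dplyr::mutate(visits, record_id = dplyr::row_number(),
                            .before = 1L)

    targets <- tibble(patient_id = population$patient_id[py$pi],
                      year = py$year, target_tablets = py$target)
    attr(visits, "annual_targets") <- targets
    visits
  })
}

empty_visits <- function() {
  tibble(
    record_id = integer(), patient_id = character(),
    visit_date = as.Date(character()), institution_id = character(),
    institution_level = character(), in_county = logical(),
    prescriber_is_psychiatrist = logical(), tablets_dispensed = integer(),
    reason = character()
  )
}

#' Simulate a complete synthetic claims data set
#'
#' Convenience wrapper: draws the population, the latent dose groups and
#' the visit stream under one seed.
#'
#' @inheritParams generate_population
#' @return list with elements `patients` (attribute tibble), `visits`
#'   (visit tibble) and `institutions` (roster tibble).
#' @examples
#' claims <- simulate_claims(generator_config(n_patients = 50, seed = 7))
#' nrow(claims$patients)
#' @export
simulate_claims <- function(config, seed = config$seed) {
  population <- generate_population(config, seed)
  visits <- generate_visits(population, config, seed)
  list(patients = population, visits = visits,
       institutions = institution_roster(config))
}
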