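# Synthetic claims generator: determinism, marginals, conservation,
# latent propensity model.

test_that("identical config and seed give byte-identical output", {
  cfg <- small_config(n = 300, seed = 17)
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$visits, b$visits)
  # a different seed changes the stream
  c <- simulate_claims(cfg, seed = 18)
  expect_false(identical(a$visits, c$visits))
})

test_that("population marginals match configured targets within sampling error", {
  cfg <- generator_config(n_patients = 5290, seed = 101)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 5290)

  p_f <- 0.6395
  tol <- 3 * sqrt(p_f * (1 - p_f) / 5290)
  expect_lt(abs(mean(pop$gender == "female") - p_f), tol)

  # age bands, among the in-range share
  inr <- pop[pop$age_years >= 40 & pop$age_years <= 80, ]
  bands <- table(age_band(inr$age_years)) / nrow(inr)
  for (b in names(cfg$age_band_weights)) {
    w <- cfg$age_band_weights[[b]]
    expect_lt(abs(bands[[b]] - w), 3 * sqrt(w * (1 - w) / nrow(inr)))
  }

  for (spec in list(c("catastrophic_cert", cfg$cert_prob),
                    c("chronic_disease", cfg$chronic_prob))) {
    p <- as.numeric(spec[2])
    expect_lt(abs(mean(pop[[spec[1]]]) - p), 3 * sqrt(p * (1 - p) / 5290))
  }
})

test_that("zero patients give an empty, well-typed population", {
  pop <- generate_population(generator_config(n_patients = 0))
  expect_equal(nrow(pop), 0)
  expect_true(all(c("patient_id", "gender", "age_years") %in% names(pop)))
  expect_equal(nrow(generate_visits(pop, generator_config(n_patients = 0))), 0)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(generator_config(n_patients = -5), "n_patients",
               class = "zolnet_config_error")
  expect_error(generator_config(cert_prob = 1.4), "cert_prob",
               class = "zolnet_config_error")
  expect_error(generator_config(gender_split = c(female = 0.7, male = 0.4)),
               "gender_split", class = "zolnet_config_error")
  expect_error(generator_config(institution_counts = c(
    regional = 0, district = 0, clinic = 0, psychiatric_hospital = 0)),
    "institution_counts", class = "zolnet_config_error")
})

test_that("zeroed propensity model gives P(high) = 1/2 for everyone", {
  cfg <- small_config(n = 50)
  cfg$coefficients <- list(intercept = 0)
  pop <- generate_population(cfg)
  expect_equal(dose_group_propensity(pop, cfg), rep(0.5, 50))
})

test_that("intercept calibration targets the cohort-level high fraction", {
  cfg <- generator_config(n_patients = 20000, seed = 31)
  claims <- simulate_claims(cfg)
  sel <- select_cohort(claims$patients, claims$visits)
  dose <- classify_dose(claims$visits, sel)
  f <- group_proportions(dose)[["high"]]
  target <- cfg$target_high_fraction
  # binomial error around the calibration target, plus slack for the
  # approximation in the retention weighting
  expect_lt(abs(f - target), 4 * sqrt(target * (1 - target) / nrow(dose)))
})

test_that("single-covariate generating odds ratios are recovered at large n", {
  # crude OR of simulated group membership vs the flag, other effects off
  recover_or <- function(flag_col, coef_name, or, cfg_args = list()) {
    cfg <- do.call(generator_config,
                   c(list(n_patients = 100000, seed = 77), cfg_args))
    cfg$coefficients <- setNames(list(0, log(or)), c("intercept", coef_name))
    pop <- generate_population(cfg)
    grp <- assign_dose_group_latent(pop, cfg)
    x <- pop[[flag_col]]
    if (is.factor(x)) x <- x == "male"
    tab <- table(x, grp)
    est <- log((tab["TRUE", "high"] * tab["FALSE", "low"]) /
                 (tab["TRUE", "low"] * tab["FALSE", "high"]))
    se <- sqrt(sum(1 / tab))
    expect_lt(abs(est - log(or)), 3 * se)
  }
  recover_or("gender", "male", 1.33)
  recover_or("chronic_disease", "chronic", 4.27,
             cfg_args = list(chronic_prob = 0.5))
})

test_that("annual dispensed tablets equal the drawn annual target", {
  cfg <- small_config(n = 120, seed = 5)
  visits <- generate_visits(generate_population(cfg), cfg)
  targets <- attr(visits, "annual_targets")
  sums <- visits |>
    dplyr::mutate(year = as.integer(format(visit_date, "%Y"))) |>
    dplyr::group_by(patient_id, year) |>
    dplyr::summarise(total = sum(tablets_dispensed), .groups = "drop")
  joined <- dplyr::inner_join(sums, targets, by = c("patient_id", "year"))
  expect_equal(joined$total, joined$target_tablets)
  # drawn targets exist for every dispensing patient-year
  expect_equal(nrow(dplyr::anti_join(sums, targets,
                                     by = c("patient_id", "year"))), 0)
  expect_true(all(visits$tablets_dispensed <= cfg$max_tablets_per_visit))
  expect_true(all(visits$tablets_dispensed >= 1))
})

test_that("visit order is a strict deterministic total order per patient", {
  cfg <- small_config(n = 80, seed = 9)
  visits <- generate_visits(generate_population(cfg), cfg)
  by_p <- split(visits, visits$patient_id)
  for (v in by_p[1:10]) {
    key <- order(v$visit_date, v$institution_id, v$record_id)
    expect_equal(key, seq_len(nrow(v)))
  }
  expect_false(any(duplicated(visits$record_id)))
})

test_that("a single shared institution yields no inter-institution movement", {
  cfg <- generator_config(
    n_patients = 60, seed = 4,
    institution_counts = c(regional = 0, district = 0, clinic = 1,
                           psychiatric_hospital = 0),
    shopping_intensity = c(low = 1, high = 1))
  claims <- simulate_claims(cfg)
  expect_equal(unique(claims$visits$institution_id), "C01")
  sel <- select_cohort(claims$patients, claims$visits)
  dose <- classify_dose(claims$visits, sel)
  for (g in c("low", "high")) {
    net <- build_network(claims$visits, dose, g)
    expect_equal(nrow(net$edges), 0)
  }
})

test_that("raising high-group shopping intensity raises expected high-network edge count", {
  mean_edges <- function(intensity_high) {
    counts <- vapply(1:8, function(s) {
      cfg <- generator_config(
        n_patients = 300, seed = 100 + s, years = 2007:2008,
        shopping_intensity = c(low = 2, high = intensity_high))
      claims <- simulate_claims(cfg)
      sel <- select_cohort(claims$patients, claims$visits)
      dose <- classify_dose(claims$visits, sel)
      nrow(build_network(claims$visits, dose, "high")$edges)
    }, numeric(1))
    mean(counts)
  }
  e4 <- mean_edges(4)
  e7 <- mean_edges(7)
  expect_gt(e7, e4)
})
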