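# Small builders for hand-crafted claims fixtures.

toy_patients <- function(df) {
  out <- tibble::as_tibble(df)
  defaults <- list(gender = "female", age_years = 55L, premium_band = "mid",
                   catastrophic_cert = FALSE, chronic_disease = TRUE,
                   in_county = TRUE, deceased = FALSE)
  for (col in names(defaults)) {
    if (!col %in% names(out)) out[[col]] <- rep(defaults[[col]], nrow(out))
  }
  out$gender <- factor(out$gender, levels = c("female", "male"))
  out$premium_band <- factor(out$premium_band, levels = c("low", "mid", "high"))
  for (col in paste0("reason_", reason_categories())) {
    if (!col %in% names(out)) out[[col]] <- FALSE
  }
  out
}

toy_visits <- function(df) {
  out <- tibble::as_tibble(df)
  n <- nrow(out)
  if (!"visit_date" %in% names(out)) out$visit_date <- as.Date("2008-06-01")
  out$visit_date <- as.Date(out$visit_date)
  if (!"institution_id" %in% names(out)) out$institution_id <- "C01"
  if (!"institution_level" %in% names(out)) out$institution_level <- "clinic"
  if (!"in_county" %in% names(out)) out$in_county <- TRUE
  if (!"prescriber_is_psychiatrist" %in% names(out)) {
    out$prescriber_is_psychiatrist <- FALSE
  }
  if (!"tablets_dispensed" %in% names(out)) out$tablets_dispensed <- 30L
  if (!"reason" %in% names(out)) out$reason <- "other"
  out$record_id <- seq_len(n)
  out
}

# n visits on distinct dates in `year` for one patient
toy_visit_seq <- function(patient_id, year, institutions,
                          tablets = 30L) {
  n <- length(institutions)
  toy_visits(tibble::tibble(
    patient_id = patient_id,
    visit_date = as.Date(sprintf("%d-01-01", year)) + seq_len(n) - 1,
    institution_id = institutions,
    tablets_dispensed = rep_len(tablets, n)
  ))
}

small_config <- function(n = 400, seed = 1, ...) {
  generator_config(n_patients = n, seed = seed, ...)
}
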