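#' Classify cohort members into low- and high-dose users
#'
#' Sums each cohort member's index-year dispensed tablets and converts them
#' to Defined Daily Doses (DDD). For 10 mg tablets and the WHO DDD of
#' 10 mg/day, one tablet is one DDD, and users are split at an annual
#' consumption of 360 tablets: `<= 360` is low-dose, `> 360` high-dose.
#' A prescription's tablets count in the calendar year of its visit date.
#'
#' @param visits visit tibble.
#' @param cohort character vector of patient ids, or a `cohort_trace` from
#'   [select_cohort()].
#' @param index_year analysis year (default 2008).
#' @param threshold_tablets classification threshold (default 360).
#' @param mg_per_tablet,mg_per_ddd tablet strength and DDD in mg (both
#'   default 10, giving 1 tablet = 1 DDD).
#' @return tibble of class `dose_classification` with columns `patient_id`,
#'   `annual_tablets`, `annual_ddd`, `group` (factor low/high). Errors if a
#'   cohort member has no index-year prescription record, which signals the
#'   selection and classification stages were run on inconsistent inputs.
#' @examples
#' claims <- simulate_claims(generator_config(n_patients = 200, seed = 3))
#' sel <- select_cohort(claims$patients, claims$visits)
#' dose <- classify_dose(claims$visits, sel)
#' group_proportions(dose)
#' @export
classify_dose <- function(visits, cohort, index_year = 2008,
                          threshold_tablets = 360,
                          mg_per_tablet = 10, mg_per_ddd = 10) {
  if (inherits(cohort, "cohort_trace")) cohort <- cohort$cohort
  cohort <- unique(as.character(cohort))

  idx <- visits[as.integer(format(visits$visit_date, "%Y")) == index_year &
                  visits$patient_id %in% cohort, , drop = FALSE]
  totals <- idx |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(annual_tablets = sum(.data$tablets_dispensed),
                     n_rx = sum(.data$tablets_dispensed > 0),
                     .groups = "drop")

  missing <- setdiff(cohort, totals$patient_id[totals$n_rx > 0])
  if (length(missing) > 0) {
    abort(sprintf(
      "contract violation: %d cohort member(s) (e.g. %s) have no index-year prescription record; cohort selection and dose classification were run on inconsistent inputs",
      length(missing), missing[1]), class = "zolnet_contract_error")
  }

  out <- totals |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      annual_tablets = as.integer(.data$annual_tablets),
      annual_ddd = .data$annual_tablets * mg_per_tablet / mg_per_ddd,
      group = factor(ifelse(.data$annual_tablets > threshold_tablets,
                            "high", "low"),
                     levels = c("low", "high"))) |>
    dplyr::arrange(.data$patient_id)
  attr(out, "threshold_tablets") <- threshold_tablets
  attr(out, "index_year") <- index_year
  class(out) <- c("dose_classification", class(out))
  out
}

#' Low/high dose group proportions
#'
#' @param classifications tibble from [classify_dose()] (or any tibble with
#'   a `group` factor of low/high).
#' @return named numeric `c(low = , high = )`, fractions summing to 1.
#' @export
group_proportions <- function(classifications) {
  if (nrow(classifications) == 0) {
    abort("group proportions are undefined for an empty classification",
          class = "zolnet_contract_error")
  }
  tab <- table(factor(classifications$group, levels = c("low", "high")))
  c(low = as.numeric(tab[["low"]]) / sum(tab),
    high = as.numeric(tab[["high"]]) / sum(tab))
}

#' @export
print.dose_classification <- function(x, ...) {
  p <- group_proportions(x)
  cat(sprintf("<dose_classification> %d patients: %.2f%% low, %.2f%% high (threshold %d tablets)\n",
              nrow(x), 100 * p[["low"]], 100 * p[["high"]],
              attr(x, "threshold_tablets")))
  NextMethod()
}
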