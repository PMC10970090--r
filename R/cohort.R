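#' Cohort selection criteria
#'
#' Inclusion/exclusion rules applied by [select_cohort()], mirroring a
#' study-flowchart funnel for chronic zolpidem users: county residence,
#' age 40-80 at the start of the index year, exclusion of presumed-deceased
#' patients, at least `min_rx_year1` prescription events in the year before
#' the index year, at least `min_rx_index` in the index year, removal of
#' records with missing mandatory fields, and collapse of duplicated
#' patient ids.
#'
#' @param index_year analysis year (default 2008).
#' @param age_min,age_max inclusive age window (default 40-80).
#' @param min_rx_year1 minimum prescription events in `index_year - 1`
#'   (default 4).
#' @param min_rx_index minimum prescription events in `index_year`
#'   (default 1).
#' @param require_in_county drop patients outside the study county
#'   (default TRUE).
#' @param exclude_deceased drop presumed-deceased patients (default TRUE).
#' @return object of class `zolnet_criteria`.
#' @export
cohort_criteria <- function(index_year = 2008, age_min = 40, age_max = 80,
                            min_rx_year1 = 4, min_rx_index = 1,
                            require_in_county = TRUE,
                            exclude_deceased = TRUE) {
  check_count(min_rx_year1, "min_rx_year1")
  check_count(min_rx_index, "min_rx_index")
  if (age_min > age_max) config_abort("age_min", "must not exceed age_max")
  structure(list(index_year = as.integer(index_year),
                 age_min = age_min, age_max = age_max,
                 min_rx_year1 = as.integer(min_rx_year1),
                 min_rx_index = as.integer(min_rx_index),
                 require_in_county = isTRUE(require_in_county),
                 exclude_deceased = isTRUE(exclude_deceased)),
            class = "zolnet_criteria")
}

as_criteria <- function(criteria) {
  if (inherits(criteria, "zolnet_criteria")) return(criteria)
  if (is.list(criteria)) {
    known <- names(formals(cohort_criteria))
    bad <- setdiff(names(criteria), known)
    if (length(bad) > 0) {
      config_abort(bad[1], "is not a recognised cohort criterion")
    }
    return(do.call(cohort_criteria, criteria))
  }
  abort("`criteria` must be a cohort_criteria() object or a named list",
        class = "zolnet_config_error")
}

#' Count prescription events for one patient-year
#'
#' A prescription event is a visit record with `tablets_dispensed > 0`;
#' zero-tablet records are visits without dispensing and do not count.
#'
#' @param visits visit tibble (as from [generate_visits()]).
#' @param patient_id a single patient id; an id absent from `visits`
#'   counts 0.
#' @param year calendar year.
#' @return integer count.
#' @export
annual_prescription_count <- function(visits, patient_id, year) {
  pid <- patient_id
  sum(visits$patient_id == pid &
        as.integer(format(visits$visit_date, "%Y")) == year &
        visits$tablets_dispensed > 0, na.rm = TRUE)
}

# per-patient prescription-event counts for one year (vectorised)
rx_counts_by_patient <- function(visits, year) {
  v <- visits[as.integer(format(visits$visit_date, "%Y")) == year &
                visits$tablets_dispensed > 0, , drop = FALSE]
  tab <- table(v$patient_id)
  setNames(as.integer(tab), names(tab))
}

#' Apply the cohort-selection funnel
#'
#' Applies the inclusion/exclusion filters in a fixed order — residence,
#' age, deceased, prior-year prescription frequency, index-year presence,
#' missing mandatory fields, duplicated patient ids — and records how many
#' patients each filter removes. A patient failing several filters is
#' counted once, at the first failing filter, so the attrition counts
#' partition the input.
#'
#' @param patients patient attribute tibble (one row per patient record;
#'   duplicated `patient_id`s are collapsed at the final step).
#' @param visits visit tibble.
#' @param criteria a [cohort_criteria()] object or a named list of its
#'   arguments.
#' @param filter_order permutation of the seven filter names; the default
#'   is the flowchart order. Permuting filters cannot change the final
#'   cohort, only the per-step attribution of removals.
#' @return an object of class `cohort_trace`: a list with `trace`
#'   (tibble `filter`, `n_removed`, `n_remaining`), `cohort` (character
#'   patient ids), `patients` (the surviving attribute rows) and
#'   `criteria`. `tidy()` returns the trace.
#' @examples
#' claims <- simulate_claims(generator_config(n_patients = 200, seed = 3))
#' sel <- select_cohort(claims$patients, claims$visits, cohort_criteria())
#' tidy(sel)
#' @export
select_cohort <- function(patients, visits, criteria = cohort_criteria(),
                          filter_order = NULL) {
  criteria <- as_criteria(criteria)
  iy <- criteria$index_year

  mandatory <- c("patient_id", "gender", "age_years", "premium_band",
                 "catastrophic_cert", "chronic_disease")
  mandatory <- intersect(mandatory, names(patients))

  rx1 <- rx_counts_by_patient(visits, iy - 1L)
  rx0 <- rx_counts_by_patient(visits, iy)
  n_rx <- function(ids, counts) {
    out <- counts[ids]
    out[is.na(out)] <- 0L
    unname(out)
  }

  steps <- list(
    residence = function(df) {
      if (!criteria$require_in_county) rep(TRUE, nrow(df))
      else !is.na(df$in_county) & df$in_county
    },
    age = function(df) {
      !is.na(df$age_years) & df$age_years >= criteria$age_min &
        df$age_years <= criteria$age_max
    },
    deceased = function(df) {
      if (!criteria$exclude_deceased) rep(TRUE, nrow(df))
      else is.na(df$deceased) | !df$deceased
    },
    year1_frequency = function(df) {
      n_rx(df$patient_id, rx1) >= criteria$min_rx_year1
    },
    index_year_presence = function(df) {
      n_rx(df$patient_id, rx0) >= criteria$min_rx_index
    },
    missing_fields = function(df) {
      stats::complete.cases(df[mandatory])
    },
    duplicates = function(df) {
      !duplicated(df$patient_id)
    }
  )

  if (!is.null(filter_order)) {
    if (!setequal(filter_order, names(steps)) ||
        length(filter_order) != length(steps)) {
      config_abort("filter_order",
                   "must be a permutation of the seven filter names")
    }
    steps <- steps[filter_order]
  }

  surviving <- patients
  trace <- tibble(filter = character(), n_removed = integer(),
                  n_remaining = integer())
  for (nm in names(steps)) {
    keep <- steps[[nm]](surviving)
    trace <- dplyr::add_row(trace, filter = nm,
                            n_removed = sum(!keep),
                            n_remaining = sum(keep))
    surviving <- surviving[keep, , drop = FALSE]
  }

  structure(list(trace = trace,
                 cohort = surviving$patient_id,
                 patients = as_tibble(surviving),
                 criteria = criteria,
                 n_input = nrow(patients)),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", x$n_input, " records in, ",
      length(x$cohort), " patients in cohort\n", sep = "")
  print(x$trace)
  invisible(x)
}

#' @rdname select_cohort
#' @param x a `cohort_trace`.
#' @param ... unused.
#' @method tidy cohort_trace
#' @export
tidy.cohort_trace <- function(x, ...) x$trace

#' @rdname select_cohort
#' @method glance cohort_trace
#' @export
glance.cohort_trace <- function(x, ...) {
  tibble(n_input = x$n_input,
         n_cohort = length(x$cohort),
         n_removed = x$n_input - length(x$cohort),
         index_year = x$criteria$index_year)
}
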