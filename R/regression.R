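# Multivariable logistic regression of high-dose membership on the
# demographic/insurance/clinical covariates, reported as adjusted odds
# ratios (aOR) with Wald 95% confidence intervals, plus an optional
# SPSS-style stepwise selection (forward entry on Wald p with backward
# removal checking).

#' Regression specification
#'
#' Defines the outcome coding (low = 0, high = 1), the candidate covariate
#' terms with their reference levels (female; age 71-80; premium band
#' `high`; no certification; no chronic disease; no visit-reason flag),
#' and the selection procedure.
#'
#' @param covariates character vector of term names among `"gender"`,
#'   `"age_band"`, `"premium_band"`, `"catastrophic_cert"`,
#'   `"chronic_disease"` and the `reason_*` indicator columns.
#' @param selection `"none"` (fit all terms) or `"stepwise"`.
#' @param entry_p Wald p-value required to enter (default 0.05).
#' @param stay_p Wald p-value required to stay (default 0.10).
#' @return object of class `zolnet_regression_spec`.
#' @export
regression_spec <- function(covariates = default_regression_covariates(),
                            selection = c("none", "stepwise"),
                            entry_p = 0.05, stay_p = 0.10) {
  selection <- rlang::arg_match(selection)
  # stay_p = entry_p = 1 is the degenerate "keep everything" setting that
  # reduces stepwise selection to the full-model fit
  if (!(entry_p > 0 && entry_p <= stay_p && stay_p <= 1)) {
    config_abort("entry_p", "must satisfy 0 < entry_p <= stay_p <= 1")
  }
  structure(list(covariates = covariates, selection = selection,
                 entry_p = entry_p, stay_p = stay_p),
            class = "zolnet_regression_spec")
}

#' @rdname regression_spec
#' @export
default_regression_covariates <- function() {
  c("gender", "age_band", "premium_band", "catastrophic_cert",
    "chronic_disease",
    "reason_mood_disorder", "reason_hypertension",
    "reason_other_emotional_disturbances", "reason_gastrointestinal_disease",
    "reason_coronary_heart_disease", "reason_degenerative_arthritis")
}

#' Assemble the regression analysis frame
#'
#' Joins patient attributes with dose classifications, derives the age
#' band, and releveles factors so each term's reference is the one used in
#' the aOR table (female, 71-80, premium `high`, FALSE flags).
#'
#' @param patients patient attribute tibble.
#' @param dose_groups tibble from [classify_dose()].
#' @return tibble with one row per classified patient: `group` plus the
#'   candidate covariates.
#' @export
regression_data <- function(patients, dose_groups) {
  df <- dplyr::inner_join(as_tibble(dose_groups)[c("patient_id", "group")],
                          patients, by = "patient_id")
  df$age_band <- stats::relevel(age_band(df$age_years), ref = "71-80")
  df$premium_band <- stats::relevel(factor(df$premium_band,
                                           levels = c("low", "mid", "high")),
                                    ref = "high")
  df$gender <- factor(df$gender, levels = c("female", "male"))
  dplyr::select(df, "patient_id", "group",
                dplyr::any_of(c("gender", "age_band", "premium_band",
                                "catastrophic_cert", "chronic_disease")),
                dplyr::starts_with("reason_"))
}

#' Fit the multivariable logistic model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], convergence tolerance 1e-10, up to 100
#' iterations) of high-dose membership on the specified covariates.
#' Standard errors come from the observed information; confidence
#' intervals are Wald intervals `exp(coef +/- 1.96 * SE)`.
#'
#' Quasi-complete separation (a coefficient walking past +/-15) and rank
#' deficiency are reported as errors naming the offending columns rather
#' than silently returning unstable estimates.
#'
#' @param data tibble from [regression_data()] (or any tibble with a
#'   `group` low/high column and the covariates).
#' @param spec a [regression_spec()].
#' @return object of class `zol_logistic`; use [tidy()] for the per-level
#'   aOR table and [glance()] for model-level statistics.
#' @examples
#' claims <- simulate_claims(generator_config(n_patients = 1500, seed = 11))
#' sel <- select_cohort(claims$patients, claims$visits)
#' dose <- classify_dose(claims$visits, sel)
#' fit <- fit_logistic(regression_data(claims$patients, dose))
#' tidy(fit)
#' @export
fit_logistic <- function(data, spec = regression_spec()) {
  terms <- intersect(spec$covariates, names(data))
  fit_logistic_terms(data, terms, spec)
}

fit_logistic_terms <- function(data, terms, spec) {
  y <- as.integer(factor(data$group, levels = c("low", "high"))) - 1L
  if (anyNA(y)) abort("`group` must be low/high", class = "zolnet_config_error")
  if (sum(y) == 0 || sum(y) == length(y)) {
    abort("outcome needs at least one event and one non-event",
          class = "zolnet_fit_error")
  }
  df <- data
  df$.y <- y
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  form <- as.formula(paste(".y ~", rhs))

  X <- model.matrix(form, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("rank-deficient design: collinear column(s) ",
                 paste(dropped, collapse = ", ")),
          class = "zolnet_fit_error")
  }

  fit <- suppressWarnings(
    glm(form, family = binomial(), data = df,
        control = list(epsilon = 1e-10, maxit = 100))
  )
  cf <- coef(fit)
  big <- names(cf)[abs(cf) > 15 & names(cf) != "(Intercept)"]
  if (length(big) > 0) {
    abort(paste0("separation detected for covariate(s) ",
                 paste(big, collapse = ", "),
                 " (|coefficient| > 15)"),
          class = "zolnet_separation_error")
  }

  structure(list(fit = fit, terms = terms, spec = spec,
                 selected_terms = terms,
                 n = nrow(df), n_event = sum(y),
                 converged = fit$converged),
            class = "zol_logistic")
}

#' @export
print.zol_logistic <- function(x, ...) {
  cat(sprintf("<zol_logistic> n=%d (%d high-dose), terms: %s\n",
              x$n, x$n_event,
              if (length(x$selected_terms)) paste(x$selected_terms, collapse = ", ")
              else "(intercept only)"))
  print(tidy(x))
  invisible(x)
}

#' Tidy the fitted model into an aOR table
#'
#' One row per non-reference coefficient (intercept excluded): log-odds
#' estimate, SE, adjusted odds ratio `exp(estimate)`, Wald 95% CI and
#' two-sided Wald p-value.
#'
#' @param x a `zol_logistic` object.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`, `std.error`, `aOR`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @method tidy zol_logistic
#' @export
tidy.zol_logistic <- function(x, ...) {
  cf <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  keep <- names(cf) != "(Intercept)"
  tibble(
    term = names(cf)[keep],
    estimate = as.numeric(cf[keep]),
    std.error = as.numeric(se[keep]),
    aOR = exp(as.numeric(cf[keep])),
    conf.low = exp(as.numeric(cf[keep]) - 1.96 * as.numeric(se[keep])),
    conf.high = exp(as.numeric(cf[keep]) + 1.96 * as.numeric(se[keep])),
    p.value = 2 * pnorm(-abs(as.numeric(cf[keep]) / as.numeric(se[keep])))
  )
}

#' @rdname tidy.zol_logistic
#' @method glance zol_logistic
#' @export
glance.zol_logistic <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event,
         logLik = as.numeric(logLik(x$fit)),
         deviance = x$fit$deviance,
         df.residual = x$fit$df.residual,
         converged = x$converged,
         n_terms = length(x$selected_terms))
}

# term-level Wald chi-square test (all dummy columns of the term jointly)
term_wald_p <- function(fit, term) {
  asg <- attr(model.matrix(fit), "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  j <- which(labs == term)
  idx <- which(asg == j)
  if (length(idx) == 0) return(NA_real_)
  b <- coef(fit)[idx]
  V <- vcov(fit)[idx, idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  as.numeric(pchisq(stat, df = length(idx), lower.tail = FALSE))
}

#' Stepwise covariate selection
#'
#' Forward selection with backward checking on term-level Wald tests:
#' starting from the intercept-only model, at each step the candidate term
#' with the smallest Wald p-value below `entry_p` is added; after each
#' addition, any included term whose p-value exceeds `stay_p` is removed;
#' the procedure stops when no term enters or leaves. Ties are broken by
#' term name, so the result is deterministic for a given data set.
#'
#' @inheritParams fit_logistic
#' @return a `zol_logistic` fitted on the selected terms, with
#'   `selected_terms` recording the outcome of selection (possibly empty:
#'   intercept-only model).
#' @export
stepwise_select <- function(data, spec = regression_spec(selection = "stepwise")) {
  candidates <- sort(intersect(spec$covariates, names(data)))
  included <- character()
  seen <- character()  # guard against enter/remove oscillation

  repeat {
    changed <- FALSE
    # forward: best candidate by Wald p of its term in the augmented model
    remaining <- setdiff(candidates, included)
    if (length(remaining) > 0) {
      pvals <- vapply(remaining, function(tm) {
        f <- try(fit_logistic_terms(data, c(included, tm), spec),
                 silent = TRUE)
        if (inherits(f, "try-error")) return(NA_real_)
        term_wald_p(f$fit, tm)
      }, numeric(1))
      ok <- !is.na(pvals) & pvals < spec$entry_p
      if (any(ok)) {
        best <- remaining[ok][order(pvals[ok], remaining[ok])][1]
        included <- c(included, best)
        changed <- TRUE
      }
    }
    # backward: drop the worst included term above stay_p
    if (length(included) > 0) {
      f <- fit_logistic_terms(data, included, spec)
      pin <- vapply(included, function(tm) term_wald_p(f$fit, tm), numeric(1))
      bad <- !is.na(pin) & pin > spec$stay_p
      if (any(bad)) {
        worst <- included[bad][order(-pin[bad], included[bad])][1]
        included <- setdiff(included, worst)
        changed <- TRUE
      }
    }
    state <- paste(sort(included), collapse = "|")
    if (!changed || state %in% seen) break
    seen <- c(seen, state)
  }

  out <- fit_logistic_terms(data, included, spec)
  out$selected_terms <- included
  out
}
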