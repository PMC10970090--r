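# Descriptive tables, per-group network summaries, file exports and the
# end-to-end pipeline.

#' Descriptive characteristics table
#'
#' Counts and percentages per covariate level, in the layout of a clinical
#' "Table 1": with `by_group = FALSE` percentages use the whole cohort as
#' denominator; with `by_group = TRUE` counts are split by dose group and
#' percentages are computed within each group. Percentages are rounded
#' half-up to `digits` decimals; a group of size zero reports blank
#' (`NA`) percentages rather than zeros.
#'
#' @param patients patient attribute tibble (cohort members).
#' @param dose_groups tibble from [classify_dose()].
#' @param by_group split by dose group (default FALSE).
#' @param digits decimal places for percentages (default 2).
#' @return tibble with columns `covariate`, `level`, and either `n`, `pct`
#'   or `n_low`, `pct_low`, `n_high`, `pct_high`.
#' @examples
#' claims <- simulate_claims(generator_config(n_patients = 400, seed = 2))
#' sel <- select_cohort(claims$patients, claims$visits)
#' dose <- classify_dose(claims$visits, sel)
#' descriptive_table(sel$patients, dose)
#' @export
descriptive_table <- function(patients, dose_groups = NULL,
                              by_group = FALSE, digits = 2) {
  df <- as_tibble(patients)
  if (by_group) {
    if (is.null(dose_groups)) {
      abort("`dose_groups` is required when `by_group = TRUE`",
            class = "zolnet_config_error")
    }
    df <- dplyr::inner_join(df,
                            as_tibble(dose_groups)[c("patient_id", "group")],
                            by = "patient_id")
  }

  spec <- list(
    gender = function(d) factor(d$gender, levels = c("female", "male")),
    age = function(d) age_band(d$age_years),
    premium = function(d) factor(d$premium_band,
                                 levels = c("low", "mid", "high")),
    catastrophic_cert = function(d) factor(ifelse(d$catastrophic_cert,
                                                  "yes", "no"),
                                           levels = c("yes", "no")),
    chronic_disease = function(d) factor(ifelse(d$chronic_disease,
                                                "yes", "no"),
                                         levels = c("yes", "no"))
  )
  for (rc in intersect(reason_cols(), names(df))) {
    local({
      col <- rc
      spec[[col]] <<- function(d) factor(ifelse(d[[col]], "yes", "no"),
                                         levels = c("yes", "no"))
    })
  }

  one_block <- function(cov_name, f) {
    if (nrow(df) == 0) {
      return(tibble(covariate = character(), level = character()))
    }
    lv <- f(df)
    if (!by_group) {
      tab <- table(lv)
      tibble(covariate = cov_name, level = names(tab),
             n = as.integer(tab),
             pct = percent_of(as.integer(tab), nrow(df), digits))
    } else {
      tl <- table(lv[df$group == "low"])
      th <- table(lv[df$group == "high"])
      tibble(covariate = cov_name, level = names(tl),
             n_low = as.integer(tl),
             pct_low = percent_of(as.integer(tl), sum(tl), digits),
             n_high = as.integer(th),
             pct_high = percent_of(as.integer(th), sum(th), digits))
    }
  }

  out <- purrr::imap_dfr(spec, ~ one_block(.y, .x))
  if (nrow(df) == 0) {
    out <- if (by_group) {
      tibble(covariate = character(), level = character(),
             n_low = integer(), pct_low = numeric(),
             n_high = integer(), pct_high = numeric())
    } else {
      tibble(covariate = character(), level = character(),
             n = integer(), pct = numeric())
    }
  }
  out
}

#' aOR table shaped for reporting
#'
#' Expands a fitted model into the familiar published layout: one row per
#' covariate level including reference rows (aOR exactly 1, blank CI),
#' per-group counts, half-up rounded aOR and CI, p-values and
#' significance stars.
#'
#' @param fit a `zol_logistic` object.
#' @param data the analysis frame the model was fitted on (for the
#'   per-group level counts).
#' @return tibble with columns `term`, `level`, `n_low`, `n_high`, `aOR`,
#'   `conf.low`, `conf.high`, `p.value`, `sig`, `reference`.
#' @export
regression_table <- function(fit, data) {
  td <- tidy(fit)
  stars <- function(p) {
    dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                     p < 0.05 ~ "*", TRUE ~ "")
  }
  rows <- list()
  for (tm in fit$selected_terms) {
    x <- data[[tm]]
    logical_term <- is.logical(x)
    if (logical_term) x <- factor(ifelse(x, "yes", "no"),
                                  levels = c("no", "yes"))
    x <- droplevels(as.factor(x))
    ref <- levels(x)[1]
    for (lv in levels(x)) {
      n_low <- sum(x == lv & data$group == "low")
      n_high <- sum(x == lv & data$group == "high")
      if (lv == ref) {
        rows[[length(rows) + 1]] <- tibble(
          term = tm, level = lv, n_low = n_low, n_high = n_high,
          aOR = 1, conf.low = NA_real_, conf.high = NA_real_,
          p.value = NA_real_, sig = "", reference = TRUE)
      } else {
        coefname <- if (logical_term) paste0(tm, "TRUE") else paste0(tm, lv)
        r <- td[td$term == coefname, ]
        if (nrow(r) == 0) next
        rows[[length(rows) + 1]] <- tibble(
          term = tm, level = lv, n_low = n_low, n_high = n_high,
          aOR = round_half_up(r$aOR, 2),
          conf.low = round_half_up(r$conf.low, 2),
          conf.high = round_half_up(r$conf.high, 2),
          p.value = r$p.value, sig = stars(r$p.value), reference = FALSE)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Export a network to GraphML and edge-list CSV
#'
#' Node attributes `level` and `in_county`, edge attributes `raw_weight`
#' and `display_weight` are carried into the GraphML file, so the graph
#' can be styled in any downstream viewer.
#'
#' @param network an `institution_network`.
#' @param graphml_path,edges_path output paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the paths written.
#' @export
export_network <- function(network, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    readr::write_csv(network$edges, edges_path)
  }
  invisible(c(graphml = graphml_path, edges = edges_path))
}

#' Pipeline configuration
#'
#' @param generator a [generator_config()].
#' @param criteria a [cohort_criteria()]; defaults to the generator's
#'   index year.
#' @param threshold_tablets dose threshold (default 360).
#' @param network_mode `"precedence"` or `"consecutive"`.
#' @param normalized_betweenness logical (default FALSE).
#' @param regression a [regression_spec()].
#' @param seed global seed (default the generator's).
#' @return object of class `zolnet_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            criteria = cohort_criteria(index_year = generator$index_year),
                            threshold_tablets = 360,
                            network_mode = c("precedence", "consecutive"),
                            normalized_betweenness = FALSE,
                            regression = regression_spec(),
                            seed = generator$seed) {
  network_mode <- rlang::arg_match(network_mode)
  structure(list(generator = generator, criteria = criteria,
                 threshold_tablets = threshold_tablets,
                 network_mode = network_mode,
                 normalized_betweenness = isTRUE(normalized_betweenness),
                 regression = regression, seed = as.integer(seed)),
            class = "zolnet_pipeline_config")
}

# CSV with a seed-stamped comment header, round-trippable via read_output_csv
write_output_csv <- function(df, path, seed) {
  cat(sprintf("# seed: %d\n", seed), readr::format_csv(df),
      sep = "", file = path)
  invisible(path)
}

#' Read a pipeline output CSV
#'
#' @param path CSV written by [run_pipeline()] (seed comment header).
#' @return tibble.
#' @export
read_output_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulation, cohort selection, dose classification, per-group network
#' construction (with and without psychiatrist aggregation), the
#' regression, and all file outputs: `patients.csv`, `visits.csv`,
#' `attrition.csv`, `dose_groups.csv`, per-group GraphML + edge CSVs,
#' `metrics.json` (density plus top-10 in-degree/betweenness rankings per
#' group, ties broken by node id), `regression_table.csv` and
#' `manifest.json` (seed, config hash, file list, package version).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); default a fresh
#'   temporary directory.
#' @param quiet suppress stage messages (default TRUE).
#' @return (invisibly) a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("zolnet_run_"),
                         quiet = TRUE) {
  stopifnot(inherits(config, "zolnet_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  seed <- config$seed

  say("simulate", "generating %d patients", config$generator$n_patients)
  claims <- simulate_claims(config$generator, seed)
  write_output_csv(claims$patients, file.path(out_dir, "patients.csv"), seed)
  write_output_csv(claims$visits, file.path(out_dir, "visits.csv"), seed)

  say("cohort", "applying selection filters")
  sel <- select_cohort(claims$patients, claims$visits, config$criteria)
  write_output_csv(tidy(sel), file.path(out_dir, "attrition.csv"), seed)

  say("dose", "classifying %d cohort members", length(sel$cohort))
  dose <- classify_dose(claims$visits, sel,
                        index_year = config$criteria$index_year,
                        threshold_tablets = config$threshold_tablets)
  write_output_csv(as_tibble(dose), file.path(out_dir, "dose_groups.csv"), seed)

  say("network", "building per-group networks (%s mode)", config$network_mode)
  metrics_json <- list(seed = seed)
  networks <- list()
  for (psy in c("off", "aggregate")) {
    for (grp in c("low", "high")) {
      net <- build_network(claims$visits, dose, group = grp,
                           mode = config$network_mode, psychiatrists = psy,
                           index_year = config$criteria$index_year)
      key <- paste0(grp, if (psy == "aggregate") "_psychiatrists" else "")
      networks[[key]] <- net
      export_network(net,
                     graphml_path = file.path(out_dir, paste0("network_", key, ".graphml")))
      write_output_csv(net$edges,
                       file.path(out_dir, paste0("edges_", key, ".csv")), seed)
      m <- network_metrics(net, normalized = config$normalized_betweenness)
      metrics_json[[key]] <- list(
        density = network_density(net),
        n_nodes = nrow(net$nodes),
        n_edges = nrow(net$edges),
        top_in_degree = top_nodes(m, "in_degree")[c("node", "in_degree")],
        top_betweenness = top_nodes(m, "betweenness")[c("node", "betweenness")]
      )
    }
  }
  jsonlite::write_json(metrics_json, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("regress", "fitting logistic model (%s selection)",
      config$regression$selection)
  rdata <- regression_data(sel$patients, dose)
  fit <- if (config$regression$selection == "stepwise") {
    stepwise_select(rdata, config$regression)
  } else {
    fit_logistic(rdata, config$regression)
  }
  write_output_csv(regression_table(fit, rdata),
                   file.path(out_dir, "regression_table.csv"), seed)

  say("report", "writing descriptive tables and manifest")
  write_output_csv(descriptive_table(sel$patients),
                   file.path(out_dir, "table1.csv"), seed)
  write_output_csv(descriptive_table(sel$patients, dose, by_group = TRUE),
                   file.path(out_dir, "table2_descriptives.csv"), seed)

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = seed,
    config_hash = rlang::hash(unclass_recursive(config)),
    package_version = as.character(utils::packageVersion("zolnet")),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(out_dir = out_dir, claims = claims, selection = sel,
                 dose = dose, networks = networks, fit = fit,
                 manifest = manifest))
}

# strip classes/attributes so hashing is stable across sessions
unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_recursive)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns the path invisibly;
#'   `read_pipeline_config()` returns a `zolnet_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  gen <- unclass(config$generator)
  gen$coefficients <- lapply(gen$coefficients, function(z) z %||% "calibrate")
  # yaml drops names of atomic vectors; store the named ones as maps
  for (nm in c("gender_split", "age_band_weights", "premium_weights",
               "reason_prevalence", "institution_counts",
               "shopping_intensity", "visit_rate")) {
    gen[[nm]] <- as.list(gen[[nm]])
  }
  yaml::write_yaml(list(
    generator = gen,
    criteria = unclass(config$criteria),
    threshold_tablets = config$threshold_tablets,
    network_mode = config$network_mode,
    normalized_betweenness = config$normalized_betweenness,
    regression = unclass(config$regression),
    seed = config$seed
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- y$generator
  gen$coefficients <- lapply(gen$coefficients,
                             function(z) if (identical(z, "calibrate")) NULL else z)
  for (nm in c("gender_split", "age_band_weights", "premium_weights",
               "reason_prevalence", "institution_counts",
               "shopping_intensity", "visit_rate")) {
    gen[[nm]] <- unlist(gen[[nm]])
  }
  generator <- do.call(generator_config, gen)
  criteria <- do.call(cohort_criteria, y$criteria)
  regression <- do.call(regression_spec, y$regression)
  pipeline_config(generator = generator, criteria = criteria,
                  threshold_tablets = y$threshold_tablets,
                  network_mode = y$network_mode,
                  normalized_betweenness = y$normalized_betweenness,
                  regression = regression, seed = y$seed)
}
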