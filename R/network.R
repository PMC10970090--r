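# Directed institution networks induced by patients' temporally ordered
# zolpidem visits. Two edge semantics are supported:
#
#   precedence  — edge A -> B whenever at least one patient of the group
#                 visits A strictly before B (any prior visit counts);
#                 raw_weight = number of such patients.
#   consecutive — edges from adjacent pairs in each patient's ordered
#                 visit sequence; raw_weight = number of transitions.
#
# Visit order is the package-wide total order (visit_date, institution_id,
# record_id), so ties on the same day break deterministically.

#' Build a per-group institution network
#'
#' Restricts the visit stream to the index year and one dose group, orders
#' each patient's visits deterministically, and induces a directed weighted
#' graph over institutions. With `psychiatrists = "aggregate"` every visit
#' prescribed by a psychiatrist is reassigned to a single
#' `psychiatrist_aggregate` node before edges are formed, mirroring
#' analyses that treat psychiatrists as one actor in the network.
#'
#' Edge weights: `raw_weight` counts patients (precedence mode, default) or
#' transitions (consecutive mode); with `weight_by = "pairs"` precedence
#' mode counts ordered visit pairs instead of patients. `display_weight`
#' is `log10(1 + raw_weight)`, the logarithmic transform conventionally
#' used for drawing edge thickness.
#'
#' @param visits visit tibble.
#' @param dose_groups tibble from [classify_dose()].
#' @param group `"low"` or `"high"`.
#' @param mode `"precedence"` (default) or `"consecutive"`.
#' @param psychiatrists `"off"` (default) or `"aggregate"`.
#' @param index_year analysis year (default the classification's).
#' @param county_only drop visits at out-of-county institutions first
#'   (default FALSE; out-of-county nodes are kept and flagged).
#' @param weight_by `"patients"` (default) or `"pairs"`; precedence mode
#'   only.
#' @return object of class `institution_network`: list with `nodes`
#'   (tibble `node`, `level`, `in_county`), `edges` (tibble `from`, `to`,
#'   `raw_weight`, `display_weight`), `group`, `mode`, `psychiatrists`,
#'   `n_patients`, `n_visits`. `tidy()` returns the edges, `glance()` the
#'   density and counts.
#' @examples
#' claims <- simulate_claims(generator_config(n_patients = 300, seed = 5))
#' sel <- select_cohort(claims$patients, claims$visits)
#' dose <- classify_dose(claims$visits, sel)
#' net <- build_network(claims$visits, dose, group = "high")
#' glance(net)
#' @export
build_network <- function(visits, dose_groups, group = c("high", "low"),
                          mode = c("precedence", "consecutive"),
                          psychiatrists = c("off", "aggregate"),
                          index_year = attr(dose_groups, "index_year") %||% 2008,
                          county_only = FALSE,
                          weight_by = c("patients", "pairs")) {
  group <- rlang::arg_match(group)
  mode <- rlang::arg_match(mode)
  psychiatrists <- rlang::arg_match(psychiatrists)
  weight_by <- rlang::arg_match(weight_by)

  ids <- dose_groups$patient_id[dose_groups$group == group]
  v <- visits[visits$patient_id %in% ids &
                as.integer(format(visits$visit_date, "%Y")) == index_year, ,
              drop = FALSE]
  if (county_only) v <- v[v$in_county, , drop = FALSE]

  if (length(ids) == 0) {
    warn(sprintf("dose group '%s' has no patients; returning empty network",
                 group))
  }

  if (psychiatrists == "aggregate" && nrow(v) > 0) {
    agg <- v$prescriber_is_psychiatrist
    v$institution_id[agg] <- "PSY"
    v$institution_level[agg] <- "psychiatrist_aggregate"
    v$in_county[agg] <- TRUE
  }

  # deterministic total order of each patient's visits
  if (!"record_id" %in% names(v)) v$record_id <- seq_len(nrow(v))
  v <- dplyr::arrange(v, .data$patient_id, .data$visit_date,
                      .data$institution_id, .data$record_id)

  nodes <- v |>
    dplyr::distinct(node = .data$institution_id,
                    level = .data$institution_level,
                    in_county = .data$in_county) |>
    dplyr::distinct(.data$node, .keep_all = TRUE) |>
    dplyr::arrange(.data$node)

  edges <- if (nrow(v) == 0) {
    tibble(from = character(), to = character(), raw_weight = integer())
  } else if (mode == "consecutive") {
    v |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(to = dplyr::lead(.data$institution_id)) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$to), .data$institution_id != .data$to) |>
      dplyr::count(from = .data$institution_id, .data$to,
                   name = "raw_weight")
  } else {
    # precedence: A -> B iff the patient's first visit at A comes before
    # some visit at B, i.e. first-position(A) < last-position(B)
    pos <- v |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(.pos = dplyr::row_number()) |>
      dplyr::group_by(.data$patient_id, .data$institution_id) |>
      dplyr::summarise(first_pos = min(.data$.pos),
                       last_pos = max(.data$.pos),
                       n_visits = dplyr::n(), .groups = "drop")
    pairs <- dplyr::inner_join(
      pos, pos, by = "patient_id", suffix = c("_a", "_b"),
      relationship = "many-to-many") |>
      dplyr::filter(.data$institution_id_a != .data$institution_id_b,
                    .data$first_pos_a < .data$last_pos_b)
    if (weight_by == "patients") {
      dplyr::count(pairs, from = .data$institution_id_a,
                   to = .data$institution_id_b, name = "raw_weight")
    } else {
      # ordered visit pairs (a at A, b at B, a before b); with positions of
      # A-visits p and B-visits q: #{(p, q): p < q}
      vp <- v |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::mutate(.pos = dplyr::row_number()) |>
        dplyr::ungroup() |>
        dplyr::select("patient_id", "institution_id", ".pos")
      dplyr::inner_join(vp, vp, by = "patient_id",
                        suffix = c("_a", "_b"),
                        relationship = "many-to-many") |>
        dplyr::filter(.data$institution_id_a != .data$institution_id_b,
                      .data$.pos_a < .data$.pos_b) |>
        dplyr::count(from = .data$institution_id_a,
                     to = .data$institution_id_b, name = "raw_weight")
    }
  }
  edges <- edges |>
    dplyr::mutate(raw_weight = as.integer(.data$raw_weight),
                  display_weight = log10(1 + .data$raw_weight)) |>
    dplyr::arrange(.data$from, .data$to)

  structure(list(nodes = nodes, edges = edges, group = group, mode = mode,
                 psychiatrists = psychiatrists, index_year = index_year,
                 n_patients = length(unique(v$patient_id)),
                 n_visits = nrow(v)),
            class = "institution_network")
}

#' @export
print.institution_network <- function(x, ...) {
  cat(sprintf("<institution_network> group=%s mode=%s psychiatrists=%s\n",
              x$group, x$mode, x$psychiatrists))
  cat(sprintf("  %d nodes, %d edges, %d patients, %d visits; density %.3f\n",
              nrow(x$nodes), nrow(x$edges), x$n_patients, x$n_visits,
              network_density(x)))
  invisible(x)
}

#' @rdname build_network
#' @param x an `institution_network`.
#' @param ... unused.
#' @method tidy institution_network
#' @export
tidy.institution_network <- function(x, ...) x$edges

#' @rdname build_network
#' @method glance institution_network
#' @export
glance.institution_network <- function(x, ...) {
  tibble(group = x$group, mode = x$mode, psychiatrists = x$psychiatrists,
         n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_patients = x$n_patients, n_visits = x$n_visits,
         density = network_density(x))
}

# igraph representation (isolated nodes preserved)
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[c("from", "to", "raw_weight", "display_weight")],
    directed = TRUE, vertices = network$nodes)
}

#' Construct an institution network from node and edge tables
#'
#' Low-level constructor for building a network directly from an edge
#' list, e.g. when re-analysing an exported graph. Self-loops are
#' rejected; missing node attributes default to `clinic` / in-county.
#'
#' @param edges tibble with columns `from`, `to` and optionally
#'   `raw_weight` (default 1).
#' @param nodes optional tibble with columns `node` and optionally
#'   `level`, `in_county`; defaults to the nodes appearing in `edges`.
#' @param group,mode labels carried on the object (defaults `"high"`,
#'   `"precedence"`).
#' @return an `institution_network`.
#' @export
as_institution_network <- function(edges, nodes = NULL, group = "high",
                                   mode = "precedence") {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    config_abort("edges", "must have `from` and `to` columns")
  }
  if (any(edges$from == edges$to)) {
    config_abort("edges", "must not contain self-loops")
  }
  if (!"raw_weight" %in% names(edges)) edges$raw_weight <- 1L
  edges$raw_weight <- as.integer(edges$raw_weight)
  if (any(edges$raw_weight < 1)) {
    config_abort("edges", "raw_weight must be >= 1")
  }
  edges$display_weight <- log10(1 + edges$raw_weight)
  if (is.null(nodes)) {
    nodes <- tibble(node = sort(unique(c(edges$from, edges$to))))
  } else {
    nodes <- as_tibble(nodes)
  }
  if (!"level" %in% names(nodes)) nodes$level <- "clinic"
  if (!"in_county" %in% names(nodes)) nodes$in_county <- TRUE
  structure(list(nodes = nodes[c("node", "level", "in_county")],
                 edges = dplyr::arrange(edges[c("from", "to", "raw_weight",
                                                "display_weight")],
                                        .data$from, .data$to),
                 group = group, mode = mode, psychiatrists = "off",
                 index_year = NA_integer_,
                 n_patients = NA_integer_, n_visits = NA_integer_),
            class = "institution_network")
}
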