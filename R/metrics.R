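#' Directed network density
#'
#' Number of directed edges divided by `n * (n - 1)` possible ordered
#' pairs; defined as 0 for networks with fewer than two nodes. A value
#' near 1 means patients' medication-seeking connects almost every ordered
#' pair of institutions.
#'
#' @param network an `institution_network` from [build_network()].
#' @return a number in `[0, 1]`.
#' @export
network_density <- function(network) {
  n <- nrow(network$nodes)
  if (n < 2) return(0)
  nrow(network$edges) / (n * (n - 1))
}

#' Node in-degree
#'
#' Number of distinct predecessor institutions per node (unweighted
#' incoming edges): how many other institutions patients had visited
#' before arriving at this one.
#'
#' @inheritParams network_density
#' @return named integer vector over nodes.
#' @export
network_in_degree <- function(network) {
  g <- as_igraph(network)
  d <- igraph::degree(g, mode = "in", loops = FALSE)
  setNames(as.integer(d), names(d))
}

#' Betweenness centrality
#'
#' For each node v, the sum over ordered pairs (s, t) with s != t != v of
#' the fraction of shortest directed s-to-t paths that pass through v;
#' pairs with no connecting path contribute 0. Shortest paths are
#' unweighted (edge weights only affect display). Unnormalised scores are
#' the default; `normalized = TRUE` divides by `(n - 1) * (n - 2)`.
#'
#' @inheritParams network_density
#' @param normalized divide by `(n - 1) * (n - 2)` (default FALSE).
#' @return named numeric vector over nodes.
#' @export
network_betweenness <- function(network, normalized = FALSE) {
  g <- as_igraph(network)
  b <- igraph::betweenness(g, directed = TRUE, weights = NA)
  n <- nrow(network$nodes)
  if (normalized) {
    b <- if (n > 2) b / ((n - 1) * (n - 2)) else b * 0
  }
  setNames(as.numeric(b), names(b))
}

#' All network metrics at once
#'
#' @inheritParams network_betweenness
#' @return object of class `network_metrics`: a tibble with one row per
#'   node (`node`, `level`, `in_county`, `in_degree`, `betweenness`) and
#'   attributes `density`, `group`, `mode`. `glance()` summarises.
#' @examples
#' claims <- simulate_claims(generator_config(n_patients = 300, seed = 5))
#' sel <- select_cohort(claims$patients, claims$visits)
#' dose <- classify_dose(claims$visits, sel)
#' m <- network_metrics(build_network(claims$visits, dose, "high"))
#' glance(m)
#' @export
network_metrics <- function(network, normalized = FALSE) {
  ind <- network_in_degree(network)
  btw <- network_betweenness(network, normalized = normalized)
  out <- network$nodes |>
    dplyr::mutate(in_degree = as.integer(ind[.data$node]),
                  betweenness = as.numeric(btw[.data$node])) |>
    dplyr::arrange(dplyr::desc(.data$in_degree), .data$node)
  attr(out, "density") <- network_density(network)
  attr(out, "group") <- network$group
  attr(out, "mode") <- network$mode
  attr(out, "normalized") <- normalized
  class(out) <- c("network_metrics", class(out))
  out
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> group=%s density=%.3f\n",
              attr(x, "group") %||% "?", attr(x, "density")))
  NextMethod()
}

#' @rdname network_metrics
#' @param x a `network_metrics` object.
#' @param ... unused.
#' @method glance network_metrics
#' @export
glance.network_metrics <- function(x, ...) {
  tibble(group = attr(x, "group"), density = attr(x, "density"),
         n_nodes = nrow(x),
         max_in_degree = if (nrow(x)) max(x$in_degree) else NA_integer_,
         max_betweenness = if (nrow(x)) max(x$betweenness) else NA_real_)
}

#' Top-k nodes by a metric
#'
#' Ranking helper for report tables; ties broken by node id so rankings
#' are reproducible.
#'
#' @param metrics a [network_metrics()] tibble.
#' @param by `"in_degree"` or `"betweenness"`.
#' @param k number of nodes (default 10).
#' @return tibble of the top `k` rows.
#' @export
top_nodes <- function(metrics, by = c("in_degree", "betweenness"), k = 10) {
  by <- rlang::arg_match(by)
  metrics |>
    as_tibble() |>
    dplyr::arrange(dplyr::desc(.data[[by]]), .data$node) |>
    head(k)
}
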