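# Independent graph-metric oracle used to cross-check the package's
# density / in-degree / betweenness implementation.
#
# Distances come from boolean powers of the adjacency matrix; the number
# of shortest s->t paths is the (s, t) entry of A^d at d = dist(s, t)
# (every walk whose length equals the shortest distance is a simple
# shortest path). Betweenness then follows from the counting identity
#   sigma_st(v) = sigma_sv * sigma_vt   when d(s,v) + d(v,t) = d(s,t),
# summed over ordered pairs. No Brandes-style accumulation is involved.

oracle_metrics <- function(adj) {
  n <- nrow(adj)
  diag(adj) <- 0
  density <- if (n < 2) 0 else sum(adj) / (n * (n - 1))
  in_degree <- colSums(adj > 0)

  D <- matrix(Inf, n, n)
  diag(D) <- 0
  powers <- vector("list", max(n - 1, 1))
  Ak <- adj
  for (d in seq_len(max(n - 1, 1))) {
    powers[[d]] <- Ak
    newly <- Ak > 0 & !is.finite(D)
    D[newly] <- d
    Ak <- Ak %*% adj
  }
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t && is.finite(D[s, t])) {
      sigma[s, t] <- powers[[D[s, t]]][s, t]
    }
  }

  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v) next
      if (!is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
    btw[v] <- acc
  }
  list(density = density, in_degree = as.integer(in_degree),
       betweenness = btw)
}

random_digraph <- function(n = NULL, p = NULL) {
  if (is.null(n)) n <- sample(2:8, 1)
  if (is.null(p)) p <- runif(1, 0.1, 0.6)
  adj <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(adj) <- 0L
  adj
}

adj_to_network <- function(adj) {
  n <- nrow(adj)
  ids <- sprintf("N%02d", seq_len(n))
  idx <- which(adj > 0, arr.ind = TRUE)
  edges <- tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]])
  nodes <- tibble::tibble(node = ids)
  as_institution_network(edges, nodes)
}
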