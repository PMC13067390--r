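#' Convert a connectivity matrix to a nonnegative weighted graph
#'
#' Standard preparation for weighted graph metrics: negative z-values are set
#' to zero (the metrics are defined for nonnegative weights) and the
#' remaining weights are divided by the matrix maximum so all weights lie in
#' `[0, 1]` and inverse-weight distances are at least 1.
#'
#' @param fc symmetric connectivity matrix (zero diagonal).
#' @return symmetric nonnegative weight matrix with zero diagonal; all-zero
#'   when no positive weights exist.
#' @export
to_graph <- function(fc) {
  stopifnot(is.matrix(fc), nrow(fc) == ncol(fc))
  w <- fc
  w[w < 0] <- 0
  diag(w) <- 0
  mx <- max(w)
  if (mx > 0) w <- w / mx
  w
}

as_igraph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of the inverse weighted shortest-path
#' length, with edge length `1/weight`; disconnected pairs contribute 0.
#' With weights in `[0, 1]` (see [to_graph()]) efficiency lies in `[0, 1]`,
#' reaching 1 on a complete unit-weight graph. Higher values indicate a more
#' integrated network.
#'
#' @param w nonnegative symmetric weight matrix, zero diagonal.
#' @return efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  n <- nrow(w)
  if (n < 2) stop("global efficiency requires at least 2 nodes")
  if (all(w == 0)) return(0)
  g <- as_igraph(w)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Modularity Q of a given partition
#'
#' Newman's weighted modularity
#' `Q = sum_c (e_cc / W - gamma * (a_c / W)^2)` where `e_cc` is the total
#' within-community weight, `a_c` the community's total degree and `W` the
#' total weight.
#'
#' @param w nonnegative symmetric weight matrix, zero diagonal.
#' @param membership integer community label per node.
#' @param gamma resolution parameter (default 1).
#' @return Q in `[-1, 1]`.
#' @export
modularity_q <- function(w, membership, gamma = 1) {
  stopifnot(length(membership) == nrow(w))
  g <- as_igraph(w)
  igraph::modularity(g, as.integer(factor(membership)),
                     weights = igraph::E(g)$weight, resolution = gamma)
}

#' Maximized modularity (Louvain, seeded restarts)
#'
#' Maximizes weighted modularity with the Louvain heuristic at resolution
#' `gamma`, taking the best of `n_repeats` seeded restarts (ties broken by
#' highest Q, then by lexicographically smallest canonical label sequence).
#' Higher values indicate a more segregated (modular) network.
#'
#' @param w nonnegative symmetric weight matrix with positive total weight.
#' @param gamma resolution parameter (default 1).
#' @param n_repeats number of restarts (default 20).
#' @param seed integer seed for reproducible restarts.
#' @return list with `q` (maximized modularity) and `membership`.
#' @export
modularity <- function(w, gamma = 1, n_repeats = 20, seed = 1L) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  if (sum(w) <= 0) stop("modularity requires positive total weight")
  g <- as_igraph(w)
  ew <- igraph::E(g)$weight
  best_q <- -Inf
  best_m <- NULL
  for (r in seq_len(n_repeats)) {
    cl <- with_seed(seed + r, igraph::cluster_louvain(g, weights = ew,
                                                      resolution = gamma))
    m <- canonical_membership(igraph::membership(cl))
    q <- modularity_q(w, m, gamma)
    if (q > best_q + 1e-12 ||
        (abs(q - best_q) <= 1e-12 && !is.null(best_m) &&
         paste(m, collapse = ",") < paste(best_m, collapse = ","))) {
      best_q <- q
      best_m <- m
    }
  }
  list(q = best_q, membership = best_m)
}

## Relabel communities in order of first appearance (canonical form for
## deterministic tie-breaking).
canonical_membership <- function(m) {
  as.integer(factor(m, levels = unique(m)))
}
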