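## Probability-weighted network topology. Centrality is computed on the
## thresholded network (dense complete matrices make betweenness
## meaningless); shortest paths carry a traversal cost of 1/P_in per edge,
## so high-probability interactions are short.

## weighted igraph of the pairs at or above the working cutoff
pnet_graph <- function(pnet, cutoff) {
  net <- threshold_network(pnet, cutoff)
  g <- as_igraph(net)
  if (n_edges(net) > 0) {
    w <- pnet$pin[cbind(match(net$edges[, 1], pnet$protein_ids),
                        match(net$edges[, 2], pnet$protein_ids))]
    igraph::E(g)$pin <- w
    igraph::E(g)$cost <- 1 / w
  }
  g
}

#' Probability-weighted degree
#'
#' `wDEG(i)` is the sum of the interaction probabilities of the edges
#' incident to protein i, over edges retained at the working cutoff.
#'
#' @param pnet a `probabilistic_network`.
#' @param protein optional single protein id; default returns all.
#' @param cutoff working probability threshold (default 0.1).
#' @return named numeric vector (or scalar when `protein` is given).
#' @export
weighted_degree <- function(pnet, protein = NULL, cutoff = 0.1) {
  M <- pnet$pin * (pnet$pin >= cutoff)
  out <- rowSums(M)
  names(out) <- pnet$protein_ids
  if (!is.null(protein)) {
    if (!protein %in% pnet$protein_ids) stop("unknown protein: ", protein)
    return(out[[protein]])
  }
  out
}

#' Probability-weighted betweenness
#'
#' Standard weighted betweenness centrality on the thresholded network:
#' each edge carries a traversal cost of `1 / P_in`; for every pair (s, t)
#' with `s != i != t`, the fraction of minimum-cost s-t paths passing
#' through i is accumulated. Unreachable pairs contribute nothing.
#'
#' @inheritParams weighted_degree
#' @return named numeric vector (or scalar when `protein` is given).
#' @export
weighted_betweenness <- function(pnet, protein = NULL, cutoff = 0.1) {
  g <- pnet_graph(pnet, cutoff)
  out <- if (igraph::ecount(g) == 0) {
    stats::setNames(rep(0, length(pnet$protein_ids)), pnet$protein_ids)
  } else {
    igraph::betweenness(g, directed = FALSE, weights = igraph::E(g)$cost)
  }
  if (!is.null(protein)) {
    if (!protein %in% pnet$protein_ids) stop("unknown protein: ", protein)
    return(out[[protein]])
  }
  out
}

#' Global topology of the thresholded network
#'
#' Computes, at a given working cutoff: edge density (existing over
#' potential edges), Newman modularity of a supplied cluster assignment
#' (unweighted, omitted when no assignment is given), Freeman degree
#' centralization (1 for a star, 0 for a regular topology), and the
#' average shortest-path length in traversal-cost units (1/P_in per edge)
#' over reachable pairs, together with the fraction of reachable pairs.
#'
#' @param pnet a `probabilistic_network`.
#' @param cutoff working probability threshold (default 0.1).
#' @param assign optional `cluster_assignment` defining the communities
#'   for modularity.
#' @return a list of class `global_metrics`: `density`, `modularity` (may
#'   be `NULL`), `centralization`, `aspl`, `reachable_fraction`,
#'   `n_edges`.
#' @export
global_metrics <- function(pnet, cutoff = 0.1, assign = NULL) {
  g <- pnet_graph(pnet, cutoff)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  density <- m / choose(n, 2)
  modularity <- NULL
  if (!is.null(assign)) {
    membership <- assign$cluster[igraph::V(g)$name]
    modularity <- if (m > 0) igraph::modularity(g, membership) else NA_real_
  }
  centralization <- igraph::centr_degree(g, loops = FALSE)$centralization
  if (m > 0) {
    D <- igraph::distances(g, weights = igraph::E(g)$cost)
    off <- D[upper.tri(D)]
    reachable <- is.finite(off)
    aspl <- if (any(reachable)) mean(off[reachable]) else NA_real_
    reach_frac <- mean(reachable)
  } else {
    aspl <- NA_real_
    reach_frac <- 0
  }
  structure(list(density = density, modularity = modularity,
                 centralization = centralization, aspl = aspl,
                 reachable_fraction = reach_frac, n_edges = m,
                 cutoff = cutoff),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(
    "<global_metrics> cutoff %.3g: %d edges, density %.4g, centralization %.4g,\n  aspl %.4g (reachable %.1f%%)%s\n",
    x$cutoff, x$n_edges, x$density, x$centralization, x$aspl,
    100 * x$reachable_fraction,
    if (is.null(x$modularity)) "" else sprintf(", modularity %.4g", x$modularity)))
  invisible(x)
}

#' Empirical significance of weighted centralities
#'
#' Compares each protein's wDEG and wBET to `n_random` Erdos-Renyi G(n, m)
#' networks with the same node and edge counts as the thresholded network;
#' each replicate reuses the observed multiset of edge probabilities in
#' permuted order, so only the wiring is randomised. The empirical
#' p-value uses the add-one estimator against the distribution of
#' replicate maxima:
#' `p_i = (1 + #\{replicates whose maximum score >= observed_i\}) /
#' (1 + n_random)`, which can never reach zero. Each metric's p-values are
#' BH-adjusted; `q_min` is the per-protein minimum of the two q-values.
#'
#' @param pnet a `probabilistic_network`.
#' @param cutoff working probability threshold (default 0.1).
#' @param n_random number of random replicates (>= 100; default 1000).
#' @param seed integer RNG seed.
#' @return data frame of class `centrality_scores` with columns `protein`,
#'   `wdeg`, `wbet`, `p_wdeg`, `p_wbet`, `q_wdeg`, `q_wbet`, `q_min`.
#' @export
centrality_significance <- function(pnet, cutoff = 0.1, n_random = 1000,
                                    seed = 1) {
  if (n_random < 100) stop("n_random must be at least 100")
  n <- length(pnet$protein_ids)
  obs_deg <- weighted_degree(pnet, cutoff = cutoff)
  obs_bet <- weighted_betweenness(pnet, cutoff = cutoff)
  net <- threshold_network(pnet, cutoff)
  m <- n_edges(net)
  if (m < 1 || m > choose(n, 2)) {
    stop("cannot build G(n, m) replicates with n = ", n, ", m = ", m)
  }
  weights <- pnet$pin[cbind(match(net$edges[, 1], pnet$protein_ids),
                            match(net$edges[, 2], pnet$protein_ids))]
  max_deg <- numeric(n_random)
  max_bet <- numeric(n_random)
  withr::with_seed(seed, {
    for (r in seq_len(n_random)) {
      g <- igraph::sample_gnm(n, m)
      w <- sample(weights)
      max_deg[r] <- max(igraph::strength(g, weights = w))
      max_bet[r] <- max(igraph::betweenness(g, directed = FALSE,
                                            weights = 1 / w))
    }
  })
  p_deg <- vapply(obs_deg, function(x) (1 + sum(max_deg >= x)) / (1 + n_random),
                  numeric(1))
  p_bet <- vapply(obs_bet, function(x) (1 + sum(max_bet >= x)) / (1 + n_random),
                  numeric(1))
  q_deg <- fdr_adjust(p_deg)
  q_bet <- fdr_adjust(p_bet)
  out <- data.frame(protein = pnet$protein_ids,
                    wdeg = unname(obs_deg), wbet = unname(obs_bet),
                    p_wdeg = unname(p_deg), p_wbet = unname(p_bet),
                    q_wdeg = unname(q_deg), q_wbet = unname(q_bet),
                    q_min = pmin(unname(q_deg), unname(q_bet)),
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_scores", "data.frame")
  out
}
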