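# Shared fixtures and independent oracles, all built in code.

# small deterministic networks ------------------------------------------------

toy_net <- function(edges) interaction_network(do.call(rbind, edges))

# random Erdos-Renyi interaction network over letter ids
random_net <- function(n, p, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n))
    pairs <- t(utils::combn(ids, 2))
    keep <- stats::runif(nrow(pairs)) < p
    interaction_network(pairs[keep, , drop = FALSE], nodes = ids)
  })
}

# random symmetric probability matrix (dense), zero diagonal
random_pnet <- function(n, seed) {
  withr::with_seed(seed, {
    P <- matrix(0, n, n)
    P[upper.tri(P)] <- stats::runif(n * (n - 1) / 2)
    P <- P + t(P)
    probabilistic_network(sprintf("p%02d", seq_len(n)), P)
  })
}

# pnet from an explicit upper-triangle edge list: list(c("a","b", p), ...)
pnet_from_edges <- function(ids, edges) {
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  for (e in edges) {
    P[e[[1]], e[[2]]] <- as.numeric(e[[3]])
    P[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  }
  probabilistic_network(ids, P)
}

# a conditional model with hand-set likelihood ratios (2 bins per channel);
# t/c < 0.5 falls in bin 1, >= 0.5 in bin 2
manual_model <- function(prior, t_ratio = 1, c_ratio = 1) {
  lik <- function(r) {
    e1 <- c(1 / (1 + r), r / (1 + r))
    rbind(e0 = rev(e1), e1 = e1)
  }
  structure(list(t_edges = c(0, 0.5, 1), c_edges = c(-1, 0.5, 1),
                 lik_t = lik(t_ratio), lik_c = lik(c_ratio),
                 prior = prior, smoothing = 1, has_coexpression = TRUE,
                 n_train_edges = 1L),
            class = "conditional_model")
}

# memoised standard benchmark runs so several test files can share them
.bench_cache <- new.env(parent = emptyenv())
get_benchmark <- function(seed) {
  key <- as.character(seed)
  if (is.null(.bench_cache[[key]])) {
    .bench_cache[[key]] <- benchmark_pipeline(benchmark_spec(seed = seed))
  }
  .bench_cache[[key]]
}

# independent oracles ---------------------------------------------------------

# minimum-cost path length and betweenness by exhaustive simple-path
# enumeration (igraph only enumerates paths; all scoring is done here)
enum_paths <- function(pnet, cutoff = 0.1) {
  net <- threshold_network(pnet, cutoff)
  g <- as_igraph(net)
  cost <- function(path) {
    ids <- igraph::V(g)$name[path]
    sum(1 / pnet$pin[cbind(ids[-length(ids)], ids[-1])])
  }
  ids <- pnet$protein_ids
  n <- length(ids)
  bet <- stats::setNames(rep(0, n), ids)
  dist <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(dist) <- 0
  for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
    paths <- igraph::all_simple_paths(g, from = s, to = t)
    if (length(paths) == 0) next
    costs <- vapply(paths, cost, numeric(1))
    mc <- min(costs)
    dist[s, t] <- dist[t, s] <- mc
    minimal <- paths[costs <= mc + 1e-9]
    thru <- rep(0, n)
    for (p in minimal) {
      inner <- as.integer(p)[-c(1, length(p))]
      thru[inner] <- thru[inner] + 1
    }
    bet <- bet + thru / length(minimal)
  }
  list(betweenness = bet, distances = dist)
}

# upper-tail hypergeometric by direct pmf summation
enum_hyper <- function(N, B, n, b) {
  xs <- b:min(n, B)
  sum(choose(B, xs) * choose(N - B, n - xs)) / choose(N, n)
}

# two-sided Fisher p by enumerating all tables with the observed margins
enum_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); tot <- sum(tab)
  xs <- max(0, c1 - (tot - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, tot - r1, c1)
  obs <- stats::dhyper(tab[1, 1], r1, tot - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
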