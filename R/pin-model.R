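## The probabilistic interaction model: P_in = posterior probability that a
## protein pair interacts directly, given transitivity (T) and co-expression
## (C) evidence, with conditional likelihoods fitted on a reference
## interactome (e = 1) versus a degree-preserving decoy (e = 0).

#' Transitivity of a protein pair
#'
#' Transitivity quantifies how much of the combined neighbourhood of two
#' proteins is shared: `T = |S| / (|S| + |X|)` where `S` is the set of
#' shared third-party partners and `X` the set of exclusive third-party
#' partners. The pair members themselves are excluded from both sets, so a
#' direct a-b edge contributes nothing to T by itself -- only rewiring
#' among third parties moves the score. `T = 0` when neither protein has a
#' third-party partner.
#'
#' This is the Jaccard index over third-party neighbourhoods, the canonical
#' shared-versus-exclusive partner ratio.
#'
#' @param net an `interaction_network`.
#' @param a,b distinct protein ids present in `net`.
#' @return T in \[0, 1\].
#' @examples
#' net <- interaction_network(rbind(
#'   c("a", "x"), c("a", "y"), c("a", "z"),
#'   c("b", "y"), c("b", "z"), c("b", "w")))
#' compute_transitivity(net, "a", "b")  # shared {y,z}, exclusive {x,w} -> 0.5
#' @export
compute_transitivity <- function(net, a, b) {
  if (a == b) stop("transitivity is undefined for a self-pair")
  na <- setdiff(neighbors_of(net, a), c(a, b))
  nb <- setdiff(neighbors_of(net, b), c(a, b))
  shared <- intersect(na, nb)
  total <- union(na, nb)
  if (length(total) == 0) return(0)
  length(shared) / length(total)
}

#' All-pairs transitivity matrix
#'
#' Vectorised equivalent of [compute_transitivity()] for every unordered
#' pair of `ids`. Third-party partners are counted over the full node set
#' of `net`, so proteins outside `ids` still contribute evidence. Proteins
#' in `ids` absent from `net` have empty neighbourhoods and T = 0.
#'
#' @param net an `interaction_network`.
#' @param ids protein ids to score (default: all nodes of `net`).
#' @return symmetric matrix of transitivity values, zero diagonal.
#' @export
transitivity_matrix <- function(net, ids = net$nodes) {
  ids <- unique(as.character(ids))
  all_nodes <- union(net$nodes, ids)
  A <- adjacency_matrix(net, nodes = all_nodes)
  deg <- rowSums(A)
  S <- A %*% A                        # shared third-party partner counts
  U <- outer(deg, deg, "+") - S - 2 * A  # union of third-party partners
  Tm <- ifelse(U > 0, S / U, 0)
  diag(Tm) <- 0
  Tm[ids, ids, drop = FALSE]
}

#' Co-expression of a gene pair
#'
#' Pearson correlation of the two expression profiles across samples.
#' Returns `NA` ("missing") when either gene is absent from the matrix or
#' either profile has zero variance; missing co-expression is a value the
#' model tolerates (the pair is scored on transitivity alone), not an
#' error.
#'
#' @param expr numeric expression matrix (genes x samples).
#' @param a,b gene ids.
#' @return correlation in \[-1, 1\], or `NA`.
#' @export
compute_coexpression <- function(expr, a, b) {
  if (is.null(expr) || !(a %in% rownames(expr)) || !(b %in% rownames(expr))) {
    return(NA_real_)
  }
  x <- expr[a, ]; y <- expr[b, ]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' All-pairs co-expression matrix
#'
#' @param expr numeric expression matrix (genes x samples), or `NULL`.
#' @param ids gene ids to score.
#' @return symmetric matrix of Pearson correlations with `NA` for missing
#'   genes or zero-variance profiles; `NA` diagonal is set to 1 for present
#'   genes but is never used (self-pairs are not scored).
#' @export
coexpression_matrix <- function(expr, ids) {
  ids <- unique(as.character(ids))
  n <- length(ids)
  C <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  if (is.null(expr)) return(C)
  present <- intersect(ids, rownames(expr))
  if (length(present) >= 2) {
    sub <- expr[present, , drop = FALSE]
    ok <- apply(sub, 1, stats::sd) > 0
    if (sum(ok) >= 2) {
      cc <- suppressWarnings(stats::cor(t(sub[ok, , drop = FALSE])))
      C[rownames(cc), colnames(cc)] <- cc
    }
  }
  C
}

#' Degree-preserving decoy network
#'
#' Builds the non-interacting class (e = 0) by rewiring the input with
#' double-edge swaps (10 x |E| attempted swaps): two edges (a,b) and (c,d)
#' are replaced by (a,d) and (c,b) whenever that creates neither loops nor
#' multi-edges. Node set and degree sequence are exactly preserved, so
#' decoy transitivity is compared at matched degrees. Deterministic for a
#' given seed.
#'
#' @param net an `interaction_network` with at least 2 edges.
#' @param seed integer RNG seed.
#' @return an `interaction_network` with the same nodes and degrees.
#' @export
make_decoy_network <- function(net, seed = 1) {
  if (n_edges(net) < 2) stop("need at least 2 edges to rewire")
  g <- as_igraph(net)
  rew <- withr::with_seed(seed,
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = 10 * n_edges(net))))
  el <- igraph::as_edgelist(rew, names = TRUE)
  out <- interaction_network(el, nodes = net$nodes)
  if (setequal(pair_key(out$edges[, 1], out$edges[, 2]),
               pair_key(net$edges[, 1], net$edges[, 2]))) {
    warning("decoy identical to input: no feasible double-edge swap ",
            "(e.g. star topology); returning the network unchanged")
  }
  out
}

bin_edges_from_spec <- function(bins, lo, hi) {
  if (length(bins) == 1) {
    if (bins < 2) stop("need at least 2 bins")
    seq(lo, hi, length.out = bins + 1)
  } else {
    if (abs(bins[1] - lo) > 1e-12 || abs(bins[length(bins)] - hi) > 1e-12 ||
        is.unsorted(bins, strictly = TRUE)) {
      stop("bin edges must increase strictly from ", lo, " to ", hi)
    }
    as.numeric(bins)
  }
}

bin_index <- function(values, edges) {
  findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

bin_probs <- function(values, edges, smoothing) {
  k <- length(edges) - 1
  counts <- tabulate(bin_index(values, edges), nbins = k)
  p <- counts + smoothing
  p / sum(p)
}

#' Fit the conditional evidence model
#'
#' Estimates binned likelihoods `P(T | e)` and `P(C | e)` for the
#' interacting class (`e = 1`, the edges of the reference network) and the
#' non-interacting class (`e = 0`, the edges of a degree-preserving decoy
#' of the same network). Transitivity is computed on the reference network
#' for both samples; co-expression comes from `expr`, with missing values
#' excluded from the fit. Likelihood histograms receive a Laplace
#' pseudocount of `smoothing` per bin and are renormalised, so every bin
#' carries positive mass and the posterior never saturates at exactly 0 or
#' 1.
#'
#' @param true_net reference `interaction_network` (the e = 1 evidence).
#' @param expr expression matrix, or `NULL` to fit a transitivity-only
#'   model.
#' @param t_bins number of equal-width T bins on \[0, 1\], or explicit bin
#'   edges (default 20).
#' @param c_bins number of equal-width C bins on \[-1, 1\], or explicit bin
#'   edges (default 40).
#' @param smoothing pseudocount added to every bin (default 1).
#' @param prior class prior `P(e = 1)` in (0, 1), or `"auto"` for the edge
#'   density of the training network, `|E| / choose(n, 2)`.
#' @param seed RNG seed for the decoy rewiring.
#' @return an object of class `conditional_model`: bin edges, per-class
#'   likelihood matrices (rows `e0`, `e1`), `prior`, `smoothing`, and
#'   `has_coexpression` (FALSE when the C channel could not be fitted).
#' @export
fit_conditional_models <- function(true_net, expr = NULL,
                                   t_bins = 20, c_bins = 40,
                                   smoothing = 1, prior = "auto",
                                   seed = 1) {
  stopifnot(inherits(true_net, "interaction_network"))
  if (n_edges(true_net) == 0) stop("cannot fit on an empty network")
  t_edges <- bin_edges_from_spec(t_bins, 0, 1)
  c_edges <- bin_edges_from_spec(c_bins, -1, 1)
  if (smoothing < 0) stop("smoothing must be >= 0")

  decoy <- make_decoy_network(true_net, seed = seed)
  Tmat <- transitivity_matrix(true_net)
  t_pos <- Tmat[cbind(true_net$edges[, 1], true_net$edges[, 2])]
  t_neg <- Tmat[cbind(decoy$edges[, 1], decoy$edges[, 2])]

  Cmat <- coexpression_matrix(expr, true_net$nodes)
  c_pos <- Cmat[cbind(true_net$edges[, 1], true_net$edges[, 2])]
  c_neg <- Cmat[cbind(decoy$edges[, 1], decoy$edges[, 2])]
  c_pos <- c_pos[!is.na(c_pos)]
  c_neg <- c_neg[!is.na(c_neg)]
  has_c <- length(c_pos) > 0 && length(c_neg) > 0

  lik_t <- rbind(e0 = bin_probs(t_neg, t_edges, smoothing),
                 e1 = bin_probs(t_pos, t_edges, smoothing))
  lik_c <- if (has_c) {
    rbind(e0 = bin_probs(c_neg, c_edges, smoothing),
          e1 = bin_probs(c_pos, c_edges, smoothing))
  } else {
    k <- length(c_edges) - 1
    rbind(e0 = rep(1 / k, k), e1 = rep(1 / k, k))  # flat: C uninformative
  }

  if (identical(prior, "auto")) {
    prior <- n_edges(true_net) / choose(n_nodes(true_net), 2)
  }
  if (!is.numeric(prior) || prior <= 0 || prior >= 1) {
    stop("prior must lie strictly in (0, 1)")
  }
  structure(list(t_edges = t_edges, c_edges = c_edges,
                 lik_t = lik_t, lik_c = lik_c,
                 prior = prior, smoothing = smoothing,
                 has_coexpression = has_c,
                 n_train_edges = n_edges(true_net)),
            class = "conditional_model")
}

#' @export
print.conditional_model <- function(x, ...) {
  cat(sprintf(
    "<conditional_model> %d T bins, %d C bins (%s), prior P(e=1) = %.4g, fitted on %d edges\n",
    ncol(x$lik_t), ncol(x$lik_c),
    if (x$has_coexpression) "fitted" else "disabled",
    x$prior, x$n_train_edges))
  invisible(x)
}

#' Posterior interaction probability
#'
#' Applies Bayes' rule to the binned evidence, treating T and C as
#' conditionally independent given the class:
#' \deqn{P_{in} = \frac{\pi P(T|1) P(C|1)}{\pi P(T|1) P(C|1) +
#'   (1-\pi) P(T|0) P(C|0)}}
#' with \eqn{\pi} the class prior. When co-expression is missing (`NA`) or
#' the model's C channel is disabled, the C factors are omitted and the
#' pair is scored on transitivity alone.
#'
#' @param model a fitted `conditional_model`.
#' @param t transitivity value(s) in \[0, 1\].
#' @param c co-expression value(s) in \[-1, 1\] or `NA`; recycled against
#'   `t`.
#' @return posterior probabilities in \[0, 1\], same length as `t`.
#' @export
posterior_pin <- function(model, t, c = NA_real_) {
  stopifnot(inherits(model, "conditional_model"))
  c <- rep_len(c, length(t))
  ti <- bin_index(t, model$t_edges)
  num <- model$prior * model$lik_t["e1", ti]
  den0 <- (1 - model$prior) * model$lik_t["e0", ti]
  use_c <- model$has_coexpression & !is.na(c)
  if (any(use_c)) {
    ci <- bin_index(c[use_c], model$c_edges)
    num[use_c] <- num[use_c] * model$lik_c["e1", ci]
    den0[use_c] <- den0[use_c] * model$lik_c["e0", ci]
  }
  unname(num / (num + den0))
}

#' Score every protein pair of a catalog
#'
#' Computes the posterior interaction probability for all
#' `choose(n, 2)` unordered pairs of catalog proteins: transitivity from
#' the evidence network (third parties outside the catalog still count),
#' co-expression from `expr` where available, then [posterior_pin()] under
#' the fitted model. Pairs without usable co-expression fall back to
#' transitivity-only evidence rather than being dropped.
#'
#' @param catalog a `protein_catalog` or character vector of protein ids
#'   (n >= 2).
#' @param evidence_net `interaction_network` supplying transitivity
#'   evidence (normally the network the model was trained on).
#' @param expr expression matrix or `NULL`.
#' @param model a fitted `conditional_model`.
#' @return a `probabilistic_network` over the catalog proteins.
#' @export
build_ps_network <- function(catalog, evidence_net, expr = NULL, model) {
  ids <- if (inherits(catalog, "protein_catalog")) catalog$protein_id else
    as.character(catalog)
  if (length(ids) < 2) stop("catalog must contain at least 2 proteins")
  Tmat <- transitivity_matrix(evidence_net, ids)
  Cmat <- coexpression_matrix(expr, ids)
  n <- length(ids)
  ut <- which(upper.tri(Tmat))
  p <- posterior_pin(model, Tmat[ut], Cmat[ut])
  P <- matrix(0, n, n)
  P[ut] <- p
  P <- P + t(P)
  probabilistic_network(ids, P)
}

#' Serialise / load a fitted conditional model
#'
#' The model (bin edges, likelihood tables, prior, smoothing) is written
#' as JSON so that a scored network can be audited or re-scored later.
#'
#' @param model a `conditional_model`.
#' @param path JSON file path.
#' @return `path` (write) or a `conditional_model` (read).
#' @export
write_conditional_model <- function(model, path) {
  stopifnot(inherits(model, "conditional_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_conditional_model
#' @export
read_conditional_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("lik_t", "lik_c")) {
    lik <- x[[nm]]
    if (!is.matrix(lik)) lik <- do.call(rbind, lapply(lik, unlist))
    dimnames(lik) <- list(c("e0", "e1"), NULL)
    x[[nm]] <- lik
  }
  structure(x, class = "conditional_model")
}
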