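#' Construct an undirected interaction network
#'
#' The basic deterministic network container used throughout spliceonet: a
#' set of protein identifiers (case-sensitive gene symbols) and a set of
#' unordered, unweighted edges between them. Self-edges are rejected and
#' duplicate edges (including reversed duplicates) are collapsed.
#'
#' @param edges two-column character matrix or data frame of protein pairs;
#'   may have zero rows.
#' @param nodes character vector of protein ids. Defaults to the endpoints
#'   occurring in `edges`; supply explicitly to keep isolated proteins.
#' @param edge_source optional character vector tagging the provenance of
#'   each edge (recycled if length 1).
#' @return An object of class `interaction_network` with elements `nodes`
#'   (character), `edges` (m x 2 character matrix, each row sorted) and
#'   `edge_source`.
#' @examples
#' net <- interaction_network(rbind(c("A", "B"), c("B", "C")))
#' net$nodes
#' @export
interaction_network <- function(edges = NULL, nodes = NULL, edge_source = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(0), ncol = 2,
                 dimnames = list(NULL, c("protein_a", "protein_b")))
    src <- character(0)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    if (any(em[, 1] == em[, 2])) {
      stop("self-edges are not allowed in an interaction network")
    }
    em <- canonical_pairs(em)
    src <- if (is.null(edge_source)) rep(NA_character_, nrow(em)) else
      rep_len(as.character(edge_source), nrow(em))
    keep <- !duplicated(pair_key(em[, 1], em[, 2]))
    em <- em[keep, , drop = FALSE]
    src <- src[keep]
    dimnames(em) <- list(NULL, c("protein_a", "protein_b"))
  }
  nodes <- if (is.null(nodes)) sort(unique(c(em))) else unique(as.character(nodes))
  missing <- setdiff(c(em), nodes)
  if (length(missing) > 0) {
    stop("edge endpoints absent from node set: ", paste(missing, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = em, edge_source = src),
            class = "interaction_network")
}

## rows sorted so that (a,b) and (b,a) collapse to one key
canonical_pairs <- function(em) {
  a <- pmin(em[, 1], em[, 2])
  b <- pmax(em[, 1], em[, 2])
  cbind(a, b, deparse.level = 0)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges / nodes of a network
#' @param net an `interaction_network`.
#' @return integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

#' Convert an interaction network to an igraph graph
#'
#' Isolated proteins are preserved as degree-zero vertices.
#'
#' @param net an `interaction_network`.
#' @return an undirected [igraph::graph] with vertex attribute `name`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0) {
    idx <- rbind(match(net$edges[, 1], net$nodes),
                 match(net$edges[, 2], net$nodes))
    g <- igraph::add_edges(g, as.vector(idx))
  }
  g
}

#' Binary adjacency matrix of an interaction network
#'
#' @param net an `interaction_network`.
#' @param nodes optional node ordering / superset; proteins without edges get
#'   zero rows.
#' @return symmetric 0/1 integer matrix with dimnames.
#' @export
adjacency_matrix <- function(net, nodes = net$nodes) {
  nodes <- unique(as.character(nodes))
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges[, 1], nodes)
    j <- match(net$edges[, 2], nodes)
    keep <- !is.na(i) & !is.na(j)
    A[cbind(i[keep], j[keep])] <- 1L
    A[cbind(j[keep], i[keep])] <- 1L
  }
  A
}

#' Neighbour set of a protein
#' @param net an `interaction_network`.
#' @param protein a protein id present in the network.
#' @return character vector of interaction partners (possibly empty).
#' @export
neighbors_of <- function(net, protein) {
  if (!protein %in% net$nodes) stop("unknown protein: ", protein)
  e <- net$edges
  sort(unique(c(e[e[, 2] == protein, 1], e[e[, 1] == protein, 2])))
}

#' Construct a probabilistic interaction network
#'
#' Container for the posterior interaction probability matrix: one
#' probability per unordered protein pair. The matrix must be symmetric
#' with entries in \[0, 1\]; the diagonal is structurally zero because
#' self-interactions are never scored.
#'
#' @param protein_ids ordered character vector of n >= 2 protein symbols.
#' @param pin numeric n x n matrix of interaction probabilities.
#' @return An object of class `probabilistic_network` with elements
#'   `protein_ids` and `pin` (dimnames set to the ids).
#' @export
probabilistic_network <- function(protein_ids, pin) {
  protein_ids <- as.character(protein_ids)
  if (length(protein_ids) < 2) stop("need at least 2 proteins")
  if (anyDuplicated(protein_ids)) stop("protein ids must be unique")
  pin <- as.matrix(pin)
  n <- length(protein_ids)
  if (!all(dim(pin) == c(n, n))) stop("pin must be ", n, " x ", n)
  if (any(pin < 0 | pin > 1)) stop("probabilities must lie in [0, 1]")
  if (!isTRUE(all(pin == t(pin)))) stop("pin must be exactly symmetric")
  if (any(diag(pin) != 0)) stop("diagonal must be zero (no self-interactions)")
  dimnames(pin) <- list(protein_ids, protein_ids)
  structure(list(protein_ids = protein_ids, pin = pin),
            class = "probabilistic_network")
}

#' @export
print.probabilistic_network <- function(x, ...) {
  p <- x$pin[upper.tri(x$pin)]
  cat(sprintf(
    "<probabilistic_network> %d proteins, %d scored pairs, P_in range [%.3g, %.3g]\n",
    length(x$protein_ids), length(p), min(p), max(p)))
  invisible(x)
}

#' Threshold a probabilistic network into a deterministic one
#'
#' An edge is retained if and only if its interaction probability is greater
#' than or equal to `cutoff` (the comparison is inclusive, so a pair at
#' exactly the cutoff survives). All proteins are kept as nodes, so low
#' cutoffs and high cutoffs differ only in their edge sets.
#'
#' @param pnet a `probabilistic_network`.
#' @param cutoff probability threshold in (0, 1].
#' @return an `interaction_network` on the same protein set.
#' @export
threshold_network <- function(pnet, cutoff) {
  stopifnot(inherits(pnet, "probabilistic_network"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must be a probability in (0, 1]")
  }
  ut <- upper.tri(pnet$pin)
  sel <- which(ut & pnet$pin >= cutoff, arr.ind = TRUE)
  edges <- cbind(pnet$protein_ids[sel[, 1]], pnet$protein_ids[sel[, 2]])
  interaction_network(edges, nodes = pnet$protein_ids)
}
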