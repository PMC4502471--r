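## Functional clusters (FCs): proteins grouped by the similarity of their
## interaction-probability profiles, i.e. rows of the P_in matrix.

#' Binding-profile distance matrix
#'
#' For each pair of proteins (i, j), the Pearson correlation of their
#' P_in rows is computed over all other proteins -- columns i and j are
#' excluded from both rows because the diagonal self-probabilities are
#' structural zeros and would otherwise dominate. The distance is
#' `1 - correlation`, so identical binding profiles are at distance 0 and
#' perfectly anti-correlated ones at distance 2. A profile with zero
#' variance has no defined correlation; its distance to every other
#' protein is set to 1 (the uninformative midpoint) and a message is
#' emitted.
#'
#' @param pnet a `probabilistic_network` with at least 3 proteins.
#' @return symmetric distance matrix, zero diagonal, entries in \[0, 2\].
#' @export
profile_distance_matrix <- function(pnet) {
  stopifnot(inherits(pnet, "probabilistic_network"))
  P <- pnet$pin
  n <- nrow(P)
  if (n < 3) stop("need at least 3 proteins to correlate binding profiles")
  ## Pairwise correlation over the n-2 columns excluding i and j, computed
  ## algebraically from full-row statistics corrected for the excluded
  ## entries. Row i of P loses its entries at columns i (structurally 0)
  ## and j; the cross product P[i,] . P[j,] already excludes both terms
  ## because P[i,i] = P[j,j] = 0.
  m <- n - 2
  Sx <- matrix(rowSums(P), n, n) - P        # [i,j] = sum of row i w/o cols i,j
  Sy <- t(Sx)
  Sxx <- matrix(rowSums(P^2), n, n) - P^2
  Syy <- t(Sxx)
  Sxy <- P %*% P
  vx <- m * Sxx - Sx^2
  vy <- m * Syy - Sy^2
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  corr <- ifelse(den > 1e-12, (m * Sxy - Sx * Sy) / pmax(den, 1e-12), 0)
  corr <- matrix(pmin(1, pmax(corr, -1)), n, n)
  zerovar <- which(apply(vx <= 1e-12, 1, any))
  if (length(zerovar) > 0) {
    message("profile_distance_matrix: ", length(zerovar),
            " protein(s) with a constant excluded-pair profile; ",
            "distance set to 1 for the affected pairs")
  }
  D <- 1 - corr
  D[den <= 1e-12] <- 1
  diag(D) <- 0
  dimnames(D) <- list(pnet$protein_ids, pnet$protein_ids)
  D
}

#' Average-linkage hierarchical clustering of binding profiles
#'
#' Agglomerates the profile distance matrix with UPGMA (average linkage)
#' and cuts the tree into exactly `k` clusters. Cluster ids are contiguous
#' integers 1..k in order of first appearance along the input ordering;
#' ties in merge height are resolved deterministically by
#' [stats::hclust()].
#'
#' @param dist_matrix symmetric distance matrix (e.g. from
#'   [profile_distance_matrix()]).
#' @param k number of clusters, `2 <= k <= n`.
#' @return an object of class `cluster_assignment`: `cluster` (named
#'   integer vector), `k`, and `tree` (the `hclust` object).
#' @export
hierarchical_clusters <- function(dist_matrix, k) {
  n <- nrow(dist_matrix)
  if (k < 2 || k > n) stop("k must lie in [2, ", n, "]")
  tree <- stats::hclust(stats::as.dist(dist_matrix), method = "average")
  raw <- stats::cutree(tree, k = k)
  relab <- match(raw, unique(raw))  # contiguous ids, first-appearance order
  cl <- stats::setNames(as.integer(relab), names(raw))
  structure(list(cluster = cl, k = as.integer(k), tree = tree),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d proteins in %d clusters (sizes: %s)\n",
              length(x$cluster), x$k,
              paste(tabulate(x$cluster, x$k), collapse = ", ")))
  invisible(x)
}

#' Normalised cluster-cluster connectivity
#'
#' The connectivity between functional clusters I and J is the probability
#' mass on pairs spanning the two clusters, normalised by the total mass
#' connecting either cluster to the whole network (counting the spanning
#' mass once):
#' \deqn{C_{IJ} = \frac{\sum_{i \in I, j \in J} P_{ij}}
#'   {\sum_{i \in I, n \in N} P_{in} + \sum_{j \in J, n \in N} P_{jn}
#'    - \sum_{i \in I, j \in J} P_{ij}}}
#' The result lies in \[0, 1\] and is symmetric in I and J. A zero
#' denominator (both clusters fully disconnected) yields 0.
#'
#' @param pnet a `probabilistic_network`.
#' @param assign a `cluster_assignment` on the same proteins.
#' @param i_cluster,j_cluster distinct cluster ids.
#' @return connectivity value in \[0, 1\].
#' @export
cluster_connectivity <- function(pnet, assign, i_cluster, j_cluster) {
  if (i_cluster == j_cluster) stop("clusters must be distinct")
  cl <- assign$cluster[pnet$protein_ids]
  I <- which(cl == i_cluster)
  J <- which(cl == j_cluster)
  if (length(I) == 0 || length(J) == 0) stop("empty cluster")
  P <- pnet$pin
  cross <- sum(P[I, J, drop = FALSE])
  total_i <- sum(P[I, , drop = FALSE])
  total_j <- sum(P[J, , drop = FALSE])
  den <- total_i + total_j - cross
  if (den <= 0) return(0)
  cross / den
}
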