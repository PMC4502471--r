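## Enrichment statistics: hypergeometric over-representation of functional
## terms within clusters, BH false-discovery-rate adjustment, and the 2x2
## Fisher exact test used for activator/repressor partition contrasts.

#' Hypergeometric enrichment p-value
#'
#' One-sided upper-tail probability of drawing at least `b` term-annotated
#' proteins when `n` cluster members are sampled without replacement from a
#' network of `N` proteins of which `B` carry the term:
#' `p = sum_{x = b}^{min(n, B)} HG(x; N, B, n)`. The observed overlap is
#' included in the tail (standard over-representation test), so `b = 0`
#' gives `p = 1`.
#'
#' @param N total proteins in the network.
#' @param B proteins annotated with the term.
#' @param n proteins in the cluster.
#' @param b proteins in both.
#' @return upper-tail p-value.
#' @examples
#' hypergeometric_enrichment(N = 10, B = 5, n = 5, b = 5)  # 1/252
#' @export
hypergeometric_enrichment <- function(N, B, n, b) {
  stopifnot(b >= 0, b <= min(n, B), n <= N, B <= N)
  stats::phyper(b - 1, m = B, n = N - B, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; output is order-aligned with the input and
#' clipped to \[0, 1\].
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the total probability of all tables with the
#' observed margins whose hypergeometric probability does not exceed that
#' of the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Cluster-by-term enrichment table
#'
#' Runs [hypergeometric_enrichment()] for every cluster x term combination
#' and adjusts all p-values jointly as one family with
#' Benjamini-Hochberg. The conventional reporting threshold for the
#' resulting q-values is 0.1.
#'
#' @param assign a `cluster_assignment`.
#' @param terms data frame with columns `protein_id` and `term` (one row
#'   per annotation), or a `protein_catalog` whose `functional_terms` are
#'   used.
#' @param q_max optional q-value filter applied to the returned table
#'   (default `NULL`: return everything).
#' @return data frame with columns `cluster`, `term`, `b`, `n`, `B`, `N`,
#'   `p`, `q`, sorted by q then p.
#' @export
enrich_clusters <- function(assign, terms, q_max = NULL) {
  stopifnot(inherits(assign, "cluster_assignment"))
  if (inherits(terms, "protein_catalog")) {
    terms <- data.frame(
      protein_id = rep(terms$protein_id,
                       lengths(terms$functional_terms)),
      term = unlist(terms$functional_terms),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("protein_id", "term") %in% names(terms)))
  proteins <- names(assign$cluster)
  terms <- terms[terms$protein_id %in% proteins, , drop = FALSE]
  N <- length(proteins)
  term_sets <- split(terms$protein_id, terms$term)
  rows <- list()
  for (cl in seq_len(assign$k)) {
    members <- proteins[assign$cluster == cl]
    for (tm in names(term_sets)) {
      B <- length(unique(term_sets[[tm]]))
      b <- length(intersect(members, term_sets[[tm]]))
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, term = tm, b = b, n = length(members), B = B, N = N,
        p = hypergeometric_enrichment(N, B, length(members), b),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p)
  out <- out[order(out$q, out$p), , drop = FALSE]
  if (!is.null(q_max)) out <- out[out$q < q_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}
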