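## Cross-validation of probabilistic versus deterministic interaction
## prediction: positive pairs are direct edges of an independent test
## network; negative pairs are protein pairs in different connected
## components of the test network (shortest path length -> infinity), so
## neither a direct nor an indirect association is expected. Reachable but
## non-adjacent pairs are ambiguous and enter neither set.

#' Positive and negative evaluation pairs from a test network
#'
#' @param test_net an `interaction_network`.
#' @return list with character matrices `positives` (direct edges) and
#'   `negatives` (cross-component pairs); a warning is raised when the
#'   network is a single connected component and no negatives exist.
#' @export
build_pos_neg_sets <- function(test_net) {
  stopifnot(inherits(test_net, "interaction_network"))
  if (n_nodes(test_net) == 0) stop("empty test network")
  g <- as_igraph(test_net)
  comp <- igraph::components(g)$membership
  nodes <- test_net$nodes
  cross <- which(outer(comp, comp, "!=") & upper.tri(diag(length(nodes))),
                 arr.ind = TRUE)
  negatives <- cbind(nodes[cross[, 1]], nodes[cross[, 2]])
  if (nrow(negatives) == 0) {
    warning("test network is a single connected component: no negative pairs")
  }
  colnames(negatives) <- c("protein_a", "protein_b")
  list(positives = test_net$edges, negatives = negatives)
}

mcc_from_counts <- function(TP, TN, FP, FN) {
  den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
    sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  if (den == 0) return(list(mcc = 0, degenerate = TRUE))
  list(mcc = (as.numeric(TP) * TN - as.numeric(FP) * FN) / den,
       degenerate = FALSE)
}

#' Score a predictor against positive/negative pair sets
#'
#' A probabilistic predictor calls a pair "interacting" when its P_in is
#' at or above `threshold`; a deterministic predictor (an
#' `interaction_network`) calls exactly its own edges. Pairs absent from a
#' probabilistic predictor's protein set score 0 (never predicted) and are
#' counted in `n_unscored`.
#'
#' Metrics: `sensitivity = TP / (TP + FN)`,
#' `specificity = TN / (TN + FP)`, and Matthews correlation
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined
#' as 0 (with `mcc_degenerate = TRUE`) when any marginal vanishes.
#'
#' @param predictor a `probabilistic_network` or `interaction_network`.
#' @param positives,negatives two-column character matrices of disjoint
#'   protein pairs (e.g. from [build_pos_neg_sets()]).
#' @param threshold probability threshold; required for probabilistic
#'   input, ignored for deterministic input.
#' @return a list of class `validation_report`: `threshold`, `counts`
#'   (TP/TN/FP/FN), `sensitivity`, `specificity`, `mcc`,
#'   `mcc_degenerate`, `n_unscored`.
#' @export
evaluate_predictions <- function(predictor, positives, negatives,
                                 threshold = NULL) {
  positives <- as.matrix(positives)
  negatives <- as.matrix(negatives)
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    stop("both positive and negative sets must be non-empty")
  }
  if (length(intersect(pair_key(positives[, 1], positives[, 2]),
                       pair_key(negatives[, 1], negatives[, 2]))) > 0) {
    stop("positive and negative sets overlap")
  }
  n_unscored <- 0L
  predict_pairs <- function(pairs) {
    if (inherits(predictor, "probabilistic_network")) {
      if (is.null(threshold)) {
        stop("a threshold is required for a probabilistic predictor")
      }
      i <- match(pairs[, 1], predictor$protein_ids)
      j <- match(pairs[, 2], predictor$protein_ids)
      known <- !is.na(i) & !is.na(j)
      n_unscored <<- n_unscored + sum(!known)
      out <- logical(nrow(pairs))
      out[known] <- predictor$pin[cbind(i[known], j[known])] >= threshold
      out
    } else if (inherits(predictor, "interaction_network")) {
      pair_key(pairs[, 1], pairs[, 2]) %in%
        pair_key(predictor$edges[, 1], predictor$edges[, 2])
    } else {
      stop("unsupported predictor")
    }
  }
  pos_hit <- predict_pairs(positives)
  neg_hit <- predict_pairs(negatives)
  TP <- sum(pos_hit); FN <- sum(!pos_hit)
  FP <- sum(neg_hit); TN <- sum(!neg_hit)
  mcc <- mcc_from_counts(TP, TN, FP, FN)
  structure(list(
    threshold = if (inherits(predictor, "probabilistic_network")) threshold
                else NA_real_,
    counts = c(TP = TP, TN = TN, FP = FP, FN = FN),
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP),
    mcc = mcc$mcc, mcc_degenerate = mcc$degenerate,
    n_unscored = n_unscored),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> thr %s | TP %d FN %d FP %d TN %d | sens %.3f spec %.3f MCC %.3f%s\n",
    ifelse(is.na(x$threshold), "edge", format(x$threshold)),
    x$counts["TP"], x$counts["FN"], x$counts["FP"], x$counts["TN"],
    x$sensitivity, x$specificity, x$mcc,
    if (x$mcc_degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Remove test edges from a training network
#'
#' Drops every training edge that also appears in the test network (in
#' either orientation), leaving only neighbouring interactions as
#' transitivity evidence. The node set is unchanged.
#'
#' @param train_net,test_net `interaction_network`s.
#' @return the held-out training `interaction_network`.
#' @export
holdout_training_network <- function(train_net, test_net) {
  drop <- pair_key(train_net$edges[, 1], train_net$edges[, 2]) %in%
    pair_key(test_net$edges[, 1], test_net$edges[, 2])
  interaction_network(train_net$edges[!drop, , drop = FALSE],
                      nodes = train_net$nodes,
                      edge_source = train_net$edge_source[!drop])
}

#' Residuals between two probability matrices
#'
#' Quantifies how much the posterior changes between two scorings of the
#' same protein set (e.g. with and without a direct edge in the evidence
#' network): per unordered pair the residual is `|P_with - P_without|`.
#'
#' @param pnet_with,pnet_without `probabilistic_network`s over the same
#'   ordered protein set.
#' @param eps residual magnitude of interest (default 0.1).
#' @return list with `fraction_unaffected` (residual < `eps`; for
#'   `eps = 0`, exactly equal), `exceed_count` (the remaining pairs), and
#'   `n_pairs`.
#' @export
residual_comparison <- function(pnet_with, pnet_without, eps = 0.1) {
  if (!identical(pnet_with$protein_ids, pnet_without$protein_ids)) {
    stop("protein orderings differ")
  }
  ut <- upper.tri(pnet_with$pin)
  res <- abs(pnet_with$pin[ut] - pnet_without$pin[ut])
  unaffected <- if (eps > 0) res < eps else res == 0
  list(fraction_unaffected = mean(unaffected),
       exceed_count = sum(!unaffected),
       n_pairs = length(res))
}

#' Area under the ROC curve of a score-based ranking
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counted half.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) true-class labels, same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
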