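## IP-MS overlay: score unique-peptide count tables from
## doxycycline-inducible bait immunoprecipitations, classify ligands as
## nuclease-resistant (nucR, RNA-independent) or nuclease-sensitive (nucS,
## RNA-dependent), and relate the resulting ligand sets to the
## probabilistic network.

#' Peptide-count enrichment score
#'
#' `logE = log2(p_plus / (p_minus + 1))`: log2 ratio of unique peptide
#' counts in the induced (Dox+) versus uninduced (Dox-) purification, with
#' a pseudo-count in the denominator so proteins undetected without
#' induction remain scoreable. `p_plus = 0` yields `-Inf` (never
#' enriched).
#'
#' A protein counts as enriched when `logE` is strictly greater than 1.
#' The strict inequality is deliberate: it guarantees both a more than
#' two-fold ratio and, when the control is empty, at least three peptides
#' (`log2(2/1) = 1` fails, `log2(3/1) ~ 1.585` passes).
#'
#' @param p_plus,p_minus non-negative integer unique-peptide counts
#'   (vectorised).
#' @return numeric logE value(s).
#' @examples
#' compute_logE(4, 1)   # exactly 1: at the cutoff, not enriched
#' compute_logE(3, 0)   # ~1.585: enriched
#' @export
compute_logE <- function(p_plus, p_minus) {
  if (any(p_plus < 0) || any(p_minus < 0)) stop("counts must be non-negative")
  if (any(p_plus != round(p_plus)) || any(p_minus != round(p_minus))) {
    stop("counts must be integers")
  }
  ifelse(p_plus == 0, -Inf, log2(p_plus / (p_minus + 1)))
}

LOGE_CUTOFF <- 1

#' Read an IP-MS peptide-count table
#'
#' TSV columns: `bait`, `ligand`, `condition` (`nuclease` /
#' `no_nuclease`), `replicate`, `p_dox_plus`, `p_dox_minus`.
#'
#' @param path file path.
#' @return data frame of per-replicate records.
#' @export
read_ipms_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("bait", "ligand", "condition", "replicate",
            "p_dox_plus", "p_dox_minus")
  if (!all(need %in% names(df))) {
    stop("IP-MS table needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Classify bait ligands from IP-MS counts
#'
#' Replicate counts are pooled by summation per (ligand, condition) before
#' scoring; a ligand is enriched in a condition when its pooled
#' `logE > 1`. Ligands enriched in the nuclease-treated purification are
#' nuclease-resistant (`nucR`, interactions surviving RNA removal);
#' ligands enriched only without nuclease are nuclease-sensitive (`nucS`,
#' RNA-dependent co-purification). Every other catalog protein is
#' `undetected`, so bait + nucR + nucS + undetected partition the catalog.
#'
#' @param records data frame as from [read_ipms_table()], for a single
#'   bait. A row listing the bait as its own ligand is removed with a
#'   warning.
#' @param catalog a `protein_catalog` or character vector of catalog
#'   protein ids (must contain the bait).
#' @return an object of class `ligand_set`: `bait`, `nucR`, `nucS`,
#'   `undetected` (character vectors) and `scores` (pooled counts and logE
#'   per ligand and condition).
#' @export
select_enriched <- function(records, catalog) {
  ids <- if (inherits(catalog, "protein_catalog")) catalog$protein_id else
    as.character(catalog)
  bait <- unique(records$bait)
  if (length(bait) != 1) stop("records must concern a single bait")
  if (!bait %in% ids) stop("bait absent from catalog")
  if (any(records$ligand == bait)) {
    warning("bait listed as its own ligand; dropping ",
            sum(records$ligand == bait), " row(s)")
    records <- records[records$ligand != bait, , drop = FALSE]
  }
  bad_cond <- setdiff(unique(records$condition), c("nuclease", "no_nuclease"))
  if (length(bad_cond) > 0) stop("unknown condition(s): ",
                                 paste(bad_cond, collapse = ", "))
  agg <- stats::aggregate(cbind(p_dox_plus, p_dox_minus) ~ ligand + condition,
                          data = records, FUN = sum)
  agg$logE <- compute_logE(agg$p_dox_plus, agg$p_dox_minus)
  agg$enriched <- agg$logE > LOGE_CUTOFF
  nucR <- sort(agg$ligand[agg$condition == "nuclease" & agg$enriched])
  nucS <- sort(setdiff(agg$ligand[agg$condition == "no_nuclease" & agg$enriched],
                       nucR))
  undetected <- sort(setdiff(ids, c(bait, nucR, nucS)))
  structure(list(bait = bait, nucR = nucR, nucS = nucS,
                 undetected = undetected, scores = agg),
            class = "ligand_set")
}

#' @export
print.ligand_set <- function(x, ...) {
  cat(sprintf("<ligand_set> bait %s: %d nucR, %d nucS, %d undetected\n",
              x$bait, length(x$nucR), length(x$nucS), length(x$undetected)))
  invisible(x)
}

group_pin <- function(pnet, bait, members) {
  members <- intersect(members, pnet$protein_ids)
  pnet$pin[bait, members]
}

#' P_in distribution of bait-ligand interactions by ligand class
#'
#' Bins the bait-partner interaction probabilities of the nucR, nucS and
#' undetected groups into P_in intervals and normalises each group's
#' counts by its own size, so the three profiles are comparable
#' proportions. Each detected group is additionally compared to the
#' undetected background with a two-sided Mann-Whitney U test on the raw
#' bait-partner P_in values; an empty group's test is skipped and flagged
#' with `NA`.
#'
#' @param pnet a `probabilistic_network` containing the bait.
#' @param ligset a `ligand_set` for that bait.
#' @param breaks P_in interval edges on \[0, 1\] (default deciles).
#' @return list with `proportions` (groups x intervals matrix, rows sum to
#'   1), `p_nucR`, `p_nucS` (Mann-Whitney p-values or `NA`), and
#'   `group_sizes`.
#' @export
pin_distribution_overlay <- function(pnet, ligset,
                                     breaks = seq(0, 1, by = 0.1)) {
  bait <- ligset$bait
  if (!bait %in% pnet$protein_ids) stop("bait absent from network")
  groups <- list(nucR = ligset$nucR, nucS = ligset$nucS,
                 undetected = ligset$undetected)
  vals <- lapply(groups, function(g) group_pin(pnet, bait, g))
  k <- length(breaks) - 1
  props <- t(vapply(vals, function(v) {
    if (length(v) == 0) return(rep(NA_real_, k))
    tabulate(bin_index(v, breaks), nbins = k) / length(v)
  }, numeric(k)))
  colnames(props) <- paste0("(", utils::head(breaks, -1), ",",
                            utils::tail(breaks, -1), "]")
  mw <- function(g) {
    if (length(vals[[g]]) == 0 || length(vals$undetected) == 0) return(NA_real_)
    stats::wilcox.test(vals[[g]], vals$undetected, exact = FALSE)$p.value
  }
  list(proportions = props,
       p_nucR = mw("nucR"), p_nucS = mw("nucS"),
       group_sizes = lengths(vals))
}

#' Network proximity of ligand classes to the bait
#'
#' Minimum-cost path lengths (edge cost `1 / P_in`, network thresholded at
#' `cutoff`) from the bait to each protein, summarised per ligand class.
#' Proteins unreachable from the bait are excluded from the means and
#' counted. Each detected class is compared to the undetected background
#' with a two-sided Mann-Whitney U test.
#'
#' @param pnet a `probabilistic_network` containing the bait.
#' @param ligset a `ligand_set` for that bait.
#' @param cutoff working probability threshold (default 0.1).
#' @return list with per-group `mean_dist`, `n_reachable`,
#'   `n_unreachable`, plus `p_nucR` and `p_nucS`.
#' @export
bait_proximity <- function(pnet, ligset, cutoff = 0.1) {
  bait <- ligset$bait
  if (!bait %in% pnet$protein_ids) stop("bait absent from network")
  g <- pnet_graph(pnet, cutoff)
  if (igraph::degree(g, bait) == 0) {
    stop("bait is isolated at cutoff ", cutoff)
  }
  d <- igraph::distances(g, v = bait, weights = igraph::E(g)$cost)[1, ]
  groups <- list(nucR = ligset$nucR, nucS = ligset$nucS,
                 undetected = ligset$undetected)
  dists <- lapply(groups, function(gr) {
    x <- d[intersect(gr, pnet$protein_ids)]
    x[is.finite(x)]
  })
  mw <- function(gname) {
    if (length(dists[[gname]]) == 0 || length(dists$undetected) == 0) {
      return(NA_real_)
    }
    stats::wilcox.test(dists[[gname]], dists$undetected, exact = FALSE)$p.value
  }
  list(mean_dist = vapply(dists, function(x)
         if (length(x) > 0) mean(x) else NA_real_, numeric(1)),
       n_reachable = lengths(dists),
       n_unreachable = vapply(names(groups), function(gname)
         length(intersect(groups[[gname]], pnet$protein_ids)) -
           length(dists[[gname]]), integer(1)),
       distances = dists,
       p_nucR = mw("nucR"), p_nucS = mw("nucS"))
}

#' Observed versus expected ligand recovery per functional cluster
#'
#' For each functional cluster, the expected proportion is the share of
#' the bait's predicted partners (catalog proteins with
#' `P_in(bait, .) >= cutoff`) falling in that cluster; the observed
#' proportion is the share of IP-MS ligands (nucR and nucS) in that
#' cluster. An ordinary least-squares fit of observed on expected
#' summarises how well the probabilistic network anticipates the IP-MS
#' recovery; both proportion series sum to 1 over clusters.
#'
#' @param pnet a `probabilistic_network`.
#' @param assign a `cluster_assignment` over the network proteins.
#' @param ligset a `ligand_set`.
#' @param cutoff working probability threshold (default 0.1).
#' @return list with `r_squared`, `slope`, `intercept` and `points` (data
#'   frame: cluster, expected, observed).
#' @export
fc_regression <- function(pnet, assign, ligset, cutoff = 0.1) {
  bait <- ligset$bait
  if (!bait %in% pnet$protein_ids) stop("bait absent from network")
  cl <- assign$cluster
  predicted <- setdiff(pnet$protein_ids[pnet$pin[bait, ] >= cutoff], bait)
  ligands <- intersect(c(ligset$nucR, ligset$nucS), names(cl))
  if (length(predicted) == 0) stop("no predicted partners at cutoff ", cutoff)
  if (length(ligands) == 0) stop("no IP-MS ligands to regress")
  ks <- seq_len(assign$k)
  expected <- vapply(ks, function(k)
    sum(cl[predicted] == k, na.rm = TRUE), numeric(1)) / length(predicted)
  observed <- vapply(ks, function(k)
    sum(cl[ligands] == k, na.rm = TRUE), numeric(1)) / length(ligands)
  if (assign$k < 3) {
    stop("fewer than 3 clusters; regression not meaningful")
  }
  fit <- stats::lm(observed ~ expected)
  ## summary.lm warns on an exactly perfect fit; R^2 = 1 is a valid outcome
  list(r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       points = data.frame(cluster = ks, expected = expected,
                           observed = observed))
}

#' Screen annotated complexes for full-member bait connectivity
#'
#' For every annotated complex, counts how many member proteins form a
#' predicted interaction (`P_in >= cutoff`) with the bait, and flags
#' complexes whose members all do ("full coverage"). Members absent from
#' the network are ignored; the bait itself is not counted as a member.
#'
#' @param complexes data frame with columns `complex_id` and `protein_id`.
#' @param pnet a `probabilistic_network`.
#' @param bait bait protein id.
#' @param cutoff working probability threshold (default 0.1).
#' @return data frame (one row per complex) with `complex_id`,
#'   `n_members`, `n_pass`, `coverage`, `min_pin`, `max_pin`,
#'   `full_coverage`, ranked by coverage then size.
#' @export
complex_screen <- function(complexes, pnet, bait, cutoff = 0.1) {
  stopifnot(all(c("complex_id", "protein_id") %in% names(complexes)))
  if (!bait %in% pnet$protein_ids) stop("bait absent from network")
  rows <- lapply(split(complexes$protein_id, complexes$complex_id),
                 function(members) {
    members <- setdiff(intersect(unique(members), pnet$protein_ids), bait)
    if (length(members) == 0) {
      return(data.frame(n_members = 0L, n_pass = 0L, coverage = NA_real_,
                        min_pin = NA_real_, max_pin = NA_real_,
                        full_coverage = FALSE))
    }
    p <- pnet$pin[bait, members]
    data.frame(n_members = length(members), n_pass = sum(p >= cutoff),
               coverage = mean(p >= cutoff),
               min_pin = min(p), max_pin = max(p),
               full_coverage = all(p >= cutoff))
  })
  out <- do.call(rbind, rows)
  out <- cbind(complex_id = names(rows), out)
  out <- out[order(-ifelse(is.na(out$coverage), -1, out$coverage),
                   -out$n_members), , drop = FALSE]
  rownames(out) <- NULL
  out
}
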