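## Seeded synthetic benchmarks. The generators emulate the data the
## toolkit consumes in real studies: a modular "true" interactome (the
## spliceosome's sub-complex organisation), a co-expression compendium in
## which co-module pairs correlate, an observed network degraded by
## false-positive and false-negative interactions (spurious and
## undersampled screens), and overdispersed IP-MS unique-peptide counts
## enriched for genuine bait ligands. Every output is a pure function of
## (spec, seed).

#' Benchmark specification
#'
#' Bundles all generator parameters. Defaults describe the standard
#' benchmark used throughout the test suite: 120 proteins in 6 modules of
#' 20, intra-module edge probability 0.35 versus 0.02 between modules, 30
#' expression samples, and observed networks in which 15% of true edges
#' are missed and a matching 15% of spurious edges are added.
#'
#' @param n_proteins number of catalog proteins.
#' @param n_modules number of planted modules (proteins are split evenly).
#' @param p_intra,p_inter within/between-module edge probabilities
#'   (`p_intra > p_inter` for an informative benchmark).
#' @param n_samples expression samples.
#' @param coexpr_effect loading of each gene on its module's latent
#'   expression factor; with `noise_sd` it sets the within-module
#'   correlation `coexpr_effect^2 / (coexpr_effect^2 + noise_sd^2)`
#'   (default 1 and 0.5: correlation 0.8).
#' @param noise_sd per-gene Gaussian noise standard deviation.
#' @param fp_rate fraction of spurious edges added to an observation,
#'   relative to the true edge count.
#' @param fn_rate probability that a true edge is missed.
#' @param bait_id IP-MS bait protein (default the first protein).
#' @param ligand_enrichment mean peptide-count multiplier of a true ligand
#'   in the induced purification.
#' @param baseline_count mean background unique-peptide count per
#'   replicate.
#' @param dispersion negative-binomial size parameter of the count model
#'   (smaller = more overdispersed).
#' @param n_replicates IP-MS replicates per condition.
#' @param seed mandatory integer seed; all generators derive their RNG
#'   streams from it.
#' @return a list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_proteins = 120, n_modules = 6,
                           p_intra = 0.35, p_inter = 0.02,
                           n_samples = 30, coexpr_effect = 1,
                           noise_sd = 0.5, fp_rate = 0.15, fn_rate = 0.15,
                           bait_id = NULL, ligand_enrichment = 8,
                           baseline_count = 2, dispersion = 4,
                           n_replicates = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_proteins >= 2, n_modules >= 1, n_proteins >= n_modules,
            p_intra >= 0, p_intra <= 1, p_inter >= 0, p_inter <= 1,
            fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate <= 1,
            n_samples >= 3, ligand_enrichment > 0, dispersion > 0,
            n_replicates >= 1)
  ids <- sprintf("P%03d", seq_len(n_proteins))
  structure(list(n_proteins = n_proteins, n_modules = n_modules,
                 p_intra = p_intra, p_inter = p_inter,
                 n_samples = n_samples, coexpr_effect = coexpr_effect,
                 noise_sd = noise_sd, fp_rate = fp_rate, fn_rate = fn_rate,
                 bait_id = if (is.null(bait_id)) ids[1] else bait_id,
                 ligand_enrichment = ligand_enrichment,
                 baseline_count = baseline_count, dispersion = dispersion,
                 n_replicates = n_replicates,
                 protein_ids = ids, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Planted-partition true interactome
#'
#' Every within-module pair becomes an edge with probability `p_intra`,
#' every between-module pair with `p_inter`, independently.
#'
#' @param spec a `benchmark_spec`.
#' @return list with `network` (an `interaction_network` over all catalog
#'   proteins) and `modules` (named integer vector of planted labels).
#' @export
generate_true_interactome <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  mods <- sort(stats::setNames(rep(seq_len(spec$n_modules),
                                   length.out = spec$n_proteins),
                               NULL))
  mods <- stats::setNames(mods, spec$protein_ids)
  ids <- spec$protein_ids
  n <- length(ids)
  same <- outer(mods, mods, "==")
  prob <- ifelse(same, spec$p_intra, spec$p_inter)
  ut <- which(upper.tri(prob))
  draw <- withr::with_seed(spec$seed, stats::runif(length(ut)) < prob[ut])
  sel <- arrayInd(ut[draw], c(n, n))
  net <- interaction_network(cbind(ids[sel[, 1]], ids[sel[, 2]]),
                             nodes = ids)
  list(network = net, modules = mods)
}

#' Module-factor expression matrix
#'
#' Each module gets an independent latent factor across samples; each gene
#' is `coexpr_effect x (its module factor) + N(0, noise_sd)` noise, so
#' co-module genes correlate and cross-module genes do not. With
#' `coexpr_effect = 0` the matrix is pure noise.
#'
#' @param modules named integer module labels (from
#'   [generate_true_interactome()]).
#' @param spec a `benchmark_spec`.
#' @return numeric matrix (proteins x samples).
#' @export
generate_expression <- function(modules, spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  n <- length(modules)
  withr::with_seed(spec$seed + 1L, {
    factors <- matrix(stats::rnorm(spec$n_modules * spec$n_samples),
                      spec$n_modules, spec$n_samples)
    noise <- matrix(stats::rnorm(n * spec$n_samples, sd = spec$noise_sd),
                    n, spec$n_samples)
  })
  expr <- spec$coexpr_effect * factors[modules, , drop = FALSE] + noise
  dimnames(expr) <- list(names(modules),
                         sprintf("S%02d", seq_len(spec$n_samples)))
  expr
}

#' Degrade a true interactome into an observed network
#'
#' Emulates an imperfect interaction screen: each true edge is missed
#' (dropped) with probability `fn_rate`, and spurious edges are added by
#' drawing `Binomial(|E|, fp_rate)` pairs uniformly from the true
#' non-edges, so `fp_rate` is the expected ratio of spurious to true
#' interactions.
#'
#' @param true_net the true `interaction_network`.
#' @param fp_rate,fn_rate degradation rates in \[0, 1).
#' @param seed integer RNG seed.
#' @return the observed `interaction_network` (same node set).
#' @export
degrade_interactome <- function(true_net, fp_rate, fn_rate, seed) {
  stopifnot(fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate <= 1)
  m <- n_edges(true_net)
  nodes <- true_net$nodes
  A <- adjacency_matrix(true_net)
  withr::with_seed(seed, {
    keep <- stats::runif(m) >= fn_rate
    nonedge_idx <- which(upper.tri(A) & A == 0L)
    n_fp <- stats::rbinom(1, m, fp_rate)
    n_fp <- min(n_fp, length(nonedge_idx))
    fp_idx <- if (n_fp > 0) sample(nonedge_idx, n_fp) else integer(0)
  })
  sel <- arrayInd(fp_idx, dim(A))
  edges <- rbind(true_net$edges[keep, , drop = FALSE],
                 cbind(nodes[sel[, 1]], nodes[sel[, 2]]))
  interaction_network(edges, nodes = nodes)
}

#' Synthetic IP-MS peptide-count table with planted ligands
#'
#' Plants ligands of a bait and emits per-replicate unique-peptide counts
#' for two purification conditions. Nuclease-condition (RNA-independent)
#' ligands are drawn from the bait's direct partners in the thresholded
#' probabilistic network, with inclusion probability proportional to
#' `P_in(bait, .)` (capped at 1, proportionality constant 2). The
#' no-nuclease condition additionally recruits two-hop partners (each with
#' probability 0.5), mimicking RNA-bridged co-purification. Counts are
#' negative binomial (`mu = baseline_count`, size `dispersion`) for
#' background, with the induced (Dox+) mean multiplied by
#' `ligand_enrichment` for planted ligands; rows where every count is zero
#' are omitted, as in a real detection table.
#'
#' @param pnet a `probabilistic_network`.
#' @param spec a `benchmark_spec` (supplies bait, count model, replicates
#'   and seed).
#' @param cutoff threshold defining direct/two-hop partners (default 0.1).
#' @return list with `records` (data frame in [read_ipms_table()] layout)
#'   and `truth` (planted `nucR`, `nucS` and their union `all`).
#' @export
generate_ipms_counts <- function(pnet, spec, cutoff = 0.1) {
  stopifnot(inherits(spec, "benchmark_spec"))
  bait <- spec$bait_id
  if (!bait %in% pnet$protein_ids) stop("bait absent from network")
  net <- threshold_network(pnet, cutoff)
  direct <- neighbors_of(net, bait)
  twohop <- setdiff(unique(unlist(lapply(direct, neighbors_of, net = net))),
                    c(bait, direct))
  others <- setdiff(pnet$protein_ids, bait)
  withr::with_seed(spec$seed + 2L, {
    p_inc <- pmin(1, 2 * pnet$pin[bait, direct])
    nucR_true <- direct[stats::runif(length(direct)) < p_inc]
    nucS_true <- twohop[stats::runif(length(twohop)) < 0.5]

    draw <- function(mu, n) stats::rnbinom(n, mu = mu, size = spec$dispersion)
    rows <- list()
    for (cond in c("nuclease", "no_nuclease")) {
      ligands <- if (cond == "nuclease") nucR_true else c(nucR_true, nucS_true)
      for (rep_i in seq_len(spec$n_replicates)) {
        mu_plus <- ifelse(others %in% ligands,
                          spec$ligand_enrichment * spec$baseline_count,
                          spec$baseline_count)
        p_plus <- draw(mu_plus, length(others))
        p_minus <- draw(spec$baseline_count, length(others))
        rows[[length(rows) + 1]] <- data.frame(
          bait = bait, ligand = others, condition = cond, replicate = rep_i,
          p_dox_plus = p_plus, p_dox_minus = p_minus,
          stringsAsFactors = FALSE)
      }
    }
  })
  records <- do.call(rbind, rows)
  records <- records[records$p_dox_plus + records$p_dox_minus > 0, ,
                     drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       truth = list(nucR = sort(nucR_true), nucS = sort(nucS_true),
                    all = sort(c(nucR_true, nucS_true))))
}

#' Probabilistic network with a planted high-probability hub
#'
#' Builds a sparse random probabilistic network in which one protein (the
#' hub) carries high-probability interactions with every other protein,
#' while background pairs are sparse and weaker. Used to validate the
#' centrality null calibration: the hub should dominate both weighted
#' degree and weighted betweenness.
#'
#' @param n number of proteins (>= 3).
#' @param background_density probability that a non-hub pair carries a
#'   background interaction.
#' @param hub_range,background_range P_in ranges for hub and background
#'   interactions.
#' @param seed integer RNG seed.
#' @return list with `pnet` (a `probabilistic_network`) and `hub` (the hub
#'   protein id, always the first protein).
#' @export
generate_hub_pnet <- function(n = 60, background_density = 0.05,
                              hub_range = c(0.7, 0.95),
                              background_range = c(0.1, 0.4), seed) {
  stopifnot(n >= 3)
  ids <- sprintf("P%03d", seq_len(n))
  P <- matrix(0, n, n)
  withr::with_seed(seed, {
    ut <- which(upper.tri(P))
    sel <- arrayInd(ut, c(n, n))
    is_hub <- sel[, 1] == 1
    keep_bg <- !is_hub & stats::runif(length(ut)) < background_density
    P[ut[is_hub]] <- stats::runif(sum(is_hub), hub_range[1], hub_range[2])
    P[ut[keep_bg]] <- stats::runif(sum(keep_bg), background_range[1],
                                   background_range[2])
  })
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  list(pnet = probabilistic_network(ids, P), hub = ids[1])
}

#' Run the full synthetic benchmark pipeline
#'
#' Generates the true interactome, expression and degraded observation,
#' fits the conditional model on the observation, and scores every
#' catalog pair. This is the standard object on which model recovery,
#' clustering, topology and IP-MS overlays are evaluated.
#'
#' @param spec a `benchmark_spec`.
#' @return list with `spec`, `modules`, `true_net`, `expr`, `observed`,
#'   `model` and `pnet`.
#' @export
benchmark_pipeline <- function(spec) {
  truth <- generate_true_interactome(spec)
  expr <- generate_expression(truth$modules, spec)
  observed <- degrade_interactome(truth$network, spec$fp_rate, spec$fn_rate,
                                  seed = spec$seed + 3L)
  model <- fit_conditional_models(observed, expr, seed = spec$seed + 4L)
  pnet <- build_ps_network(spec$protein_ids, observed, expr, model)
  list(spec = spec, modules = truth$modules, true_net = truth$network,
       expr = expr, observed = observed, model = model, pnet = pnet)
}
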