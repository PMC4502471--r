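# IP-MS enrichment scoring, ligand classification and network overlays.

test_that("logE follows the pseudo-count log-ratio with -Inf for undetected", {
  expect_equal(compute_logE(4, 1), 1.0)
  expect_equal(compute_logE(0, 7), -Inf)
  expect_equal(compute_logE(3, 0), log2(3))
  expect_error(compute_logE(-1, 0), "non-negative")
  expect_error(compute_logE(1.5, 0), "integers")
})

test_that("strict enrichment guarantees >2-fold and >= 3 peptides over empty control", {
  grid <- expand.grid(p_plus = 0:100, p_minus = 0:100)
  enriched <- compute_logE(grid$p_plus, grid$p_minus) > 1
  expect_true(all(grid$p_plus[enriched] > 2 * (grid$p_minus[enriched] + 1)))
  expect_true(all(grid$p_plus[enriched & grid$p_minus == 0] >= 3))
  expect_false(any(enriched[grid$p_plus == 4 & grid$p_minus == 1]))
})

test_that("ligand classification partitions the catalog into nucR/nucS/undetected", {
  catalog <- c("BAIT", "L1", "L2", "L3", "L4")
  rec <- function(lig, cond, rep_i, plus, minus)
    data.frame(bait = "BAIT", ligand = lig, condition = cond,
               replicate = rep_i, p_dox_plus = plus, p_dox_minus = minus)
  records <- rbind(
    rec("L1", "nuclease", 1, 5, 0), rec("L1", "no_nuclease", 1, 6, 0),
    rec("L2", "nuclease", 1, 2, 0), rec("L2", "no_nuclease", 1, 8, 0),
    rec("L3", "nuclease", 1, 0, 0), rec("L3", "no_nuclease", 1, 0, 0))
  ls <- select_enriched(records, catalog)
  expect_equal(ls$nucR, "L1")           # enriched in both; nuclease wins
  expect_equal(ls$nucS, "L2")           # log2(2/1) = 1 fails, log2(8/1) = 3 passes
  expect_setequal(ls$undetected, c("L3", "L4"))
  # exhaustive and disjoint partition
  expect_setequal(c(ls$bait, ls$nucR, ls$nucS, ls$undetected), catalog)
  expect_length(intersect(ls$nucR, ls$nucS), 0)

  # replicates pool by summation: 2+2 peptides over empty control is enriched
  reps <- rbind(rec("L1", "nuclease", 1, 2, 0), rec("L1", "nuclease", 2, 2, 0))
  expect_equal(select_enriched(reps, catalog)$nucR, "L1")

  expect_warning(
    ls2 <- select_enriched(rbind(records, rec("BAIT", "nuclease", 1, 50, 0)),
                           catalog),
    "own ligand")
  expect_false("BAIT" %in% c(ls2$nucR, ls2$nucS))
})

make_ligset <- function(bait, nucR, nucS, catalog) {
  structure(list(bait = bait, nucR = nucR, nucS = nucS,
                 undetected = sort(setdiff(catalog, c(bait, nucR, nucS))),
                 scores = NULL), class = "ligand_set")
}

test_that("the P_in overlay separates constructed ligand and background groups", {
  ids <- c("B", sprintf("R%d", 1:6), sprintf("U%d", 1:6))
  edges <- c(lapply(sprintf("R%d", 1:6), function(x) list("B", x, 0.95)),
             lapply(sprintf("U%d", 1:6), function(x) list("B", x, 0.05)))
  pn <- pnet_from_edges(ids, edges)
  ls <- make_ligset("B", sprintf("R%d", 1:6), character(0), ids)
  ov <- pin_distribution_overlay(pn, ls)
  expect_equal(unname(ov$proportions["nucR", 10]), 1)   # all in (0.9, 1]
  expect_equal(unname(ov$proportions["undetected", 1]), 1)
  expect_lt(ov$p_nucR, 0.05)
  expect_true(is.na(ov$p_nucS))                         # empty group skipped
  sums <- rowSums(ov$proportions, na.rm = TRUE)
  expect_equal(unname(sums[c("nucR", "undetected")]), c(1, 1))
})

test_that("the overlay test holds its size under the null", {
  ids <- c("B", sprintf("X%02d", 1:40))
  rejections <- 0
  for (s in 1:30) {
    pn <- withr::with_seed(s, {
      P <- matrix(0, 41, 41)
      P[1, -1] <- P[-1, 1] <- runif(40)          # iid bait probabilities
      probabilistic_network(ids, P)
    })
    lig <- withr::with_seed(1000 + s, sample(ids[-1], 10))
    ls <- make_ligset("B", lig, character(0), ids)
    ov <- pin_distribution_overlay(pn, ls)
    if (ov$p_nucR < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)   # no rejection in >= 90% of null draws
})

test_that("bait proximity matches exhaustive path enumeration", {
  pn <- random_pnet(7, seed = 71)
  ls <- make_ligset(pn$protein_ids[1], pn$protein_ids[2:3],
                    pn$protein_ids[4], pn$protein_ids)
  bp <- bait_proximity(pn, ls, cutoff = 0.3)
  oracle <- enum_paths(pn, cutoff = 0.3)
  d <- oracle$distances[pn$protein_ids[1], ]
  expect_equal(unname(bp$mean_dist["nucR"]),
               mean(d[pn$protein_ids[2:3]][is.finite(d[pn$protein_ids[2:3]])]))
  un <- ls$undetected
  expect_equal(unname(bp$mean_dist["undetected"]),
               mean(d[un][is.finite(d[un])]))
})

test_that("bait proximity orders adjacent ligands before distant background", {
  ids <- c("B", "R1", "R2", "M", "U1", "U2")
  pn <- pnet_from_edges(ids, list(
    list("B", "R1", 0.9), list("B", "R2", 0.9), list("B", "M", 0.9),
    list("M", "U1", 0.9), list("M", "U2", 0.9)))
  ls <- make_ligset("B", c("R1", "R2"), character(0), ids)
  bp <- bait_proximity(pn, ls)
  expect_lt(bp$mean_dist["nucR"], bp$mean_dist["undetected"])
  iso <- pnet_from_edges(ids, list(list("R1", "R2", 0.9)))
  expect_error(bait_proximity(iso, ls), "isolated")
})

test_that("the FC regression recovers proportionality and rejects shuffles", {
  bench <- get_benchmark(101)
  cl <- hierarchical_clusters(profile_distance_matrix(bench$pnet), k = 6)
  bait <- bench$spec$bait_id
  predicted <- setdiff(
    bench$pnet$protein_ids[bench$pnet$pin[bait, ] >= 0.1], bait)
  # observed ligands exactly = predicted partners -> proportions identical
  ls <- make_ligset(bait, predicted, character(0), bench$pnet$protein_ids)
  fr <- fc_regression(bench$pnet, cl, ls)
  expect_equal(fr$r_squared, 1.0)
  expect_equal(sum(fr$points$expected), 1)
  expect_equal(sum(fr$points$observed), 1)

  # invariance to cluster relabeling
  relab <- cl
  perm <- c(3, 1, 2, 6, 4, 5)
  relab$cluster <- setNames(perm[cl$cluster], names(cl$cluster))
  fr2 <- fc_regression(bench$pnet, relab, ls)
  expect_equal(fr2$r_squared, fr$r_squared)

  # ligands unrelated to the network structure: R^2 collapses
  low <- 0
  for (s in 1:20) {
    shuffled <- withr::with_seed(s, sample(bench$pnet$protein_ids[-1],
                                           length(predicted)))
    frs <- fc_regression(bench$pnet, cl,
                         make_ligset(bait, shuffled, character(0),
                                     bench$pnet$protein_ids))
    if (frs$r_squared < 0.2) low <- low + 1
  }
  expect_gte(low, 18)   # >= 90% of shuffles
})

test_that("the complex screen flags full-member coverage", {
  ids <- c("B", "c1", "c2", "c3", "d1")
  pn <- pnet_from_edges(ids, list(
    list("B", "c1", 0.5), list("B", "c2", 0.5), list("B", "c3", 0.5),
    list("B", "d1", 0.05)))
  cx <- data.frame(complex_id = c(rep("good", 3), rep("bad", 2)),
                   protein_id = c("c1", "c2", "c3", "c1", "d1"))
  scr <- complex_screen(cx, pn, "B")
  expect_true(scr$full_coverage[scr$complex_id == "good"])
  expect_false(scr$full_coverage[scr$complex_id == "bad"])  # d1 below cutoff
  expect_equal(scr$complex_id[1], "good")                   # ranked first
})

test_that("a planted complex is uniquely recovered among decoys", {
  bench <- get_benchmark(101)
  bait <- bench$spec$bait_id
  mods <- bench$modules
  planted <- setdiff(names(mods)[mods == mods[bait]], bait)[1:7]
  decoys <- withr::with_seed(81, lapply(1:12, function(i)
    sample(setdiff(names(mods), c(bait, planted)), 7)))
  cx <- data.frame(
    complex_id = rep(c("planted", sprintf("decoy%02d", 1:12)), each = 7),
    protein_id = c(planted, unlist(decoys)))
  scr <- complex_screen(cx, bench$pnet, bait)
  expect_identical(scr$complex_id[scr$full_coverage], "planted")
})
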