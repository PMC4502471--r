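# Transitivity, co-expression, decoy fitting and the Bayesian posterior.

test_that("transitivity is the shared/exclusive third-party ratio", {
  net <- toy_net(list(c("a", "x"), c("a", "y"), c("a", "z"),
                      c("b", "x"), c("b", "y"), c("b", "z")))
  expect_equal(compute_transitivity(net, "a", "b"), 1.0)

  net <- toy_net(list(c("a", "x"), c("a", "y"), c("b", "w"), c("b", "z")))
  expect_equal(compute_transitivity(net, "a", "b"), 0.0)

  net <- toy_net(list(c("a", "x"), c("a", "y"), c("a", "z"),
                      c("b", "y"), c("b", "z"), c("b", "w")))
  expect_equal(compute_transitivity(net, "a", "b"), 0.5)  # {y,z} vs {x,w}

  expect_error(compute_transitivity(net, "a", "a"), "self")
  expect_error(compute_transitivity(net, "a", "nope"), "unknown")
})

test_that("a direct edge does not alter the pair's transitivity", {
  net <- toy_net(list(c("a", "x"), c("a", "y"), c("b", "y"), c("b", "z")))
  with_direct <- interaction_network(rbind(net$edges, c("a", "b")))
  expect_equal(compute_transitivity(with_direct, "a", "b"),
               compute_transitivity(net, "a", "b"))
})

test_that("the all-pairs transitivity matrix agrees with pairwise set enumeration", {
  for (seed in 1:3) {
    net <- random_net(12, p = 0.3, seed = seed)
    Tm <- transitivity_matrix(net)
    expect_true(all(Tm == t(Tm)))
    ids <- net$nodes
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(Tm[ids[i], ids[j]],
                   compute_transitivity(net, ids[i], ids[j]))
    }
  }
})

test_that("co-expression is Pearson correlation with missing as a value", {
  expr <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1),
                g4 = c(1, 2, 4), flat = c(5, 5, 5))
  colnames(expr) <- paste0("s", 1:3)
  expect_equal(compute_coexpression(expr, "g1", "g2"), 1.0)
  expect_equal(compute_coexpression(expr, "g1", "g3"), -1.0)
  expect_equal(compute_coexpression(expr, "g1", "g4"), 0.981980506,
               tolerance = 1e-8)
  expect_true(is.na(compute_coexpression(expr, "g1", "flat")))
  expect_true(is.na(compute_coexpression(expr, "g1", "absent")))
  Cm <- coexpression_matrix(expr, c("g1", "g4", "flat", "absent"))
  expect_equal(Cm["g1", "g4"], 0.981980506, tolerance = 1e-8)
  expect_true(all(is.na(Cm["flat", c("g1", "g4")])))
  expect_true(all(is.na(Cm["absent", ])))
})

test_that("decoy rewiring preserves nodes and degree sequence, seeded", {
  net <- random_net(50, p = 0.12, seed = 3)
  d1 <- make_decoy_network(net, seed = 1)
  expect_identical(d1$nodes, net$nodes)
  expect_equal(n_edges(d1), n_edges(net))
  deg <- function(x) sort(table(factor(c(x$edges), levels = x$nodes)))
  expect_equal(deg(d1), deg(net))

  d1b <- make_decoy_network(net, seed = 1)
  expect_identical(d1$edges, d1b$edges)
  d2 <- make_decoy_network(net, seed = 2)
  expect_false(identical(d1$edges, d2$edges))
  # decoy must actually differ from the input for a rewireable network
  expect_false(setequal(pair_key(d1$edges[, 1], d1$edges[, 2]),
                        pair_key(net$edges[, 1], net$edges[, 2])))

  star <- toy_net(list(c("c", "a"), c("c", "b"), c("c", "d")))
  expect_warning(make_decoy_network(star, seed = 1), "unchanged")
  expect_error(make_decoy_network(toy_net(list(c("a", "b"))), seed = 1),
               "at least 2")
})

test_that("conditional likelihoods normalise and separate a modular network", {
  spec <- benchmark_spec(seed = 5)
  truth <- generate_true_interactome(spec)
  expr <- generate_expression(truth$modules, spec)
  model <- fit_conditional_models(truth$network, expr, seed = 9)
  expect_equal(sum(model$lik_t["e0", ]), 1, tolerance = 1e-9)
  expect_equal(sum(model$lik_t["e1", ]), 1, tolerance = 1e-9)
  expect_equal(sum(model$lik_c["e0", ]), 1, tolerance = 1e-9)
  expect_equal(sum(model$lik_c["e1", ]), 1, tolerance = 1e-9)
  expect_true(all(model$lik_t > 0) && all(model$lik_c > 0))

  # interacting pairs in a modular network carry more transitivity
  Tm <- transitivity_matrix(truth$network)
  decoy <- make_decoy_network(truth$network, seed = 9)
  t_pos <- Tm[cbind(truth$network$edges[, 1], truth$network$edges[, 2])]
  t_neg <- Tm[cbind(decoy$edges[, 1], decoy$edges[, 2])]
  expect_gt(mean(t_pos), mean(t_neg))
})

test_that("the automatic prior is the training edge density", {
  net <- random_net(10, p = 1, seed = 1)           # complete, then trim
  net <- interaction_network(net$edges[1:9, ], nodes = net$nodes)
  # the 9-edge subgraph is star-like, so the decoy may warn about swaps
  model <- suppressWarnings(fit_conditional_models(net, expr = NULL, seed = 2))
  expect_equal(model$prior, 9 / 45)
  expect_false(model$has_coexpression)
  expect_error(fit_conditional_models(interaction_network(nodes = c("a", "b"))),
               "empty")
})

test_that("the posterior follows Bayes' rule on the binned evidence", {
  # uninformative evidence returns the prior
  m <- manual_model(prior = 0.3, t_ratio = 1, c_ratio = 1)
  expect_equal(posterior_pin(m, t = 0.8, c = 0.9), 0.3)
  # likelihood ratio 3 at even prior gives 3/4
  m <- manual_model(prior = 0.5, t_ratio = 3, c_ratio = 1)
  expect_equal(posterior_pin(m, t = 0.8, c = 0.9), 0.75)
  # missing co-expression drops the C factors
  m <- manual_model(prior = 0.5, t_ratio = 3, c_ratio = 5)
  expect_equal(posterior_pin(m, t = 0.8, c = NA), 0.75)
  # monotone in the joint likelihood ratio at fixed prior
  ratios <- c(0.2, 0.5, 1, 2, 5, 20)
  post <- vapply(ratios, function(r)
    posterior_pin(manual_model(0.3, t_ratio = r), t = 0.8, c = NA),
    numeric(1))
  expect_true(all(diff(post) > 0))
})

test_that("a smoothed model never returns exactly 0 or 1", {
  net <- random_net(20, p = 0.25, seed = 6)
  model <- fit_conditional_models(net, expr = NULL, smoothing = 1, seed = 1)
  tt <- seq(0, 1, length.out = 41)
  p <- posterior_pin(model, tt)
  expect_true(all(p > 0 & p < 1))
})

test_that("build_ps_network scores every unordered catalog pair", {
  bench <- get_benchmark(101)
  pn <- bench$pnet
  expect_equal(length(pn$protein_ids), 120)
  expect_true(all(pn$pin == t(pn$pin)))
  expect_true(all(pn$pin >= 0 & pn$pin <= 1))
  expect_true(all(diag(pn$pin) == 0))

  small <- build_ps_network(c("P001", "P002", "P003", "P004"),
                            bench$observed, bench$expr, bench$model)
  expect_equal(sum(upper.tri(small$pin)), 6)
  expect_error(build_ps_network("P001", bench$observed, bench$expr,
                                bench$model), "at least 2")
})

test_that("scores are invariant to catalog ordering", {
  bench <- get_benchmark(101)
  ids <- bench$spec$protein_ids[1:30]
  p1 <- build_ps_network(ids, bench$observed, bench$expr, bench$model)
  perm <- rev(ids)
  p2 <- build_ps_network(perm, bench$observed, bench$expr, bench$model)
  expect_equal(p2$pin[ids, ids], p1$pin[ids, ids])
})

test_that("removing a direct edge barely moves the pair's posterior", {
  bench <- get_benchmark(101)
  edges <- bench$observed$edges
  take <- seq(1, nrow(edges), length.out = 25)
  deltas <- vapply(take, function(k) {
    e <- edges[k, ]
    without <- interaction_network(edges[-k, , drop = FALSE],
                                   nodes = bench$observed$nodes)
    Tm <- transitivity_matrix(without, e)
    Cm <- coexpression_matrix(bench$expr, e)
    p_without <- posterior_pin(bench$model, Tm[1, 2], Cm[1, 2])
    abs(bench$pnet$pin[e[1], e[2]] - p_without)
  }, numeric(1))
  expect_lt(stats::median(deltas), 0.1)
})

test_that("a fitted model serialises to JSON and back", {
  bench <- get_benchmark(101)
  f <- withr::local_tempfile(fileext = ".json")
  write_conditional_model(bench$model, f)
  m2 <- read_conditional_model(f)
  expect_equal(m2$lik_t, bench$model$lik_t)
  expect_equal(m2$lik_c, bench$model$lik_c)
  expect_equal(m2$prior, bench$model$prior)
  tt <- c(0.03, 0.2, 0.77)
  expect_equal(posterior_pin(m2, tt), posterior_pin(bench$model, tt))
})
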