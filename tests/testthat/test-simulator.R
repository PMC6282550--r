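test_that("simulation replays deterministically under a fixed seed", {
  cfg <- sim_config(oracle_params(), T = 20, seed = 7, conditioning = "survival")
  t1 <- simulate_bd_tree(cfg)
  t2 <- simulate_bd_tree(cfg)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$tips, t2$tips)
  expect_identical(to_newick(t1), to_newick(t2))
})

test_that("pure-birth runs never lose lineages and every lineage survives", {
  cfg <- sim_config(bd_params(0.3, 0), T = 20, seed = 11)
  trees <- simulate_bd_trees(cfg, 20)
  for (tr in trees) {
    expect_true(all(tr$events$kind == "speciation"))
    expect_gte(length(tr$tips), 1L)
    cl <- classify_lineages(tr)
    expect_true(all(cl$status == "surviving"))
  }
})

test_that("unconditioned runs match the analytic survival probability and mean size", {
  cfg <- sim_config(oracle_params(), T = 20, seed = 123)
  n_rep <- 10000
  trees <- simulate_bd_trees(cfg, n_rep)
  tips <- vapply(trees, function(tr) length(tr$tips), integer(1))
  s_hat <- mean(tips >= 1)
  s <- survival_probability(oracle_params(), 20)
  expect_lt(abs(s_hat - s), 1.96 * sqrt(s * (1 - s) / n_rep) + 1e-9)
  # mean tip count (including extinct runs) is exp((lambda - mu) T)
  expect_lt(abs(mean(tips) - exp(0.1 * 20)),
            3 * stats::sd(tips) / sqrt(n_rep))
})

test_that("surviving-run sizes follow the zero-truncated geometric law", {
  cfg <- sim_config(oracle_params(), T = 20, seed = 99, conditioning = "survival")
  trees <- simulate_bd_trees(cfg, 5000)
  sizes <- vapply(trees, function(tr) length(tr$tips), integer(1))
  d <- clade_size_distribution(oracle_params(), 20)
  expect_gt(chisq_pvalue(sizes, d), 0.01)
})

test_that("lineage classification separates plesions from the surviving spine", {
  # hand-built history: founder speciates at t=2; the daughter dies at t=5;
  # the founder survives to T=10
  tree <- structure(list(
    events = data.frame(time = c(2, 5), kind = c("speciation", "extinction"),
                        lineage = c(1L, 2L), child = c(2L, NA)),
    tips = 1L, n_lineages = 2L, T = 10, params = oracle_params()),
    class = "bd_tree")
  cl <- classify_lineages(tree)
  expect_identical(cl$status, c("surviving", "plesion"))
  expect_identical(cl$plesion_origins, c(1L, 0L))
  expect_identical(lineage_counts(list(tree), 3, "n"), 2L)
  expect_identical(lineage_counts(list(tree), 3, "m"), 1L)
  expect_identical(lineage_counts(list(tree), 6, "n"), 1L)
  # a root that dies leaves only plesions
  dead <- structure(list(
    events = data.frame(time = 4, kind = "extinction", lineage = 1L, child = NA),
    tips = integer(0), n_lineages = 1L, T = 10, params = oracle_params()),
    class = "bd_tree")
  expect_identical(classify_lineages(dead)$status, "plesion")
})

test_that("plesion production along stem paths runs at about twice the speciation rate", {
  # along a reconstructed surviving path, speciation events occur at the
  # elevated observed rate (2 - s) lambda; all of them except the crown
  # splits (rate s lambda) leave a plesion on one side, so plesions arise
  # at 2 lambda (1 - s) per path-Myr, with s the survival probability over
  # the time left to the present. A plesion can hang off either side: the
  # new child's subtree may die (child-side), or the mother's own
  # continuation may die while the path continues through the child
  # (mother-side, surv_until equal to that child's birth).
  p <- oracle_params()
  cfg <- sim_config(p, T = 40, seed = 31, conditioning = "survival")
  trees <- simulate_bd_trees(cfg, 1500)
  t_half <- 20
  origins <- 0
  exposure <- 0
  for (tr in trees) {
    cl <- classify_lineages(tr)
    # exposure: time each lineage spends on a reconstructed path (alive
    # with descendants still ahead), clipped to the first half of the run
    on_path_until <- pmin(cl$surv_until, cl$death, tr$T, t_half)
    exposure <- exposure + sum(pmax(0, on_path_until - pmin(cl$birth, t_half)))
    ev <- tr$events
    sp <- ev[ev$kind == "speciation" & ev$time <= t_half, , drop = FALSE]
    if (nrow(sp) > 0) {
      su <- cl$surv_until
      child_side <- su[sp$lineage] > sp$time & su[sp$child] == -Inf
      mother_side <- su[sp$child] > -Inf & su[sp$lineage] == sp$time
      origins <- origins + sum(child_side) + sum(mother_side)
    }
  }
  rate_hat <- origins / exposure
  s_mid <- survival_probability(p, 30) # time left at the window midpoint
  predicted <- 2 * p$lambda * (1 - s_mid)
  se <- sqrt(origins) / exposure
  expect_lt(abs(rate_hat - predicted), 3 * se + 0.1 * predicted)
})

test_that("Newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  cfg <- sim_config(oracle_params(), T = 30, seed = 5, conditioning = "survival")
  trees <- simulate_bd_trees(cfg, 40)
  big <- trees[[which.max(vapply(trees, function(x) x$n_lineages, integer(1)))]]
  nwk <- to_newick(big)
  ph <- ape::read.tree(text = nwk)
  expect_identical(length(ph$tip.label), as.integer(big$n_lineages))
  root_edge <- if (is.null(ph$root.edge)) 0 else ph$root.edge
  # total branch length equals the summed lifespan of all lineages
  lt <- classify_lineages(big)
  lifespan <- sum(pmin(lt$death, big$T) - lt$birth)
  expect_equal(sum(ph$edge.length) + root_edge, lifespan, tolerance = 1e-9)
  # extant tips sit at depth T; extinct tips end at their extinction time
  depth <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)] + root_edge
  extant <- grepl("extant", ph$tip.label)
  expect_equal(depth[extant], rep(big$T, sum(extant)), tolerance = 1e-9)
  expect_true(all(depth[!extant] < big$T))
})

test_that("single-lineage and root-extinct trees export to well-formed Newick", {
  lone <- structure(list(
    events = data.frame(time = numeric(0), kind = character(0),
                        lineage = integer(0), child = integer(0)),
    tips = 1L, n_lineages = 1L, T = 12, params = oracle_params()),
    class = "bd_tree")
  expect_identical(to_newick(lone), "(L1_extant:12);")
  dead <- structure(list(
    events = data.frame(time = 4, kind = "extinction", lineage = 1L, child = NA),
    tips = integer(0), n_lineages = 1L, T = 12, params = oracle_params()),
    class = "bd_tree")
  expect_identical(to_newick(dead), "(L1_extinct:4);")
})

test_that("empirical distributions have the right boundaries", {
  cfg <- sim_config(oracle_params(), T = 20, seed = 17, conditioning = "size_window",
                    nT_target = 10, window_frac = 0)
  trees <- simulate_bd_trees(cfg, 300)
  d0 <- empirical_distribution(trees, 0, "n")
  expect_identical(support(d0), 1L)
  dT <- empirical_distribution(trees, 20, "m")
  expect_identical(support(dT), 10L)
  expect_error(empirical_distribution(list(), 5, "n"), "empty")
  expect_gt(attr(trees, "attempts"), 300)
})

test_that("impossible conditioning fails with an acceptance-rate diagnostic", {
  cfg <- sim_config(oracle_params(), T = 20, seed = 3,
                    conditioning = "size_window", nT_target = 5000,
                    window_frac = 0, max_attempts = 200)
  expect_error(simulate_bd_trees(cfg, 1), "acceptance")
})
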