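test_that("Yule trees have the right shape and are reproducible", {
  t2 <- simulate_tree(2, seed = 1)
  d <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(d[1], d[2])                      # ultrametric cherry
  t64 <- simulate_tree(64, seed = 2)
  expect_equal(t64$Nnode, 63)                   # binary: n - 1 internal nodes
  expect_identical(ape::write.tree(simulate_tree(64, seed = 2)),
                   ape::write.tree(t64))
  expect_false(identical(ape::write.tree(simulate_tree(64, seed = 3)),
                         ape::write.tree(t64)))
})

test_that("Brownian traits follow the variance law and sibling correlation", {
  tree <- simulate_tree(32, seed = 4)
  expect_equal(unname(simulate_traits(tree, 0)), rep(0, 32))
  h <- max(ape::node.depth.edgelength(tree))
  # variance across replicate simulations ~ sigma^2 * tip depth
  tips <- vapply(1:300, function(s) simulate_traits(tree, 1, seed = s)[1],
                 numeric(1))
  expect_lt(abs(var(tips) - h) / h, 0.35)
  # matrix form: one column per dimension
  tm <- simulate_traits(tree, 1, seed = 5, n_dims = 3)
  expect_equal(dim(tm), c(32, 3))
  # sibling tips are strongly correlated over replicates
  D <- patristic_distances(tree)
  diag(D) <- Inf
  sib <- which(D == min(D), arr.ind = TRUE)[1, ]
  pair <- t(vapply(1:200, function(s) simulate_traits(tree, 1, seed = s)[sib],
                   numeric(2)))
  expect_gt(cor(pair[, 1], pair[, 2]), 0.6)
})

test_that("the selection assembler filters by niche distance", {
  traits <- c(a = 0, b = 10)
  # strong filter at environment 0: taxon 'a' dominates at any depth
  x <- suppressWarnings(
    assemble_selection(as.matrix(traits), 0, sigma_w = 0.5, depth = 1000,
                       fitness = c(1, 1), drift_theta = Inf, seed = 1))
  expect_equal(sum(x), 1000)
  expect_gt(x["a"], 990)
  # very wide filter reduces to the fitness-weighted neutral draw
  set.seed(2); fit <- rlnorm(2)
  y <- assemble_selection(as.matrix(traits), 0, sigma_w = 1e6, depth = 1e5,
                          fitness = fit, drift_theta = Inf, seed = 3)
  expect_equal(unname(y["a"] / sum(y)), fit[1] / sum(fit), tolerance = 0.02)
  expect_error(assemble_selection(as.matrix(traits), 0, sigma_w = 0,
                                  depth = 10), "sigma_w")
})

test_that("the neutral assembler tracks the metacommunity as m grows", {
  set.seed(6)
  prof <- rlnorm(50); prof <- prof / sum(prof); names(prof) <- paste0("o", 1:50)
  x <- assemble_neutral(prof, m = 1, depth = 50000, seed = 1)
  expect_equal(sum(x), 50000)
  expect_lt(max(abs(x / 50000 - prof)), 0.02)   # high coupling: profile recovered
  # drift increases divergence between replicate samples monotonically in m
  div <- vapply(c(0.01, 0.1, 0.9), function(m) {
    pairs <- vapply(1:12, function(i) {
      a <- assemble_neutral(prof, m, 2000, seed = 2 * i)
      b <- assemble_neutral(prof, m, 2000, seed = 2 * i + 1)
      sum(abs(a - b)) / sum(a + b)
    }, numeric(1))
    mean(pairs)
  }, numeric(1))
  expect_true(all(diff(div) < 0))
  expect_error(assemble_neutral(prof, 0, 100), "m must be")
  expect_error(assemble_neutral(prof * 2, 0.5, 100), "sum to 1")
})

test_that("scenario datasets satisfy their structural contract", {
  for (scn in c("selection_variable", "selection_homogeneous",
                "neutral_well_mixed", "neutral_dispersal_limited")) {
    sc <- suppressWarnings(
      make_scenario(scenario_config(scn, n_taxa = 64,
                                    samples_per_group = 4, depth = 1000,
                                    seed = 11)))
    expect_equal(dim(sc$counts), c(12, 64))
    expect_equal(unname(rowSums(sc$counts)), rep(1000, 12))
    expect_setequal(sc$tree$tip.label, colnames(sc$counts))
    expect_equal(sc$design$sample_id, rownames(sc$counts))
    expect_equal(nrow(sc$truth), 12)
  }
  # bit-exact reproducibility from (config, seed)
  a <- make_scenario(scenario_config("selection_variable", seed = 9))
  b <- make_scenario(scenario_config("selection_variable", seed = 9))
  expect_identical(a$counts, b$counts)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("stronger filters never weaken phylogenetic clustering", {
  # NTI is non-decreasing as sigma_w shrinks (checked on a fixed seed grid)
  ntis <- vapply(c(1.5, 0.6, 0.25), function(swf) {
    sc <- make_scenario(scenario_config("selection_homogeneous",
                                        sigma_w_factor = swf, n_taxa = 100,
                                        samples_per_group = 4, depth = 2000,
                                        seed = 10))
    mean(nti(sc$counts, sc$tree, n_randomizations = 99, seed = 2)$nti)
  }, numeric(1))
  expect_true(all(diff(ntis) > -0.5))   # monotone up to sampling tolerance
  expect_gt(ntis[3], ntis[1])
})
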