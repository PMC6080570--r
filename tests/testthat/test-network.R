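test_that("correlations of log abundances behave at the edges", {
  set.seed(4)
  base <- matrix(rpois(8 * 4, 30) + 1, 8, 4,
                 dimnames = list(paste0("s", 1:8), paste0("o", 1:4)))
  base[, 2] <- base[, 1] * 2          # identical log-profile up to a constant
  r <- suppressWarnings(correlation_matrix(base))
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["o1", "o2"], 1, tolerance = 1e-6)  # pseudocount breaks exactness
  expect_lt(max(abs(r - t(r))), 1e-12)
  expect_true(all(abs(r) <= 1 + 1e-12))
})

test_that("thresholding uses the inclusive cutoff and records signs", {
  r <- diag(4)
  dimnames(r) <- list(paste0("o", 1:4), paste0("o", 1:4))
  r["o1", "o2"] <- r["o2", "o1"] <- 0.89
  r["o1", "o3"] <- r["o3", "o1"] <- 0.88
  r["o2", "o3"] <- r["o3", "o2"] <- -0.95
  net <- threshold_network(r, 0.89)
  el <- igraph::as_edgelist(net)
  pairs <- apply(el, 1, function(x) paste(sort(x), collapse = "-"))
  expect_setequal(pairs, c("o1-o2", "o2-o3"))   # 0.89 in, 0.88 out
  expect_setequal(igraph::E(net)$sign, c("+", "-"))
  expect_false("o4" %in% igraph::V(net)$name)   # isolated node dropped
  net2 <- threshold_network(r, 0.89, keep_isolated = TRUE)
  expect_true("o4" %in% igraph::V(net2)$name)
  # edge count non-increasing in the cutoff
  set.seed(9)
  rr <- cor(matrix(rnorm(100), 10, 10)); dimnames(rr) <- dimnames(diag(10))
  rownames(rr) <- colnames(rr) <- paste0("x", 1:10)
  ec <- vapply(c(0.2, 0.4, 0.6, 0.8),
               function(ct) igraph::ecount(threshold_network(rr, ct)), numeric(1))
  expect_true(all(diff(ec) <= 0))
})

test_that("the K4 panel matches closed forms", {
  r <- matrix(1, 4, 4, dimnames = list(paste0("o", 1:4), paste0("o", 1:4)))
  net <- threshold_network(r, 0.89)
  pan <- topology_panel(net)
  expect_equal(pan$avgK, 3)
  expect_equal(pan$D, 1)
  expect_equal(pan$avgCC, 1)
  expect_equal(pan$Con, 1)
  expect_equal(pan$positive_fraction, 1)
  expect_lt(abs(pan$M), 1e-12)
})

test_that("connectedness counts reachable ordered pairs", {
  # two disjoint triangles: each node reaches 2 of 5 others
  r <- diag(6); rownames(r) <- colnames(r) <- paste0("o", 1:6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    r[p[1], p[2]] <- r[p[2], p[1]] <- 1
  net <- threshold_network(r, 0.5)
  pan <- topology_panel(net)
  expect_equal(pan$Con, 12 / 30)
  expect_equal(pan$avgCC, 1)
  mods <- detect_modules(net)
  # disconnected components never share a module
  memb <- mods$membership
  expect_true(length(unique(memb[paste0("o", 1:3)])) == 1)
  expect_true(length(unique(memb[paste0("o", 4:6)])) == 1)
  expect_false(memb["o1"] == memb["o4"])
})

test_that("greedy modules recover planted cliques with the right modularity", {
  # two 5-cliques joined by one edge
  r <- diag(10); rownames(r) <- colnames(r) <- paste0("o", 1:10)
  for (i in 1:5) for (j in 1:5) if (i != j) r[i, j] <- 1
  for (i in 6:10) for (j in 6:10) if (i != j) r[i, j] <- 1
  r[5, 6] <- r[6, 5] <- 1
  net <- threshold_network(r, 0.5)
  mods <- detect_modules(net)
  memb <- mods$membership
  expect_equal(length(unique(memb[paste0("o", 1:5)])), 1)
  expect_equal(length(unique(memb[paste0("o", 6:10)])), 1)
  # hand-evaluated modularity of that partition: E=21, within 20,
  # degree sums 21 each: M = 20/21 - 2*(21/42)^2
  expect_equal(mods$modularity, 20 / 21 - 2 * (21 / 42)^2, tolerance = 1e-12)
  expect_gte(mods$modularity, -0.5)
  expect_lte(mods$modularity, 1)
})

test_that("Zi and Pi follow their formulas", {
  # star-like toy: hub o1 connects both cliques
  r <- diag(6); rownames(r) <- colnames(r) <- paste0("o", 1:6)
  edges <- list(c(2, 3), c(2, 4), c(3, 4), c(5, 6))
  for (p in edges) r[p[1], p[2]] <- r[p[2], p[1]] <- 1
  r[1, 2] <- r[2, 1] <- 1
  r[1, 5] <- r[5, 1] <- 1
  net <- threshold_network(r, 0.5)
  mods <- list(membership = c(o1 = 1L, o2 = 1L, o3 = 1L, o4 = 1L,
                              o5 = 2L, o6 = 2L))
  zp <- zi_pi(net, mods)
  rownames(zp) <- zp$otu
  # o1 splits its 2 links evenly across modules: Pi = 1 - 2*(1/2)^2
  expect_equal(zp["o1", "Pi"], 0.5)
  # nodes with all links inside their module: Pi = 0
  expect_equal(zp["o3", "Pi"], 0)
  expect_equal(zp["o6", "Pi"], 0)
  # module 2 has equal within-degrees -> Zi = 0
  expect_equal(zp["o5", "Zi"], 0)
  expect_true(all(zp$Pi >= 0 & zp$Pi <= 1))
})

test_that("role classification partitions the Zi-Pi plane", {
  zp <- data.frame(otu = paste0("o", 1:6), module = 1L, degree = 1,
                   Zi = c(3.0, 0.0, 3.0, 1.0, 2.5, 2.6),
                   Pi = c(0.7, 0.0, 0.1, 0.8, 0.62, 0.62))
  out <- classify_roles(zp)
  expect_equal(out$role,
               c("network hub", "peripheral", "module hub", "connector",
                 "peripheral",        # boundary Zi = 2.5, Pi = 0.62 -> <= side
                 "module hub"))       # Zi > 2.5, Pi = 0.62 (not > 0.62)
  expect_equal(out$keystone, out$role != "peripheral")
  expect_true(all(table(out$role) >= 0))  # every node exactly one role
  expect_equal(sum(table(out$role)), 6)
})

test_that("panel identities hold on random graphs", {
  set.seed(12)
  for (rep in 1:3) {
    rr <- cor(matrix(rnorm(15 * 40), 40, 15))
    rownames(rr) <- colnames(rr) <- paste0("o", 1:15)
    net <- threshold_network(rr, 0.3)
    if (igraph::ecount(net) == 0) next
    pan <- topology_panel(net)
    expect_equal(pan$avgK, 2 * pan$n_edges / pan$n_nodes, tolerance = 1e-12)
    expect_equal(pan$D, pan$avgK / (pan$n_nodes - 1), tolerance = 1e-12)
    expect_true(pan$Con >= 0 && pan$Con <= 1)
  }
})

test_that("per-group network wrapper runs end to end", {
  sc <- make_scenario(scenario_config("neutral_well_mixed", n_taxa = 40,
                                      samples_per_group = 6, depth = 2000,
                                      seed = 5))
  res <- suppressWarnings(group_network(sc$counts, sc$design, "G1",
                                        cutoff = 0.6))
  expect_s3_class(res$roles, "data.frame")
  expect_true(all(res$roles$role %in%
                    c("peripheral", "connector", "module hub", "network hub")))
  expect_equal(res$panel$n_nodes, igraph::vcount(res$network))
})
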