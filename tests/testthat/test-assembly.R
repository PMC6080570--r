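test_that("MNTD matches hand values and picante", {
  tr <- cherry_tree()   # d(X,Y)=2, cross-pairs 4
  m <- count_fixture(rbind(c(9, 1, 0, 0), c(1, 1, 1, 1)),
                     otus = c("X", "Y", "Z", "W"))
  got <- mntd(m, tr)
  expect_equal(unname(got[1]), 2)  # two taxa at distance 2, any weights
  # star tree: all pairwise distances equal, weighting irrelevant
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ms <- count_fixture(rbind(c(4, 3, 2, 1)), otus = c("A", "B", "C", "D"))
  expect_equal(unname(mntd(ms, star)), 2)
  expect_equal(unname(mntd(ms, star, weighted = FALSE)), 2)
  # single-taxon sample is undefined
  m1 <- count_fixture(rbind(c(5, 0, 0, 0)), otus = c("X", "Y", "Z", "W"))
  expect_warning(v <- mntd(m1, tr), "undefined")
  expect_true(is.na(v))
  if (requireNamespace("picante", quietly = TRUE)) {
    set.seed(21)
    tr2 <- ape::rtree(12)
    m2 <- count_fixture(matrix(rpois(5 * 12, 2), 5, 12),
                        otus = tr2$tip.label)
    m2[rowSums(m2 > 0) < 2, 1:2] <- 1
    D <- ape::cophenetic.phylo(tr2)
    expect_equal(unname(mntd(m2, tr2)),
                 picante::mntd(m2, D, abundance.weighted = TRUE),
                 tolerance = 1e-12)
    expect_equal(unname(mntd(m2, tr2, weighted = FALSE)),
                 picante::mntd(m2, D, abundance.weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("betaMNTD matches the formula, picante, and is symmetric", {
  tr <- cherry_tree()
  m <- count_fixture(rbind(c(5, 0, 0, 0), c(0, 0, 5, 0)),
                     otus = c("X", "Y", "Z", "W"))
  expect_equal(beta_mntd(m, tr)[1, 2], 4)  # collapses to d(X,Z)
  ident <- count_fixture(rbind(c(2, 3, 0, 1), c(2, 3, 0, 1)),
                         otus = c("X", "Y", "Z", "W"))
  expect_equal(beta_mntd(ident, tr)[1, 2], 0)
  set.seed(31)
  tr2 <- ape::rtree(15)
  m2 <- count_fixture(matrix(rpois(6 * 15, 3), 6, 15), otus = tr2$tip.label)
  m2[, 1] <- m2[, 1] + 1
  bm <- beta_mntd(m2, tr2)
  expect_equal(bm, t(bm))
  expect_equal(unname(diag(bm)), rep(0, 6))
  if (requireNamespace("picante", quietly = TRUE)) {
    ref <- as.matrix(picante::comdistnt(m2, ape::cophenetic.phylo(tr2),
                                        abundance.weighted = TRUE))
    expect_equal(bm, ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("NTI detects planted clade structure and is centred under the null", {
  tree <- simulate_tree(64, seed = 13)
  D <- patristic_distances(tree)
  cl <- cutree(hclust(as.dist(D), "average"), k = 4)
  clade <- names(cl)[cl == which.max(tabulate(cl))][1:8]
  m <- matrix(0, 2, 64, dimnames = list(c("clustered", "random"),
                                        tree$tip.label))
  m["clustered", clade] <- 5
  set.seed(3); m["random", sample(tree$tip.label, 8)] <- 5
  res <- nti(m, tree, n_randomizations = 400, seed = 11)
  expect_gt(res$nti[res$sample == "clustered"], 1.5)
  # degenerate null on a star tree is flagged and zeroed
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  ms <- count_fixture(rbind(c(1, 1, 1, 0)), otus = c("A", "B", "C", "D"))
  expect_warning(res2 <- nti(ms, star, n_randomizations = 50, seed = 1),
                 "degenerate")
  expect_equal(res2$nti, 0)
})

test_that("betaNTI separates planted clades and is calibrated for random draws", {
  tree <- simulate_tree(100, seed = 23)
  D <- patristic_distances(tree)
  cl <- cutree(hclust(as.dist(D), "average"), k = 2)
  c1 <- names(cl)[cl == 1]; c2 <- names(cl)[cl == 2]
  skip_if(length(c1) < 8 || length(c2) < 8)
  m <- matrix(0, 2, 100, dimnames = list(c("a", "b"), tree$tip.label))
  set.seed(7)
  m["a", sample(c1, 8)] <- 5
  m["b", sample(c2, 8)] <- 5
  bn <- beta_nti(m, tree, n_randomizations = 300, seed = 5)
  expect_gt(bn$beta_nti[1, 2], 2)   # distant clades: divergence signal
  # random draws from the whole tree: roughly standard-normal z
  set.seed(9)
  mr <- t(vapply(1:10, function(i) {
    x <- numeric(100); x[sample(100, 15)] <- rpois(15, 4) + 1; x
  }, numeric(100)))
  dimnames(mr) <- list(paste0("s", 1:10), tree$tip.label)
  bnr <- beta_nti(mr, tree, n_randomizations = 199, seed = 5)
  ut <- upper.tri(bnr$beta_nti)
  expect_gt(mean(abs(bnr$beta_nti[ut]) <= 2), 0.85)
  expect_equal(bnr$beta_nti, t(bnr$beta_nti))
})

test_that("Raup-Crick is bounded, symmetric, and flags identical pairs", {
  set.seed(41)
  m <- count_fixture(matrix(rpois(6 * 30, 3), 6, 30))
  m[1, ] <- m[2, ]                       # identical pair
  m[, 1] <- m[, 1] + 1
  rc <- raup_crick_bray(m, n_randomizations = 199, seed = 3)
  expect_true(all(rc$rc_bray >= -1 & rc$rc_bray <= 1))
  expect_equal(rc$rc_bray, t(rc$rc_bray))
  expect_lt(rc$rc_bray[1, 2], -0.9)      # obs BC = 0 beats ~every null
  # samples built by the null process itself are centred
  set.seed(55)
  base <- count_fixture(matrix(rpois(8 * 40, 4), 8, 40))
  base[, 1] <- base[, 1] + 1
  occ <- colSums(base > 0); ab <- colSums(base)
  nul <- asmscope:::null_community_table(base, pmax(occ, 1e-9), pmax(ab, 1e-9))
  rc2 <- raup_crick_bray(nul, n_randomizations = 199, seed = 5,
                         metacommunity = base)
  vals <- rc2$rc_bray[upper.tri(rc2$rc_bray)]
  expect_lt(abs(mean(vals)), 0.5)        # centred near 0, not saturated
})

test_that("the five-way classifier applies the quoted thresholds", {
  bnti <- c(2.5, -2.5, 0, 0, 0, 2.0, -2.0, 0, 0)
  rc <- c(0, 0, 0.99, -0.99, 0, 0.99, -0.99, 0.95, -0.95)
  got <- classify_processes(bnti, rc)
  expect_equal(got, c("variable selection", "homogeneous selection",
                      "dispersal limitation", "homogenizing dispersal",
                      "drift",
                      "dispersal limitation",   # bNTI = 2 is not > 2
                      "homogenizing dispersal", # bNTI = -2 is not < -2
                      "drift", "drift"))        # RC = +-0.95 not beyond
  expect_true(is.na(classify_processes(NA_real_, 0.5)))
  expect_error(classify_processes(c(1, 2), 1), "matching shape")
})

test_that("process fractions sum to one with the right pair counts", {
  sc <- make_scenario(scenario_config("neutral_well_mixed", n_taxa = 40,
                                      samples_per_group = 8, depth = 1000,
                                      seed = 3))
  pairs <- pairwise_assembly(sc$counts, sc$tree, n_randomizations = 99,
                             seed = 2)
  expect_equal(nrow(pairs), 24 * 23 / 2)
  fr <- process_fractions(pairs, sc$design)
  for (g in unique(fr$comparison)) {
    sub <- fr[fr$comparison == g, ]
    expect_equal(sum(sub$fraction), 1, tolerance = 1e-12)
    expect_equal(sum(sub$count), 28)   # C(8,2)
  }
  fr_all <- process_fractions(pairs, sc$design, scope = "all_pairs")
  expect_equal(sum(fr_all$count), nrow(pairs))
  # invariant to pair ordering
  fr2 <- process_fractions(pairs[sample(nrow(pairs)), ], sc$design)
  expect_equal(fr[order(fr$comparison, fr$process), ],
               fr2[order(fr2$comparison, fr2$process), ],
               ignore_attr = TRUE)
})

test_that("beta deviation detects forced homogeneity and stays quiet under the null", {
  set.seed(61)
  base <- count_fixture(matrix(rpois(6 * 50, 4), 6, 50),
                        samples = paste0("s", 1:6))
  base[, 1] <- base[, 1] + 1
  des <- data.frame(sample_id = paste0("s", 1:6), group = rep("g", 6))
  # observed communities forced identical: actual centroid 0, strong signal
  ident <- base; for (i in 2:6) ident[i, ] <- ident[1, ]
  rownames(ident) <- paste0("s", 1:6)
  res <- null_beta_deviation(ident, des, "braycurtis",
                             n_randomizations = 99, seed = 4)
  expect_equal(res$actual_centroid, 0)
  expect_gt(res$null_centroid, 0)
  expect_lt(res$p_value, 0.05)
  # data generated by the null engine itself: mostly non-significant
  occ <- pmax(colSums(base > 0), 1e-9); ab <- pmax(colSums(base), 1e-9)
  ps <- vapply(1:10, function(i) {
    set.seed(100 + i)
    obs <- asmscope:::null_community_table(base, occ, ab)
    null_beta_deviation(obs, des, "braycurtis", n_randomizations = 99,
                        seed = i)$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
  # output shape mirrors the per-group, per-metric table
  expect_named(res, c("group", "metric", "actual_centroid", "null_centroid",
                      "F", "p_value"))
})
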