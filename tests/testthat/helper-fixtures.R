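# shared fixtures and independent brute-force oracles

# three-tip worked tree: ((A:1,B:1):1,C:2);
worked_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# two-cherry tree with all unit branches: patristic d(X,Y)=2, cross pairs 4
cherry_tree <- function() ape::read.tree(text = "((X:1,Y:1):1,(Z:1,W:1):1);")

count_fixture <- function(m, samples = NULL, otus = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(m)))
  if (is.null(otus)) otus <- paste0("o", seq_len(ncol(m)))
  dimnames(m) <- list(samples, otus)
  m
}

# a 6-sample, 2-group toy distance matrix with clear group separation
toy_distance_6 <- function() {
  set.seed(421)
  pts <- rbind(matrix(rnorm(6, 0, 0.4), 3, 2),
               matrix(rnorm(6, 3, 0.4), 3, 2))
  rownames(pts) <- paste0("s", 1:6)
  as.matrix(dist(pts))
}

toy_design_6 <- function() {
  data.frame(sample_id = paste0("s", 1:6), group = rep(c("A", "B"), each = 3))
}

# --- independent oracles (straight-line code, no shared helpers) -----------

# PERMANOVA pseudo-F written independently from the implementation
oracle_permanova_f <- function(d, groups) {
  n <- nrow(d)
  levs <- unique(groups)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (lv in levs) {
    idx <- which(groups == lv)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + d[i, j]^2
    ssw <- ssw + acc / length(idx)
  }
  ssb <- sst - ssw
  if (ssw < 1e-14) return(Inf)
  (ssb / (length(levs) - 1)) / (ssw / (n - length(levs)))
}

# exhaustive PERMANOVA p over all distinct assignments of a 3+3 labeling
oracle_permanova_p_33 <- function(d, groups) {
  f_obs <- oracle_permanova_f(d, groups)
  combos <- combn(6, 3)
  hits <- 0
  for (k in seq_len(ncol(combos))) {
    g <- rep("B", 6); g[combos[, k]] <- "A"
    if (oracle_permanova_f(d, g) >= f_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combos)
}

# ANOSIM R and exhaustive p, independent rank computation
oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  vals <- c(); within <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    vals <- c(vals, d[i, j]); within <- c(within, groups[i] == groups[j])
  }
  rk <- rank(vals)
  (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
}

oracle_anosim_p_33 <- function(d, groups) {
  r_obs <- oracle_anosim_r(d, groups)
  combos <- combn(6, 3)
  hits <- 0
  for (k in seq_len(ncol(combos))) {
    g <- rep("B", 6); g[combos[, k]] <- "A"
    if (oracle_anosim_r(d, g) >= r_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combos)
}

# max-over-groups IndVal of one taxon, written independently
oracle_indval_stat <- function(x, groups) {
  levs <- unique(groups)
  means <- sapply(levs, function(lv) mean(x[groups == lv]))
  if (sum(means) == 0) return(0)
  a <- means / sum(means)
  b <- sapply(levs, function(lv) mean(x[groups == lv] > 0))
  max(a * b)
}

# exhaustive IndVal p over all 70 assignments of a 4+4 labeling
oracle_indval_p_44 <- function(x, groups) {
  obs <- oracle_indval_stat(x, groups)
  combos <- combn(8, 4)
  hits <- 0
  for (k in seq_len(ncol(combos))) {
    g <- rep("B", 8); g[combos[, k]] <- "A"
    if (oracle_indval_stat(x, g) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(combos)
}
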