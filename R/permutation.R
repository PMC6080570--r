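## ---- permutation machinery -------------------------------------------------

# multinomial coefficient: number of distinct label assignments of a factor
n_distinct_assignments <- function(g) {
  n <- length(g)
  exp(lgamma(n + 1) - sum(lgamma(table(g) + 1)))
}

#' Enumerate all distinct assignments of a label multiset
#'
#' Returns every distinct way of assigning the observed multiset of group
#' labels to the samples; used for exact permutation p-values on small
#' designs.
#'
#' @param g factor of group labels.
#' @param max_n refuse to enumerate beyond this many assignments.
#' @return integer matrix, one assignment per row, entries are level indices
#'   of `g`.
#' @export
enumerate_assignments <- function(g, max_n = 1e5) {
  g <- as.factor(g)
  total <- n_distinct_assignments(g)
  if (total > max_n)
    stop("too many distinct assignments (", format(total), ") to enumerate")
  sizes <- table(g)
  k <- length(sizes)
  recurse <- function(free, lev) {
    if (lev == k) {
      m <- matrix(0L, 1, length(g))
      m[1, free] <- k
      return(m)
    }
    picks <- combn(free, sizes[lev])
    out <- vector("list", ncol(picks))
    for (j in seq_len(ncol(picks))) {
      sub <- recurse(setdiff(free, picks[, j]), lev + 1L)
      sub[, picks[, j]] <- lev
      out[[j]] <- sub
    }
    do.call(rbind, out)
  }
  recurse(seq_along(g), 1L)
}

# shared driver: observed statistic vs statistics over permuted labelings.
# stat_fun takes an integer vector of level indices. Exact enumeration is
# substituted automatically when the number of distinct assignments is small.
permutation_p <- function(g, stat_fun, n_permutations, seed,
                          exhaustive_limit = 10000) {
  obs <- stat_fun(as.integer(g))
  total <- n_distinct_assignments(g)
  if (total <= exhaustive_limit) {
    assign <- enumerate_assignments(g)
    perm_stats <- apply(assign, 1, stat_fun)
    p <- mean(perm_stats >= obs - 1e-12)
    list(statistic = obs, p_value = p, n_permutations = nrow(assign),
         exact = TRUE, perm_stats = perm_stats)
  } else {
    set.seed(seed)
    perm_stats <- vapply(seq_len(n_permutations), function(i)
      stat_fun(as.integer(g)[sample.int(length(g))]), numeric(1))
    p <- (sum(perm_stats >= obs - 1e-12) + 1) / (n_permutations + 1)
    list(statistic = obs, p_value = p, n_permutations = n_permutations,
         exact = FALSE, perm_stats = perm_stats)
  }
}

## ---- PERMANOVA -------------------------------------------------------------

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the squared-distance sums of squares between and within groups:
#' SS_total = (1/N) sum_{i<j} d_ij^2, SS_within = sum_g (1/n_g)
#' sum_{i<j in g} d_ij^2, pseudo-F = (SS_between/(a-1)) / (SS_within/(N-a)),
#' R^2 = SS_between/SS_total. The p-value comes from permuting group labels;
#' on small designs every distinct assignment is enumerated and the p-value
#' is exact, otherwise the Monte Carlo (b+1)/(m+1) estimator is used so p is
#' never zero.
#'
#' @param d distance matrix over samples.
#' @param design grouping (see [group_factor()]); every group needs >= 2
#'   samples.
#' @param n_permutations Monte Carlo permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list with `statistic` (pseudo-F), `r_squared`, `p_value`,
#'   `n_permutations`, `exact`, `seed`.
#' @export
permanova <- function(d, design, n_permutations = 999, seed = 1L) {
  d <- validate_distance_matrix(d)
  g <- group_factor(design, rownames(d), min_size = 2L)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  d2 <- d^2
  n <- nrow(d)
  a <- nlevels(g)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(gl) {
    ss_within <- 0
    for (lv in seq_len(a)) {
      idx <- which(gl == lv)
      ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss_between <- ss_total - ss_within
    if (ss_within <= 1e-14) return(Inf)
    (ss_between / (a - 1)) / (ss_within / (n - a))
  }
  res <- permutation_p(g, f_stat, n_permutations, seed)
  r2 <- if (is.infinite(res$statistic)) 1 else
    (res$statistic * (a - 1)) / (res$statistic * (a - 1) + (n - a))
  list(statistic = res$statistic, r_squared = r2,
       p_value = res$p_value, n_permutations = res$n_permutations,
       exact = res$exact, seed = seed)
}

## ---- ANOSIM ----------------------------------------------------------------

#' Analysis of similarity
#'
#' Ranks all N(N-1)/2 pairwise distances (mid-ranks for ties) and contrasts
#' mean between-group vs mean within-group ranks:
#' R = (rank_between - rank_within) / (N(N-1)/4). R is 1 when every
#' between-group distance exceeds every within-group distance and is near 0
#' under exchangeability. p-value by label permutation as in [permanova()].
#'
#' @inheritParams permanova
#' @return list with `statistic` (R), `p_value`, `n_permutations`, `exact`,
#'   `seed`.
#' @export
anosim <- function(d, design, n_permutations = 999, seed = 1L) {
  d <- validate_distance_matrix(d)
  g <- group_factor(design, rownames(d), min_size = 2L)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  n <- nrow(d)
  ut <- upper.tri(d)
  rk <- rank(d[ut])                # mid-ranks for ties
  pair_idx <- which(ut, arr.ind = TRUE)
  denom <- n * (n - 1) / 4
  r_stat <- function(gl) {
    within <- gl[pair_idx[, 1]] == gl[pair_idx[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  res <- permutation_p(g, r_stat, n_permutations, seed)
  list(statistic = res$statistic, p_value = res$p_value,
       n_permutations = res$n_permutations, exact = res$exact, seed = seed)
}

## ---- PERMDISP dispersion distances ----------------------------------------

#' Distance of each sample to its group centroid (PERMDISP dispersions)
#'
#' Centroid distances are computed directly from the distance matrix via the
#' Gower identity d^2(x, c_g) = (1/n_g) sum_{i in g} d^2(x, i) -
#' (1/n_g^2) sum_{i<j in g} d^2(i, j), avoiding an explicit ordination
#' embedding. For non-Euclidean dissimilarities the identity can produce
#' small negative squared distances; these are truncated to 0 and counted in
#' a warning.
#'
#' @param d distance matrix.
#' @param design grouping; every group needs >= 2 samples.
#' @return named numeric vector: each sample's distance to its own group
#'   centroid.
#' @export
permdisp_distances <- function(d, design) {
  d <- validate_distance_matrix(d)
  g <- group_factor(design, rownames(d), min_size = 2L)
  d2 <- d^2
  out <- numeric(nrow(d))
  truncated <- 0L
  for (lv in levels(g)) {
    idx <- which(g == lv)
    ng <- length(idx)
    within <- sum(d2[idx, idx]) / 2
    centroid_term <- within / ng^2
    sq <- rowSums(d2[idx, idx, drop = FALSE]) / ng - centroid_term
    neg <- sq < 0
    truncated <- truncated + sum(neg & sq < -1e-12)
    sq[neg] <- 0
    out[idx] <- sqrt(sq)
  }
  if (truncated > 0)
    warning(truncated, " negative squared centroid distance(s) truncated to 0 ",
            "(non-Euclidean dissimilarity)")
  stats::setNames(out, rownames(d))
}
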