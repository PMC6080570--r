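## ---- indicator species analysis (IndVal) -----------------------------------

# indicator analysis accepts counts or relative abundances: named matrix,
# finite, non-negative (integrality not required)
check_abundance_matrix <- function(x) {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance matrix must have sample row names and taxon column names")
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundance matrix must be finite and non-negative")
  x
}

# core statistic on a level-index labeling; returns groups x taxa IndVal
indval_components <- function(x, gl, k) {
  means <- rowsum(x, gl) / as.vector(table(factor(gl, levels = seq_len(k))))
  tot <- colSums(means)
  A <- sweep(means, 2, tot, "/")
  A[, tot == 0] <- 0
  B <- rowsum((x > 0) * 1, gl) / as.vector(table(factor(gl, levels = seq_len(k))))
  list(A = A, B = B, iv = A * B)
}

#' Dufrene-Legendre indicator values
#'
#' For taxon j and group g, specificity A_gj is the group's mean abundance of
#' j divided by the sum of group means, fidelity B_gj is the fraction of
#' group-g samples where j is present (abundance > 0), and
#' IndVal_j = max_g A_gj * B_gj. A is scale-free, so counts and relative
#' abundances give identical results; relative abundances are the intended
#' input.
#'
#' @param x samples x taxa count or relative-abundance matrix.
#' @param design grouping (see [group_factor()]); >= 2 groups.
#' @return list with matrices `A`, `B` (groups x taxa), numeric `indval` per
#'   taxon, character `best_group` (group achieving the max), logical
#'   `absent` flagging taxa absent everywhere (IndVal 0), and
#'   `mean_abundance` (overall mean relative abundance per taxon).
#' @export
indval <- function(x, design) {
  x <- check_abundance_matrix(x)
  g <- group_factor(design, rownames(x))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  cmp <- indval_components(x, as.integer(g), nlevels(g))
  dimnames(cmp$A) <- dimnames(cmp$B) <- list(levels(g), colnames(x))
  iv <- apply(cmp$iv, 2, max)
  best <- levels(g)[apply(cmp$iv, 2, which.max)]
  absent <- colSums(x) == 0
  best[absent] <- NA_character_
  rel <- x / pmax(rowSums(x), .Machine$double.eps)
  list(A = cmp$A, B = cmp$B,
       indval = stats::setNames(iv, colnames(x)),
       best_group = stats::setNames(best, colnames(x)),
       absent = stats::setNames(absent, colnames(x)),
       mean_abundance = colMeans(rel))
}

#' Permutation significance of indicator values
#'
#' For each taxon the test statistic is its max-over-groups IndVal; group
#' labels are permuted over samples and p = (count of permuted statistics >=
#' observed + 1)/(n_permutations + 1). When the number of distinct label
#' assignments is at most `exhaustive_limit`, all assignments are enumerated
#' and p is exact (count/total, the identity assignment included).
#'
#' @inheritParams indval
#' @param n_permutations Monte Carlo permutations (default 999).
#' @param seed RNG seed.
#' @param exhaustive_limit switch to full enumeration when the number of
#'   distinct assignments is at most this (default 10000).
#' @return list with `indval` (observed), `p_value` per taxon, `exact`,
#'   `n_permutations`.
#' @export
indval_test <- function(x, design, n_permutations = 999, seed = 1L,
                        exhaustive_limit = 10000) {
  x <- check_abundance_matrix(x)
  g <- group_factor(design, rownames(x))
  if (nlevels(g) < 2) stop("need >= 2 groups")
  k <- nlevels(g)
  obs <- apply(indval_components(x, as.integer(g), k)$iv, 2, max)
  total <- n_distinct_assignments(g)
  if (total <= exhaustive_limit) {
    assign <- enumerate_assignments(g)
    hits <- numeric(ncol(x))
    for (r in seq_len(nrow(assign))) {
      iv <- apply(indval_components(x, assign[r, ], k)$iv, 2, max)
      hits <- hits + (iv >= obs - 1e-12)
    }
    p <- hits / nrow(assign)
    exact <- TRUE
    m <- nrow(assign)
  } else {
    set.seed(seed)
    hits <- numeric(ncol(x))
    gl <- as.integer(g)
    for (r in seq_len(n_permutations)) {
      iv <- apply(indval_components(x, gl[sample.int(length(gl))], k)$iv, 2, max)
      hits <- hits + (iv >= obs - 1e-12)
    }
    p <- (hits + 1) / (n_permutations + 1)
    exact <- FALSE
    m <- n_permutations
  }
  list(indval = stats::setNames(obs, colnames(x)),
       p_value = stats::setNames(p, colnames(x)),
       exact = exact, n_permutations = m, seed = seed)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a
#' named step so the screening pipeline is explicit about its multiplicity
#' correction.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Screen indicator taxa
#'
#' Keeps taxa passing all three gates: overall mean relative abundance
#' strictly above `min_mean_abundance`, IndVal strictly above `min_indval`,
#' and FDR q strictly below `max_q`. Defaults reproduce the common screening
#' rule (abundance > 0.1%, IndVal > 0.4, q < 0.05).
#'
#' @param x samples x taxa abundance matrix.
#' @param design grouping.
#' @param n_permutations,seed passed to [indval_test()].
#' @param min_mean_abundance,min_indval,max_q the three gates.
#' @return data.frame (one row per retained taxon): taxon, group, A, B,
#'   indval, mean_abundance, p_value, q_value; sorted by decreasing IndVal.
#'   The full unfiltered table is attached as attribute `"full"`.
#' @export
screen_indicators <- function(x, design, n_permutations = 999, seed = 1L,
                              min_mean_abundance = 0.001, min_indval = 0.4,
                              max_q = 0.05) {
  iv <- indval(x, design)
  tst <- indval_test(x, design, n_permutations = n_permutations, seed = seed)
  q <- bh_fdr(tst$p_value)
  g <- iv$best_group
  A <- ifelse(is.na(g), NA_real_, iv$A[cbind(g, names(iv$indval))])
  B <- ifelse(is.na(g), NA_real_, iv$B[cbind(g, names(iv$indval))])
  full <- data.frame(taxon = names(iv$indval), group = g, A = A, B = B,
                     indval = iv$indval, mean_abundance = iv$mean_abundance,
                     p_value = tst$p_value, q_value = q,
                     row.names = NULL, stringsAsFactors = FALSE)
  keep <- full$mean_abundance > min_mean_abundance &
    full$indval > min_indval & full$q_value < max_q
  keep[is.na(keep)] <- FALSE
  out <- full[keep, , drop = FALSE]
  out <- out[order(-out$indval), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}
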