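## ---- community assembly null models ----------------------------------------

#' Patristic distance matrix aligned to a count table
#'
#' Dense tip-to-tip path-length distances, computed once per tree and
#' reordered to the table's OTU columns so downstream queries are O(1).
#'
#' @param tree rooted `phylo`.
#' @param otu_ids OTU identifiers to align to (default: all tips).
#' @return symmetric matrix of patristic distances.
#' @export
patristic_distances <- function(tree, otu_ids = tree$tip.label) {
  tree <- validate_tree(tree)
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing) > 0)
    stop(length(missing), " OTU(s) are not tips of the tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
  D <- ape::cophenetic.phylo(tree)
  D[otu_ids, otu_ids, drop = FALSE]
}

# shared input preparation for the phylogenetic statistics
phylo_inputs <- function(counts, tree, weighted, prune = FALSE) {
  counts <- validate_count_table(counts)
  counts <- match_tree_table(counts, tree, prune = prune)
  D <- patristic_distances(tree, colnames(counts))
  W <- if (weighted) relative_abundance(counts) else (counts > 0) * 1
  list(counts = counts, D = D, W = W)
}

#' Mean nearest taxon distance (MNTD) per sample
#'
#' For each present taxon, the patristic distance to its nearest other
#' present taxon; averaged with relative-abundance weights (`weighted =
#' TRUE`, the default) or equally (unweighted). Samples with fewer than two
#' present taxa return NA with a warning.
#'
#' @param counts samples x OTUs count matrix.
#' @param tree rooted `phylo` whose tips cover the table's OTUs.
#' @param weighted abundance-weight the average (default TRUE).
#' @return named numeric vector of per-sample MNTD.
#' @export
mntd <- function(counts, tree, weighted = TRUE) {
  inp <- phylo_inputs(counts, tree, weighted)
  out <- cpp_mntd(inp$D, inp$W, seq_len(ncol(inp$D)) - 1L)
  if (anyNA(out)) warning(sum(is.na(out)), " sample(s) with < 2 taxa; MNTD undefined")
  stats::setNames(out, rownames(inp$counts))
}

#' Nearest taxon index (NTI) per sample
#'
#' NTI = -(MNTD_obs - mean MNTD_null) / sd(MNTD_null), the negated
#' standardized effect size of MNTD against a taxa-labels null that shuffles
#' tip identities across the whole tree. Positive NTI indicates phylogenetic
#' clustering (terminal taxa closer than expected), negative NTI
#' overdispersion.
#'
#' @inheritParams mntd
#' @param n_randomizations tip shuffles (default 1000).
#' @param seed RNG seed.
#' @return data.frame: sample, mntd_obs, null_mean, null_sd, nti. Samples
#'   with a degenerate null (sd = 0, e.g. a star tree) get NTI 0 with a
#'   warning.
#' @export
nti <- function(counts, tree, n_randomizations = 1000, seed = 1L,
                weighted = TRUE) {
  inp <- phylo_inputs(counts, tree, weighted)
  t <- ncol(inp$D)
  obs <- cpp_mntd(inp$D, inp$W, seq_len(t) - 1L)
  set.seed(seed)
  nulls <- matrix(NA_real_, n_randomizations, nrow(inp$counts))
  for (r in seq_len(n_randomizations))
    nulls[r, ] <- cpp_mntd(inp$D, inp$W, sample.int(t) - 1L)
  mu <- colMeans(nulls)
  sdev <- apply(nulls, 2, stats::sd)
  nti_v <- -(obs - mu) / sdev
  degenerate <- is.finite(obs) & (is.na(sdev) | sdev < 1e-12)
  if (any(degenerate)) {
    warning(sum(degenerate), " sample(s) with degenerate null (sd = 0); NTI set to 0")
    nti_v[degenerate] <- 0
  }
  data.frame(sample = rownames(inp$counts), mntd_obs = obs, null_mean = mu,
             null_sd = sdev, nti = nti_v, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pairwise beta mean nearest taxon distance (betaMNTD)
#'
#' betaMNTD(A, B) = 0.5 * \[sum over taxa i in A of f_iA * min_{j in B}
#' d(i, j) + the symmetric term\], with f the within-sample relative
#' abundances (weighted) or 1/richness (unweighted). Zero when the samples
#' share identical supports-with-zero-distance, symmetric by construction.
#'
#' @inheritParams mntd
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
beta_mntd <- function(counts, tree, weighted = TRUE) {
  inp <- phylo_inputs(counts, tree, weighted)
  out <- cpp_beta_mntd(inp$D, inp$W, seq_len(ncol(inp$D)) - 1L)
  dimnames(out) <- list(rownames(inp$counts), rownames(inp$counts))
  out
}

#' Pairwise beta nearest taxon index (betaNTI)
#'
#' z-score of the observed betaMNTD of each sample pair against tip-label
#' shuffle nulls. One shared set of shuffles per randomization index is
#' reused across all pairs, so the whole matrix costs one betaMNTD
#' evaluation per shuffle. |betaNTI| > 2 flags pairs whose phylogenetic
#' turnover departs from the null (selection).
#'
#' @inheritParams mntd
#' @param n_randomizations tip shuffles (default 999).
#' @param seed RNG seed.
#' @return list with matrices `beta_mntd` (observed), `beta_nti`,
#'   `null_mean`, `null_sd`. Pairs with a degenerate null get betaNTI 0.
#' @export
beta_nti <- function(counts, tree, n_randomizations = 999, seed = 1L,
                     weighted = TRUE) {
  inp <- phylo_inputs(counts, tree, weighted)
  t <- ncol(inp$D)
  n <- nrow(inp$counts)
  obs <- cpp_beta_mntd(inp$D, inp$W, seq_len(t) - 1L)
  set.seed(seed)
  acc <- matrix(0, n, n); acc2 <- matrix(0, n, n)
  for (r in seq_len(n_randomizations)) {
    nul <- cpp_beta_mntd(inp$D, inp$W, sample.int(t) - 1L)
    acc <- acc + nul
    acc2 <- acc2 + nul^2
  }
  mu <- acc / n_randomizations
  sdev <- sqrt(pmax(acc2 / n_randomizations - mu^2, 0) *
                 n_randomizations / (n_randomizations - 1))
  z <- (obs - mu) / sdev
  degen <- sdev < 1e-12
  z[degen] <- 0
  diag(z) <- 0
  nm <- rownames(inp$counts)
  dimnames(obs) <- dimnames(z) <- dimnames(mu) <- dimnames(sdev) <- list(nm, nm)
  if (any(degen[upper.tri(degen)]))
    warning(sum(degen[upper.tri(degen)]), " pair(s) with degenerate null; betaNTI set to 0")
  list(beta_mntd = obs, beta_nti = z, null_mean = mu, null_sd = sdev,
       n_randomizations = n_randomizations, seed = seed)
}

## ---- Raup-Crick on Bray-Curtis ---------------------------------------------

# one null realisation of every sample: keep each sample's observed richness
# and total reads; draw which taxa occur with probability proportional to
# occupancy frequency across the metacommunity, then allocate the reads among
# the drawn taxa with probability proportional to metacommunity relative
# abundance.
null_community_table <- function(counts, occ_freq, abund_freq) {
  n <- nrow(counts); t <- ncol(counts)
  rich <- rowSums(counts > 0)
  totals <- rowSums(counts)
  out <- matrix(0, n, t, dimnames = dimnames(counts))
  for (s in seq_len(n)) {
    chosen <- sample.int(t, rich[s], prob = occ_freq)
    out[s, chosen] <- rmultinom(1, totals[s], prob = abund_freq[chosen])
  }
  out
}

#' Bray-Curtis-based Raup-Crick (RCbray)
#'
#' For every sample pair, compares the observed Bray-Curtis dissimilarity
#' with dissimilarities between null communities that preserve each sample's
#' richness and read total while drawing taxon identities by occupancy
#' frequency and read allocations by metacommunity relative abundance. One
#' null realisation of every sample is generated per randomization and all
#' pairs are compared against it.
#' RC = 2 * \[(number of null BC below observed) + 0.5 * ties\] /
#' n_randomizations - 1, in \[-1, 1\]; RC near +1 means communities are more
#' dissimilar than the null expects (e.g. dispersal limitation), near -1
#' more similar (homogenizing dispersal).
#'
#' @param counts samples x OTUs count matrix (rarefied input recommended).
#' @param n_randomizations null realisations (default 999).
#' @param seed RNG seed.
#' @param metacommunity optional larger count table supplying occupancy and
#'   abundance frequencies (default: `counts` itself).
#' @return list with matrices `rc_bray` and `bray_obs`.
#' @export
raup_crick_bray <- function(counts, n_randomizations = 999, seed = 1L,
                            metacommunity = NULL) {
  counts <- validate_count_table(counts)
  meta <- if (is.null(metacommunity)) counts else validate_count_table(metacommunity)
  if (!identical(colnames(meta), colnames(counts)))
    stop("metacommunity must share the table's OTU columns")
  occ_freq <- colSums(meta > 0)
  abund_freq <- colSums(meta)
  if (all(occ_freq == 0)) stop("empty metacommunity")
  # guard: a taxon present in `counts` must be drawable
  occ_freq <- pmax(occ_freq, ifelse(colSums(counts > 0) > 0, 1e-9, 0))
  abund_freq <- pmax(abund_freq, ifelse(colSums(counts) > 0, 1e-9, 0))
  obs <- bray_curtis_matrix(counts)
  n <- nrow(counts)
  less <- matrix(0, n, n); ties <- matrix(0, n, n)
  set.seed(seed)
  for (r in seq_len(n_randomizations)) {
    nul <- null_community_table(counts, occ_freq, abund_freq)
    num <- as.matrix(stats::dist(nul, method = "manhattan"))
    den <- outer(rowSums(nul), rowSums(nul), "+")
    bc <- num / den
    less <- less + (bc < obs - 1e-12)
    ties <- ties + (abs(bc - obs) <= 1e-12)
  }
  rc <- 2 * (less + 0.5 * ties) / n_randomizations - 1
  diag(rc) <- 0
  dimnames(rc) <- dimnames(obs)
  list(rc_bray = rc, bray_obs = obs, n_randomizations = n_randomizations,
       seed = seed)
}

## ---- process classification ------------------------------------------------

#' Five-way assembly process classification from (betaNTI, RCbray)
#'
#' betaNTI > 2: variable selection. betaNTI < -2: homogeneous selection.
#' |betaNTI| <= 2 with RCbray > 0.95: dispersal limitation; RCbray < -0.95:
#' homogenizing dispersal; otherwise drift (undominated). Thresholds are
#' strict, so boundary-equal values fall to the less extreme category.
#' Missing values in either input give NA.
#'
#' @param beta_nti numeric vector or matrix of betaNTI values.
#' @param rc_bray matching RCbray values.
#' @return character labels with the same shape as the inputs.
#' @export
classify_processes <- function(beta_nti, rc_bray) {
  if (!identical(dim(beta_nti), dim(rc_bray)) ||
      length(beta_nti) != length(rc_bray))
    stop("beta_nti and rc_bray must have matching shape")
  lab <- ifelse(beta_nti > 2, "variable selection",
         ifelse(beta_nti < -2, "homogeneous selection",
         ifelse(rc_bray > 0.95, "dispersal limitation",
         ifelse(rc_bray < -0.95, "homogenizing dispersal", "drift"))))
  lab[is.na(beta_nti) | is.na(rc_bray)] <- NA_character_
  if (is.matrix(beta_nti)) dimnames(lab) <- dimnames(beta_nti)
  lab
}

#' Assembly process labels for every sample pair
#'
#' Runs [beta_nti()] and [raup_crick_bray()] and tabulates one row per
#' unordered sample pair with the observed statistics and the process label.
#'
#' @inheritParams mntd
#' @param n_randomizations null randomizations for both engines (default
#'   999).
#' @param seed RNG seed (the two engines use `seed` and `seed + 1`).
#' @param metacommunity optional table for the RC null frequencies.
#' @return data.frame: sample_a, sample_b, beta_mntd, beta_nti, bray_curtis,
#'   rc_bray, process.
#' @export
pairwise_assembly <- function(counts, tree, n_randomizations = 999, seed = 1L,
                              weighted = TRUE, metacommunity = NULL) {
  bn <- beta_nti(counts, tree, n_randomizations = n_randomizations,
                 seed = seed, weighted = weighted)
  rc <- raup_crick_bray(counts, n_randomizations = n_randomizations,
                        seed = seed + 1L, metacommunity = metacommunity)
  idx <- which(upper.tri(bn$beta_nti), arr.ind = TRUE)
  lab <- classify_processes(bn$beta_nti, rc$rc_bray)
  data.frame(sample_a = rownames(bn$beta_nti)[idx[, 1]],
             sample_b = rownames(bn$beta_nti)[idx[, 2]],
             beta_mntd = bn$beta_mntd[idx],
             beta_nti = bn$beta_nti[idx],
             bray_curtis = rc$bray_obs[idx],
             rc_bray = rc$rc_bray[idx],
             process = lab[idx],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-group fractions of assembly processes
#'
#' @param pairs data.frame from [pairwise_assembly()].
#' @param design grouping.
#' @param scope `"within_group"` (default: per group, over that group's
#'   pairs) or `"all_pairs"` (one row per group pair, including
#'   between-group comparisons labelled `"A-B"`).
#' @return data.frame: comparison, process, count, fraction; fractions sum
#'   to 1 within each comparison. Pairs with missing labels are excluded
#'   with a warning.
#' @export
process_fractions <- function(pairs, design,
                              scope = c("within_group", "all_pairs")) {
  scope <- match.arg(scope)
  samples <- unique(c(pairs$sample_a, pairs$sample_b))
  g <- group_factor(design, samples)
  ga <- as.character(g[pairs$sample_a]); gb <- as.character(g[pairs$sample_b])
  if (anyNA(pairs$process)) {
    warning(sum(is.na(pairs$process)), " pair(s) without a process label excluded")
    keep <- !is.na(pairs$process)
    pairs <- pairs[keep, ]; ga <- ga[keep]; gb <- gb[keep]
  }
  comparison <- ifelse(ga == gb, ga,
                       paste(pmin(ga, gb), pmax(ga, gb), sep = "-"))
  if (scope == "within_group") {
    keep <- ga == gb
    small <- setdiff(levels(g), comparison[keep])
    if (length(small) > 0)
      stop("group(s) without within-group pairs: ", paste(small, collapse = ", "))
    pairs <- pairs[keep, ]; comparison <- comparison[keep]
  }
  processes <- c("variable selection", "homogeneous selection",
                 "dispersal limitation", "homogenizing dispersal", "drift")
  out <- do.call(rbind, lapply(split(pairs$process, comparison), function(p) {
    cnt <- table(factor(p, levels = processes))
    data.frame(process = processes, count = as.integer(cnt),
               fraction = as.numeric(cnt) / length(p))
  }))
  out <- data.frame(comparison = rep(names(split(pairs$process, comparison)),
                                     each = length(processes)),
                    out, row.names = NULL, stringsAsFactors = FALSE)
  out
}

## ---- null-model beta deviation (dispersion test) ---------------------------

# one-way ANOVA F between the "obs" dispersion values (given by index set
# idx1) and the rest; specialised to two groups so the permutation loop is
# O(n1) per permutation
dispersion_f2 <- function(x, sst, n, idx1) {
  n1 <- length(idx1); n2 <- n - n1
  s1 <- sum(x[idx1]); s <- sum(x)
  grand <- s / n
  ssb <- n1 * (s1 / n1 - grand)^2 + n2 * ((s - s1) / n2 - grand)^2
  ssw <- sst - ssb
  if (ssw <= 1e-300) return(Inf)
  ssb / (ssw / (n - 2))
}

#' Null-model deviation of beta diversity (per-group dispersion test)
#'
#' Tests, per group, whether the observed beta diversity differs from a
#' stochastic null expectation. The group's observed distance-to-centroid
#' dispersions (via [permdisp_distances()]) are compared with dispersions of
#' null communities generated by the same richness/occupancy/abundance
#' engine as [raup_crick_bray()], using the group's samples as the
#' metacommunity; one null realisation of every sample per randomization,
#' with centroid distances computed within each realisation. F is the
#' one-way ANOVA F between the observed dispersion values and the pooled
#' null dispersion values. The p-value permutes the observed/null labels at
#' the realisation level (each randomization's dispersion values stay
#' together, since values within one realisation are correlated): F is
#' recomputed with each null realisation playing the "observed" role, and p
#' is the +1-corrected rank of the observed F among them. A significant
#' result means the observed dispersion departs from the stochastic null
#' (deterministic assembly); a non-significant one is consistent with
#' stochasticity.
#'
#' @param counts samples x OTUs count matrix.
#' @param design grouping; each group needs >= 3 samples.
#' @param metric `"braycurtis"` or `"jaccard"`.
#' @param n_randomizations null realisations per group (default 999); also
#'   the number of block permutations behind the p-value.
#' @param seed RNG seed.
#' @return data.frame, one row per group: group, metric, actual_centroid,
#'   null_centroid, F, p_value.
#' @export
null_beta_deviation <- function(counts, design,
                                metric = c("braycurtis", "jaccard"),
                                n_randomizations = 999, seed = 1L) {
  metric <- match.arg(metric)
  counts <- validate_count_table(counts)
  g <- group_factor(design, rownames(counts), min_size = 3L)
  dist_fun <- if (metric == "braycurtis") bray_curtis_matrix else jaccard_matrix
  rows <- lapply(levels(g), function(lv) {
    sub <- counts[g == lv, , drop = FALSE]
    one <- rep(lv, nrow(sub)); names(one) <- rownames(sub)
    obs_disp <- permdisp_distances(dist_fun(sub), one)
    occ_freq <- pmax(colSums(sub > 0), ifelse(colSums(sub > 0) > 0, 1e-9, 0))
    abund_freq <- pmax(colSums(sub), ifelse(colSums(sub) > 0, 1e-9, 0))
    set.seed(seed)
    null_disp <- vector("list", n_randomizations)
    for (r in seq_len(n_randomizations)) {
      nul <- null_community_table(sub, occ_freq, abund_freq)
      null_disp[[r]] <- permdisp_distances(dist_fun(nul), one)
    }
    null_all <- unlist(null_disp)
    x <- c(obs_disp, null_all)
    if (stats::var(x) < 1e-300) {
      warning("group ", lv, ": degenerate dispersions; F undefined")
      return(data.frame(group = lv, metric = metric,
                        actual_centroid = mean(obs_disp),
                        null_centroid = mean(null_all),
                        F = NA_real_, p_value = NA_real_))
    }
    N <- length(x); n1 <- length(obs_disp)
    sst <- sum(x^2) - N * mean(x)^2
    f_obs <- dispersion_f2(x, sst, N, seq_len(n1))
    # block permutation: each null realisation takes a turn as "observed"
    hits <- 0L
    for (r in seq_len(n_randomizations)) {
      idx <- n1 + (r - 1L) * n1 + seq_len(n1)
      if (dispersion_f2(x, sst, N, idx) >= f_obs - 1e-12) hits <- hits + 1L
    }
    data.frame(group = lv, metric = metric,
               actual_centroid = mean(obs_disp),
               null_centroid = mean(null_all),
               F = f_obs, p_value = (hits + 1) / (n_randomizations + 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
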