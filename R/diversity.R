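## ---- alpha diversity -------------------------------------------------------

#' Observed OTU richness per sample
#'
#' @param counts samples x OTUs count matrix (rarefied input recommended; a
#'   warning is issued when row sums are unequal).
#' @return named integer vector of per-sample richness.
#' @export
observed_otus <- function(counts) {
  counts <- validate_count_table(counts)
  if (length(unique(rowSums(counts))) > 1)
    warning("row sums are unequal; richness is depth-dependent, consider rarefying")
  rowSums(counts > 0)
}

#' Faith's phylogenetic diversity per sample
#'
#' PD of a sample is the sum of branch lengths of the minimal subtree
#' connecting the sample's OTUs to the root (root-inclusive convention: the
#' stem from the root to a single-tip sample counts).
#'
#' @param counts samples x OTUs count matrix.
#' @param tree rooted `phylo` with branch lengths; all present OTUs must be
#'   tips unless `prune = TRUE`.
#' @param prune drop (with a warning) OTU columns absent from the tree rather
#'   than erroring.
#' @return named numeric vector of per-sample PD.
#' @export
faith_pd <- function(counts, tree, prune = FALSE) {
  counts <- validate_count_table(counts)
  tree <- validate_tree(tree)
  counts <- match_tree_table(counts, tree, prune = prune)
  ntip <- length(tree$tip.label)
  # edge x tip incidence: which tips descend from each edge
  desc <- edge_descendant_tips(tree)
  pres <- t(counts > 0)[tree$tip.label, , drop = FALSE]  # tips x samples
  hits <- desc %*% pres                                   # edges x samples
  pd <- as.numeric(crossprod(hits > 0, tree$edge.length))
  stats::setNames(pd, rownames(counts))
}

# logical edge x tip matrix marking the tips below each edge (postorder pass)
edge_descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- matrix(FALSE, nnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  out <- below[tree$edge[, 2], , drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

# drop or reject table OTUs that are not tree tips
match_tree_table <- function(counts, tree, prune = FALSE) {
  extra <- setdiff(colnames(counts), tree$tip.label)
  if (length(extra) > 0) {
    if (!prune)
      stop(length(extra), " OTU(s) absent from the tree (set prune = TRUE to drop): ",
           paste(utils::head(extra, 5), collapse = ", "))
    warning("pruning ", length(extra), " OTU(s) absent from the tree")
    counts <- counts[, setdiff(colnames(counts), extra), drop = FALSE]
  }
  counts
}

## ---- distance matrices -----------------------------------------------------

#' Validate a sample-by-sample distance matrix
#'
#' Checks symmetry (within 1e-12), an exactly zero diagonal, non-negativity,
#' and matching row/column names.
#'
#' @param d square numeric matrix with sample names.
#' @param range optional length-2 numeric bounds the values must fall in.
#' @return the validated matrix.
#' @export
validate_distance_matrix <- function(d, range = NULL) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must have matching row and column sample names")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be exactly zero")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (!is.null(range) && (min(d) < range[1] - 1e-12 || max(d) > range[2] + 1e-12))
    stop("distance values outside [", range[1], ", ", range[2], "]")
  d
}

#' Jaccard distance matrix on presence/absence
#'
#' d(x, y) = 1 - |Px intersect Py| / |Px union Py| over the OTU presence sets.
#' A pair of all-zero samples has an empty union; its distance is defined as 0
#' with a warning.
#'
#' @param counts samples x OTUs count matrix (>= 2 samples).
#' @return symmetric hollow distance matrix in \[0, 1\].
#' @export
jaccard_matrix <- function(counts) {
  counts <- validate_count_table(counts)
  if (nrow(counts) < 2) stop("need >= 2 samples")
  p <- (counts > 0) * 1
  shared <- tcrossprod(p)
  rich <- rowSums(p)
  un <- outer(rich, rich, "+") - shared
  d <- 1 - shared / un
  if (any(un == 0)) {
    warning("pair(s) of all-zero samples; Jaccard distance set to 0")
    d[un == 0] <- 0
  }
  diag(d) <- 0
  validate_distance_matrix(d, range = c(0, 1))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over OTU abundances.
#'
#' @param counts samples x OTUs abundance matrix with positive row sums.
#' @return symmetric hollow distance matrix in \[0, 1\].
#' @export
bray_curtis_matrix <- function(counts) {
  counts <- validate_count_table(counts)
  if (nrow(counts) < 2) stop("need >= 2 samples")
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("all-zero sample(s): ", paste(rownames(counts)[totals == 0], collapse = ", "))
  num <- as.matrix(stats::dist(counts, method = "manhattan"))
  den <- outer(totals, totals, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(counts), rownames(counts))
  validate_distance_matrix(d, range = c(0, 1))
}

#' Within- and between-group dissimilarity samples
#'
#' Splits the off-diagonal distances into the multiset of within-group
#' pairwise distances for each group and the multiset of between-group
#' distances for each group pair (the raw values behind intra/inter-group
#' dissimilarity boxplots).
#'
#' @param d distance matrix.
#' @param design grouping (see [group_factor()]).
#' @return data.frame with columns `comparison` (e.g. `"A"` or `"A-B"`),
#'   `type` (`"within"`/`"between"`), `sample_a`, `sample_b`, `distance`.
#' @export
intra_inter_dissimilarity <- function(d, design) {
  d <- validate_distance_matrix(d)
  g <- group_factor(design, rownames(d))
  idx <- which(upper.tri(d), arr.ind = TRUE)
  ga <- g[idx[, 1]]; gb <- g[idx[, 2]]
  within <- ga == gb
  comparison <- ifelse(within, as.character(ga),
                       paste(pmin(as.character(ga), as.character(gb)),
                             pmax(as.character(ga), as.character(gb)), sep = "-"))
  data.frame(comparison = comparison,
             type = ifelse(within, "within", "between"),
             sample_a = rownames(d)[idx[, 1]],
             sample_b = rownames(d)[idx[, 2]],
             distance = d[idx],
             stringsAsFactors = FALSE)
}
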