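#' @useDynLib asmscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rmultinom rlnorm rnorm runif sd quantile rgamma
#'   p.adjust var t.test aggregate
#' @importFrom utils read.table write.table combn
NULL

## ---- count table model -----------------------------------------------------

#' Validate an OTU count table
#'
#' A count table is an integer matrix with samples as rows and OTUs as
#' columns, unique non-empty dimnames, and non-negative integral entries.
#' All table-consuming functions in the package call this validator.
#'
#' @param counts matrix to validate.
#' @return the validated matrix (storage mode coerced to numeric), invisibly
#'   usable as input elsewhere.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts)) stop("count table must be a matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must carry sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts))) stop("count table contains missing or non-finite values")
  if (any(counts < 0)) stop("count table contains negative values")
  nonint <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint) > 0) {
    stop(sprintf("non-integer count %g at sample '%s', OTU '%s'",
                 counts[nonint[1, 1], nonint[1, 2]],
                 rownames(counts)[nonint[1, 1]], colnames(counts)[nonint[1, 2]]))
  }
  storage.mode(counts) <- "double"
  counts
}

#' Read an OTU count table from a tab-separated file
#'
#' Accepts either orientation and the BIOM TSV export dialect, whose header
#' line starts with `#OTU ID` (that dialect stores OTUs as rows). The result
#' is always normalized to samples x OTUs.
#'
#' @param path path to a TSV file with one header row and one identifier
#'   column.
#' @param orientation `"samples_as_rows"` or `"otus_as_rows"`. Default
#'   `"samples_as_rows"` unless a `#OTU ID` header is detected, which forces
#'   `"otus_as_rows"`.
#' @return validated count matrix, samples x OTUs.
#' @export
read_count_table <- function(path, orientation = c("samples_as_rows", "otus_as_rows")) {
  first <- readLines(path, n = 2L)
  first <- first[!grepl("^# ", first)]          # BIOM banner comments
  biom_style <- length(first) > 0 && grepl("^#OTU ID\t", first[[1]])
  if (biom_style && missing(orientation)) orientation <- "otus_as_rows"
  orientation <- match.arg(orientation)
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE, comment.char = "", quote = "",
                   skip = if (biom_style) grep("^#OTU ID\t", readLines(path))[1] - 1 else 0)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(df)[which(bad)[1]]
    cell <- df[[which(bad)[1]]]
    row <- rownames(df)[which(is.na(suppressWarnings(as.numeric(cell))) |
                                abs(suppressWarnings(as.numeric(cell)) -
                                      round(suppressWarnings(as.numeric(cell)))) > 1e-8)[1]]
    stop(sprintf("non-numeric value in column '%s' (row '%s')", col, row))
  }
  m <- as.matrix(df)
  if (orientation == "otus_as_rows") m <- t(m)
  validate_count_table(m)
}

#' Write a count table as TSV
#'
#' @param counts samples x OTUs matrix.
#' @param path output path.
#' @param orientation which dimension goes on rows in the file.
#' @export
write_count_table <- function(counts, path,
                              orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "otus_as_rows") t(counts) else counts
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (orientation == "otus_as_rows") "#OTU ID" else "sample_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree from a Newick file
#'
#' @param path Newick file containing a single rooted tree with branch
#'   lengths.
#' @return an [ape::read.tree()] `phylo` object, validated: rooted, with
#'   non-negative branch lengths.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree) || !inherits(tree, "phylo")) stop("could not parse Newick tree from ", path)
  validate_tree(tree)
}

#' @rdname read_tree
#' @param tree a `phylo` object to validate in place of a file.
#' @export
validate_tree <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  # basal polytomies are accepted (common in 16S reference trees); ape's
  # node numbering still gives a unique root at Ntip + 1
  tree
}

#' Read a sample metadata table
#'
#' Expects tab-separated columns `sample_id` and `group`, plus optional
#' numeric covariates (age, height, weight) and `gender`.
#'
#' @param path TSV file path.
#' @return data.frame with at least `sample_id` and `group` columns.
#' @export
read_metadata <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "")
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("metadata must have 'sample_id' and 'group' columns")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  df
}

#' Read an OTU taxonomy map
#'
#' Two tab-separated columns: OTU id and a `k__...;p__...;...;g__...` lineage
#' string.
#'
#' @param path TSV file path (no header required; a header line starting with
#'   `otu_id` is skipped).
#' @return named character vector, OTU id -> lineage string.
#' @export
read_taxonomy <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (nrow(df) > 0 && df[1, 1] %in% c("otu_id", "#OTU ID")) df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2) stop("taxonomy file needs two tab-separated columns")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

## ---- group design ----------------------------------------------------------

#' Coerce a grouping specification to a named factor over samples
#'
#' @param design either a data.frame with `sample_id`/`group` columns, a named
#'   vector/factor of group labels, or a factor aligned with `sample_ids`.
#' @param sample_ids sample identifiers the grouping must cover.
#' @param min_size minimum group size to require (default 1).
#' @return factor of group labels named by sample id, in `sample_ids` order.
#' @export
group_factor <- function(design, sample_ids, min_size = 1L) {
  if (is.data.frame(design)) {
    g <- stats::setNames(as.character(design$group), design$sample_id)
  } else {
    g <- design
    if (is.null(names(g)) && length(g) == length(sample_ids)) names(g) <- sample_ids
    g <- stats::setNames(as.character(g), names(g))
  }
  missing <- setdiff(sample_ids, names(g))
  if (length(missing) > 0)
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  g <- factor(g[sample_ids])
  small <- table(g) < min_size
  if (any(small))
    stop("groups with fewer than ", min_size, " samples: ",
         paste(names(which(small)), collapse = ", "))
  g
}

## ---- table operations ------------------------------------------------------

#' Rarefy a count table to even depth
#'
#' Each sample is subsampled without replacement (multivariate hypergeometric
#' draw) to exactly `depth` reads, emulating even-depth normalization of a
#' sequencing run. Deterministic for a given seed.
#'
#' @param counts samples x OTUs count matrix.
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed for the subsampling RNG.
#' @param drop_empty drop OTU columns that become all-zero (default FALSE;
#'   columns are retained so OTU sets stay comparable across tables).
#' @param drop_deficient drop (with a warning) samples whose total is below
#'   `depth` instead of erroring.
#' @return rarefied count matrix; every row sum equals `depth` exactly.
#' @export
rarefy <- function(counts, depth, seed = 1L, drop_empty = FALSE,
                   drop_deficient = FALSE) {
  counts <- validate_count_table(counts)
  if (depth < 1) stop("depth must be >= 1")
  totals <- rowSums(counts)
  deficient <- totals < depth
  if (any(deficient)) {
    if (!drop_deficient)
      stop("samples with fewer than ", depth, " reads: ",
           paste(rownames(counts)[deficient], collapse = ", "))
    warning("dropping ", sum(deficient), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[deficient], collapse = ", "))
    counts <- counts[!deficient, , drop = FALSE]
  }
  set.seed(seed)
  out <- t(apply(counts, 1, function(x) {
    if (sum(x) == depth) return(x)
    picked <- sample.int(sum(x), depth)
    # map read indices back to OTUs via cumulative counts
    tabulate(findInterval(picked - 1, cumsum(x)) + 1L, nbins = length(x))
  }))
  dimnames(out) <- dimnames(counts)
  stopifnot(all(rowSums(out) == depth))
  if (drop_empty) out <- out[, colSums(out) > 0, drop = FALSE]
  validate_count_table(out)
}

#' Aggregate OTU counts by taxonomy at a given rank
#'
#' Columns sharing the same lineage prefix down to `rank` are summed. OTUs
#' absent from the map, or whose lineage has an empty field at `rank`, are
#' pooled into a single `"unclassified"` column; totals are conserved.
#'
#' @param counts samples x OTUs count matrix.
#' @param taxonomy named character vector OTU id -> lineage string
#'   (`k__;p__;c__;o__;f__;g__` delimited by `;`).
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return samples x taxa count matrix.
#' @export
aggregate_taxa <- function(counts, taxonomy,
                           rank = c("genus", "family", "order", "class",
                                    "phylum", "kingdom")) {
  counts <- validate_count_table(counts)
  rank <- match.arg(rank)
  if (length(taxonomy) == 0) stop("empty taxonomy map")
  level <- match(rank, c("kingdom", "phylum", "class", "order", "family", "genus"))
  lineage <- taxonomy[colnames(counts)]
  label <- vapply(lineage, function(s) {
    if (is.na(s)) return("unclassified")
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    if (length(parts) < level) return("unclassified")
    x <- sub("^[a-z]__", "", parts[level])
    if (!nzchar(x)) "unclassified" else x
  }, character(1), USE.NAMES = FALSE)
  agg <- t(rowsum(t(counts), group = label))
  stopifnot(abs(sum(agg) - sum(counts)) < 1e-8)
  validate_count_table(agg)
}

#' Filter OTUs by prevalence
#'
#' Keeps OTUs present (count > 0) in strictly more than `min_fraction` of the
#' samples — the "detected in more than 50% of samples" rule used before
#' co-occurrence analysis. Set `strict = FALSE` for a >= comparison.
#'
#' @param counts samples x OTUs count matrix.
#' @param min_fraction prevalence threshold in (0, 1].
#' @param strict if TRUE (default) require prevalence strictly above the
#'   threshold.
#' @return filtered count matrix (possibly with zero columns).
#' @export
filter_prevalence <- function(counts, min_fraction = 0.5, strict = TRUE) {
  counts <- validate_count_table(counts)
  if (min_fraction <= 0 || min_fraction > 1) stop("min_fraction must be in (0, 1]")
  prev <- colMeans(counts > 0)
  keep <- if (strict) prev > min_fraction else prev >= min_fraction
  counts[, keep, drop = FALSE]
}

#' Convert counts to relative abundances
#'
#' @param counts samples x OTUs count matrix with positive row sums.
#' @return matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  counts <- validate_count_table(counts)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop("all-zero sample(s): ", paste(rownames(counts)[totals == 0], collapse = ", "))
  sweep(counts, 1, totals, "/")
}
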