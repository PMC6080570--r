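## ---- co-occurrence networks ------------------------------------------------

#' Pearson correlation matrix of log-transformed relative abundances
#'
#' Counts are converted to relative abundances, a pseudocount equal to 0.01
#' times the smallest nonzero relative abundance in the table is added, and
#' Pearson correlations are computed on log10 of the result. Input is
#' expected to be prevalence-filtered (see [filter_prevalence()]).
#' Zero-variance OTUs get correlation 0 with a warning.
#'
#' @param counts samples x OTUs count matrix.
#' @return symmetric correlation matrix (OTUs x OTUs) with unit diagonal.
#' @export
correlation_matrix <- function(counts) {
  counts <- validate_count_table(counts)
  rel <- relative_abundance(counts)
  pseudo <- 0.01 * min(rel[rel > 0])
  lg <- log10(rel + pseudo)
  novar <- apply(lg, 2, stats::var) == 0
  r <- suppressWarnings(cor(lg, method = "pearson"))
  if (any(novar)) {
    warning(sum(novar), " zero-variance OTU(s); their correlations set to 0")
    r[novar, ] <- 0
    r[, novar] <- 0
  }
  diag(r) <- 1
  r[is.na(r)] <- 0
  r
}

#' Build a co-occurrence network at a fixed correlation cutoff
#'
#' An edge joins OTUs i and j (i != j) iff |r_ij| >= cutoff; the sign of r is
#' recorded on the edge and |r| is its weight. Isolated nodes are dropped by
#' default.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param cutoff absolute-correlation threshold in (0, 1\]; edges use the
#'   inclusive `>=` convention.
#' @param keep_isolated retain nodes with no edges (default FALSE).
#' @return an [igraph::graph] with vertex attribute `name` and edge
#'   attributes `r`, `weight` (= |r|) and `sign` (`"+"`/`"-"`).
#' @export
threshold_network <- function(corr, cutoff = 0.89, keep_isolated = FALSE) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (max(abs(corr - t(corr))) > 1e-12) stop("correlation matrix must be symmetric")
  adj <- abs(corr) >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  ends <- igraph::as_edgelist(g, names = FALSE)
  rvals <- corr[cbind(ends[, 1], ends[, 2])]
  igraph::E(g)$r <- rvals
  igraph::E(g)$weight <- abs(rvals)
  igraph::E(g)$sign <- ifelse(rvals >= 0, "+", "-")
  if (!keep_isolated)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g
}

#' Topological panel of a co-occurrence network
#'
#' Computes the standard descriptive panel: node and edge counts, average
#' degree avgK = 2E/n, density D = 2E/(n(n-1)), average clustering
#' coefficient avgCC (nodes with degree < 2 contribute 0 by default),
#' connectedness Con = fraction of ordered node pairs that are reachable,
#' modularity M of the greedy module partition, the fraction of positive
#' edges, and the R^2 of an ordinary least-squares fit of log10(frequency)
#' on log10(degree) over observed positive degrees (scale-free fit).
#'
#' @param net network from [threshold_network()].
#' @param modules optional result of [detect_modules()]; computed if missing.
#' @param cc_exclude_low_degree if TRUE, average the clustering coefficient
#'   over nodes of degree >= 2 only instead of counting them as 0.
#' @return one-row data.frame: n_nodes, n_edges, avgK, avgCC, D, Con, M,
#'   positive_fraction, powerlaw_R2.
#' @export
topology_panel <- function(net, modules = NULL, cc_exclude_low_degree = FALSE) {
  n <- igraph::vcount(net)
  if (n < 2) stop("need >= 2 nodes")
  e <- igraph::ecount(net)
  if (e == 0) {
    warning("network has no edges; panel is degenerate")
    return(data.frame(n_nodes = n, n_edges = 0, avgK = 0, avgCC = 0, D = 0,
                      Con = 0, M = 0, positive_fraction = NA_real_,
                      powerlaw_R2 = NA_real_))
  }
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  avg_cc <- if (cc_exclude_low_degree) mean(cc[deg >= 2]) else mean(cc)
  comp <- igraph::components(net)$csize
  con <- sum(comp * (comp - 1)) / (n * (n - 1))
  if (is.null(modules)) modules <- detect_modules(net)
  pos <- if (!is.null(igraph::E(net)$sign)) mean(igraph::E(net)$sign == "+") else NA_real_
  tab <- table(deg[deg > 0])
  k <- as.numeric(names(tab)); fr <- as.numeric(tab)
  r2 <- if (length(k) >= 3) summary(stats::lm(log10(fr) ~ log10(k)))$r.squared else NA_real_
  data.frame(n_nodes = n, n_edges = e, avgK = 2 * e / n, avgCC = avg_cc,
             D = 2 * e / (n * (n - 1)), Con = con, M = modules$modularity,
             positive_fraction = pos, powerlaw_R2 = r2)
}

#' Detect network modules by greedy modularity maximization
#'
#' Runs deterministic greedy agglomeration (fast-greedy community detection)
#' on the unweighted, unsigned graph and reports the modularity
#' M = sum_m (e_m/E - (d_m/2E)^2) of the resulting partition.
#'
#' @param net network from [threshold_network()] with >= 1 edge.
#' @param seed retained for interface stability; the greedy algorithm is
#'   deterministic, so the seed does not change the result.
#' @return list with `membership` (named integer vector) and `modularity`.
#' @export
detect_modules <- function(net, seed = 1L) {
  if (igraph::ecount(net) < 1) stop("need >= 1 edge")
  bare <- if ("weight" %in% igraph::edge_attr_names(net))
    igraph::delete_edge_attr(net, "weight") else net
  set.seed(seed)
  cm <- igraph::cluster_fast_greedy(bare)
  memb <- as.integer(igraph::membership(cm))
  m_greedy <- igraph::modularity(bare, memb)
  # a graph with no community structure (e.g. complete) can come back with a
  # negative-modularity split; the one-module-per-component partition (M = 0
  # for a connected graph) is then the better answer
  comp <- igraph::components(bare)$membership
  m_comp <- igraph::modularity(bare, comp)
  if (m_comp > m_greedy) {
    memb <- as.integer(comp)
    m_greedy <- m_comp
  }
  list(membership = stats::setNames(memb, igraph::V(net)$name),
       modularity = m_greedy)
}

#' Within-module degree z-score (Zi) and among-module connectivity (Pi)
#'
#' Zi = (k_i,own - mean k,own over the node's module) / sd; a module whose
#' within-module degrees are constant (sd 0) gets Zi = 0 for all its nodes.
#' Pi = 1 - sum_m (k_i,m / k_i)^2 over modules m. Isolated nodes get
#' Zi = Pi = 0.
#'
#' @param net network.
#' @param modules result of [detect_modules()] (or a named membership
#'   vector).
#' @return data.frame: otu, module, degree, Zi, Pi.
#' @export
zi_pi <- function(net, modules) {
  memb <- if (is.list(modules)) modules$membership else modules
  nodes <- igraph::V(net)$name
  memb <- memb[nodes]
  nm <- max(memb)
  # per-node degree into each module
  ends <- igraph::as_edgelist(net, names = TRUE)
  kim <- matrix(0, length(nodes), nm, dimnames = list(nodes, NULL))
  if (nrow(ends) > 0) {
    for (side in 1:2) {
      other <- ends[, 3 - side]
      tab <- table(factor(ends[, side], levels = nodes), factor(memb[other], levels = seq_len(nm)))
      kim <- kim + as.matrix(tab)
    }
  }
  ki <- rowSums(kim)
  kown <- kim[cbind(seq_along(nodes), memb)]
  zi <- numeric(length(nodes))
  for (m in seq_len(nm)) {
    idx <- which(memb == m)
    s <- stats::sd(kown[idx])
    zi[idx] <- if (length(idx) < 2 || is.na(s) || s == 0) 0 else
      (kown[idx] - mean(kown[idx])) / s
  }
  pi_v <- ifelse(ki == 0, 0, 1 - rowSums((kim / pmax(ki, 1))^2))
  data.frame(otu = nodes, module = as.integer(memb), degree = as.numeric(ki),
             Zi = zi, Pi = as.numeric(pi_v), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify topological roles and putative keystones from (Zi, Pi)
#'
#' Peripheral: Zi < 2.5 and Pi < 0.62. Connector: Pi > 0.62 with Zi <= 2.5.
#' Module hub: Zi > 2.5 with Pi <= 0.62. Network hub: Zi > 2.5 and
#' Pi > 0.62. Boundary values (Zi = 2.5 or Pi = 0.62) fall on the <= side.
#' Keystones are all non-peripheral nodes (module hubs, network hubs,
#' connectors).
#'
#' @param roles data.frame from [zi_pi()] (columns Zi, Pi).
#' @param zi_threshold,pi_threshold role thresholds (defaults 2.5 and 0.62).
#' @return the input data.frame with added `role` and logical `keystone`
#'   columns.
#' @export
classify_roles <- function(roles, zi_threshold = 2.5, pi_threshold = 0.62) {
  hi_z <- roles$Zi > zi_threshold
  hi_p <- roles$Pi > pi_threshold
  role <- ifelse(hi_z & hi_p, "network hub",
                 ifelse(hi_z, "module hub",
                        ifelse(hi_p, "connector", "peripheral")))
  roles$role <- role
  roles$keystone <- role != "peripheral"
  roles
}

#' Per-group co-occurrence network analysis
#'
#' Convenience wrapper running the full network stage for one group: subset
#' that group's samples, prevalence-filter (> `min_prevalence`), correlate,
#' threshold at `cutoff`, detect modules, and classify node roles.
#'
#' @param counts samples x OTUs count matrix (all groups).
#' @param design grouping.
#' @param group which group label to analyse.
#' @param min_prevalence prevalence threshold (strict >), default 0.5.
#' @param cutoff absolute-correlation edge threshold, default 0.89.
#' @return list with `network`, `modules`, `roles` (with role classes),
#'   `panel`, and `n_otus_filtered`.
#' @export
group_network <- function(counts, design, group, min_prevalence = 0.5,
                          cutoff = 0.89) {
  g <- group_factor(design, rownames(counts))
  if (!group %in% levels(g)) stop("unknown group: ", group)
  sub <- counts[g == group, , drop = FALSE]
  sub <- filter_prevalence(sub, min_prevalence)
  corr <- correlation_matrix(sub)
  net <- threshold_network(corr, cutoff)
  if (igraph::ecount(net) == 0) {
    warning("group ", group, ": no edges at cutoff ", cutoff)
    return(list(network = net, modules = NULL, roles = NULL, panel = NULL,
                n_otus_filtered = ncol(sub)))
  }
  mods <- detect_modules(net)
  roles <- classify_roles(zi_pi(net, mods))
  panel <- topology_panel(net, mods)
  list(network = net, modules = mods, roles = roles, panel = panel,
       n_otus_filtered = ncol(sub))
}
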