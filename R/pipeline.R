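## ---- end-to-end pipeline ---------------------------------------------------

#' Assemble a pipeline configuration
#'
#' Collects every input path and tuning parameter for [run_pipeline()].
#' All randomized stages draw independent seeds derived from `seed` by a
#' fixed offset scheme (prep +0, diversity +1, indicator +2, network +3,
#' assembly +4), recorded in the run manifest.
#'
#' @param table,tree,metadata,taxonomy input file paths (taxonomy optional).
#' @param out_dir output directory (created if needed).
#' @param depth rarefaction depth; NULL skips rarefaction.
#' @param n_permutations permutations for PERMANOVA/ANOSIM/IndVal.
#' @param network_cutoff,network_prevalence network stage parameters.
#' @param nti_randomizations,pair_randomizations assembly stage null sizes.
#' @param run_assembly,run_network toggles for the expensive stages.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(table, tree = NULL, metadata, taxonomy = NULL,
                            out_dir, depth = NULL, n_permutations = 999,
                            network_cutoff = 0.89, network_prevalence = 0.5,
                            nti_randomizations = 1000,
                            pair_randomizations = 999,
                            run_assembly = !is.null(tree), run_network = TRUE,
                            seed = 1L) {
  structure(list(table = table, tree = tree, metadata = metadata,
                 taxonomy = taxonomy, out_dir = out_dir, depth = depth,
                 n_permutations = n_permutations,
                 network_cutoff = network_cutoff,
                 network_prevalence = network_prevalence,
                 nti_randomizations = nti_randomizations,
                 pair_randomizations = pair_randomizations,
                 run_assembly = run_assembly, run_network = run_network,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path, id = "sample_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- id
  write_tsv(df, path)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: prep (read + optional rarefaction), diversity (alpha
#' table, Jaccard and Bray-Curtis matrices, PERMANOVA/ANOSIM report,
#' intra/inter dissimilarities), indicator screening, per-group
#' co-occurrence networks, and community assembly (NTI, pairwise
#' betaNTI/RCbray/process labels, per-group process fractions, beta
#' deviation table). Every stage writes TSV files under `out_dir` and a
#' `manifest.json` records parameters, seeds, and input checksums so a rerun
#' from the same manifest is byte-identical. A stage failure aborts with the
#' stage name; earlier outputs are retained.
#'
#' @param cfg a [pipeline_config()] (or path to a YAML config).
#' @return (invisibly) a list with the in-memory results of each stage and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  if (!inherits(cfg, "pipeline_config")) stop("cfg must be a pipeline_config()")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  results <- list()

  ## prep
  results$prep <- stage("prep", {
    counts <- read_count_table(cfg$table)
    meta <- read_metadata(cfg$metadata)
    counts <- counts[intersect(rownames(counts), meta$sample_id), , drop = FALSE]
    if (!is.null(cfg$depth))
      counts <- rarefy(counts, cfg$depth, seed = cfg$seed)
    write_matrix_tsv(counts, file.path(cfg$out_dir, "table_prepared.tsv"))
    list(counts = counts, meta = meta)
  })
  counts <- results$prep$counts
  meta <- results$prep$meta
  tree <- NULL
  if (!is.null(cfg$tree)) tree <- stage("prep", read_tree(cfg$tree))
  if (cfg$run_assembly && is.null(tree))
    stop("pipeline stage 'assembly' requires a tree; none was configured")

  ## diversity
  results$diversity <- stage("diversity", {
    alpha <- data.frame(sample_id = rownames(counts),
                        observed_otus = observed_otus(counts))
    if (!is.null(tree))
      alpha$faith_pd <- faith_pd(counts, tree, prune = TRUE)
    dj <- jaccard_matrix(counts)
    db <- bray_curtis_matrix(counts)
    stats_rows <- do.call(rbind, lapply(
      list(c("jaccard", "permanova"), c("jaccard", "anosim"),
           c("braycurtis", "permanova"), c("braycurtis", "anosim")),
      function(sp) {
        d <- if (sp[1] == "jaccard") dj else db
        r <- if (sp[2] == "permanova")
          permanova(d, meta, cfg$n_permutations, seed = cfg$seed + 1L)
        else anosim(d, meta, cfg$n_permutations, seed = cfg$seed + 1L)
        data.frame(metric = sp[1], test = sp[2], statistic = r$statistic,
                   r_squared = if (is.null(r$r_squared)) NA_real_ else r$r_squared,
                   p_value = r$p_value, n_permutations = r$n_permutations)
      }))
    write_tsv(alpha, file.path(cfg$out_dir, "alpha_diversity.tsv"))
    write_matrix_tsv(dj, file.path(cfg$out_dir, "distance_jaccard.tsv"))
    write_matrix_tsv(db, file.path(cfg$out_dir, "distance_braycurtis.tsv"))
    write_tsv(stats_rows, file.path(cfg$out_dir, "beta_statistics.tsv"))
    write_tsv(intra_inter_dissimilarity(db, meta),
              file.path(cfg$out_dir, "dissimilarity_braycurtis.tsv"))
    list(alpha = alpha, jaccard = dj, braycurtis = db, stats = stats_rows)
  })

  ## indicator
  results$indicator <- stage("indicator", {
    x <- counts
    if (!is.null(cfg$taxonomy))
      x <- aggregate_taxa(counts, read_taxonomy(cfg$taxonomy), "genus")
    scr <- screen_indicators(relative_abundance(x), meta,
                             n_permutations = cfg$n_permutations,
                             seed = cfg$seed + 2L)
    write_tsv(attr(scr, "full"), file.path(cfg$out_dir, "indval_full.tsv"))
    write_tsv(scr, file.path(cfg$out_dir, "indval_screened.tsv"))
    scr
  })

  ## network (per group)
  if (cfg$run_network) {
    results$network <- stage("network", {
      g <- group_factor(meta, rownames(counts))
      nets <- lapply(levels(g), function(lv) {
        res <- group_network(counts, meta, lv,
                             min_prevalence = cfg$network_prevalence,
                             cutoff = cfg$network_cutoff)
        if (!is.null(res$panel)) {
          write_tsv(data.frame(group = lv, res$panel),
                    file.path(cfg$out_dir, paste0("network_panel_", lv, ".tsv")))
          write_tsv(res$roles,
                    file.path(cfg$out_dir, paste0("network_roles_", lv, ".tsv")))
          el <- igraph::as_edgelist(res$network)
          write_tsv(data.frame(otu_a = el[, 1], otu_b = el[, 2],
                               r = igraph::E(res$network)$r,
                               sign = igraph::E(res$network)$sign),
                    file.path(cfg$out_dir, paste0("network_edges_", lv, ".tsv")))
          igraph::write_graph(res$network,
                              file.path(cfg$out_dir, paste0("network_", lv, ".graphml")),
                              format = "graphml")
        }
        res
      })
      names(nets) <- levels(g)
      nets
    })
  }

  ## assembly
  if (cfg$run_assembly) {
    results$assembly <- stage("assembly", {
      nti_tab <- nti(counts, tree, n_randomizations = cfg$nti_randomizations,
                     seed = cfg$seed + 4L)
      pairs <- pairwise_assembly(counts, tree,
                                 n_randomizations = cfg$pair_randomizations,
                                 seed = cfg$seed + 4L)
      fr <- process_fractions(pairs, meta, scope = "all_pairs")
      dev <- rbind(
        null_beta_deviation(counts, meta, "braycurtis",
                            n_randomizations = cfg$pair_randomizations,
                            seed = cfg$seed + 4L),
        null_beta_deviation(counts, meta, "jaccard",
                            n_randomizations = cfg$pair_randomizations,
                            seed = cfg$seed + 4L))
      write_tsv(nti_tab, file.path(cfg$out_dir, "assembly_nti.tsv"))
      write_tsv(pairs, file.path(cfg$out_dir, "assembly_pairs.tsv"))
      write_tsv(fr, file.path(cfg$out_dir, "assembly_process_fractions.tsv"))
      write_tsv(dev, file.path(cfg$out_dir, "assembly_beta_deviation.tsv"))
      list(nti = nti_tab, pairs = pairs, fractions = fr, beta_deviation = dev)
    })
  }

  ## manifest
  inputs <- Filter(Negate(is.null),
                   cfg[c("table", "tree", "metadata", "taxonomy")])
  manifest <- list(
    package = "asmscope",
    version = as.character(utils::packageVersion("asmscope")),
    config = unclass(cfg),
    stage_seeds = list(prep = cfg$seed, diversity = cfg$seed + 1L,
                       indicator = cfg$seed + 2L, network = cfg$seed + 3L,
                       assembly = cfg$seed + 4L),
    input_md5 = as.list(tools::md5sum(unlist(inputs))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Re-run a pipeline from its manifest
#'
#' Reads `manifest.json`, rebuilds the configuration it records, and reruns
#' the pipeline into `out_dir`; with unchanged inputs the TSV outputs are
#' byte-identical.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir output directory (default: the one in the manifest).
#' @return see [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  cfg <- cfg[lengths(cfg) > 0]          # JSON nulls come back empty
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  run_pipeline(do.call(pipeline_config, cfg))
}
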