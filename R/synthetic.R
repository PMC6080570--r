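## ---- synthetic communities with known assembly regimes ---------------------

#' Simulate a Yule pure-birth phylogeny
#'
#' @param n_taxa number of tips (>= 2); tips are labelled `OTU_1..OTU_n`.
#' @param birth_rate speciation rate of the pure-birth process.
#' @param seed RNG seed; the same seed reproduces the identical tree.
#' @return rooted ultrametric `phylo` with branch lengths.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("OTU_", seq_len(n_taxa))
  validate_tree(tree)
}

#' Simulate Brownian niche optima on a tree
#'
#' Each of `n_dims` independent continuous traits evolves by Brownian motion
#' from a root value of 0 with rate `trait_sigma`; closely related tips
#' therefore receive similar niche positions. A single Brownian trait is a
#' poor proxy for a conserved niche — unrelated lineages converge on the
#' same scalar value — so the niche is multivariate by default: the chance
#' that distant lineages coincide in all dimensions at once vanishes with
#' `n_dims`, which is what makes trait-based filtering phylogenetically
#' clustered at the tips.
#'
#' @param tree `phylo` with branch lengths.
#' @param trait_sigma Brownian rate (per unit branch length, per dimension);
#'   0 gives all traits 0.
#' @param seed RNG seed.
#' @param n_dims number of independent niche dimensions (default 1 returns
#'   a vector; > 1 returns a tips x dims matrix).
#' @return named numeric vector (`n_dims = 1`) or matrix of tip niche
#'   positions.
#' @export
simulate_traits <- function(tree, trait_sigma = 1, seed = 1L, n_dims = 1L) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (trait_sigma == 0) {
    out <- matrix(0, ntip, n_dims, dimnames = list(tree$tip.label, NULL))
  } else {
    set.seed(seed)
    out <- vapply(seq_len(n_dims), function(j)
      ape::rTraitCont(tree, model = "BM", sigma = trait_sigma, root.value = 0),
      numeric(ntip))
    rownames(out) <- tree$tip.label
  }
  if (n_dims == 1L) out[, 1] else out
}

#' Assemble one sample under Gaussian environmental filtering
#'
#' Expected relative abundance of taxon i is proportional to
#' exp(-(trait_i - environment)^2 / (2 sigma_w^2)) times a per-taxon
#' lognormal fitness factor; counts are a multinomial draw of `depth` reads.
#' Small `sigma_w` means strong selection around the environmental optimum;
#' very large `sigma_w` reduces to a neutral lognormal community.
#'
#' Samples drawn straight from the filtered expectation would be nearly
#' identical replicates, which no real host cohort is; `drift_theta` adds
#' per-sample ecological drift by first resampling the realised profile from
#' a Dirichlet with concentration `drift_theta * expected profile` (a small
#' effective local community size gives strong inter-individual turnover
#' among the selected taxa), then drawing the reads.
#'
#' @param traits taxon niche positions: named vector (one dimension) or
#'   tips x dims matrix from [simulate_traits()].
#' @param environment environmental optimum of the sample: scalar or a
#'   point in niche space (length = number of trait dimensions).
#' @param sigma_w niche filter width (> 0), in trait units.
#' @param depth reads to draw.
#' @param fitness per-taxon lognormal fitness factors; drawn as
#'   `rlnorm(length(traits))` when NULL. Freeze one vector per dataset so
#'   within-group similarity reflects the environment rather than the noise.
#' @param drift_theta Dirichlet concentration (effective local community
#'   size) of the per-sample drift step; `Inf` disables drift and samples
#'   the expectation directly.
#' @param seed RNG seed (used for the fitness draw when `fitness` is NULL,
#'   the drift draw, and the multinomial draw).
#' @return named integer count vector summing to `depth`.
#' @export
assemble_selection <- function(traits, environment, sigma_w, depth,
                               fitness = NULL, drift_theta = 50, seed = 1L) {
  if (sigma_w <= 0) stop("sigma_w must be > 0")
  if (!is.matrix(traits)) traits <- as.matrix(traits)
  if (length(environment) != ncol(traits))
    stop("environment must have one value per niche dimension")
  taxa <- rownames(traits)
  d2 <- rowSums(sweep(traits, 2, environment)^2)
  set.seed(seed)
  if (is.null(fitness)) fitness <- rlnorm(nrow(traits))
  base <- fitness / sum(fitness)
  # drift acts on arrival (pre-filter), selection on establishment: the
  # Dirichlet draw perturbs the neutral pool and the Gaussian kernel then
  # removes maladapted arrivals, so drift cannot resurrect filtered-out taxa
  if (is.finite(drift_theta)) {
    draw <- rgamma(length(base), shape = drift_theta * base, rate = 1)
    if (sum(draw) > 0) base <- draw / sum(draw)
  }
  w <- exp(-d2 / (2 * sigma_w^2)) * base
  if (sum(w) == 0) stop("all filter weights are zero; widen sigma_w")
  draw_min_richness(w, depth, taxa)
}

# multinomial draw retried until at least two taxa are present: a one-taxon
# community has no pairwise phylogenetic structure and poisons the
# nearest-taxon statistics downstream
draw_min_richness <- function(prob, depth, taxa, tries = 100L) {
  for (i in seq_len(tries)) {
    x <- as.integer(rmultinom(1, depth, prob = prob))
    if (sum(x > 0) >= 2) return(stats::setNames(x, taxa))
  }
  warning("community profile effectively has one taxon; ",
          "phylogenetic statistics will be undefined for this sample")
  stats::setNames(x, taxa)
}

#' Assemble one sample by neutral sampling from a metacommunity
#'
#' The sample's underlying relative-abundance profile is a Dirichlet draw
#' with concentration `m * depth * profile` around the metacommunity
#' profile, then counts are multinomial. Migration `m` near 1 couples the
#' sample tightly to the metacommunity (well-mixed); small `m` lets drift
#' drive samples apart (dispersal-limited divergence).
#'
#' @param profile metacommunity relative-abundance profile (sums to 1).
#' @param m migration/coupling parameter in (0, 1\].
#' @param depth reads to draw.
#' @param seed RNG seed.
#' @return named integer count vector summing to `depth`.
#' @export
assemble_neutral <- function(profile, m, depth, seed = 1L) {
  if (abs(sum(profile) - 1) > 1e-8) stop("metacommunity profile must sum to 1")
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  set.seed(seed)
  alpha <- m * depth * profile
  draw <- rgamma(length(profile), shape = alpha, rate = 1)   # Dirichlet via gamma
  if (sum(draw) == 0) draw <- profile
  draw_min_richness(draw / sum(draw), depth, names(profile))
}

#' Scenario configuration for the synthetic generator
#'
#' Defaults emulate a three-group, eight-samples-per-group observational
#' design over a few hundred OTUs at an even within-study sequencing depth.
#'
#' @param scenario one of `"selection_variable"` (distinct environmental
#'   optima per group, strong filtering), `"selection_homogeneous"` (one
#'   shared optimum), `"neutral_well_mixed"` (high migration from one
#'   metacommunity), `"neutral_dispersal_limited"` (per-group perturbed
#'   metacommunities, low migration).
#' @param n_taxa number of OTUs (>= 16).
#' @param n_groups,samples_per_group design shape.
#' @param depth reads per sample (>= 100).
#' @param birth_rate Yule speciation rate for the tree.
#' @param trait_sigma Brownian rate of the niche traits.
#' @param trait_dims number of niche dimensions (default 5; see
#'   [simulate_traits()]).
#' @param sigma_w_factor filter width as a multiple of the realised
#'   per-dimension trait standard deviation. Defaults to 0.5 except for
#'   `selection_homogeneous`, which defaults to 0.3: a single shared strong
#'   filter is what defines that regime, whereas the variable-selection
#'   regime draws its signal from the separation between group optima.
#' @param drift_theta effective local community size of the per-sample
#'   drift step in the selection scenarios (default 50; see
#'   [assemble_selection()]).
#' @param migration Dirichlet coupling for the neutral scenarios; defaults
#'   to 0.9 (well-mixed) or 0.01 (dispersal-limited).
#' @param seed master seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("selection_variable",
                                         "selection_homogeneous",
                                         "neutral_well_mixed",
                                         "neutral_dispersal_limited"),
                            n_taxa = 200, n_groups = 3, samples_per_group = 8,
                            depth = 5000, birth_rate = 1, trait_sigma = 1,
                            trait_dims = 5, sigma_w_factor = NULL,
                            drift_theta = 50, migration = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_taxa < 16) stop("n_taxa must be >= 16")
  if (depth < 100) stop("depth must be >= 100")
  if (is.null(sigma_w_factor))
    sigma_w_factor <- if (scenario == "selection_homogeneous") 0.25 else 0.5
  if (sigma_w_factor <= 0) stop("sigma_w_factor must be > 0")
  if (trait_dims < 1) stop("trait_dims must be >= 1")
  if (is.null(migration))
    migration <- if (scenario == "neutral_dispersal_limited") 0.01 else 0.9
  structure(list(scenario = scenario, n_taxa = n_taxa, n_groups = n_groups,
                 samples_per_group = samples_per_group, depth = depth,
                 birth_rate = birth_rate, trait_sigma = trait_sigma,
                 trait_dims = trait_dims, sigma_w_factor = sigma_w_factor,
                 drift_theta = drift_theta, migration = migration,
                 seed = seed),
            class = "scenario_config")
}

# phylogenetic density of each tip: mean distance to its k nearest neighbours
# (small = tip sits inside a tight clade)
tip_density_score <- function(D, k = 10) {
  apply(D, 1, function(row) mean(sort(row[row > 0])[seq_len(min(k, sum(row > 0)))]))
}

# deterministic choice of k reference tips for divergent group optima.
# The tree is cut into k deep clades (average-linkage on patristic
# distances recovers the tree's own deep structure), so the optima are
# separated by the deepest splits available on any tree realisation.
# Within each clade, candidates are restricted to the denser half (an
# optimum on an isolated long branch would select a one-taxon community)
# and picked greedily to maximise separation in niche (trait) space, which
# is the space the filter actually acts on.
pick_reference_tips <- function(D, traits, k) {
  dens <- tip_density_score(D)
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"), k = k)
  Td <- as.matrix(stats::dist(traits))
  chosen <- character(0)
  for (part in order(-tabulate(cl))) {
    m <- names(cl)[cl == part]
    cand <- m[dens[m] <= stats::median(dens[m])]
    if (length(cand) == 0) cand <- m
    chosen <- c(chosen, if (length(chosen) == 0) cand[which.min(dens[cand])]
                else cand[which.max(apply(Td[cand, chosen, drop = FALSE], 1, min))])
  }
  chosen
}

#' Generate a synthetic dataset under a known assembly regime
#'
#' Produces a count table, matching phylogeny, group design, and the ground
#' truth (per-sample environment, per-taxon trait) for one of four
#' scenarios:
#' * `selection_variable`: each group filters around its own environmental
#'   optimum — the realised niche of one of `n_groups` mutually distant
#'   reference tips (deterministic farthest-point choice) — with filter
#'   width `sigma_w_factor * per-dimension trait SD`; between-group pairs
#'   experience divergent selection, within-group pairs shared selection.
#' * `selection_homogeneous`: all groups filter around the niche of one
#'   (seeded random) reference tip.
#' * `neutral_well_mixed`: all samples drawn from one lognormal
#'   metacommunity with high migration; no phylogenetic structure.
#' * `neutral_dispersal_limited`: each group's metacommunity is a Dirichlet
#'   perturbation (concentration 5) of the shared one, and migration is low,
#'   so samples diverge by drift.
#'
#' @param cfg a [scenario_config()].
#' @return list with `counts` (samples x OTUs, row sums = depth), `tree`,
#'   `design` (data.frame sample_id/group), `truth` (data.frame with
#'   per-sample environment plus scenario parameters), `traits`, `config`.
#' @export
make_scenario <- function(cfg = scenario_config()) {
  if (!inherits(cfg, "scenario_config")) stop("cfg must be a scenario_config()")
  tree <- simulate_tree(cfg$n_taxa, cfg$birth_rate, seed = cfg$seed)
  traits <- simulate_traits(tree, cfg$trait_sigma, seed = cfg$seed + 1L,
                            n_dims = cfg$trait_dims)
  traits_m <- if (is.matrix(traits)) traits else as.matrix(traits)
  n <- cfg$n_groups * cfg$samples_per_group
  groups <- rep(paste0("G", seq_len(cfg$n_groups)), each = cfg$samples_per_group)
  sample_ids <- paste0(groups, "_S", rep(seq_len(cfg$samples_per_group),
                                         times = cfg$n_groups))
  # rms per-dimension spread: the natural trait-unit for the filter width
  sigma_w <- cfg$sigma_w_factor * sqrt(mean(apply(traits_m, 2, stats::var)))
  set.seed(cfg$seed + 2L)
  fitness <- rlnorm(cfg$n_taxa)                 # frozen per dataset
  # uneven lognormal abundance distribution (sdlog 3): most taxa rare, so
  # per-sample richness and taxon occupancy vary the way they do in real
  # surveys instead of every taxon occurring everywhere
  meta_profile <- {p <- rlnorm(cfg$n_taxa, sdlog = 3); p / sum(p)}
  names(meta_profile) <- names(fitness) <- tree$tip.label
  env_tips <- rep(NA_character_, cfg$n_groups)
  if (cfg$scenario == "selection_variable") {
    env_tips <- pick_reference_tips(patristic_distances(tree), traits_m,
                                    cfg$n_groups)
  } else if (cfg$scenario == "selection_homogeneous") {
    # the shared optimum is the tip whose niche neighbourhood is most
    # heritable: its nearest trait-neighbours are also its phylogenetic
    # relatives, so one strong filter assembles a clade-coherent community
    D <- patristic_distances(tree)
    Td <- as.matrix(stats::dist(traits_m))
    coherence <- vapply(rownames(D), function(t) {
      nb <- names(sort(Td[t, ]))[2:11]
      mean(D[t, nb])
    }, numeric(1))
    env_tips <- rep(names(which.min(coherence)), cfg$n_groups)
  }
  group_profiles <- NULL
  if (cfg$scenario == "neutral_dispersal_limited") {
    group_profiles <- lapply(seq_len(cfg$n_groups), function(gi) {
      d <- rgamma(cfg$n_taxa, shape = 5 * meta_profile, rate = 1)
      if (sum(d) == 0) d <- meta_profile
      stats::setNames(d / sum(d), tree$tip.label)
    })
  }
  counts <- matrix(0L, n, cfg$n_taxa, dimnames = list(sample_ids, tree$tip.label))
  envs <- rep(NA_character_, n)
  for (s in seq_len(n)) {
    gi <- match(groups[s], paste0("G", seq_len(cfg$n_groups)))
    sseed <- cfg$seed + 100L + s
    if (cfg$scenario %in% c("selection_variable", "selection_homogeneous")) {
      envs[s] <- env_tips[gi]
      counts[s, ] <- assemble_selection(traits_m, traits_m[env_tips[gi], ],
                                        sigma_w, cfg$depth,
                                        fitness = fitness,
                                        drift_theta = cfg$drift_theta,
                                        seed = sseed)
    } else {
      prof <- if (is.null(group_profiles)) meta_profile else group_profiles[[gi]]
      counts[s, ] <- assemble_neutral(prof, cfg$migration, cfg$depth,
                                      seed = sseed)
    }
  }
  design <- data.frame(sample_id = sample_ids, group = groups,
                       stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = sample_ids, group = groups,
                      environment = envs, scenario = cfg$scenario,
                      sigma_w = if (is.na(env_tips[1])) NA_real_ else sigma_w,
                      migration = cfg$migration, stringsAsFactors = FALSE)
  stopifnot(all(rowSums(counts) == cfg$depth),
            identical(sort(tree$tip.label), sort(colnames(counts))))
  list(counts = validate_count_table(counts), tree = tree, design = design,
       truth = truth, traits = traits, config = cfg)
}
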