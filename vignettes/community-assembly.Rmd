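---
title: "Inferring community assembly processes with asmscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes with asmscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmscope)
```

## The question and the model

Microbial communities are assembled by a mixture of deterministic and
stochastic processes. Deterministic *selection* filters taxa by their fit to
the local environment; stochastic *dispersal* and *drift* move and resample
individuals without regard to their traits. `asmscope` implements the
standard phylogenetic null-model framework for partitioning these processes
from a rarefied OTU table and a rooted phylogeny, plus the descriptive
analyses (diversity, indicator taxa, co-occurrence networks) that normally
accompany it.

The framework rests on one assumption worth stating plainly: **ecological
similarity is phylogenetically conserved at the terminal scale of the
tree**. If close relatives share niches, then a community assembled by
filtering holds taxa that are closer on the tree than chance predicts, and
two communities filtered by *different* environments are phylogenetically
*farther* apart than chance predicts. All the nearest-taxon statistics read
assembly history through that lens; where trait conservation fails, they
lose power (see *Limitations*).

### Within-sample statistics

The mean nearest taxon distance of sample $k$ is
$\mathrm{MNTD}_k = \sum_{i \in k} f_{ik}\, \min_{j \in k,\, j \ne i} d_{ij}$,
with $d_{ij}$ the patristic distance and $f_{ik}$ the relative abundances
(`weighted = TRUE`, the default, matching common practice). Its null
distribution comes from shuffling tip labels across the whole tree
("taxa-labels" null), 1000 shuffles by default, and

$$\mathrm{NTI}_k = -\frac{\mathrm{MNTD}_k^{obs} -
\overline{\mathrm{MNTD}_k^{null}}}{\mathrm{sd}(\mathrm{MNTD}_k^{null})},$$

so positive NTI means phylogenetic clustering (filtering), negative means
overdispersion.

### Between-sample statistics and the five processes

For a pair of samples, $\beta\mathrm{MNTD}$ averages each taxon's distance
to its nearest neighbour in the *other* sample, abundance-weighted and
symmetrized. Its z-score against the same tip-shuffle null is
$\beta\mathrm{NTI}$. Pairs with $\beta\mathrm{NTI} > 2$ experienced
*variable selection* (different filters pushed them apart), pairs with
$\beta\mathrm{NTI} < -2$ *homogeneous selection* (one shared filter held
them together).

Pairs inside the $[-2, 2]$ band are partitioned by the Bray–Curtis
Raup–Crick statistic $\mathrm{RC}_{bray}$: null pairs are built by giving
each sample its observed richness (taxa drawn with probability proportional
to occupancy across the dataset) and its observed read total (reads
allocated proportionally to metacommunity relative abundance), and

$$\mathrm{RC} = \frac{2\left[\#\{BC_{null} < BC_{obs}\} +
\tfrac{1}{2}\#\{ties\}\right]}{n_{rand}} - 1 \in [-1, 1].$$

$\mathrm{RC} > 0.95$ is *dispersal limitation* (more turnover than the null
explains), $\mathrm{RC} < -0.95$ *homogenizing dispersal* (less), and the
remainder *drift* (undominated). All five thresholds are strict
inequalities; boundary values fall to the less extreme class. The published
statement of the drift rule contains an impossible inequality
("2 < βNTI < 2"); the only consistent reading, $-2 \le \beta\mathrm{NTI}
\le 2$, is what we implement.

One set of tip shuffles per randomization index is shared across all pairs
(for βNTI), and one null realisation of every sample per randomization is
shared across all pairs (for RC). This is both faster and statistically
cleaner than independent nulls per pair, and it is what makes the full
24-sample, 999-randomization analysis run in seconds (the inner kernels are
C++).

### The beta-deviation (dispersion) test

`null_beta_deviation()` asks, per group and metric, whether observed beta
diversity differs from the stochastic expectation. Observed
distance-to-centroid dispersions (computed with the Gower identity, no
ordination) are compared with dispersions of null communities from the same
occupancy/abundance engine, using the group's samples as the metacommunity.
The p-value permutes the observed/null labels **at the realisation level**:
each null realisation takes a turn playing "observed" and the ANOVA F is
recomputed. We initially permuted individual dispersion values; that test
was anti-conservative (null rejection rate above nominal) because values
within one realisation are correlated, and the block permutation fixed the
calibration — on data generated by the null engine itself, p > 0.05 in
97–100% of replicates.

## The synthetic-community generator

`make_scenario()` emulates the post-QC state of a lifestyle-cohort
sequencing study: a rarefied table over a few hundred OTUs for 3 groups × 8
samples (defaults; both are knobs), a matching ultrametric phylogeny, and
group metadata. Its purpose is ground truth: each scenario *is* one of the
assembly regimes, so the inference machinery can be validated end to end.

Components, with the reasoning behind the non-obvious choices:

- **Tree**: Yule pure-birth (`ape::rphylo`, birth rate 1), 200 tips.
- **Niches**: five independent Brownian traits per tip (rate 1). A single
  Brownian trait turned out to be a poor niche proxy: a narrow band around
  any value contains as many distant convergent lineages as relatives (we
  measured the mean patristic distance within a 20-taxon trait band to be
  indistinguishable from a random 20-taxon draw), so scalar-trait filtering
  produces no terminal phylogenetic clustering and no βNTI signal at all.
  With five dimensions the probability of convergence in all axes at once
  is negligible and a niche neighbourhood is genuinely a phylogenetic
  neighbourhood.
- **Selection scenarios** (`assemble_selection`): expected relative
  abundance $\propto \exp(-\lVert t_i - e\rVert^2 / 2\sigma_w^2) \times$ a
  per-taxon lognormal fitness frozen per dataset. Each sample additionally
  passes through a drift step — a Dirichlet resample of the *pre-filter*
  pool with concentration `drift_theta = 50` (an effective local community
  size) — so same-environment samples contain different but related taxa.
  Without drift, replicate samples are near-identical and βMNTD nulls are
  degenerate (shared taxa sit at distance zero under every shuffle); drift
  is applied before the filter because resampling the *filtered* profile
  occasionally resurrects far-tail taxa at high abundance (small-shape
  gamma draws are all-or-nothing), which destroys the phylogenetic signal.
- **Environment optima are realized tip niches.** For
  `selection_variable`, the tree is cut into `n_groups` deep clades
  (average-linkage on patristic distances) and each group's optimum is a
  densely-surrounded tip of its own clade, chosen greedily for trait-space
  separation — guaranteeing the optima are separated by the deepest splits
  the tree offers. For `selection_homogeneous` the shared optimum is the
  tip whose ten nearest trait-neighbours are phylogenetically closest (the
  most *heritable* niche): an optimum in a trait region contaminated by
  convergent lineages assembles communities with no clade coherence. The
  filter width is `sigma_w_factor` × the per-dimension trait SD — 0.5 for
  the variable scenario and 0.25 for the homogeneous one, where the single
  shared strong filter *is* the definition of the regime.
- **Neutral scenarios** (`assemble_neutral`): sample profiles are
  Dirichlet draws with concentration $m \cdot \mathrm{depth} \cdot
  \mathrm{profile}$ around a metacommunity, then multinomial reads.
  `neutral_well_mixed` uses one metacommunity and $m = 0.9$;
  `neutral_dispersal_limited` perturbs the metacommunity per group (one
  Dirichlet draw, concentration 5) and uses $m = 0.01$ so that
  within-group divergence is dominated by drift. The metacommunity
  abundance profile is lognormal with $\sigma_{\log} = 3$: gut-style
  unevenness with many rare taxa. An even profile ($\sigma_{\log} = 1$)
  makes every taxon occur in every sample, occupancy carries no
  information, and RC saturates spuriously.

What the generator does **not** emulate: sequencing error and chimeras,
taxonomy structure beyond placeholder lineages, compositional artefacts of
primer bias, longitudinal correlation, or host covariates. A green
recovery suite therefore shows the inference machinery is correct and
calibrated on communities whose assembly history is known — not that any
particular real dataset satisfies the framework's assumptions.

## Numerical and procedural choices

- Rarefaction is multivariate hypergeometric (sampling reads without
  replacement), seeded; every output row sums to the depth exactly.
- Permutation p-values never return zero: Monte Carlo tests use the
  $(b+1)/(m+1)$ estimator, and small designs switch automatically to
  exhaustive enumeration of all distinct label assignments (≤ 10,000
  assignments), where p is exact.
- Prevalence filtering is strictly "more than" the threshold fraction
  (matching the usual "detected in more than 50% of samples" rule); a flag
  switches to ≥.
- Network correlations are Pearson on log10 relative abundances with a
  pseudocount of 0.01 × the smallest nonzero relative abundance; the edge
  rule is inclusive (|r| ≥ cutoff, default 0.89). Module detection is
  deterministic greedy modularity maximization; if the greedy split has
  lower modularity than the one-module-per-component partition (complete
  graphs), the latter is reported. Nodes of degree < 2 contribute 0 to the
  average clustering coefficient (a flag excludes them instead).
- Degenerate nulls (zero standard deviation, e.g. star phylogenies or
  near-identical sample pairs) yield NTI/βNTI of 0 with a warning rather
  than NaN; single-taxon samples yield NA MNTD with a warning.
- The RC metacommunity defaults to all samples in the table; a
  `metacommunity` argument supports within-group pools, and the choice
  materially affects within-group process fractions (with an all-sample
  pool, strong group structure reads as homogenizing dispersal within
  groups, because null pairs are drawn from the pooled frequencies).
- All stages take explicit seeds; `run_pipeline()` derives stage seeds
  from one master seed by fixed offsets and records everything in a JSON
  manifest from which a byte-identical rerun is possible.

## Validation strategy and problem sizes

The test suite validates each statistic against an independent route:
hand-derived closed forms (worked trees, K4 panels, BH step-up), brute-force
enumeration oracles (PERMANOVA/ANOSIM/IndVal p-values on 6- and 8-sample
designs), the established implementations in `vegan` and `picante`
(distances, betadisper, comdistnt — cross-checks only, never the
implementation), and regime-recovery runs on the generator. Stochastic
checks run at 3 × 8 samples × 200 taxa with 199–200 randomizations and
fixed seeds; the acceptance script uses 999–1000 randomizations at the same
design. These sizes make the default suite run in well under a minute while
leaving the null-model z-scores and fractions within sampling noise of
their large-randomization values.

## Limitations

- The homogeneous-selection signature (βNTI < −2) is intrinsically the
  framework's weakest: it requires the observed nearest-taxon distances to
  undercut a null that already picks the minimum over all present taxa. On
  tree realisations whose trait structure is convergent near the optimum,
  within-group βNTI settles around −1 to −2 and pairs classify as drift —
  a real property of the statistic, visible in our generator at some seeds
  and documented in the field. The same applies in reverse to variable
  selection on shallow trees.
- RC_bray's null allocates reads multinomially; any real overdispersion
  (including the Dirichlet sampling of our own neutral scenarios) biases RC
  positive for otherwise-exchangeable pairs. Interpret small |RC| bands
  cautiously, and the beta-deviation test against data from a *different*
  generative process accordingly.
- Single-factor designs only: host covariates are carried in metadata but
  not modelled.
- Networks at |r| ≥ 0.89 on 8 samples per group are sparse by construction;
  topology panels on such networks describe the few strongest associations,
  not the full interaction structure.
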