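---
title: "Inferring community assembly processes with ecoassembly"
author: "ecoassembly maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes with ecoassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

## The question the package answers

Given an OTU table, a rooted phylogeny over the OTUs, and sample
metadata, `ecoassembly` estimates how much of the observed community
turnover is attributable to deterministic processes (environmental
selection) versus stochastic ones (dispersal, drift). It implements the
two-stage null-model framework that has become standard in microbial
ecology — phylogenetic turnover (βMNTD/βNTI) first, Raup–Crick on
Bray–Curtis (RC~bray~) for the phylogenetically stochastic remainder —
together with the Sloan neutral community model, abundance-class
partitioning (dominant / conditionally rare / always-rare taxa),
distance–decay and permutation beta-diversity statistics, and a
maximal-information-coefficient (MIC) cooccurrence network with
keystoneness scoring.

Because the statistics are null-model based, their behaviour can only be
validated against data with known generating processes. The package
therefore ships a synthetic community generator
(`simulate_dataset()` and friends) that emulates a multi-location,
multi-depth sediment survey and exposes the assembly regime — neutral,
selection, dispersal-limited, or a mixture — as an explicit, testable
knob.

## The models

### Sloan neutral community model

For a taxon with mean relative abundance $p$ in the source pool, the
stationary distribution of its local relative abundance under neutral
immigration–drift dynamics is $\mathrm{Beta}(N m p,\; N m (1-p))$, with
$N$ the local community (read) size and $m$ the immigration
probability. The model predicts the taxon's *detection frequency*
across samples as

$$F(p) = 1 - B(d;\; N m p,\; N m (1-p)),$$

where $B$ is the regularized incomplete beta function and $d$ the
detection limit. `fit_ncm()` estimates $Nm$ by bounded least squares of
observed occurrence frequencies on $F(p)$ over
$\log_{10} Nm \in [-1, 7]$ (coarse grid then Brent refinement; the
objective is unimodal in practice), reports a generalized $R^2$, and
partitions OTUs against 95% Wilson score bands.

**Detection limit.** Detection in read-sampled data means drawing at
least one of $N$ reads, an event of probability
$1-(1-\lambda)^N$ given true local abundance $\lambda$. The
step-function approximation that underlies $F(p)$ should therefore be
centred where this probability crosses one half, i.e. at
$d = \ln 2 / N$, which is the package default. The harder one-read
threshold $d = 1/N$ is available via the `d` argument; on data generated
by the beta–multinomial process itself it inflates $\hat{Nm}$ by
roughly a third, which is why it is not the default. With
$d = \ln 2/N$ the fitted $m$ recovers the generating value with a
median relative error of a few percent across
$m \in \{0.1, 0.3, 0.5\}$ (the acceptance suite verifies ≤ 20%).

### Phylogenetic turnover: βMNTD and βNTI

The abundance-weighted between-community mean nearest taxon distance is

$$\beta\mathrm{MNTD}_{kl} = \tfrac12\Big[\sum_{i \in k} f_{ik}
\min_{j \in l} d_{ij} + \sum_{j \in l} f_{jl} \min_{i \in k}
d_{ij}\Big],$$

with $f$ relative abundances, $d$ patristic distances, and minima over
taxa present in the other sample (a shared taxon contributes zero to
its own minimum). βNTI is the standardized effect size of the observed
βMNTD against a null that shuffles taxon labels across the tips of the
phylogeny — the regional-pool null; abundance structure is untouched —
with 999 replicates by default. Pairs whose null distribution has zero
spread (e.g. a star phylogeny) are reported as `NA` with a warning
rather than as ±∞.

|βNTI| > 2 is read as deterministic assembly: βNTI < −2 homogeneous
selection (less phylogenetic turnover than chance), βNTI > 2
heterogeneous selection.

### RC~bray~

For pairs with |βNTI| ≤ 2, RC~bray~ asks whether *taxonomic* turnover
deviates from a probabilistic null assembly: each null replicate
rebuilds every sample by drawing its observed richness from the
regional pool with probability proportional to occupancy, granting each
drawn taxon one read, and allocating the remaining reads multinomially
in proportion to regional relative abundance. (The one-read guarantee
keeps the realized null richness equal to the drawn richness; it is
the convention of the abundance-based Raup–Crick literature.)
$RC = 2\,[(\#\{null < obs\} + \tfrac12\#ties)/n_{null} - \tfrac12]$,
with half-weighted ties so RC is centred at zero under exchangeability.
RC > 0.95 indicates dispersal limitation, RC < −0.95 homogenizing
dispersal, |RC| ≤ 0.95 the "undominated" remainder (weak selection,
weak dispersal, drift, diversification).

A subtlety worth knowing: rc_bray estimates occupancy and pool
abundances *from the data it is given*. One round of the null assembly
applied to arbitrary data is not a fixed point of that estimation (the
one-read guarantee flattens the re-estimated pool), so exact
self-calibration holds at the iterated fixed point of the procedure,
which is how the calibration test constructs its data.

### Process classification

`classify_processes()` applies the thresholds in the order selection →
dispersal → undominated and summarizes the fraction of sample pairs per
process. Pairs with undefined βNTI are excluded from fractions and
counted separately — signs are never fabricated.

### MIC cooccurrence network

Pairwise association uses the classic maximal information coefficient:
the maximum over grid shapes $(n_x, n_y)$ with $n_x n_y \le n^{0.6}$ of
normalized mutual information $I/\log_2\min(n_x,n_y)$, with the finer
axis equipartitioned (ties kept together) and the other axis optimized
by a dynamic program over clump boundaries capped at $c \cdot n_x$
superclumps ($c = 15$). The DP maximizes the per-column additive
decomposition of $H(P) - H(P,Q)$, which differs from mutual information
only by the constant $H(Q)$ — so it is exactly the published
column-optimization, written additively. Both axis orientations are
searched; the statistic depends only on ranks, hence is invariant to
monotone transformations. The kernel is C++ (via Rcpp), as is usual for
MIC implementations.

Raw p-values come from a *shared* permutation null (MIC of randomly
chosen OTU pairs with one member's sample order permuted), adjusted by
Benjamini–Hochberg; edges require `mic >= 0.5` and adjusted
`p < q_cutoff`, and carry the sign of the pair's Spearman ρ, since MIC
itself is unsigned. Note the floor of the permutation p-value is
$1/(n_{perm}+1)$: with the default 1,000 permutations the smallest
achievable adjusted p is of order $10^{-3} \cdot n_{pairs}/k$, so a
strict `q_cutoff = 0.001` (the default, matching large-scale practice)
requires large permutation counts; desk-scale analyses should either
raise `mic_n_perm` or relax `q_cutoff`.

Topology (degree, Brandes betweenness, classic closeness per connected
component, diameter and mean path length on the largest component) and
Louvain modules (resolution 1, module ids ranked by size, seed exposed)
come from igraph. Keystoneness is the mean of min–max-scaled degree,
$1 -$ scaled betweenness, and scaled closeness; constant centrality
vectors scale to 0 by convention.

## The synthetic generator: what it emulates, and what not

`default_study_design()` describes 7 locations along a ~19.7–28.3°N
coastal gradient, 6 sites each (7 at the first), three sediment depth
layers, and per-sample read depths uniform on 19,206–43,750 — the scale
and structure of a large amplicon survey of estuarine sediments. Mean
annual temperature declines with latitude; salinity and pH carry weaker
gradients plus noise. The regional pool is a lognormal rank-abundance
curve on a pure-birth (Yule) phylogeny rescaled to unit depth.

Assembly regimes modify Sloan sampling weights per sample:

* **neutral** — weights are the pool abundances; immigration `m`.
* **selection** — weights are multiplied by a Gaussian filter
  $\exp(-(o_i - e_s)^2 / 2\sigma_{sel}^2)$ of each taxon's optimum
  $o_i$ around the sample's environment $e_s$; an infinitely wide
  filter reproduces the neutral draw exactly (same RNG path).
* **dispersal_limited** — the immigration rate decays as
  $\exp(-d_{km}/\text{scale})$ with distance from the pool centroid.
* **mixed** — samples are allocated to component regimes in proportion
  to `mix_weights`; the metadata records each sample's true regime.

Trait optima come either from Brownian motion on the tree
(`evolve_traits()`, the default: realistic, smooth phylogenetic
signal) or from `conserved_optima()`, which cuts the tree at half its
depth, gives each resulting clade its own niche optimum, and places one
*focal clade* at a distinct optimum. The latter is the cleaner test bed
for homogeneous selection: under Brownian traits the taxa adapted to
any given environment are typically scattered across several clades
(trait overlap between deep clades is generic), so an environmental
filter produces only mild phylogenetic clustering and βNTI hovers
around −1 for most realizations. With clade-level conservatism and an
environment at the focal clade's optimum — a halophile clade in a
saline sediment, say — low immigration (`m = 0.05`) lets drift pick
different clade members in different samples, and βNTI drops clearly
below −2. The selection-detection checks use this construction; the
phylogenetic signal of the Brownian default is property-tested
separately.

What the generator does **not** emulate: sequence-level artefacts
(chimeras, primer bias), taxonomy, temporal dynamics, interaction-driven
(biotic) selection, and spatially autocorrelated environmental noise.
Passing tests therefore demonstrate that the statistics respond
correctly to the *processes they model*, not that any particular field
dataset is free of the confounders above.

## Numerical and design choices

* Shannon diversity in nats; evenness $J = H'/\ln S$, `NA` for
  single-OTU samples. Chao1 uses
  $S + F_1(F_1-1)/(2(F_2+1))$ — always finite, equal to $S$ when no
  singletons; the classic $S + F_1^2/(2F_2)$ is a flag away.
* Abundance classes: always-rare if < 0.01% in every sample; dominant
  if ≥ 0.01% in all samples *or* ≥ 1% in at least one; conditionally
  rare otherwise. Absence counts as below the rare cutoff; an OTU
  matching both the dominant and conditionally-rare phrasings goes to
  dominant. Classification is computed on the rarefied table.
* Rarefaction subsamples without replacement to an exact depth
  (vegan's `rrarefy`), drops shallower samples with a message (or
  errors, by flag), and removes emptied OTU rows.
* Community distances Hellinger-transform by default; the null models
  (RC~bray~) work on raw counts as their construction requires.
* Geographic distances use the haversine formula with Earth radius
  6371.0088 km.
* Permutation p-values use the add-one convention
  $(1 + \#exceedances)/(1 + n_{perm})$ and never report zero. PERMANOVA
  is one-factor (vegan's `adonis2` behind the interface); ANOSIM and
  Mantel similarly wrap vegan with explicit seeding. Spearman p-values
  are exact for $n \le 20$, t-approximate above.
* All stochastic functions take an explicit `seed` and restore the
  caller's RNG state; identical seeds give byte-identical outputs.

## The pipeline

`run_pipeline(pipeline_config(...))` executes rarefy → classify →
α/β-diversity → NCM → βNTI/RC → process classification (overall, per
location via `group_by`, and per abundance class via `by_class`) →
distance decay → MIC network, writing TSV/JSON stage outputs plus a
manifest with per-stage seeds and file digests. Re-running an identical
config reproduces identical outputs. Per-class reruns subset the
rarefied table by classification label and recompute distances and
nulls on a tree pruned to the subset.

Problem sizes in the shipped checks — 100–500 taxa, 10–126 samples,
999 null replicates — were chosen as the smallest sizes at which the
null-model statistics are stable; the generator's read-depth range and
the 0.01%/1% class cutoffs are the field's standard values.

A thin command-line wrapper (`inst/scripts/ecoassembly.R`) exposes
`simulate` and `run` subcommands over these functions for shell use;
everything else is meant to be driven from R.

## Known limitations

* βNTI inherits the usual caveat that its null randomizes taxon labels
  only; alternative nulls (e.g. frequency-preserving) are out of scope.
* The MIC permutation null is shared across pairs; per-pair nulls would
  be more exact and far more expensive.
* PERMANOVA is single-factor; nested or interaction designs are not
  supported.
* The NCM fit assumes a common read depth; unrarefied tables need an
  explicit `N`.
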