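# ecoassembly

Community assembly inference for microbial OTU tables.

Microbial ecologists routinely ask whether the composition of a set of
communities — say, archaeal OTUs in sediment cores collected along a
coastline — is governed by *deterministic* processes (environmental
selection) or *stochastic* ones (dispersal and ecological drift).
`ecoassembly` implements the standard two-stage null-model framework
for answering that question from an OTU count table, a rooted
phylogeny, and sample metadata, plus the surrounding analyses such a
study needs:

* **Abundance classes** — partition OTUs into dominant (≥ 0.01% in all
  samples or ≥ 1% in some), conditionally rare, and always-rare
  (< 0.01% everywhere) taxa.
* **Sloan neutral community model** — fit occurrence frequency against
  mean relative abundance, `F(p) = 1 − B(d; Nm·p, Nm·(1−p))`, to
  estimate the immigration rate `m` with fit `R²` and 95% prediction
  bands.
* **βMNTD / βNTI** — abundance-weighted beta mean nearest taxon
  distance with a tip-shuffling null; βNTI < −2 homogeneous selection,
  βNTI > 2 heterogeneous selection.
* **RC_bray** — Raup–Crick on Bray–Curtis against probabilistic null
  assembly; for |βNTI| ≤ 2, RC > 0.95 dispersal limitation, RC < −0.95
  homogenizing dispersal, |RC| ≤ 0.95 "undominated".
* **Beta statistics** — Hellinger/Bray–Curtis distances, PCoA,
  PERMANOVA, ANOSIM, Mantel tests, haversine geography, distance–decay
  regression, Spearman environment correlations.
* **MIC cooccurrence network** — prevalence filter, classic maximal
  information coefficient (Rcpp kernel) with permutation FDR,
  Spearman-signed edges, igraph topology, Louvain modules, and
  keystoneness = mean of min–max-scaled degree, 1 − betweenness, and
  closeness.
* **Synthetic community generator** — a latitudinal multi-site,
  multi-depth survey design with tunable neutral / selection /
  dispersal-limited assembly regimes, so every statistic can be tested
  against data whose generating process is known.
* **Pipeline** — `run_pipeline()` chains rarefaction → classification →
  α/β diversity → NCM → βNTI/RC → process fractions → distance decay →
  network with per-stage seeds and a digest manifest.

## Worked example

Simulate neutral communities at a known immigration rate and recover it:

```r
library(ecoassembly)

p  <- simulate_metacommunity(300, "lognormal", sdlog = 1.5, seed = 11)
cm <- sloan_sample(p, m = 0.3, N = 19206, n_samples = 40, seed = 12)
fit_ncm(cm)
#> Sloan neutral community model fit
#>   Nm = 5413.7  (m = 0.2819 at N = 19206)
#>   R2 = 0.953 over 300 OTUs, 40 samples
#>   partition: above = 193, below = 1, within = 106

alpha_diversity(cm[, 1:3])
#>   sample_id richness shannon chao1 evenness
#> 1      S001      285   4.635 288.8   0.8200
#> 2      S002      286   4.610 291.5   0.8151
#> 3      S003      282   4.593 294.0   0.8140
```

The fitted `m = 0.28` recovers the generating value 0.3 within ~6%, and
the high `R²` says occurrence frequencies track the neutral
expectation — which is exactly what neutral data should do. On real
data a low `R²` or a large above-prediction partition is evidence that
processes beyond immigration and drift structure the community.

The full assembly analysis on a simulated 126-sample survey:

```r
des   <- study_design(default_study_design()$locations,
                      sites_per_location = 6)
tree  <- simulate_tree(300, seed = 1)
model <- metacommunity_model(tree, trait_sigma = 1, seed = 2)
reg   <- regime_spec("mixed", m = 0.1, selection_strength = 0.5,
                     dispersal_scale = 500,
                     mix_weights = c(neutral = 0.4, selection = 0.4,
                                     dispersal_limited = 0.2))
cfg <- pipeline_config(out_dir = "out",
                       simulation = list(design = des, model = model,
                                         regime = reg),
                       rarefaction_depth = 3000, seed = 7)
run_pipeline(cfg)
```

writes `taxon_classes.tsv`, `alpha_diversity.tsv`, `ncm_fit.json`,
`turnover_all.tsv` (per-pair βMNTD, βNTI, RC, process),
`process_summary_*.tsv` (process fractions overall and per abundance
class), `distance_decay.json`, the MIC edge/node tables, and a
`manifest.json` of seeds and file digests. A thin CLI over `simulate`
and `run` lives in `inst/scripts/ecoassembly.R`.

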