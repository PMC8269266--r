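# Synthetic community generator -----------------------------------------
#
# Emulates a latitudinal multi-site sediment survey: a regional species pool
# with a phylogeny and phylogenetically conserved environmental optima, local
# communities assembled under neutral, selection, or dispersal-limited
# regimes, and per-sample read depths in a fixed range.

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Generates a rooted tree with positive branch lengths under a pure-birth
#' process (speciation rate 1) and rescales it to a fixed root-to-tip depth.
#' Tips are labelled `OTU0001 ...` so they can serve directly as OTU ids.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed optional RNG seed for reproducibility.
#' @param depth root-to-tip depth the tree is rescaled to (default 1).
#' @return an [ape::phylo] tree with `n_taxa` tips.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, depth = 1) {
  if (length(n_taxa) != 1 || n_taxa < 2)
    stop("`n_taxa` must be a single integer >= 2", call. = FALSE)
  .with_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tree$tip.label <- sprintf("OTU%04d", seq_len(n_taxa))
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / h * depth
    tree
  })
}

#' Evolve environmental optima along a tree by Brownian motion
#'
#' Traits start at 0 at the root and diffuse with rate `sigma` per unit
#' branch length, so the optimum of a tip has variance `sigma^2` times its
#' root-to-tip path length and closely related taxa receive similar optima
#' (the phylogenetic signal that makes selection detectable by betaNTI).
#'
#' @param tree a rooted [ape::phylo] tree with branch lengths.
#' @param sigma Brownian-motion rate (trait units per unit branch length,
#'   > 0).
#' @param seed optional RNG seed.
#' @return named numeric vector of optima, one per tip.
#' @export
evolve_traits <- function(tree, sigma = 1, seed = NULL) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object",
                                     call. = FALSE)
  if (length(sigma) != 1 || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  .with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma,
                                   root.value = 0))
}

#' Clade-level conserved environmental optima
#'
#' Constructs a niche-structured trait map with strong phylogenetic
#' conservatism: the tree is cut at a fraction of its depth, every tip
#' descending from the same lineage at the cut shares that clade's
#' niche optimum (drawn from `N(0, between_sd)` plus within-clade jitter
#' `within_sd`), and one *focal clade* — the largest clade whose size
#' falls in `focal_range` — is placed at a distinct optimum
#' `focal_optimum` away from the rest of the pool. An environment at
#' `focal_optimum` then selects an entire coherent clade, the canonical
#' homogeneous-selection scenario (think of a halophile clade in a
#' saline sediment). Brownian optima from [evolve_traits()] are the
#' smooth alternative; this constructor pins conservatism by design.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param cut_depth fraction of tree depth at which clades are defined
#'   (default 0.5).
#' @param between_sd sd of the non-focal clade optima.
#' @param within_sd within-clade jitter sd.
#' @param focal_optimum niche optimum assigned to the focal clade.
#' @param focal_range acceptable focal clade size range; if no clade
#'   qualifies the largest clade is used.
#' @param seed optional RNG seed.
#' @return named numeric vector of optima with attribute `focal_clade`
#'   (indices of the focal clade's tips).
#' @export
conserved_optima <- function(tree, cut_depth = 0.5, between_sd = 1,
                             within_sd = 0.05, focal_optimum = 3,
                             focal_range = c(40, 120), seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  .with_seed(seed, {
    nd <- ape::node.depth.edgelength(tree)
    H <- max(nd)
    n <- length(tree$tip.label)
    paths <- ape::nodepath(tree)
    grp <- vapply(seq_len(n), function(i) {
      path <- paths[[i]]
      path[max(which(nd[path] <= cut_depth * H))]
    }, integer(1))
    cl <- match(grp, unique(grp))
    mu <- rnorm(max(cl), 0, between_sd)
    tab <- table(cl)
    elig <- as.integer(names(tab)[tab >= focal_range[1] &
                                  tab <= focal_range[2]])
    focal <- if (length(elig))
      elig[which.max(tab[as.character(elig)])]
    else as.integer(names(tab)[which.max(tab)])
    mu[focal] <- focal_optimum
    opt <- mu[cl] + rnorm(n, 0, within_sd)
    names(opt) <- tree$tip.label
    attr(opt, "focal_clade") <- which(cl == focal)
    opt
  })
}

#' Simulate a regional species-abundance distribution
#'
#' Draws relative abundances for a regional pool from a lognormal or
#' Fisher log-series distribution, normalized to sum to 1 and sorted into
#' a rank-abundance curve (ties broken by taxon index).
#'
#' @param n_taxa number of taxa (>= 1).
#' @param distribution `"lognormal"` or `"logseries"`.
#' @param meanlog,sdlog lognormal parameters (`sdlog` > 0).
#' @param alpha Fisher's alpha for the log-series (> 0); the implied pool
#'   size is `pool_size` individuals.
#' @param pool_size assumed regional pool size for the log-series draw.
#' @param seed optional RNG seed.
#' @return numeric vector of relative abundances summing to 1,
#'   non-increasing.
#' @export
simulate_metacommunity <- function(n_taxa,
                                   distribution = c("lognormal", "logseries"),
                                   meanlog = 0, sdlog = 1,
                                   alpha = 20, pool_size = 1e5,
                                   seed = NULL) {
  distribution <- match.arg(distribution)
  if (length(n_taxa) != 1 || n_taxa < 1)
    stop("`n_taxa` must be a single integer >= 1", call. = FALSE)
  .with_seed(seed, {
    x <- switch(distribution,
      lognormal = {
        if (sdlog <= 0) stop("`sdlog` must be > 0", call. = FALSE)
        rlnorm(n_taxa, meanlog = meanlog, sdlog = sdlog)
      },
      logseries = {
        if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
        .rlogseries(n_taxa, alpha = alpha, pool_size = pool_size)
      })
    p <- x / sum(x)
    # stable sort: ties resolved by original taxon index
    p[order(p, seq_along(p), decreasing = c(TRUE, FALSE), method = "radix")]
  })
}

# Fisher log-series abundances: x = N / (N + alpha), pmf p_k ~ x^k / k
.rlogseries <- function(n, alpha, pool_size) {
  x <- pool_size / (pool_size + alpha)
  kmax <- 1e5
  k <- seq_len(kmax)
  pmf <- x^k / k
  cdf <- cumsum(pmf) / sum(pmf)
  k[findInterval(runif(n), cdf) + 1L]
}

#' Sample local communities under Sloan's neutral model
#'
#' For each sample and taxon, a local relative abundance is drawn from the
#' stationary Beta distribution of the Sloan neutral community model,
#' `Beta(N m p_i, N m (1 - p_i))`, and the sample's counts are a
#' multinomial draw of `N` reads on the normalized local abundances.
#' Larger `m` couples local communities more tightly to the source pool.
#'
#' @param p source-pool relative abundances (positive, summing to 1).
#' @param m immigration probability in (0, 1].
#' @param N reads per sample (>= 1); scalar or one value per sample.
#' @param n_samples number of local communities to draw.
#' @param seed optional RNG seed.
#' @return integer count matrix (taxa x samples); every column sums to its
#'   `N`.
#' @export
sloan_sample <- function(p, m, N, n_samples, seed = NULL) {
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-6)
    stop("`p` must be a strictly positive probability vector", call. = FALSE)
  if (length(m) != 1 || m <= 0 || m > 1)
    stop("`m` must be in (0, 1]", call. = FALSE)
  if (any(N < 1)) stop("`N` must be >= 1", call. = FALSE)
  N <- as.integer(round(rep_len(N, n_samples)))
  .with_seed(seed, {
    k <- length(p)
    out <- matrix(0L, nrow = k, ncol = n_samples)
    for (s in seq_len(n_samples)) {
      lam <- rbeta(k, N[s] * m * p, N[s] * m * (1 - p))
      lam[!is.finite(lam)] <- 0
      if (sum(lam) <= 0) lam <- p
      out[, s] <- rmultinom(1, N[s], lam / sum(lam))[, 1]
    }
    rownames(out) <- if (!is.null(names(p))) names(p) else
      sprintf("OTU%04d", seq_len(k))
    colnames(out) <- sprintf("S%03d", seq_len(n_samples))
    out
  })
}

#' Describe a latitudinal multi-site, multi-depth sampling design
#'
#' @param locations data.frame with columns `name`, `latitude`, `longitude`
#'   (decimal degrees), one row per location.
#' @param sites_per_location integer vector (recycled) of sites per
#'   location.
#' @param depth_layers ordered character labels for the sediment layers.
#' @param depth_range `c(min, max)` reads per sample (min >= 1).
#' @param env_gradient named list of covariates; each entry is a list with
#'   `intercept`, `lat_slope` (per degree latitude), `depth_step` (additive
#'   shift per successive depth layer) and `noise_sd`.
#' @return object of class `study_design`.
#' @export
study_design <- function(locations,
                         sites_per_location = 6,
                         depth_layers = c("0-10", "10-20", "20-30"),
                         depth_range = c(19206, 43750),
                         env_gradient = NULL) {
  stopifnot(is.data.frame(locations),
            all(c("name", "latitude", "longitude") %in% names(locations)))
  if (depth_range[1] < 1 || depth_range[2] < depth_range[1])
    stop("invalid `depth_range`", call. = FALSE)
  sites <- rep_len(sites_per_location, nrow(locations))
  structure(list(locations = locations, sites_per_location = sites,
                 depth_layers = depth_layers,
                 depth_range = as.integer(round(depth_range)),
                 env_gradient = env_gradient),
            class = "study_design")
}

#' Default study design: 7 locations on a latitudinal coastal gradient
#'
#' Seven locations spanning roughly 19.7-28.3 degrees N along a
#' southeast-coast gradient, 6 sites each (7 at the first), three sediment
#' depth layers, and per-sample read depths uniform on 19,206-43,750.
#' Mean annual temperature declines with latitude; salinity and pH carry
#' weaker gradients plus noise, mirroring the covariate structure such
#' surveys report.
#'
#' @return a [study_design] object (129 samples).
#' @export
default_study_design <- function() {
  loc <- data.frame(
    name = sprintf("L%d", 1:7),
    latitude  = c(19.7, 21.0, 21.6, 22.5, 24.4, 27.0, 28.3),
    longitude = c(109.7, 108.5, 111.8, 114.0, 118.1, 120.1, 121.1))
  study_design(
    locations = loc,
    sites_per_location = c(7, 6, 6, 6, 6, 6, 6),
    env_gradient = list(
      MAT      = list(intercept = 35.5, lat_slope = -0.55,
                      depth_step = 0, noise_sd = 0.3),
      salinity = list(intercept = 25, lat_slope = -0.3,
                      depth_step = 0.5, noise_sd = 1.5),
      pH       = list(intercept = 7.2, lat_slope = 0.02,
                      depth_step = -0.05, noise_sd = 0.15)))
}

#' Specify an assembly regime for the generator
#'
#' @param kind `"neutral"`, `"selection"`, `"dispersal_limited"`, or
#'   `"mixed"`.
#' @param m immigration probability in (0, 1].
#' @param selection_strength Gaussian filter width on the environmental
#'   axis (trait units); smaller is stronger selection.
#' @param dispersal_scale e-folding distance (km) for the decay of
#'   immigration with distance from the regional pool centroid.
#' @param mix_weights named non-negative weights over component regimes
#'   (names among neutral/selection/dispersal_limited), summing to 1.
#' @return object of class `regime_spec`.
#' @export
regime_spec <- function(kind = c("neutral", "selection",
                                 "dispersal_limited", "mixed"),
                        m = 0.3, selection_strength = NULL,
                        dispersal_scale = NULL, mix_weights = NULL) {
  kind <- match.arg(kind)
  if (m <= 0 || m > 1) stop("`m` must be in (0, 1]", call. = FALSE)
  if (kind == "selection" && (is.null(selection_strength) ||
                              selection_strength <= 0))
    stop("selection regime requires `selection_strength` > 0", call. = FALSE)
  if (kind == "dispersal_limited" && (is.null(dispersal_scale) ||
                                      dispersal_scale <= 0))
    stop("dispersal_limited regime requires `dispersal_scale` > 0",
         call. = FALSE)
  if (kind == "mixed") {
    if (is.null(mix_weights) || is.null(names(mix_weights)) ||
        any(mix_weights < 0) || abs(sum(mix_weights) - 1) > 1e-9)
      stop("mixed regime requires named non-negative `mix_weights` summing to 1",
           call. = FALSE)
    if (!all(names(mix_weights) %in%
             c("neutral", "selection", "dispersal_limited")))
      stop("unknown component regime in `mix_weights`", call. = FALSE)
    if ("selection" %in% names(mix_weights) &&
        (is.null(selection_strength) || selection_strength <= 0))
      stop("mixed regime with a selection component requires `selection_strength`",
           call. = FALSE)
    if ("dispersal_limited" %in% names(mix_weights) &&
        (is.null(dispersal_scale) || dispersal_scale <= 0))
      stop("mixed regime with a dispersal component requires `dispersal_scale`",
           call. = FALSE)
  }
  structure(list(kind = kind, m = m,
                 selection_strength = selection_strength,
                 dispersal_scale = dispersal_scale,
                 mix_weights = mix_weights),
            class = "regime_spec")
}

#' Bundle a regional pool, its phylogeny and trait optima
#'
#' @param tree [ape::phylo] tree over the pool taxa.
#' @param source_abundances relative abundances (one per tip, summing
#'   to 1); default simulated lognormal.
#' @param trait_optima named optima per tip; default Brownian motion with
#'   rate `trait_sigma`.
#' @param trait_sigma Brownian rate used when optima are simulated.
#' @param seed optional RNG seed for the simulated parts.
#' @return object of class `metacommunity_model`.
#' @export
metacommunity_model <- function(tree, source_abundances = NULL,
                                trait_optima = NULL, trait_sigma = 1,
                                seed = NULL) {
  n <- length(tree$tip.label)
  if (is.null(source_abundances))
    source_abundances <- simulate_metacommunity(n, "lognormal", sdlog = 1.5,
                                                seed = seed)
  if (any(source_abundances <= 0) || abs(sum(source_abundances) - 1) > 1e-9)
    stop("source abundances must be positive and sum to 1", call. = FALSE)
  if (length(source_abundances) != n)
    stop("one abundance per tip required", call. = FALSE)
  if (is.null(names(source_abundances)))
    names(source_abundances) <- tree$tip.label
  if (is.null(trait_optima))
    trait_optima <- evolve_traits(tree, sigma = trait_sigma,
                                  seed = if (is.null(seed)) NULL else seed + 1)
  if (!setequal(names(trait_optima), tree$tip.label))
    stop("`trait_optima` must have exactly one entry per tree tip",
         call. = FALSE)
  structure(list(n_taxa = n, source_abundances = source_abundances,
                 tree = tree, trait_optima = trait_optima[tree$tip.label],
                 trait_sigma = trait_sigma),
            class = "metacommunity_model")
}

#' Simulate a full survey dataset under an assembly regime
#'
#' Builds one sample per (location, site, depth layer) cell of the design.
#' Each sample's read depth is uniform on the design's depth range. The
#' sampling weights start from the source pool and are modified by the
#' regime: selection multiplies by a Gaussian filter
#' `exp(-(optimum - env)^2 / (2 sigma_sel^2))` of the sample's local
#' environment; dispersal limitation scales the immigration rate by
#' `exp(-d_km / dispersal_scale)` with `d_km` the great-circle distance to
#' the abundance-weighted pool centroid; the neutral component uses
#' [sloan_sample()] semantics with the regime's `m`. Under a mixed regime
#' samples are allocated to component regimes in proportion to
#' `mix_weights`. The metadata records each sample's true regime.
#'
#' @param design a [study_design].
#' @param model a [metacommunity_model].
#' @param regime a [regime_spec].
#' @param seed optional RNG seed.
#' @param env_covariate name of the covariate used as the selection axis;
#'   defaults to a latent `env` axis stored in the metadata (standardized
#'   latitude plus a per-layer offset plus noise `env_noise_sd`).
#' @param env_noise_sd sd of the noise on the latent selection axis.
#' @param env_lat_slope slope of the latent axis on latitude (trait units
#'   per degree); 0 makes the environment identical across locations.
#' @param env_intercept baseline of the latent axis (trait units). The
#'   Brownian trait distribution is centred on the root value 0, so a
#'   nonzero baseline pushes the Gaussian filter into a tail of the
#'   trait distribution, concentrating survivors in the clades that
#'   drifted there (the phylogenetic clustering homogeneous selection
#'   produces).
#' @param env_depth_step additive latent-axis shift per successive depth
#'   layer.
#' @return list with `counts` (integer matrix, taxa x samples), `metadata`
#'   (data.frame: sample_id, location, site, depth_layer, latitude,
#'   longitude, env, regime, covariates), `tree`, and `params`.
#' @export
simulate_dataset <- function(design, model, regime, seed = NULL,
                             env_lat_slope = 0.5, env_depth_step = 0.25,
                             env_noise_sd = 0.1, env_intercept = 0) {
  stopifnot(inherits(design, "study_design"),
            inherits(model, "metacommunity_model"),
            inherits(regime, "regime_spec"))
  .with_seed(seed, {
    meta <- .build_metadata(design, env_lat_slope, env_depth_step,
                            env_noise_sd, env_intercept)
    n_s <- nrow(meta)
    depths <- sample(seq(design$depth_range[1], design$depth_range[2]),
                     n_s, replace = TRUE)
    # per-sample regime assignment
    meta$regime <- if (regime$kind == "mixed")
      .allocate_mixed(regime$mix_weights, n_s) else regime$kind
    # pool centroid for dispersal limitation (abundance plays no spatial
    # role: the centroid is the mean site position)
    cen_lat <- mean(meta$latitude); cen_lon <- mean(meta$longitude)
    d_cen <- .haversine_km(meta$latitude, meta$longitude, cen_lat, cen_lon)

    p <- model$source_abundances
    opt <- model$trait_optima
    counts <- matrix(0L, nrow = model$n_taxa, ncol = n_s,
                     dimnames = list(model$tree$tip.label, meta$sample_id))
    for (s in seq_len(n_s)) {
      w <- p
      m_s <- regime$m
      kind <- meta$regime[s]
      if (kind == "selection") {
        w <- p * exp(-(opt - meta$env[s])^2 /
                       (2 * regime$selection_strength^2))
        if (sum(w) <= 0) w <- p
        w <- w / sum(w)
      } else if (kind == "dispersal_limited") {
        m_s <- max(regime$m * exp(-d_cen[s] / regime$dispersal_scale), 1e-4)
      }
      N <- depths[s]
      lam <- rbeta(length(w), N * m_s * w, N * m_s * (1 - w))
      lam[!is.finite(lam)] <- 0
      if (sum(lam) <= 0) lam <- w
      counts[, s] <- rmultinom(1, N, lam / sum(lam))[, 1]
    }
    list(counts = counts, metadata = meta, tree = model$tree,
         params = list(regime = regime, trait_sigma = model$trait_sigma,
                       env_lat_slope = env_lat_slope,
                       env_intercept = env_intercept,
                       env_depth_step = env_depth_step,
                       env_noise_sd = env_noise_sd, seed = seed))
  })
}

.build_metadata <- function(design, env_lat_slope, env_depth_step,
                            env_noise_sd, env_intercept) {
  rows <- list()
  for (i in seq_len(nrow(design$locations))) {
    loc <- design$locations[i, ]
    for (site in seq_len(design$sites_per_location[i])) {
      # sites jittered ~1 km around the location
      s_lat <- loc$latitude + (site - 1) * 0.01
      s_lon <- loc$longitude + (site - 1) * 0.01
      for (d in seq_along(design$depth_layers)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_s%d_d%d", loc$name, site, d),
          location = loc$name, site = sprintf("%s_s%d", loc$name, site),
          depth_layer = design$depth_layers[d],
          latitude = s_lat, longitude = s_lon, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, rows)
  layer_idx <- match(meta$depth_layer, design$depth_layers)
  meta$env <- env_intercept +
    env_lat_slope * (meta$latitude - mean(meta$latitude)) +
    env_depth_step * (layer_idx - 1) +
    rnorm(nrow(meta), sd = env_noise_sd)
  for (cov in names(design$env_gradient)) {
    g <- design$env_gradient[[cov]]
    meta[[cov]] <- g$intercept + g$lat_slope * meta$latitude +
      g$depth_step * (layer_idx - 1) + rnorm(nrow(meta), sd = g$noise_sd)
  }
  rownames(meta) <- NULL
  meta
}

.allocate_mixed <- function(w, n) {
  k <- names(w)
  n_each <- floor(w * n)
  rem <- n - sum(n_each)
  if (rem > 0) {
    extra <- order(w * n - n_each, decreasing = TRUE)[seq_len(rem)]
    n_each[extra] <- n_each[extra] + 1
  }
  sample(rep(k, times = n_each))
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `<prefix>_counts.tsv` (OTU x sample integers),
#' `<prefix>_tree.nwk`, `<prefix>_metadata.tsv`, and a
#' `<prefix>_params.json` sidecar with the true simulation parameters.
#'
#' @param sim result of [simulate_dataset()].
#' @param prefix output path prefix.
#' @return invisibly, the vector of paths written.
#' @export
write_dataset <- function(sim, prefix) {
  paths <- c(counts = paste0(prefix, "_counts.tsv"),
             tree = paste0(prefix, "_tree.nwk"),
             metadata = paste0(prefix, "_metadata.tsv"),
             params = paste0(prefix, "_params.json"))
  write_count_table(sim$counts, paths["counts"])
  ape::write.tree(sim$tree, paths["tree"])
  write.table(sim$metadata, paths["metadata"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  par <- sim$params
  par$regime <- unclass(par$regime)
  jsonlite::write_json(par, paths["params"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
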