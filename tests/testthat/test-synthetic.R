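# Synthetic community generator

test_that("simulate_tree produces valid, deterministic pure-birth trees", {
  expect_error(simulate_tree(1), "n_taxa")

  tr <- simulate_tree(2, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 2)
  expect_true(all(tr$edge.length > 0))

  t1 <- ape::write.tree(simulate_tree(100, seed = 7))
  t2 <- ape::write.tree(simulate_tree(100, seed = 7))
  expect_identical(t1, t2)
})

test_that("patristic distances are a metric (brute-force triple check)", {
  tr <- simulate_tree(50, seed = 3)
  d <- phylo_distance_matrix(tr)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (j in seq_len(nrow(d)))  # d[i,k] <= d[i,j] + d[j,k] for all triples
    expect_true(all(outer(d[, j], d[j, ], "+") >= d - 1e-12))
})

test_that("evolve_traits is Brownian with the stated covariance", {
  tr <- simulate_tree(10, seed = 2)
  expect_error(evolve_traits(tr, sigma = 0), "sigma")

  expect_identical(evolve_traits(tr, sigma = 1, seed = 5),
                   evolve_traits(tr, sigma = 1, seed = 5))
  # sigma -> 0 limit: all optima collapse to the root value
  expect_true(all(abs(evolve_traits(tr, sigma = 1e-9, seed = 1)) < 1e-6))

  # closed-form covariance: cov(A, B) = sigma^2 * shared path length
  tr3 <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  sigma <- 1.3
  reps <- vapply(seq_len(1000), function(i)
    evolve_traits(tr3, sigma = sigma, seed = 1000 + i)[c("A", "B")],
    numeric(2))
  cv <- stats::cov(reps[1, ], reps[2, ])
  expect_equal(cv, sigma^2 * 0.5, tolerance = 0.15)
})

test_that("trait optima carry positive phylogenetic signal", {
  tr <- simulate_tree(200, seed = 31)
  opt <- evolve_traits(tr, sigma = 1, seed = 32)
  d <- phylo_distance_matrix(tr)
  diag(d) <- Inf
  nn_dist <- function(o) {
    mean(vapply(seq_along(o),
                function(i) abs(o[i] - o[which.min(d[i, ])]), numeric(1)))
  }
  obs <- nn_dist(opt)
  set.seed(33)
  null <- replicate(199, nn_dist(sample(opt)))
  p <- (1 + sum(null <= obs)) / 200
  expect_lt(p, 0.05)
})

test_that("simulate_metacommunity yields valid abundance vectors", {
  expect_equal(simulate_metacommunity(1, seed = 1), 1.0)
  p <- simulate_metacommunity(500, "lognormal", seed = 2)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(diff(p) <= 0))
})

test_that("log-series pools have heavier singleton tails than lognormal", {
  tail_frac <- function(p) mean(p < 1 / length(p))
  wins <- vapply(1:20, function(s) {
    ls <- simulate_metacommunity(300, "logseries", alpha = 10, seed = s)
    ln <- simulate_metacommunity(300, "lognormal", sdlog = 1, seed = s)
    tail_frac(ls) > tail_frac(ln)
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("sloan_sample matches its contract", {
  p <- simulate_metacommunity(50, seed = 4)
  cm <- sloan_sample(p, m = 0.2, N = 500, n_samples = 12, seed = 5)
  expect_true(all(colSums(cm) == 500))
  expect_true(all(cm >= 0))

  # single-taxon pool: every read goes to it
  one <- sloan_sample(c(A = 1), m = 0.5, N = 100, n_samples = 3, seed = 1)
  expect_true(all(one == 100))

  # m = 1, large N: per-taxon mean relative abundance tracks the pool
  cm2 <- sloan_sample(p, m = 1, N = 20000, n_samples = 200, seed = 6)
  obs <- rowMeans(sweep(cm2, 2, colSums(cm2), "/"))
  se <- sqrt(p * (1 - p) / (20000 * 200)) + p / sqrt(200)
  expect_true(all(abs(obs - p) <= 3 * se + 1e-4))

  expect_error(sloan_sample(c(0.5, 0.1), m = 0.2, N = 10, n_samples = 2),
               "probability")
})

test_that("simulate_dataset respects the design and read-depth range", {
  des <- default_study_design()
  # default: 7 locations, 7+6x6 sites, 3 depths
  tree <- simulate_tree(80, seed = 8)
  model <- metacommunity_model(tree, seed = 9)
  sim <- simulate_dataset(des, model, regime_spec("neutral", m = 0.3),
                          seed = 10)
  expect_equal(ncol(sim$counts), (7 + 6 * 6) * 3)
  expect_true(all(colSums(sim$counts) >= 19206 &
                  colSums(sim$counts) <= 43750))
  expect_identical(colnames(sim$counts), sim$metadata$sample_id)
  expect_true(all(c("location", "site", "depth_layer", "latitude",
                    "longitude", "env", "regime", "MAT", "salinity") %in%
                  names(sim$metadata)))

  # 7 locations x 6 sites x 3 depths = 126 samples
  des126 <- study_design(des$locations, sites_per_location = 6)
  sim126 <- simulate_dataset(des126, model,
                             regime_spec("neutral", m = 0.3), seed = 10)
  expect_equal(ncol(sim126$counts), 126)

  # determinism
  sim2 <- simulate_dataset(des126, model,
                           regime_spec("neutral", m = 0.3), seed = 10)
  expect_identical(sim126$counts, sim2$counts)
  expect_identical(sim126$metadata, sim2$metadata)
})

test_that("infinitely weak selection is indistinguishable from neutral", {
  loc <- data.frame(name = "L1", latitude = 20, longitude = 110)
  des <- study_design(loc, sites_per_location = 6, depth_layers = "0-10",
                      depth_range = c(1000, 1000))
  tree <- simulate_tree(50, seed = 41)
  model <- metacommunity_model(tree, seed = 42)
  # exact pathwise limit: an infinitely wide filter reproduces the
  # neutral draw for the same seed
  sim_s <- simulate_dataset(des, model,
    regime_spec("selection", m = 0.3, selection_strength = 1e9),
    seed = 601)
  sim_n <- simulate_dataset(des, model, regime_spec("neutral", m = 0.3),
                            seed = 601)
  expect_identical(sim_s$counts, sim_n$counts)

  # statistical equivalence across independent seeds: one summary per
  # seed (within-run mean dissimilarity), rank test over seeds
  stat <- function(sim) mean(bray_curtis(sim$counts))
  sel <- neu <- numeric(10)
  for (s in 1:10) {
    sel[s] <- stat(simulate_dataset(des, model,
      regime_spec("selection", m = 0.3, selection_strength = 1e9),
      seed = 500 + s))
    neu[s] <- stat(simulate_dataset(des, model,
      regime_spec("neutral", m = 0.3), seed = 600 + s))
  }
  p <- stats::wilcox.test(sel, neu)$p.value
  expect_gt(p, 0.01)
})

test_that("identical-environment selection raises community similarity", {
  loc <- data.frame(name = "L1", latitude = 20, longitude = 110)
  des <- study_design(loc, sites_per_location = 6, depth_layers = "0-10",
                      depth_range = c(1000, 1000))
  tree <- simulate_tree(60, seed = 51)
  wins <- vapply(1:10, function(s) {
    model <- metacommunity_model(tree, seed = 52)
    sim_s <- simulate_dataset(des, model,
      regime_spec("selection", m = 0.1, selection_strength = 0.3),
      seed = 700 + s, env_lat_slope = 0, env_depth_step = 0,
      env_noise_sd = 0, env_intercept = 1)
    sim_n <- simulate_dataset(des, model, regime_spec("neutral", m = 0.1),
                              seed = 800 + s)
    mean(1 - bray_curtis(sim_s$counts)) > mean(1 - bray_curtis(sim_n$counts))
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("conserved_optima builds a niche-coherent focal clade", {
  tr <- simulate_tree(200, seed = 61)
  opt <- conserved_optima(tr, focal_optimum = 3, seed = 62)
  focal <- attr(opt, "focal_clade")
  expect_true(length(focal) >= 2)
  expect_lt(sd(opt[focal]), 0.2)
  expect_equal(mean(opt[focal]), 3, tolerance = 0.1)
  # non-focal taxa sit away from the focal optimum
  expect_gt(min(abs(opt[-focal] - 3)), 0.5)
})

test_that("write_dataset round-trips counts, tree and metadata", {
  loc <- data.frame(name = "L1", latitude = 20, longitude = 110)
  des <- study_design(loc, sites_per_location = 2,
                      depth_layers = c("0-10", "10-20"),
                      depth_range = c(200, 300))
  tree <- simulate_tree(20, seed = 71)
  model <- metacommunity_model(tree, seed = 72)
  sim <- simulate_dataset(des, model, regime_spec("neutral", m = 0.3),
                          seed = 73)
  prefix <- file.path(tempdir(), "simtest")
  paths <- write_dataset(sim, prefix)
  expect_identical(read_count_table(paths["counts"]), sim$counts)
  expect_equal(length(ape::read.tree(paths["tree"])$tip.label), 20)
  meta <- read.delim(paths["metadata"])
  expect_equal(meta$sample_id, sim$metadata$sample_id)
  unlink(paths)
})
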