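# MIC, network construction, topology, keystoneness

test_that("prevalence filter applies the >= rule and is idempotent", {
  set.seed(1)
  cm <- matrix(0L, 3, 127,
               dimnames = list(c("keep", "drop", "ubiq"),
                               sprintf("s%d", 1:127)))
  cm["keep", 1:64] <- 1L   # 64/127 = 50.4%
  cm["drop", 1:63] <- 1L   # 63/127 = 49.6%
  cm["ubiq", ] <- 2L
  extra <- matrix(stats::rpois(5 * 127, 3) + 1L, 5, 127,
                  dimnames = list(sprintf("x%d", 1:5), colnames(cm)))
  storage.mode(extra) <- "integer"
  cm <- rbind(cm, extra)
  filt <- prevalence_filter(cm, 0.5)
  expect_true("keep" %in% rownames(filt))
  expect_false("drop" %in% rownames(filt))
  expect_identical(prevalence_filter(filt, 0.5), filt)

  u <- prevalence_filter(cm, 1)
  expect_true(all(rowSums(u > 0) == 127))
  expect_false("keep" %in% rownames(u))
  few <- matrix(c(1L, 1L, 1L, 1L, 1L, 0L), 3, 2,
                dimnames = list(c("u1", "u2", "half"), c("s1", "s2")))
  expect_error(prevalence_filter(few, 1), "fewer than 3")
})

test_that("mic detects functional relationships and rejects bad input", {
  x <- seq(0, 1, length.out = 100)
  expect_gte(mic(x, 2 * x + 1), 0.99)
  # monotone-transform invariance (rank-based grids)
  expect_equal(mic(x, x), mic(x, exp(3 * x)), tolerance = 1e-6)
  expect_equal(mic(x, x), mic(rank(x), rank(x)), tolerance = 1e-6)
  # symmetry
  set.seed(2)
  a <- stats::rnorm(60); b <- a^2 + stats::rnorm(60, sd = 0.1)
  expect_equal(mic(a, b), mic(b, a), tolerance = 1e-12)
  expect_true(mic(a, b) >= 0 && mic(a, b) <= 1)

  expect_error(mic(rep(1, 50), stats::rnorm(50)), "constant")
  expect_error(mic(1:5, 1:5), "length")
})

test_that("mic_matrix yields calibrated p-values and BH adjustment", {
  set.seed(3)
  cm <- random_counts(12, 40, lambda = 20)
  cm[2, ] <- cm[1, ]  # duplicated profile: maximal MIC, minimal p
  mr <- mic_matrix(cm, n_perm = 199, seed = 4)
  dup <- mr[mr$otu_a == "OTU001" & mr$otu_b == "OTU002", ]
  expect_gte(dup$mic, 0.99)
  expect_equal(dup$p, min(mr$p), tolerance = 1e-12)
  expect_true(all(mr$q >= mr$p - 1e-12))

  # BH against the textbook step-function oracle
  m <- nrow(mr)
  ord <- order(mr$p)
  qs <- mr$p[ord] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  expect_equal(mr$q[ord], pmin(qs, 1), tolerance = 1e-12)

  # shared null: raw p is a nonincreasing step function of MIC
  ord2 <- order(mr$mic)
  expect_true(all(diff(mr$p[ord2]) <= 1e-12))
  expect_gt(max(mr$p), 0.5)
})

test_that("build_network applies both cutoffs and signs edges", {
  mr <- data.frame(
    otu_a = c("a", "a", "b"), otu_b = c("b", "c", "c"),
    mic = c(0.6, 0.6, 0.4), rho = c(-0.4, 0.5, 0.9),
    p = c(1e-4, 2e-3, 1e-7), q = c(5e-4, 1e-2, 1e-6))
  class(mr) <- c("mic_result", class(mr))
  net <- build_network(mr, mic_cutoff = 0.5, q_cutoff = 0.001)
  expect_equal(nrow(net$edges), 1)         # (a,b): mic .6, q 5e-4
  expect_equal(net$edges$sign, "-")
  expect_equal(sort(igraph::V(net$graph)$name), c("a", "b"))

  expect_warning(empty <- build_network(mr, mic_cutoff = 0.99),
                 "no edges")
  expect_equal(igraph::ecount(empty$graph), 0)
})

test_that("network topology matches hand-enumerated values", {
  # path graph A-B-C
  mr <- data.frame(otu_a = c("A", "B"), otu_b = c("B", "C"),
                   mic = 0.9, rho = 0.5, p = 1e-6, q = 1e-6)
  class(mr) <- c("mic_result", class(mr))
  net <- build_network(mr)
  topo <- network_topology(net, seed = 1)
  nd <- topo$nodes[match(c("A", "B", "C"), topo$nodes$otu_id), ]
  expect_equal(nd$betweenness, c(0, 1, 0))
  expect_equal(topo$global$diameter, 2)
  expect_equal(topo$global$average_path_length, 4 / 3, tolerance = 1e-12)

  # two disconnected 4-cliques: modularity 1/2, two modules
  cl <- expand.grid(1:4, 1:4)
  cl <- cl[cl$Var1 < cl$Var2, ]
  ed <- rbind(data.frame(otu_a = paste0("p", cl$Var1),
                         otu_b = paste0("p", cl$Var2)),
              data.frame(otu_a = paste0("q", cl$Var1),
                         otu_b = paste0("q", cl$Var2)))
  ed$mic <- 0.8; ed$rho <- 0.3; ed$p <- 1e-6; ed$q <- 1e-6
  class(ed) <- c("mic_result", class(ed))
  topo2 <- network_topology(build_network(ed), seed = 2)
  expect_equal(topo2$global$modularity, 0.5, tolerance = 1e-12)
  expect_equal(topo2$global$n_modules, 2)
  expect_equal(topo2$global$positive_edge_fraction, 1)
})

test_that("centralities agree with brute-force shortest-path oracles", {
  set.seed(5)
  for (i in 1:10) {
    adj <- random_adjacency(8, 0.4)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- sprintf("n%d", 1:8)
    topo <- network_topology(g, seed = 1)
    expect_equal(topo$nodes$betweenness, betweenness_brute(adj),
                 tolerance = 1e-8)
    expect_equal(topo$nodes$closeness, closeness_brute(adj),
                 tolerance = 1e-8)
    expect_equal(topo$nodes$degree, rowSums(adj))
  }
})

test_that("keystoneness scores the star hub highest", {
  mr <- data.frame(otu_a = "hub", otu_b = paste0("leaf", 1:4),
                   mic = 0.9, rho = 0.5, p = 1e-6, q = 1e-6)
  class(mr) <- c("mic_result", class(mr))
  ks <- keystoneness(build_network(mr), top_k = 1)
  expect_equal(ks$otu_id[1], "hub")
  expect_equal(ks$keystoneness[ks$otu_id == "hub"], 2 / 3,
               tolerance = 1e-12)
  expect_equal(unique(ks$keystoneness[ks$otu_id != "hub"]), 1 / 3,
               tolerance = 1e-12)
  expect_true(ks$keystone[1] && !any(ks$keystone[-1]))

  # ring: all centralities equal -> scaled to 0, equal scores, id order
  ring <- data.frame(otu_a = sprintf("r%d", 1:6),
                     otu_b = sprintf("r%d", c(2:6, 1)),
                     mic = 0.9, rho = 0.5, p = 1e-6, q = 1e-6)
  class(ring) <- c("mic_result", class(ring))
  suppressMessages(kr <- keystoneness(build_network(ring), top_k = 2))
  expect_equal(length(unique(kr$keystoneness)), 1)
  expect_equal(kr$otu_id, sort(kr$otu_id))
  expect_true(all(kr$keystoneness >= 0 & kr$keystoneness <= 1))
})

test_that("mutualistic communities yield more positive edges than antagonistic", {
  # 12 responder OTUs embedded in a large unresponsive background so
  # compositional closure does not couple the background to the signal
  gen <- function(opposed, seed) {
    set.seed(seed)
    n_s <- 60
    env <- stats::rnorm(n_s)
    resp <- matrix(stats::rpois(12 * n_s, 15), 12, n_s)
    sgn <- if (opposed) rep(c(1, -1), 6) else rep(1, 12)
    resp <- round(resp * exp(0.7 * outer(sgn, env)))
    bg <- matrix(stats::rpois(20 * n_s, 300), 20, n_s)
    cm <- rbind(resp, bg) + 1L
    storage.mode(cm) <- "integer"
    dimnames(cm) <- list(sprintf("o%d", 1:32), sprintf("s%d", 1:n_s))
    cm
  }
  frac_pos <- function(cm, seed) {
    mr <- mic_matrix(cm, n_perm = 199, seed = seed)
    net <- suppressWarnings(build_network(mr, mic_cutoff = 0.45,
                                          q_cutoff = 0.05))
    if (nrow(net$edges) == 0) return(NA_real_)
    mean(net$edges$sign == "+")
  }
  wins <- vapply(1:5, function(s) {
    pm <- frac_pos(gen(FALSE, s), s)
    pa <- frac_pos(gen(TRUE, s), s)
    isTRUE(pm > pa)
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})
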