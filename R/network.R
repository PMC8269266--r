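# Cooccurrence network: MIC edges, topology, modules, keystoneness ------

#' Prevalence filter for network construction
#'
#' Keeps OTUs detected (count >= 1) in at least `min_fraction` of
#' samples, the standard sparsity guard against spurious correlations.
#'
#' @param counts matrix (OTUs x samples).
#' @param min_fraction minimum detection fraction in (0, 1\]; default 0.5.
#' @return the filtered count matrix.
#' @export
prevalence_filter <- function(counts, min_fraction = 0.5) {
  .check_counts(counts)
  if (min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must be in (0, 1]", call. = FALSE)
  keep <- rowMeans(counts > 0) >= min_fraction
  if (sum(keep) < 3)
    stop("prevalence filter leaves fewer than 3 OTUs", call. = FALSE)
  counts[keep, , drop = FALSE]
}

#' Maximal information coefficient of two vectors
#'
#' Classic MIC: the maximum over grid resolutions `(nx, ny)` with
#' `nx * ny <= n^alpha` of the normalized mutual information
#' `I(X;Y) / log2(min(nx, ny))`, with grids optimized by the
#' clump-based dynamic program (clump factor `c`) and both axis
#' orientations searched. Depends only on ranks, so it is invariant to
#' monotone transformations and lies in \[0, 1\].
#'
#' @param x,y numeric vectors of equal length n >= 8, neither constant.
#' @param alpha grid-size exponent (default 0.6).
#' @param c clump factor (default 15).
#' @return MIC score in \[0, 1\].
#' @export
mic <- function(x, y, alpha = 0.6, c = 15) {
  if (length(x) != length(y) || length(x) < 8)
    stop("`x` and `y` must have equal length >= 8", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: MIC undefined", call. = FALSE)
  mic_cpp(as.numeric(x), as.numeric(y), alpha, c)
}

#' Pairwise MIC with permutation p-values and BH correction
#'
#' Computes MIC between all OTU pairs on relative abundances. Raw
#' p-values come from a shared permutation null: `n_perm` MIC values of
#' randomly chosen OTU pairs with the sample order of one member
#' permuted; `p = (1 + #{null >= obs}) / (1 + n_perm)`. Benjamini-
#' Hochberg adjustment is applied across all pairs, and Spearman rho is
#' recorded per pair as the sign carrier.
#'
#' @param counts prevalence-filtered matrix (OTUs x samples).
#' @param alpha,c MIC grid parameters.
#' @param n_perm permutation replicates (>= 100; default 1000).
#' @param seed optional RNG seed.
#' @return data.frame of class `mic_result`: otu_a, otu_b, mic, rho,
#'   p, q.
#' @export
mic_matrix <- function(counts, alpha = 0.6, c = 15, n_perm = 1000,
                       seed = NULL) {
  .check_counts(counts)
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  rel <- relative_abundance(counts)
  ids <- rownames(rel)
  n_otu <- nrow(rel)
  if (n_otu < 2) stop("need >= 2 OTUs", call. = FALSE)
  const <- apply(rel, 1, sd) == 0
  if (any(const))
    stop("constant OTU profile(s): ",
         paste(ids[const], collapse = ", "), call. = FALSE)
  pairs <- which(upper.tri(diag(n_otu)), arr.ind = TRUE)
  obs <- numeric(nrow(pairs))
  for (e in seq_len(nrow(pairs)))
    obs[e] <- mic_cpp(rel[pairs[e, 1], ], rel[pairs[e, 2], ], alpha, c)
  rho_m <- suppressWarnings(cor(t(rel), method = "spearman"))
  rho <- rho_m[pairs]
  .with_seed(seed, {
    null <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      ij <- sample.int(n_otu, 2)
      null[b] <- mic_cpp(rel[ij[1], sample.int(ncol(rel))],
                         rel[ij[2], ], alpha, c)
    }
    null <- sort(null)
    # #{null >= obs} via position of obs in the sorted null
    ge <- n_perm - findInterval(obs - 1e-12, null)
    p <- (1 + ge) / (1 + n_perm)
    out <- data.frame(otu_a = ids[pairs[, 1]], otu_b = ids[pairs[, 2]],
                      mic = obs, rho = rho, p = p,
                      q = p.adjust(p, method = "BH"), row.names = NULL)
    class(out) <- c("mic_result", class(out))
    out
  })
}

#' Build a cooccurrence network from MIC results
#'
#' Edges are the pairs with `mic >= mic_cutoff` and adjusted
#' `p < q_cutoff`; the edge sign is the sign of the pair's Spearman rho
#' (zero rho counts as positive, with a message). OTUs without a
#' surviving edge are excluded from the node set.
#'
#' @param mic_result output of [mic_matrix()].
#' @param mic_cutoff minimum MIC (default 0.5).
#' @param q_cutoff maximum adjusted p (default 0.001).
#' @return object of class `cooccurrence_network`: list with `graph`
#'   (igraph) and `edges` (data.frame incl. `sign`). Zero surviving
#'   edges yield an empty network with a warning, not an error.
#' @export
build_network <- function(mic_result, mic_cutoff = 0.5, q_cutoff = 0.001) {
  stopifnot(inherits(mic_result, "mic_result") || is.data.frame(mic_result))
  keep <- mic_result$mic >= mic_cutoff & mic_result$q < q_cutoff
  edges <- mic_result[keep, , drop = FALSE]
  if (nrow(edges) == 0) {
    warning("no edges pass the MIC/q cutoffs; returning an empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    if (any(edges$rho == 0))
      message("edge(s) with zero Spearman rho assigned positive sign")
    edges$sign <- ifelse(edges$rho < 0, "-", "+")
    g <- igraph::graph_from_data_frame(
      edges[, c("otu_a", "otu_b", "mic", "rho", "q", "sign")],
      directed = FALSE)
  }
  structure(list(graph = g, edges = edges), class = "cooccurrence_network")
}

#' Topology, centralities, and Louvain modules of a network
#'
#' Degree, Brandes betweenness (unnormalized), and classic closeness
#' (computed within each connected component) per node; diameter and
#' average path length on the largest component; Louvain modularity at
#' resolution 1 with module ids ranked by descending size.
#'
#' @param network a `cooccurrence_network` (or igraph graph) with >= 1
#'   edge.
#' @param seed optional RNG seed for the Louvain pass.
#' @return list with `nodes` (data.frame: otu_id, degree, betweenness,
#'   closeness, module) and `global` (node/edge counts, average degree,
#'   diameter, average path length, modularity, positive edge fraction,
#'   module count).
#' @export
network_topology <- function(network, seed = NULL) {
  g <- if (inherits(network, "cooccurrence_network")) network$graph
       else network
  if (igraph::ecount(g) < 1) stop("network has no edges", call. = FALSE)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  comp <- igraph::components(g)
  clo <- rep(NA_real_, igraph::vcount(g))
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    if (length(vs) == 1) { clo[vs] <- 0; next }
    sub <- igraph::induced_subgraph(g, vs)
    clo[vs] <- igraph::closeness(sub, weights = NA)
  }
  big <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  diam <- igraph::diameter(big, directed = FALSE, weights = NA)
  apl <- igraph::mean_distance(big, directed = FALSE, weights = NA)
  comm <- .with_seed(seed, igraph::cluster_louvain(g, weights = NULL))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  module <- match(as.character(memb), names(sizes))
  pos_frac <- if (inherits(network, "cooccurrence_network") &&
                  nrow(network$edges) > 0)
    mean(network$edges$sign == "+") else NA_real_
  nodes <- data.frame(otu_id = igraph::V(g)$name, degree = as.integer(deg),
                      betweenness = as.numeric(btw),
                      closeness = as.numeric(clo),
                      module = as.integer(module), row.names = NULL)
  list(nodes = nodes,
       global = list(n_nodes = igraph::vcount(g),
                     n_edges = igraph::ecount(g),
                     average_degree = mean(deg), diameter = diam,
                     average_path_length = apl,
                     modularity = igraph::modularity(comm),
                     n_modules = length(sizes),
                     positive_edge_fraction = pos_frac))
}

#' Keystoneness scores: min-max-scaled degree, 1 - betweenness, closeness
#'
#' Each of degree, betweenness (BC), and closeness (CC) is min-max
#' scaled to \[0, 1\] across nodes (a constant vector maps to 0, with a
#' message); keystoneness is the mean of scaled degree, `1 - scaled BC`,
#' and scaled CC. High scorers — well-connected, central, non-bottleneck
#' nodes — are the putative keystone taxa.
#'
#' @param topology output of [network_topology()] (or a
#'   `cooccurrence_network`, in which case topology is computed).
#' @param top_k how many top-ranked OTUs to flag (default 10).
#' @return data.frame of nodes ordered by decreasing keystoneness (ties
#'   broken by otu_id) with scaled scores and a `keystone` flag for the
#'   top `top_k`.
#' @export
keystoneness <- function(topology, top_k = 10) {
  if (inherits(topology, "cooccurrence_network"))
    topology <- network_topology(topology)
  nodes <- topology$nodes
  if (nrow(nodes) < 2)
    stop("need >= 2 nodes for keystoneness scaling", call. = FALSE)
  scale01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) {
      message("constant centrality vector min-max scaled to 0")
      return(rep(0, length(v)))
    }
    (v - rng[1]) / diff(rng)
  }
  sd_ <- scale01(nodes$degree)
  sb <- scale01(nodes$betweenness)
  sc <- scale01(nodes$closeness)
  nodes$degree_scaled <- sd_
  nodes$betweenness_scaled <- sb
  nodes$closeness_scaled <- sc
  nodes$keystoneness <- (sd_ + (1 - sb) + sc) / 3
  nodes <- nodes[order(-nodes$keystoneness, nodes$otu_id), , drop = FALSE]
  nodes$keystone <- seq_len(nrow(nodes)) <= top_k
  rownames(nodes) <- NULL
  nodes
}
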