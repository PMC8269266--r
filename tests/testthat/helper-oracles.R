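# Brute-force reference implementations, independent of the package's
# computational paths.

# patristic distance by explicit node-path enumeration
patristic_brute <- function(tree) {
  n <- length(tree$tip.label)
  # edge length indexed by child node
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  paths <- ape::nodepath(tree)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pi_ <- paths[[i]]; pj <- paths[[j]]
      # MRCA = last node of the shared root-path prefix
      k <- max(which(pi_[seq_len(min(length(pi_), length(pj)))] ==
                     pj[seq_len(min(length(pi_), length(pj)))]))
      shared <- pi_[k]
      # sum child-edge lengths from each tip up to the MRCA
      up <- function(path, mrca) {
        idx <- which(path == mrca)
        sum(elen[path[(idx + 1):length(path)]])
      }
      d[i, j] <- d[j, i] <- up(pi_, shared) + up(pj, shared)
    }
  }
  d
}

# abundance-weighted beta mean nearest taxon distance, double loop
bmntd_brute <- function(f_k, f_l, d) {
  f_k <- f_k / sum(f_k); f_l <- f_l / sum(f_l)
  tot <- 0
  for (i in which(f_k > 0)) {
    m <- Inf
    for (j in which(f_l > 0)) m <- min(m, d[i, j])
    tot <- tot + f_k[i] * m
  }
  for (j in which(f_l > 0)) {
    m <- Inf
    for (i in which(f_k > 0)) m <- min(m, d[i, j])
    tot <- tot + f_l[j] * m
  }
  tot / 2
}

# Bray-Curtis by the textbook formula
bc_brute <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Spearman rho from explicit mid-ranks
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# all-pairs shortest paths (unweighted) by BFS
shortest_paths_brute <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; level <- 0
    seen <- rep(FALSE, n); seen[s] <- TRUE
    while (length(frontier)) {
      level <- level + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] > 0 & !seen)
        d[s, nb] <- level
        seen[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# Brandes-style betweenness by explicit shortest-path counting
betweenness_brute <- function(adj) {
  n <- nrow(adj)
  d <- shortest_paths_brute(adj)
  # number of shortest paths between each pair, by DP over distance levels
  nsp <- function(s, t) {
    if (s == t) return(1)
    if (!is.finite(d[s, t])) return(0)
    sum(vapply(which(adj[t, ] > 0 & d[s, ] == d[s, t] - 1),
               function(w) nsp(s, w), numeric(1)))
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    tot <- nsp(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        bc[v] <- bc[v] + nsp(s, v) * nsp(v, t) / tot
      }
    }
  }
  bc
}

# classic closeness within components: 1 / sum of distances to reachable
closeness_brute <- function(adj) {
  d <- shortest_paths_brute(adj)
  vapply(seq_len(nrow(adj)), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) 0 else 1 / sum(dv)
  }, numeric(1))
}

# random connected-ish undirected graph adjacency on n nodes
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  # ensure at least one edge
  if (sum(a) == 0) { a[1, 2] <- a[2, 1] <- 1L }
  a
}

# small random count fixture
random_counts <- function(n_otu = 20, n_samp = 6, lambda = 8) {
  m <- matrix(stats::rpois(n_otu * n_samp, lambda), n_otu, n_samp,
              dimnames = list(sprintf("OTU%03d", seq_len(n_otu)),
                              sprintf("S%02d", seq_len(n_samp))))
  storage.mode(m) <- "integer"
  m
}
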