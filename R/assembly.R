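# Phylogenetic and Raup-Crick null models of community assembly ---------

#' Patristic distance matrix for a set of OTUs
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param otu_ids tip labels to keep (default: all tips).
#' @return symmetric matrix of tip-to-tip path lengths, zero diagonal.
#' @export
phylo_distance_matrix <- function(tree, otu_ids = tree$tip.label) {
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing))
    stop("OTUs absent from the tree: ",
         paste(head(missing, 10), collapse = ", "), call. = FALSE)
  stats::cophenetic(tree)[otu_ids, otu_ids]
}

#' Abundance-weighted beta mean nearest taxon distance for one pair
#'
#' `0.5 * [sum_i f_ik min_j d_ij + sum_j f_jl min_i d_ij]`, where the
#' minima run over the taxa present in the *other* sample; a taxon shared
#' by both samples contributes 0 to its own minimum.
#'
#' @param f_k,f_l abundance vectors over the taxa of `dist` (any
#'   non-negative weights; normalized internally).
#' @param dist patristic distance matrix covering the taxa.
#' @return the betaMNTD value (branch-length units).
#' @export
bmntd <- function(f_k, f_l, dist) {
  if (length(f_k) != nrow(dist) || length(f_l) != nrow(dist))
    stop("abundance vectors must align with `dist`", call. = FALSE)
  if (sum(f_k) <= 0 || sum(f_l) <= 0)
    stop("each sample must contain at least one present taxon",
         call. = FALSE)
  f_k <- f_k / sum(f_k); f_l <- f_l / sum(f_l)
  ik <- which(f_k > 0); il <- which(f_l > 0)
  min_kl <- apply(dist[ik, il, drop = FALSE], 1, min)  # nearest in l
  min_lk <- apply(dist[il, ik, drop = FALSE], 1, min)  # nearest in k
  0.5 * (sum(f_k[ik] * min_kl) + sum(f_l[il] * min_lk))
}

# All-pairs betaMNTD. perm optionally relabels taxa on the tree (the
# phylogeny-shuffling null): distances are read through the permutation
# while abundances stay put.
.bmntd_matrix <- function(rel, dist, presence, perm = NULL) {
  if (is.null(perm)) perm <- seq_len(nrow(dist))
  M <- min_dist_cols(dist, presence, perm)  # taxa x samples nearest-taxon
  A <- crossprod(rel, M)                    # A[k, l] = sum_i f_ik M[i, l]
  0.5 * (A + t(A))
}

#' Pairwise beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of the abundance-weighted betaMNTD against a
#' null that shuffles taxon labels across the tips of the phylogeny
#' (regional-pool null; abundance structure untouched):
#' `(obs - mean_null) / sd_null`. Pairs whose null distribution has zero
#' spread are reported as `NA` with a warning.
#'
#' @param counts matrix (OTUs x samples), >= 2 samples; rows must match
#'   `dist`.
#' @param dist patristic distance matrix over the OTUs.
#' @param n_null null replicates (>= 99; default 999).
#' @param seed optional RNG seed.
#' @return list with matrices `bnti`, `bmntd_obs`, and the
#'   `null_mean`/`null_sd` matrices (sample x sample, zero diagonal).
#' @export
bnti <- function(counts, dist, n_null = 999, seed = NULL) {
  .check_counts(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (n_null < 99) stop("`n_null` must be >= 99", call. = FALSE)
  dist <- .as_square_matrix(dist)
  if (!identical(rownames(counts), rownames(dist)))
    dist <- dist[rownames(counts), rownames(counts)]
  rel <- relative_abundance(counts)
  presence <- lapply(seq_len(ncol(rel)), function(s) which(rel[, s] > 0))
  obs <- .bmntd_matrix(rel, dist, presence)
  n_taxa <- nrow(rel)
  .with_seed(seed, {
    sum1 <- matrix(0, ncol(rel), ncol(rel))
    sum2 <- matrix(0, ncol(rel), ncol(rel))
    for (b in seq_len(n_null)) {
      nb <- .bmntd_matrix(rel, dist, presence, perm = sample.int(n_taxa))
      sum1 <- sum1 + nb
      sum2 <- sum2 + nb^2
    }
    mu <- sum1 / n_null
    sdv <- sqrt(pmax(sum2 / n_null - mu^2, 0) * n_null / (n_null - 1))
    z <- (obs - mu) / sdv
    degenerate <- sdv < 1e-12
    diag(degenerate) <- FALSE
    if (any(degenerate)) {
      z[degenerate] <- NA_real_
      warning(sum(degenerate[upper.tri(degenerate)]),
              " pair(s) with zero null spread reported as NA")
    }
    diag(z) <- 0
    dimnames(z) <- dimnames(mu) <- dimnames(sdv) <-
      list(colnames(counts), colnames(counts))
    list(bnti = z, bmntd_obs = obs, null_mean = mu, null_sd = sdv)
  })
}

#' Bray-Curtis-based Raup-Crick (RC_bray) null model
#'
#' Each null replicate reassembles every sample probabilistically from the
#' regional pool: the observed richness of taxa is drawn without
#' replacement with probability proportional to regional occupancy, each
#' drawn taxon receives one read, and the remaining reads are allocated
#' multinomially with probability proportional to regional relative
#' abundance. Bray-Curtis dissimilarities of the null communities locate
#' the observed dissimilarity in the null distribution:
#' `RC = 2 ((#null < obs + 0.5 #ties) / n_null - 0.5)`, in \[-1, 1\].
#'
#' @param counts integer matrix (OTUs x samples), >= 2 samples with
#'   positive totals.
#' @param n_null null replicates (default 999).
#' @param seed optional RNG seed.
#' @return sample x sample matrix of RC values (zero diagonal).
#' @export
rc_bray <- function(counts, n_null = 999, seed = NULL) {
  .check_integer_counts(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(colSums(counts) == 0))
    stop("sample(s) with zero total: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  n_s <- ncol(counts)
  occ <- rowSums(counts > 0)
  pool <- rowSums(counts)
  rich <- colSums(counts > 0)
  tots <- colSums(counts)
  obs <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  .with_seed(seed, {
    less <- ties <- matrix(0, n_s, n_s)
    for (b in seq_len(n_null)) {
      null <- .rc_null_community(occ, pool, rich, tots)
      nb <- as.matrix(vegan::vegdist(t(null), method = "bray"))
      dlt <- nb - obs
      less <- less + (dlt < -1e-10)
      ties <- ties + (abs(dlt) <= 1e-10)
    }
    rc <- 2 * ((less + 0.5 * ties) / n_null - 0.5)
    diag(rc) <- 0
    dimnames(rc) <- list(colnames(counts), colnames(counts))
    rc
  })
}

# one null replicate: every sample rebuilt from the regional pool
.rc_null_community <- function(occ, pool, rich, tots) {
  n_taxa <- length(occ)
  out <- matrix(0L, n_taxa, length(rich))
  for (s in seq_along(rich)) {
    drawn <- sample.int(n_taxa, rich[s], prob = occ)
    x <- rep(1L, rich[s])
    extra <- tots[s] - rich[s]
    if (extra > 0)
      x <- x + rmultinom(1, extra, pool[drawn])[, 1]
    out[drawn, s] <- x
  }
  out
}

#' Classify sample pairs into five assembly processes
#'
#' Selection first: `betaNTI < -2` is homogeneous selection, `> 2`
#' heterogeneous selection. Among phylogenetically stochastic pairs
#' (`|betaNTI| <= 2`), `RC > 0.95` is dispersal limitation, `RC < -0.95`
#' homogenizing dispersal, and `|RC| <= 0.95` "undominated" (weak
#' selection/dispersal, drift, diversification). Pairs with undefined
#' betaNTI are excluded from the fractions and counted.
#'
#' @param bnti_matrix sample x sample betaNTI matrix (from [bnti()]).
#' @param rc_matrix sample x sample RC matrix (from [rc_bray()]).
#' @param bnti_threshold,rc_threshold classification thresholds (2 and
#'   0.95).
#' @return list with `turnover` (data.frame: sample_a, sample_b, bnti,
#'   rc, process) and `summary` (data.frame of per-process counts and
#'   fractions over classified pairs, plus `n_missing` as an attribute).
#' @export
classify_processes <- function(bnti_matrix, rc_matrix,
                               bnti_threshold = 2, rc_threshold = 0.95) {
  bnti_matrix <- .as_square_matrix(bnti_matrix)
  rc_matrix <- .as_square_matrix(rc_matrix)
  if (!all(dim(bnti_matrix) == dim(rc_matrix)))
    stop("betaNTI and RC matrices must cover the same samples",
         call. = FALSE)
  ids <- colnames(bnti_matrix)
  ut <- which(upper.tri(bnti_matrix), arr.ind = TRUE)
  b <- bnti_matrix[upper.tri(bnti_matrix)]
  r <- rc_matrix[upper.tri(rc_matrix)]
  proc <- ifelse(is.na(b), NA_character_,
          ifelse(b < -bnti_threshold, "homogeneous_selection",
          ifelse(b > bnti_threshold, "heterogeneous_selection",
          ifelse(r > rc_threshold, "dispersal_limitation",
          ifelse(r < -rc_threshold, "homogenizing_dispersal",
                 "undominated")))))
  levels <- c("homogeneous_selection", "heterogeneous_selection",
              "homogenizing_dispersal", "dispersal_limitation",
              "undominated")
  turnover <- data.frame(sample_a = ids[ut[, 1]], sample_b = ids[ut[, 2]],
                         bnti = b, rc = r,
                         process = factor(proc, levels = levels),
                         row.names = NULL)
  counts <- table(turnover$process)
  n_ok <- sum(counts)
  summary <- data.frame(process = names(counts),
                        count = as.integer(counts),
                        fraction = if (n_ok > 0) as.numeric(counts) / n_ok
                                   else rep(NA_real_, length(counts)),
                        row.names = NULL)
  attr(summary, "n_missing") <- sum(is.na(proc))
  list(turnover = turnover, summary = summary)
}

#' Correlate betaNTI with pairwise environmental change
#'
#' Computes the correlation between the upper triangle of the betaNTI
#' matrix and the pairwise absolute differences `|x_k - x_l|` of a sample
#' covariate, with a Mantel-style permutation p-value (sample labels of
#' the environmental matrix permuted).
#'
#' @param bnti_matrix sample x sample betaNTI matrix.
#' @param metadata data.frame with a `sample_id` column matching the
#'   matrix and the covariate column.
#' @param covariate name of a numeric metadata column.
#' @param method correlation method (default `"spearman"`; `"pearson"`
#'   available).
#' @param n_perm permutations for the p-value (default 9999).
#' @param seed optional RNG seed.
#' @return list with `rho`, `p`, `n_pairs`.
#' @export
bnti_env_correlation <- function(bnti_matrix, metadata, covariate,
                                 method = c("spearman", "pearson"),
                                 n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  bnti_matrix <- .as_square_matrix(bnti_matrix)
  ids <- colnames(bnti_matrix)
  x <- metadata[[covariate]][match(ids, metadata$sample_id)]
  if (anyNA(x))
    stop("covariate '", covariate, "' missing for sample(s): ",
         paste(ids[is.na(x)], collapse = ", "), call. = FALSE)
  if (sd(x) == 0)
    stop("covariate '", covariate,
         "' is constant; correlation undefined", call. = FALSE)
  denv <- abs(outer(x, x, "-"))
  ok <- upper.tri(bnti_matrix) & !is.na(bnti_matrix)
  b <- bnti_matrix[ok]
  if (length(b) < 3 || sd(b) == 0)
    stop("too few (or constant) defined betaNTI pairs for a correlation",
         call. = FALSE)
  r_obs <- cor(b, denv[ok], method = method)
  .with_seed(seed, {
    n <- length(ids)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      dp <- denv[pm, pm]
      rp <- cor(b, dp[ok], method = method)
      if (!is.na(rp) && abs(rp) >= abs(r_obs) - 1e-12)
        exceed <- exceed + 1L
    }
    list(rho = r_obs, p = (1 + exceed) / (1 + n_perm),
         n_pairs = length(b))
  })
}
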