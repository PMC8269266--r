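# Beta-diversity: distances, ordination, permutation tests, decay -------

#' Bray-Curtis dissimilarity matrix
#'
#' Computes Bray-Curtis dissimilarities between samples, by default after
#' a Hellinger transformation (square root of relative abundances), which
#' damps the influence of dominant taxa.
#'
#' @param counts non-negative matrix (OTUs x samples), no all-zero sample.
#' @param hellinger apply the Hellinger transform first (default `TRUE`).
#' @return sample x sample dissimilarity matrix in \[0, 1\] with
#'   attribute `metric`.
#' @export
bray_curtis <- function(counts, hellinger = TRUE) {
  rel <- relative_abundance(counts)
  x <- if (hellinger) sqrt(rel) else rel
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centered squared-distance matrix.
#' Negative eigenvalues are retained and reported; coordinates are built
#' from positive eigenvalues only.
#'
#' @param dist distance matrix or `dist` (>= 3 samples).
#' @return list: `points` (samples x positive axes), `eig` (all
#'   eigenvalues, decreasing), `proportion` (variance share per positive
#'   axis).
#' @export
pcoa <- function(dist) {
  d <- .as_square_matrix(dist)
  n <- nrow(d)
  if (n < 3) stop("need >= 3 samples for ordination", call. = FALSE)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  list(points = pts, eig = e$values,
       proportion = e$values[pos] / sum(e$values[pos]))
}

.check_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n)
    stop("one group label per sample required", call. = FALSE)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2))
    stop("singleton group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  groups
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Pseudo-F from the among/within sum-of-squares partition of the
#' distance matrix (vegan's `adonis2`), with permutation p-value
#' `(1 + #exceedances) / (1 + n_perm)`.
#'
#' @param dist distance matrix or `dist`.
#' @param groups factor of group labels (>= 2 groups, each >= 2 members).
#' @param n_perm permutations (default 999).
#' @param seed optional RNG seed.
#' @return list with `f`, `p`, `r2`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(.as_square_matrix(dist))
  g <- .check_groups(groups, attr(d, "Size"))
  fit <- .with_seed(seed,
    vegan::adonis2(d ~ g, data = data.frame(g = g),
                   permutations = n_perm))
  list(f = fit$F[1], p = fit$`Pr(>F)`[1], r2 = fit$R2[1])
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test statistic
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' with a permutation p-value (vegan's `anosim`).
#'
#' @inheritParams permanova
#' @return list with `r`, `p`.
#' @export
anosim <- function(dist, groups, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(.as_square_matrix(dist))
  g <- .check_groups(groups, attr(d, "Size"))
  fit <- .with_seed(seed, vegan::anosim(d, g, permutations = n_perm))
  list(r = unname(fit$statistic), p = fit$signif)
}

# great-circle distance (km), Earth radius 6371.0088 km
.haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Great-circle distance matrix (haversine, km)
#'
#' @param latitudes,longitudes decimal-degree coordinates (WGS84), one
#'   per sample; optionally named.
#' @return symmetric distance matrix in kilometres.
#' @export
haversine_matrix <- function(latitudes, longitudes) {
  if (any(abs(latitudes) > 90) || any(abs(longitudes) > 180))
    stop("coordinates out of range", call. = FALSE)
  n <- length(latitudes)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    d[i, ] <- .haversine_km(latitudes[i], longitudes[i],
                            latitudes, longitudes)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (!is.null(names(latitudes)))
    dimnames(d) <- list(names(latitudes), names(latitudes))
  attr(d, "metric") <- "haversine_km"
  d
}

#' Distance decay of community similarity with geographic distance
#'
#' Correlates Bray-Curtis *similarity* (1 - dissimilarity) with
#' great-circle distance over all unordered sample pairs, with a
#' least-squares slope and a Mantel permutation p-value (two-sided on the
#' correlation).
#'
#' @param counts OTU x sample matrix.
#' @param latitudes,longitudes per-sample coordinates.
#' @param hellinger Hellinger-transform before Bray-Curtis.
#' @param n_perm Mantel permutations (default 9999).
#' @param seed optional RNG seed.
#' @return list with `r` (Pearson), `p`, `slope` (similarity per km),
#'   `intercept`, `n_pairs`.
#' @export
distance_decay <- function(counts, latitudes, longitudes,
                           hellinger = TRUE, n_perm = 9999, seed = NULL) {
  sim <- 1 - bray_curtis(counts, hellinger = hellinger)
  geo <- haversine_matrix(latitudes, longitudes)
  n <- ncol(counts)
  if (n * (n - 1) / 2 < 10) stop("need >= 10 sample pairs", call. = FALSE)
  s <- .upper_vec(sim); g <- .upper_vec(geo)
  if (max(g) == 0)
    stop("all samples co-located; decay slope undefined", call. = FALSE)
  r_obs <- cor(s, g)
  fit <- lm(s ~ g)
  .with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      gp <- geo[pm, pm]
      if (abs(cor(s, .upper_vec(gp))) >= abs(r_obs) - 1e-12)
        exceed <- exceed + 1L
    }
    list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_pairs = length(s))
  })
}

#' Mantel test between two distance matrices
#'
#' Correlation of the vectorized upper triangles with a permutation
#' p-value obtained by permuting the sample ids of one matrix (vegan's
#' `mantel`; one-sided, add-one convention).
#'
#' @param d1,d2 distance matrices or `dist` objects over the same,
#'   identically ordered samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm permutations (default 9999).
#' @param seed optional RNG seed.
#' @return list with `r`, `p`.
#' @export
mantel <- function(d1, d2, method = c("spearman", "pearson"),
                   n_perm = 9999, seed = NULL) {
  method <- match.arg(method)
  m1 <- .as_square_matrix(d1); m2 <- .as_square_matrix(d2)
  if (!all(dim(m1) == dim(m2)))
    stop("distance matrices must have the same samples", call. = FALSE)
  if (!is.null(colnames(m1)) && !is.null(colnames(m2)) &&
      !identical(colnames(m1), colnames(m2)))
    stop("distance matrix ids do not match", call. = FALSE)
  fit <- .with_seed(seed,
    vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                  method = method, permutations = n_perm))
  list(r = unname(fit$statistic), p = fit$signif)
}

#' Spearman correlations of sample features with environmental covariates
#'
#' One tie-corrected Spearman rho and two-sided p per (feature,
#' covariate) pair; exact p for n <= 20, t-approximation above. Constant
#' columns yield `NA` entries with a warning.
#'
#' @param features data.frame/matrix of per-sample values (samples as
#'   rows).
#' @param covariates data.frame/matrix of per-sample covariates (same
#'   rows).
#' @return long data.frame: feature, covariate, rho, p.
#' @export
env_correlations <- function(features, covariates) {
  features <- as.data.frame(features)
  covariates <- as.data.frame(covariates)
  if (nrow(features) != nrow(covariates) || nrow(features) < 5)
    stop("features and covariates need the same >= 5 samples",
         call. = FALSE)
  n <- nrow(features)
  out <- expand.grid(feature = names(features),
                     covariate = names(covariates),
                     stringsAsFactors = FALSE)
  out$rho <- out$p <- NA_real_
  warned <- character(0)
  for (i in seq_len(nrow(out))) {
    x <- features[[out$feature[i]]]
    y <- covariates[[out$covariate[i]]]
    if (sd(x) == 0 || sd(y) == 0) {
      warned <- c(warned, paste(out$feature[i], out$covariate[i]))
      next
    }
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = n <= 20))
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  if (length(warned))
    warning("constant column(s), correlation undefined for: ",
            paste(warned, collapse = "; "))
  out[, c("feature", "covariate", "rho", "p")]
}
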