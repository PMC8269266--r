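# Sloan neutral community model -----------------------------------------

#' Predicted detection frequency under the Sloan neutral model
#'
#' The probability that a taxon with mean relative abundance `p` in the
#' source pool is detected (local abundance above the detection limit `d`)
#' in a local community coupled to the pool with strength `Nm`:
#' `1 - pbeta(d, Nm p, Nm (1 - p))`.
#'
#' @param Nm product of local community size and immigration rate (> 0).
#' @param p mean relative abundance(s) in (0, 1).
#' @param d detection limit as a fraction (typically 1/N).
#' @return predicted occurrence frequency in \[0, 1\] (vectorized over
#'   `p`).
#' @export
predict_frequency <- function(Nm, p, d) {
  if (Nm <= 0) stop("`Nm` must be > 0", call. = FALSE)
  if (any(p <= 0 | p >= 1)) stop("`p` must lie in (0, 1)", call. = FALSE)
  if (d <= 0 || d >= 1) stop("`d` must lie in (0, 1)", call. = FALSE)
  1 - pbeta(d, Nm * p, Nm * (1 - p))
}

#' Fit the Sloan neutral community model to a count table
#'
#' Regresses each OTU's occurrence frequency (fraction of samples where it
#' is detected) on the frequency predicted from its mean relative
#' abundance, estimating `Nm` by bounded least squares over
#' `log10(Nm) in [-1, 7]`. 95% prediction bands are Wilson score
#' intervals on the predicted frequency with the number of samples as
#' trials; OTUs are partitioned into above/within/below the bands.
#'
#' The default detection limit is `d = ln2 / N` with `N` the common
#' (rarefied) sample depth: detection means drawing at least one of `N`
#' reads, an event of probability `1 - (1 - lambda)^N` given a true
#' relative abundance `lambda`, and the step-function approximation
#' underlying the model is centred where that probability crosses 1/2,
#' i.e. at `lambda ~ ln2/N`. The harder one-read threshold is available
#' as `d = 1/N`; it systematically inflates `Nm` on read-sampled data.
#'
#' @param counts integer matrix (OTUs x samples) with >= 10 OTUs. Columns
#'   must share a common total unless `N` is supplied.
#' @param N reads-per-sample override; defaults to the common column sum
#'   (error if columns differ and no override is given).
#' @param d detection limit as a fraction; default `log(2) / N`.
#' @param conf band coverage (default 0.95).
#' @return object of class `ncm_fit`: list with `Nm`, `m`, `N`, `d`,
#'   `R2`, `n_samples`, and per-OTU data.frame `otus` (p, freq,
#'   predicted, lower, upper, partition).
#' @export
fit_ncm <- function(counts, N = NULL, d = NULL, conf = 0.95) {
  .check_integer_counts(counts)
  if (nrow(counts) < 10) stop("need >= 10 OTUs to fit the model",
                              call. = FALSE)
  tot <- colSums(counts)
  if (is.null(N)) {
    if (diff(range(tot)) > 0)
      stop("column sums differ; rarefy first or pass an explicit `N`",
           call. = FALSE)
    N <- tot[1]
  }
  N <- as.numeric(N)
  if (is.null(d)) d <- log(2) / N
  if (d <= 0 || d >= 1) stop("`d` must lie in (0, 1)", call. = FALSE)
  rel <- sweep(counts, 2, tot, "/")
  p <- rowMeans(rel)
  freq <- rowMeans(counts > 0)
  keep <- p > 0 & freq > 0
  p <- p[keep]; freq <- freq[keep]
  if (all(freq == 1))
    stop("degenerate fit: every OTU is present in every sample",
         call. = FALSE)
  ss <- function(lognm) sum((freq - predict_frequency(10^lognm, p, d))^2)
  # coarse grid bracket, then Brent refinement (objective unimodal in
  # practice)
  grid <- seq(-1, 7, by = 0.25)
  g0 <- grid[which.min(vapply(grid, ss, numeric(1)))]
  opt <- optimize(ss, lower = max(-1, g0 - 0.5), upper = min(7, g0 + 0.5))
  Nm <- 10^opt$minimum
  pred <- predict_frequency(Nm, p, d)
  SSres <- opt$objective
  SStot <- sum((freq - mean(freq))^2)
  R2 <- 1 - SSres / SStot
  n_s <- ncol(counts)
  band <- .wilson_band(pred, n_s, conf)
  partition <- ifelse(freq > band$upper, "above",
               ifelse(freq < band$lower, "below", "within"))
  otus <- data.frame(otu_id = names(p), p = p, freq = freq,
                     predicted = pred, lower = band$lower,
                     upper = band$upper, partition = partition,
                     row.names = NULL)
  structure(list(Nm = Nm, m = Nm / N, N = N, d = d, R2 = R2,
                 n_samples = n_s, otus = otus),
            class = "ncm_fit")
}

# Wilson score interval on a proportion `ph` with `n` trials
.wilson_band <- function(ph, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  cen <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  list(lower = pmax(0, cen - hw), upper = pmin(1, cen + hw))
}

#' Summarize a neutral-model fit
#'
#' @param fit an `ncm_fit` object.
#' @return list with Nm, m, N, d, R2, n_samples and the above/within/below
#'   OTU counts; serializes cleanly to JSON/TSV.
#' @export
ncm_report <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  tab <- table(factor(fit$otus$partition,
                      levels = c("above", "within", "below")))
  list(Nm = fit$Nm, m = fit$m, N = fit$N, d = fit$d, R2 = fit$R2,
       n_samples = fit$n_samples, n_otus = nrow(fit$otus),
       n_above = as.integer(tab["above"]),
       n_within = as.integer(tab["within"]),
       n_below = as.integer(tab["below"]))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  Nm = %.1f  (m = %.4f at N = %d)\n", x$Nm, x$m, x$N))
  cat(sprintf("  R2 = %.3f over %d OTUs, %d samples\n", x$R2,
              nrow(x$otus), x$n_samples))
  tab <- table(x$otus$partition)
  cat("  partition:", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}
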