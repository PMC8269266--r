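# Count-table I/O, rarefaction, abundance classes, alpha diversity ------

#' Read an OTU count table from TSV
#'
#' Expects a header row of sample ids and a first column of OTU ids; every
#' cell must parse as a non-negative integer. Format problems are reported
#' with the offending row/column.
#'
#' @param path file path.
#' @return integer matrix (OTUs x samples).
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2)
    stop("count table format error: need a header and at least one OTU row",
         call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  n_col <- length(header)
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("count table format error: duplicate sample id", call. = FALSE)
  body <- fields[-1]
  otu_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(otu_ids))
    stop("count table format error: duplicate OTU id '",
         otu_ids[anyDuplicated(otu_ids)], "'", call. = FALSE)
  mat <- matrix(0L, nrow = length(body), ncol = length(sample_ids),
                dimnames = list(otu_ids, sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_col)
      stop(sprintf("count table format error: row %d ('%s') has %d fields, expected %d",
                   i + 1L, row[1], length(row), n_col), call. = FALSE)
    vals <- suppressWarnings(as.numeric(row[-1]))
    bad <- which(is.na(vals) | vals < 0 | vals != floor(vals))
    if (length(bad))
      stop(sprintf("count table format error: cell '%s' at row '%s', column '%s' is not a non-negative integer",
                   row[-1][bad[1]], row[1], sample_ids[bad[1]]),
           call. = FALSE)
    mat[i, ] <- as.integer(vals)
  }
  mat
}

#' Write an OTU count table as TSV
#'
#' @param counts integer matrix (OTUs x samples).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(counts, path) {
  .check_integer_counts(counts)
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to a fixed depth
#'
#' Each retained sample is subsampled uniformly without replacement to
#' exactly `depth` reads (vegan's `rrarefy`). Samples with fewer reads than
#' `depth` are dropped (with a message) or trigger an error. OTUs left with
#' all-zero rows are removed.
#'
#' @param counts integer matrix (OTUs x samples).
#' @param depth target reads per sample (>= 1).
#' @param seed optional RNG seed; fixed seed gives identical output.
#' @param drop_below if `TRUE` (default) drop shallow samples, otherwise
#'   error.
#' @return rarefied integer matrix; all columns sum to `depth`.
#' @export
rarefy <- function(counts, depth, seed = NULL, drop_below = TRUE) {
  .check_integer_counts(counts)
  if (length(depth) != 1 || depth < 1)
    stop("`depth` must be a single integer >= 1", call. = FALSE)
  tot <- colSums(counts)
  shallow <- tot < depth
  if (all(shallow))
    stop("rarefaction depth ", depth, " exceeds every sample's total",
         call. = FALSE)
  if (any(shallow)) {
    if (!drop_below)
      stop("samples below rarefaction depth: ",
           paste(colnames(counts)[shallow], collapse = ", "), call. = FALSE)
    message("rarefy: dropping ", sum(shallow), " sample(s) below depth ",
            depth, ": ", paste(colnames(counts)[shallow], collapse = ", "))
    counts <- counts[, !shallow, drop = FALSE]
  }
  # vegan warns when a table has no singletons ("should be used with
  # observed counts"); advisory only, and common for simulated tables
  out <- .with_seed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(counts), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(out) <- "integer"
  out[rowSums(out) > 0, , drop = FALSE]
}

#' Per-sample relative abundances
#'
#' @param counts non-negative matrix (OTUs x samples) with no all-zero
#'   sample.
#' @return matrix of proportions; each column sums to 1.
#' @export
relative_abundance <- function(counts) {
  .check_counts(counts)
  tot <- colSums(counts)
  zero <- tot == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  sweep(counts, 2, tot, "/")
}

#' Partition OTUs into dominant / conditionally rare / always-rare classes
#'
#' An OTU is *always rare* if its relative abundance is below `rare_cutoff`
#' (0.01%) in every sample; *dominant* if it is at least `rare_cutoff` in
#' all samples or reaches `dominant_cutoff` (1%) in at least one sample;
#' and *conditionally rare* otherwise (never reaching 1%, but dropping
#' below 0.01% somewhere). Absence counts as below the rare cutoff. The
#' three classes partition the OTU set; OTUs formally matching both the
#' dominant and conditionally-rare definitions go to dominant.
#'
#' @param rel_abund proportion matrix (columns sum to 1), e.g. from
#'   [relative_abundance()] on a rarefied table.
#' @param rare_cutoff,dominant_cutoff fractions with
#'   `0 < rare_cutoff < dominant_cutoff < 1`.
#' @return data.frame with columns `otu_id` and `class` (factor with
#'   levels dominant, conditionally_rare, always_rare).
#' @export
classify_taxa <- function(rel_abund, rare_cutoff = 1e-4,
                          dominant_cutoff = 1e-2) {
  if (!(rare_cutoff > 0 && rare_cutoff < dominant_cutoff &&
        dominant_cutoff < 1))
    stop("cutoffs must satisfy 0 < rare_cutoff < dominant_cutoff < 1",
         call. = FALSE)
  if (max(abs(colSums(rel_abund) - 1)) > 1e-6)
    stop("`rel_abund` columns must sum to 1", call. = FALSE)
  mx <- apply(rel_abund, 1, max)
  mn <- apply(rel_abund, 1, min)
  cls <- ifelse(mx < rare_cutoff, "always_rare",
         ifelse(mn >= rare_cutoff | mx >= dominant_cutoff, "dominant",
                "conditionally_rare"))
  data.frame(otu_id = rownames(rel_abund),
             class = factor(cls, levels = c("dominant", "conditionally_rare",
                                            "always_rare")),
             row.names = NULL)
}

#' Per-sample alpha diversity
#'
#' Computes OTU richness, Shannon-Wiener H' (natural log), Chao1, and
#' Pielou evenness J = H'/ln(S). Chao1 uses the singleton/doubleton form
#' `S + F1 (F1 - 1) / (2 (F2 + 1))` (always finite; equals S when there
#' are no singletons); `classic = TRUE` gives `S + F1^2 / (2 F2)` instead
#' (infinite-free only when F2 > 0). Evenness is `NA` for single-OTU
#' samples.
#'
#' @param counts integer matrix (OTUs x samples), per-sample total >= 1.
#' @param classic use the classic Chao1 estimator.
#' @return data.frame: sample_id, richness, shannon, chao1, evenness.
#' @export
alpha_diversity <- function(counts, classic = FALSE) {
  .check_integer_counts(counts)
  if (any(colSums(counts) < 1))
    stop("every sample needs at least one read", call. = FALSE)
  S <- colSums(counts > 0)
  H <- vegan::diversity(t(counts), index = "shannon")
  F1 <- colSums(counts == 1)
  F2 <- colSums(counts == 2)
  chao1 <- if (classic) {
    ifelse(F2 > 0, S + F1^2 / (2 * F2), S + F1 * (F1 - 1) / 2)
  } else {
    S + F1 * (F1 - 1) / (2 * (F2 + 1))
  }
  J <- ifelse(S > 1, H / log(S), NA_real_)
  data.frame(sample_id = colnames(counts), richness = as.integer(S),
             shannon = as.numeric(H), chao1 = as.numeric(chao1),
             evenness = as.numeric(J), row.names = NULL)
}
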