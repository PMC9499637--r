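# Feature-table IO, filtering and CSS normalization.

#' Read a feature table from TSV
#'
#' Reads a tab-separated table with a header of feature (or sample) names and
#' the first column holding IDs. A leading `#OTU ID` header cell (dense
#' BIOM-TSV dialect) is accepted. Tables written features-as-rows are
#' transposed to the canonical samples x features layout via `orientation`.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows are samples (default) or
#'   `"features"` if rows are features.
#' @return A [FeatureTable-class].
#' @export
readFeatureTable <- function(path, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# Constructed from biom file"))
    df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                            comment.char = "")
  else
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate IDs in first column of ", path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric cells in ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "features") m <- t(m)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative value at sample '%s', feature '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
         call. = FALSE)
  featureTable(m)
}

#' Write a FeatureTable to TSV (samples as rows)
#'
#' @param table FeatureTable.
#' @param path output path.
#' @param idColumn name of the first (sample ID) column.
#' @export
writeFeatureTable <- function(table, path, idColumn = "sample_id") {
  v <- tableValues(table)
  df <- data.frame(rownames(v), v, check.names = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy map
#'
#' Two-column TSV (feature ID, semicolon-delimited lineage). Greengenes-style
#' rank prefixes (`k__`, `p__`, ...) are stripped.
#'
#' @param path file path.
#' @return named character vector: feature ID -> lineage string.
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  lineage <- gsub("(^|;)\\s*[a-z]__", "\\1", as.character(df[[2L]]))
  stats::setNames(lineage, as.character(df[[1L]]))
}

#' Filter low-abundance, low-prevalence features
#'
#' Retains features whose total count across all samples is at least
#' `minTotalFraction` of the grand total AND which are non-zero in at least
#' `minPrevalence` of the samples (both comparisons use `>=`). The sample set
#' is unchanged. Defaults are the 1%-of-total-reads and 25%-prevalence rules.
#'
#' @param table count FeatureTable.
#' @param minTotalFraction minimum per-feature total as fraction of the grand
#'   total (default 0.01).
#' @param minPrevalence minimum fraction of samples with a non-zero count
#'   (default 0.25).
#' @return filtered FeatureTable; the IDs of removed features are attached as
#'   attribute `"removed"`.
#' @export
filterFeatures <- function(table, minTotalFraction = 0.01,
                           minPrevalence = 0.25) {
  v <- tableValues(table)
  totals <- colSums(v)
  grand <- sum(totals)
  prevalence <- colMeans(v > 0)
  keep <- totals >= minTotalFraction * grand & prevalence >= minPrevalence
  if (!any(keep))
    stop("filtering removed every feature", call. = FALSE)
  out <- table[, which(keep)]
  attr(out, "removed") <- featureIds(table)[!keep]
  out
}

# Per-sample CSS scaling factor: sum of the sample's counts that are <= the
# empirical quantile (at level q) of its non-zero counts.
cssFactors <- function(v, quantile) {
  apply(v, 1L, function(row) {
    nz <- row[row > 0]
    if (!length(nz))
      stop("sample with all-zero counts", call. = FALSE)
    qv <- stats::quantile(nz, probs = quantile, names = FALSE, type = 7)
    sum(row[row <= qv])
  })
}

#' Data-adaptive CSS reference quantile
#'
#' Scans quantile levels on a fixed grid and returns the smallest level at
#' which the median relative deviation of the per-sample cumulative sums from
#' their across-sample reference (the median) first exceeds `threshold`.
#' Falls back to 0.5 with a warning when the criterion never triggers (e.g.
#' all samples identical).
#'
#' @param table count FeatureTable with >= 2 samples.
#' @param grid quantile levels to scan.
#' @param threshold instability threshold on the median relative deviation.
#' @return quantile level in (0, 1).
#' @export
cssReferenceQuantile <- function(table, grid = seq(0.05, 0.95, by = 0.05),
                                 threshold = 0.1) {
  v <- tableValues(table)
  if (nrow(v) < 2L)
    stop("need at least two samples", call. = FALSE)
  if (any(rowSums(v) == 0))
    stop("sample with all-zero counts", call. = FALSE)
  for (l in grid) {
    s <- cssFactors(v, l)
    ref <- stats::median(s)
    if (ref > 0) {
      dev <- stats::median(abs(s - ref) / ref)
      if (dev > threshold) return(l)
    }
  }
  warning("stability criterion never triggered; falling back to quantile 0.5")
  0.5
}

#' Cumulative sum scaling normalization
#'
#' Divides each count by its sample's CSS scaling factor (the sum of counts
#' up to the sample's `quantile` of non-zero counts) and multiplies by
#' `scale`. Zero counts stay zero; scaling a sample's counts by any c > 0
#' leaves its normalized row unchanged.
#'
#' @param table count FeatureTable.
#' @param quantile reference quantile in (0, 1); typically from
#'   [cssReferenceQuantile()].
#' @param scale output scale (default 1000).
#' @return normalized FeatureTable; per-sample factors attached as attribute
#'   `"factors"`.
#' @export
cssNormalize <- function(table, quantile = 0.5, scale = 1000) {
  if (quantile <= 0 || quantile >= 1)
    stop("'quantile' must be in (0, 1)", call. = FALSE)
  v <- tableValues(table)
  f <- cssFactors(v, quantile)
  if (any(f == 0))
    stop("CSS scaling factor of 0 for sample(s): ",
         paste(rownames(v)[f == 0], collapse = ", "), call. = FALSE)
  out <- featureTable(v / f * scale, featureMeta(table))
  attr(out, "factors") <- f
  out
}

#' Aggregate features by taxonomy rank
#'
#' Sums features sharing the same lineage truncated at `rank`. Features
#' missing from `taxonomy` are pooled into `"Unassigned"`. Per-sample totals
#' are conserved exactly.
#'
#' @param table FeatureTable.
#' @param taxonomy named character vector (feature ID -> semicolon-delimited
#'   lineage `phylum;family;genus`, deeper ranks allowed).
#' @param rank one of `"phylum"`, `"family"`, `"genus"`.
#' @return aggregated FeatureTable.
#' @export
aggregateTaxonomy <- function(table, taxonomy,
                              rank = c("phylum", "family", "genus")) {
  rank <- match.arg(rank)
  depth <- match(rank, c("phylum", "family", "genus"))
  v <- tableValues(table)
  lineage <- taxonomy[featureIds(table)]
  lab <- vapply(lineage, function(x) {
    if (is.na(x) || !nzchar(x)) return("Unassigned")
    parts <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
    parts <- parts[seq_len(min(depth, length(parts)))]
    if (!length(parts) || !nzchar(parts[length(parts)])) "Unassigned"
    else paste(parts, collapse = ";")
  }, character(1L), USE.NAMES = FALSE)
  groups <- unique(lab)
  agg <- vapply(groups, function(g)
    rowSums(v[, lab == g, drop = FALSE]), numeric(nrow(v)))
  if (nrow(v) == 1L) agg <- matrix(agg, nrow = 1L, dimnames =
    list(rownames(v), groups))
  featureTable(agg)
}

#' Convert counts to relative abundances
#'
#' @param table FeatureTable with positive row sums.
#' @return FeatureTable whose rows each sum to 1.
#' @export
relativeAbundance <- function(table) {
  v <- tableValues(table)
  rs <- rowSums(v)
  if (any(rs == 0))
    stop("zero row sum for sample(s): ",
         paste(rownames(v)[rs == 0], collapse = ", "), call. = FALSE)
  featureTable(v / rs, featureMeta(table))
}
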