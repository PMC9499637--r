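# Alpha/beta diversity, PCoA, PERMANOVA, intragroup distances.

#' Alpha diversity of one sample
#'
#' Shannon and (Gini-)Simpson are computed on proportions via
#' \pkg{vegan}; Chao1 uses the bias-corrected closed form
#' `S_obs + F1*(F1-1) / (2*(F2+1))` with F1/F2 the singleton/doubleton
#' counts, and therefore requires integer counts. Richness estimators need
#' raw counts, so alpha diversity is intended for unnormalized tables.
#'
#' @param countsRow non-negative numeric vector with at least one positive
#'   entry.
#' @param metric one of `"shannon"`, `"simpson"`, `"chao1"`.
#' @param base logarithm base for Shannon (default 2, the convention of the
#'   usual ecology toolkits; use `exp(1)` for nats).
#' @return a single number.
#' @examples
#' alphaDiversity(c(10, 10, 10, 10), "shannon")  # log2(4) = 2
#' @export
alphaDiversity <- function(countsRow, metric = c("shannon", "simpson", "chao1"),
                           base = 2) {
  metric <- match.arg(metric)
  x <- as.numeric(countsRow)
  if (any(x < 0) || any(!is.finite(x)))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (sum(x) == 0)
    stop("all-zero sample", call. = FALSE)
  switch(metric,
    shannon = as.numeric(vegan::diversity(x, index = "shannon", base = base)),
    simpson = as.numeric(vegan::diversity(x, index = "simpson")),
    chao1 = {
      if (any(abs(x - round(x)) > 1e-8))
        stop("chao1 requires integer counts", call. = FALSE)
      x <- round(x)
      sObs <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
    })
}

#' Bray-Curtis distance matrix
#'
#' `d(i,j) = 1 - 2 * sum(min(x_i, x_j)) / (sum(x_i) + sum(x_j))`, computed by
#' \pkg{vegan}.
#'
#' @param table FeatureTable with positive row sums.
#' @return a `stats::dist` object labeled with the sample IDs.
#' @export
brayCurtis <- function(table) {
  v <- tableValues(table)
  if (any(rowSums(v) == 0))
    stop("zero row sum", call. = FALSE)
  vegan::vegdist(v, method = "bray")
}

# Coerce dist / labeled square matrix to a validated square matrix.
asDistanceMatrix <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(m))) stop("distances must be finite", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric",
                                       call. = FALSE)
  if (max(abs(diag(m))) > 1e-12) stop("diagonal must be zero", call. = FALSE)
  if (any(m < 0)) stop("distances must be non-negative", call. = FALSE)
  if (is.null(rownames(m))) dimnames(m) <- list(seq_len(nrow(m)),
                                                seq_len(nrow(m)))
  m
}

#' Principal coordinate analysis
#'
#' Classical metric MDS: Gower double-centering of `-d^2/2` followed by an
#' eigendecomposition (via [stats::cmdscale()]). Axes with non-positive
#' eigenvalues are dropped from the coordinates but all eigenvalues are
#' reported. Variance proportions are positive eigenvalues over the sum of
#' all positive eigenvalues, so they sum to at most 1 for `k < n`.
#'
#' @param dm `dist` or symmetric distance matrix.
#' @param k number of axes requested (`k < n`).
#' @return list with `coordinates` (n x k' matrix, k' <= k), `eigenvalues`
#'   (all n, decreasing), `proportions` (per returned axis).
#' @export
pcoa <- function(dm, k = 2) {
  m <- asDistanceMatrix(dm)
  n <- nrow(m)
  if (k >= n) stop("k must be smaller than the number of samples",
                   call. = FALSE)
  res <- suppressWarnings(stats::cmdscale(m, k = k, eig = TRUE))
  eig <- res$eig
  pos <- sum(eig > 1e-12)
  kKeep <- min(k, pos)
  coords <- res$points[, seq_len(kKeep), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(kKeep))
  rownames(coords) <- rownames(m)
  props <- pmax(eig[seq_len(kKeep)], 0) / sum(pmax(eig, 0))
  list(coordinates = coords, eigenvalues = eig, proportions = props)
}

# All distinct assignments of a label multiset to n positions (columns), or
# NULL when their number exceeds `cap`. Used for exhaustive PERMANOVA.
enumerateLabelings <- function(labels, cap) {
  f <- factor(labels)
  counts <- table(f)
  total <- exp(lgamma(length(f) + 1) - sum(lgamma(counts + 1)))
  if (total > cap + 0.5) return(NULL)
  recur <- function(remaining) {
    n <- sum(remaining)
    if (n == 0L) return(matrix(integer(0), nrow = 0L, ncol = 1L))
    out <- NULL
    for (g in which(remaining > 0L)) {
      rem <- remaining
      rem[g] <- rem[g] - 1L
      sub <- recur(rem)
      out <- cbind(out, rbind(rep.int(g, ncol(sub)), sub))
    }
    out
  }
  idx <- recur(as.integer(counts))
  matrix(levels(f)[idx], nrow = length(f))
}

permanovaF <- function(d2, labels) {
  n <- nrow(d2)
  groups <- unique(labels)
  g <- length(groups)
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  ssWithin <- 0
  for (gr in groups) {
    idx <- which(labels == gr)
    sub <- d2[idx, idx, drop = FALSE]
    ssWithin <- ssWithin + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssBetween <- ssTotal - ssWithin
  (ssBetween / (g - 1)) / (ssWithin / (n - g))
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from total and within-group sums of squared distances; the p
#' value comes from label permutation with the add-one estimator
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. When the number of
#' distinct label assignments is at most `nPerm`, the full enumeration is
#' used instead and `p = #\{F >= F_obs\} / #assignments` (the observed
#' assignment included) is exact.
#'
#' @param dm `dist` or symmetric distance matrix.
#' @param labels group labels (>= 2 groups, each with >= 2 samples).
#' @param nPerm number of random permutations (default 999).
#' @param seed RNG seed for the permutation stream.
#' @return list with `pseudoF`, `p`, `nPerm`, and `exhaustive` (logical).
#' @export
permanova <- function(dm, labels, nPerm = 999, seed = 1) {
  m <- asDistanceMatrix(dm)
  labels <- as.character(labels)
  if (length(labels) != nrow(m))
    stop("labels length must match the distance matrix", call. = FALSE)
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L)) stop("singleton group: ",
                          paste(names(tab)[tab < 2], collapse = ", "),
                          call. = FALSE)
  d2 <- m^2
  fObs <- permanovaF(d2, labels)
  all <- enumerateLabelings(labels, cap = nPerm)
  if (!is.null(all)) {
    fAll <- apply(all, 2L, function(l) permanovaF(d2, l))
    p <- mean(fAll >= fObs - 1e-12)
    return(list(pseudoF = fObs, p = p, nPerm = ncol(all), exhaustive = TRUE))
  }
  fPerm <- withSeed(seed, vapply(seq_len(nPerm), function(i)
    permanovaF(d2, sample(labels)), numeric(1L)))
  p <- (1 + sum(fPerm >= fObs - 1e-12)) / (1 + nPerm)
  list(pseudoF = fObs, p = p, nPerm = nPerm, exhaustive = FALSE)
}

#' Within-group pairwise distances and their comparison
#'
#' Extracts all within-group pairwise distances per group and compares the
#' groups by a Kruskal-Wallis test on those distance multisets.
#'
#' @param dm `dist` or symmetric distance matrix.
#' @param labels group labels (each group >= 2 samples).
#' @return list with `distances` (named list of numeric vectors, one per
#'   group, each of length n_g*(n_g-1)/2) and `test` (list with `H`, `p`).
#' @export
intragroupDistances <- function(dm, labels) {
  m <- asDistanceMatrix(dm)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L)) stop("singleton group", call. = FALSE)
  dists <- lapply(names(tab), function(g) {
    idx <- which(labels == g)
    sub <- m[idx, idx, drop = FALSE]
    as.numeric(sub[upper.tri(sub)])
  })
  names(dists) <- names(tab)
  kw <- kruskalWallis(unlist(dists),
                      rep(names(dists), lengths(dists)))
  list(distances = dists, test = kw)
}
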