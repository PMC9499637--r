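# Univariate group tests, multiplicity control, clinical stratification.

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square p value on g-1 degrees of freedom. When
#' every value is identical the statistic is undefined after tie correction
#' and the degenerate result H = 0, p = 1 is returned.
#'
#' @param values numeric vector.
#' @param labels group labels (>= 2 groups, total n >= 3).
#' @return list with `H` and `p`.
#' @export
kruskalWallis <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(values) < 3L) stop("need total n >= 3", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, labels)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided test; the exact null distribution is used when
#' `length(x) + length(y) <= 12` and there are no ties, otherwise the normal
#' approximation with tie correction (the behaviour of
#' [stats::wilcox.test()], which backs this function).
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U` (the statistic for `x`) and two-sided `p`.
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Adjust p values for multiple testing
#'
#' Bonferroni (`min(1, m*p)`) or Benjamini-Hochberg step-up FDR, via
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @return adjusted p values, same order as the input.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "bh_fdr")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = if (method == "bonferroni") "bonferroni"
                  else "BH")
}

#' Pearson correlation with p value
#'
#' Pairwise-complete deletion of missing entries; p from the t transform on
#' n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, and `n` (complete pairs used).
#' @export
pearsonCorrelation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Stratify samples by a clinical variable
#'
#' Labels each non-missing sample according to a scheme that is either a
#' single threshold with direction (e.g. the anti-GAD `> 1 U/mL` cut-off) or
#' an ordered list of half-open intervals (e.g. the blood-pH severity strata
#' normal `>= 7.32`, moderate `[7.10, 7.32)`, severe `< 7.10`). Missing
#' values are excluded; their IDs are attached as attribute `"excluded"`.
#'
#' @param clinical data.frame with sample IDs as row names.
#' @param variable column name to stratify on.
#' @param scheme either `list(threshold =, direction = ">"|">="|"<"|"<=",
#'   labels = c(low, high))` or `list(breaks = , labels = )` where `breaks`
#'   are the interval edges (length = labels + 1, increasing, half-open
#'   `[lo, hi)` with the outer edges -Inf/Inf allowed).
#' @return factor of labels named by sample ID (non-missing samples only).
#' @examples
#' cl <- data.frame(blood_pH = c(7.40, 7.20, 7.05),
#'                  row.names = c("a", "b", "c"))
#' stratifySamples(cl, "blood_pH", phStrataScheme())
#' @export
stratifySamples <- function(clinical, variable, scheme) {
  if (!variable %in% colnames(clinical))
    stop("variable '", variable, "' not in clinical table", call. = FALSE)
  x <- clinical[[variable]]
  ids <- rownames(clinical)
  ok <- is.finite(x)
  lab <- rep(NA_character_, length(x))
  if (!is.null(scheme$threshold)) {
    dir <- match.arg(scheme$direction, c(">", ">=", "<", "<="))
    labs <- scheme$labels
    if (length(labs) != 2L) stop("threshold scheme needs 2 labels",
                                 call. = FALSE)
    hit <- switch(dir, ">" = x > scheme$threshold,
                  ">=" = x >= scheme$threshold,
                  "<" = x < scheme$threshold,
                  "<=" = x <= scheme$threshold)
    lab[ok] <- ifelse(hit[ok], labs[2L], labs[1L])
  } else if (!is.null(scheme$breaks)) {
    br <- scheme$breaks
    labs <- scheme$labels
    if (length(br) != length(labs) + 1L || is.unsorted(br, strictly = TRUE))
      stop("breaks must be strictly increasing with length = labels + 1",
           call. = FALSE)
    # half-open [lo, hi): findInterval with left.open = FALSE
    bin <- findInterval(x[ok], br, rightmost.closed = FALSE, left.open = FALSE)
    if (any(bin < 1L | bin > length(labs)))
      stop("values outside the scheme range", call. = FALSE)
    lab[ok] <- labs[bin]
  } else stop("scheme must provide 'threshold' or 'breaks'", call. = FALSE)
  out <- factor(lab[ok], levels = unique(scheme$labels))
  names(out) <- ids[ok]
  attr(out, "excluded") <- ids[!ok]
  out
}

#' Blood-pH severity strata scheme
#'
#' Ordered intervals severe `pH < 7.10`, moderate `7.10 <= pH < 7.32`,
#' normal `pH >= 7.32`.
#' @export
phStrataScheme <- function() {
  list(breaks = c(-Inf, 7.10, 7.32, Inf),
       labels = c("severe", "moderate", "normal"))
}

#' Binary blood-pH split at 7.32
#'
#' `pH >= 7.32` vs `pH < 7.32`; the boundary value 7.32 is labeled
#' `"pH>=7.32"`.
#' @export
phBinaryScheme <- function() {
  list(threshold = 7.32, direction = ">=",
       labels = c("pH<7.32", "pH>=7.32"))
}

#' Anti-GAD cut-off scheme (> 1 U/mL)
#'
#' The boundary value 1 is labeled low (`<=1`).
#' @export
antiGadScheme <- function() {
  list(threshold = 1, direction = ">", labels = c("antiGAD<=1", "antiGAD>1"))
}

#' Per-feature differential testing with multiplicity control
#'
#' Applies a Kruskal-Wallis (any number of groups) or Mann-Whitney (two
#' groups) test to every feature column, adjusts the p values, and flags
#' features. With `alphaRaw` set, the flag is the conjunction
#' `p <= alphaRaw & p_adj <= alpha` (the dual-threshold rule); otherwise
#' `p_adj <= alpha` alone.
#'
#' @param table FeatureTable (relative abundances for taxa, concentrations
#'   for metabolites).
#' @param labels group labels aligned with the samples.
#' @param test `"kruskal_wallis"` or `"mann_whitney"`.
#' @param adjust `"bh_fdr"` or `"bonferroni"`.
#' @param alpha threshold on the adjusted p (default 0.1).
#' @param alphaRaw optional threshold on the raw p (default 0.05; set NULL to
#'   flag on the adjusted p only).
#' @return data.frame: feature, statistic, p, p_adj, per-group medians,
#'   direction (group with the highest median), flag.
#' @export
differentialFeatures <- function(table, labels,
                                 test = c("kruskal_wallis", "mann_whitney"),
                                 adjust = c("bh_fdr", "bonferroni"),
                                 alpha = 0.1, alphaRaw = 0.05) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  v <- tableValues(table)
  labels <- factor(labels)
  if (length(labels) != nrow(v))
    stop("labels length must match samples", call. = FALSE)
  if (test == "mann_whitney" && nlevels(labels) != 2L)
    stop("mann_whitney requires exactly two groups", call. = FALSE)
  res <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    if (test == "kruskal_wallis") {
      t <- kruskalWallis(x, labels)
      c(statistic = t$H, p = t$p)
    } else {
      t <- mannWhitney(x[labels == levels(labels)[1L]],
                       x[labels == levels(labels)[2L]])
      c(statistic = t$U, p = t$p)
    }
  })
  res <- do.call(rbind, res)
  med <- vapply(levels(labels), function(g)
    apply(v[labels == g, , drop = FALSE], 2L, stats::median),
    numeric(ncol(v)))
  if (ncol(v) == 1L) med <- matrix(med, nrow = 1L,
                                   dimnames = list(colnames(v),
                                                   levels(labels)))
  colnames(med) <- paste0("median_", levels(labels))
  pAdj <- adjustPvalues(res[, "p"], adjust)
  flag <- pAdj <= alpha
  if (!is.null(alphaRaw)) flag <- flag & res[, "p"] <= alphaRaw
  data.frame(feature = colnames(v), statistic = res[, "statistic"],
             p = res[, "p"], p_adj = pAdj, med,
             direction = colnames(med)[max.col(med)],
             flag = flag, row.names = NULL, check.names = FALSE)
}
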