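# Low-level multi-block fusion, repeated double cross-validation,
# VIP-consistency feature selection, permutation testing.

#' Frobenius norm
#'
#' Square root of the sum of squared matrix entries.
#'
#' @param x numeric matrix or vector with finite entries.
#' @return a single non-negative number.
#' @examples
#' frobeniusNorm(matrix(c(3, 0, 4, 0), 2))  # 5
#' @export
frobeniusNorm <- function(x) {
  if (any(!is.finite(x))) stop("non-finite entries", call. = FALSE)
  sqrt(sum(as.numeric(x)^2))
}

# --- fold-local preprocessing -------------------------------------------

ensureColnames <- function(m, prefix = "V") {
  if (is.null(colnames(m)))
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  m
}

# Fast two-pass autoscale of the training rows of a matrix; exact zeros for
# constant columns so fold-local zero-variance dropping is reliable.
trainAutoscale <- function(x, idx) {
  xt <- x[idx, , drop = FALSE]
  n <- nrow(xt)
  cm <- colMeans(xt)
  xc <- xt - rep(cm, each = n)
  s <- sqrt(colSums(xc * xc) / (n - 1))
  kept <- which(s > 1e-12)
  if (!length(kept))
    stop("every column has zero variance in the training partition",
         call. = FALSE)
  scaled <- xc[, kept, drop = FALSE] * rep(1 / s[kept], each = n)
  list(scaled = scaled,
       transform = list(type = "autoscale", centers = cm[kept],
                        scales = s[kept], kept = kept, p = ncol(x)))
}

# Preprocess training rows of a matrix (autoscale) or a named block list
# (autoscale per block, then division by the training-block Frobenius norm,
# then concatenation). Returns the preprocessed training matrix and a
# transform record for out-of-sample rows.
foldPreprocess <- function(x, idx) {
  if (is.matrix(x)) {
    fa <- trainAutoscale(ensureColnames(x), idx)
    return(list(train = fa$scaled, transform = fa$transform))
  }
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("x must be a matrix or a named list of block matrices",
         call. = FALSE)
  parts <- list(); recs <- list()
  for (nm in names(x)) {
    m <- ensureColnames(as.matrix(x[[nm]]))
    fa <- trainAutoscale(m, idx)
    fn <- frobeniusNorm(fa$scaled)
    if (fn == 0) stop("block '", nm, "' has zero Frobenius norm",
                      call. = FALSE)
    parts[[nm]] <- fa$scaled / fn
    colnames(parts[[nm]]) <- paste(nm, colnames(m)[fa$transform$kept],
                                   sep = ":")
    recs[[nm]] <- list(inner = fa$transform, fnorm = fn)
  }
  fused <- do.call(cbind, parts)
  list(train = fused,
       transform = list(type = "blocks", blocks = recs,
                        colnames = colnames(fused)))
}

sliceRows <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE]
  else lapply(x, function(b) as.matrix(b)[idx, , drop = FALSE])
}

nRows <- function(x) if (is.matrix(x)) nrow(x) else nrow(as.matrix(x[[1L]]))

#' Fuse data blocks by Frobenius-norm scaling and concatenation
#'
#' Low-level fusion: each block is preprocessed (autoscaled column-wise by
#' default), divided by its own Frobenius norm so every block contributes
#' unit total variance-scale, and the blocks are concatenated row-wise
#' (samples stay rows). Multiplying a raw block by any c > 0 leaves the
#' fused matrix unchanged. Fused column names are prefixed with the block
#' name (`block:feature`).
#'
#' @param blocks named list of numeric matrices (or FeatureTables) sharing an
#'   identical ordered sample index.
#' @param preprocess `"autoscale"` (default) or `"none"`.
#' @return a [FusedBlockSet-class].
#' @export
fuseBlocks <- function(blocks, preprocess = c("autoscale", "none")) {
  preprocess <- match.arg(preprocess)
  if (!is.list(blocks) || is.null(names(blocks)) || length(blocks) < 1L)
    stop("'blocks' must be a named list", call. = FALSE)
  mats <- lapply(blocks, function(b)
    if (is(b, "FeatureTable")) tableValues(b) else as.matrix(b))
  ref <- rownames(mats[[1L]])
  for (nm in names(mats))
    if (!identical(rownames(mats[[nm]]), ref))
      stop("block '", nm, "' has a different sample index", call. = FALSE)
  parts <- list(); recs <- list(); norms <- numeric(0); map <- list()
  at <- 0L
  for (nm in names(mats)) {
    m <- ensureColnames(mats[[nm]])
    if (preprocess == "autoscale") {
      fa <- trainAutoscale(m, seq_len(nrow(m)))
      pre <- fa$scaled
      inner <- fa$transform
    } else {
      pre <- m
      inner <- list(type = "identity")
    }
    fn <- frobeniusNorm(pre)
    if (fn == 0) stop("block '", nm, "' has zero Frobenius norm",
                      call. = FALSE)
    sc <- pre / fn
    colnames(sc) <- paste(nm, colnames(pre), sep = ":")
    parts[[nm]] <- sc
    recs[[nm]] <- list(inner = inner, fnorm = fn)
    norms[nm] <- fn
    map[[nm]] <- at + seq_len(ncol(sc))
    at <- at + ncol(sc)
  }
  fused <- do.call(cbind, parts)
  rownames(fused) <- ref
  new("FusedBlockSet", fused = fused, blockNorms = norms, blockMap = map,
      transform = list(type = "blocks", blocks = recs,
                       colnames = colnames(fused)))
}

#' @describeIn fuseBlocks the fused samples x columns matrix
#' @param x a FusedBlockSet.
#' @export
fusedMatrix <- function(x) { stopifnot(is(x, "FusedBlockSet")); x@fused }

#' @describeIn fuseBlocks block name -> fused column indices
#' @export
blockMap <- function(x) { stopifnot(is(x, "FusedBlockSet")); x@blockMap }

# --- folds ----------------------------------------------------------------

#' Stratified fold assignment
#'
#' Shuffles each class separately (under `seed`) and deals its samples
#' round-robin over the `k` folds, so fold class proportions match the data
#' as closely as integer counts allow.
#'
#' @param labels class labels.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return list of `k` integer vectors partitioning `seq_along(labels)`.
#' @export
stratifiedFolds <- function(labels, k, seed = 1) {
  f <- factor(labels)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (length(f) < k) stop("more folds than samples", call. = FALSE)
  folds <- vector("list", k)
  withSeed(seed, {
    start <- 0L
    for (cl in levels(f)) {
      idx <- sample(which(f == cl))
      fold <- ((start + seq_along(idx) - 1L) %% k) + 1L
      for (j in seq_len(k))
        folds[[j]] <- c(folds[[j]], idx[fold == j])
      start <- start + length(idx)   # rotate so small classes spread evenly
    }
  })
  lapply(folds, sort)
}

# --- rDCV -----------------------------------------------------------------

#' Configuration for repeated double cross-validation
#'
#' @param outerFolds outer folds K_out (>= 2; default 5).
#' @param innerFolds inner folds K_in (>= 2; default 5).
#' @param repeats repetitions R (>= 1; default 20).
#' @param maxComp maximum number of PLS components scanned (default 10).
#' @param vipThreshold VIP selection threshold (default 1.15).
#' @param vipConsistency fraction of repeats in which a feature must reach
#'   the threshold to be selected (default 0.5).
#' @param seed master seed; per-repeat substreams are derived from it.
#' @return a validated configuration list.
#' @export
rdcvConfig <- function(outerFolds = 5, innerFolds = 5, repeats = 20,
                       maxComp = 10, vipThreshold = 1.15,
                       vipConsistency = 0.5, seed = 1) {
  if (outerFolds < 2L || innerFolds < 2L)
    stop("outerFolds and innerFolds must be >= 2", call. = FALSE)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  if (maxComp < 1L) stop("maxComp must be >= 1", call. = FALSE)
  if (vipThreshold < 0) stop("vipThreshold must be positive", call. = FALSE)
  if (vipConsistency <= 0 || vipConsistency > 1)
    stop("vipConsistency must be in (0, 1]", call. = FALSE)
  list(outerFolds = as.integer(outerFolds),
       innerFolds = as.integer(innerFolds),
       repeats = as.integer(repeats), maxComp = as.integer(maxComp),
       vipThreshold = vipThreshold, vipConsistency = vipConsistency,
       seed = as.integer(seed))
}

# NIPALS PLS1 that truncates (instead of failing) when the rank is
# exhausted; returns possibly fewer components than requested.
nipalsTrunc <- function(x, y, ncomp) {
  out <- tryCatch(nipalsPls1(x, y, ncomp), error = function(e) NULL)
  if (!is.null(out)) return(out)
  for (a in rev(seq_len(ncomp - 1L))) {
    out <- tryCatch(nipalsPls1(x, y, a), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  NULL
}

# Continuous predictions for every component count 1..A from one fit.
predictAllComp <- function(fit, yMean, xTest) {
  A <- length(fit$q)
  PtW <- crossprod(fit$P, fit$W)
  B <- vapply(seq_len(A), function(a)
    as.numeric(fit$W[, seq_len(a), drop = FALSE] %*%
      solve(PtW[seq_len(a), seq_len(a), drop = FALSE], fit$q[seq_len(a)])),
    numeric(nrow(fit$W)))
  yMean + xTest %*% B
}

#' Repeated double cross-validation for (multi-block) PLS-DA
#'
#' Nested cross-validation: per repetition, a stratified outer split
#' estimates performance while, inside every outer training partition, a
#' stratified inner cross-validation selects the number of PLS components
#' minimizing the pooled inner misclassification error (ties go to the
#' smallest A). All preprocessing (per-block autoscaling and Frobenius
#' scaling) is estimated on the training partition of each fold and applied
#' frozen to held-out rows, so test data never influence preprocessing,
#' model-size selection, or the fit. Per repeat, the figures of merit are
#' computed from the pooled out-of-fold predictions, and a VIP vector is
#' recorded from a refit on all samples at the repeat's median chosen A
#' (half-integer medians round down, consistent with the smallest-A tie
#' rule).
#'
#' @param x samples x features matrix, or a named list of block matrices
#'   sharing the sample order (fused fold-locally).
#' @param labels two-class labels.
#' @param config see [rdcvConfig()].
#' @param positiveClass class coded 1 (default: second sorted level).
#' @param folds optional list of outer-fold index vectors reused for every
#'   repeat (used by the permutation test to freeze the fold structure).
#' @return an [RDCVResult-class].
#' @export
rdcv <- function(x, labels, config = rdcvConfig(), positiveClass = NULL,
                 folds = NULL) {
  f <- binaryLabels(labels, positiveClass)
  n <- nRows(x)
  if (length(f) != n) stop("labels length must match rows", call. = FALSE)
  if (is.null(folds) && min(table(f)) < config$outerFolds)
    stop("each class needs at least 'outerFolds' samples", call. = FALSE)
  if (n < 2L * config$outerFolds)
    stop("need n >= 2 * outerFolds", call. = FALSE)
  pos <- levels(f)[2L]
  y01 <- as.numeric(f == pos)

  loop <- rdcvLoop(x, f, y01, config, folds, collectPred = TRUE)
  merits <- loop$merits
  chosenA <- loop$chosenA
  R <- config$repeats

  # per-repeat VIP from a refit on all samples at the median chosen A
  ppAll <- foldPreprocess(x, seq_len(n))
  featNames <- colnames(ppAll$train)
  pAll <- length(featNames)
  blockAnn <- if (is.matrix(x)) rep(NA_character_, pAll) else
    sub(":.*$", "", featNames)
  vipMat <- matrix(NA_real_, R, pAll, dimnames = list(NULL, featNames))
  refitCache <- list()
  for (r in seq_len(R)) {
    aRep <- max(1L, as.integer(floor(stats::median(chosenA[r, ],
                                                   na.rm = TRUE))))
    key <- as.character(aRep)
    if (is.null(refitCache[[key]])) {
      fitAll <- nipalsTrunc(ppAll$train, y01 - mean(y01),
                            min(aRep, n - 1L, pAll))
      refitCache[[key]] <- if (is.null(fitAll)) rep(NA_real_, pAll) else
        vipFromFit(fitAll)
    }
    vipMat[r, ] <- refitCache[[key]]
  }

  ms <- c(accuracy_mean = mean(merits[, 1L]), accuracy_sd = stats::sd(merits[, 1L]),
          sensitivity_mean = mean(merits[, 2L]), sensitivity_sd = stats::sd(merits[, 2L]),
          specificity_mean = mean(merits[, 3L]), specificity_sd = stats::sd(merits[, 3L]))
  if (R == 1L) ms[c(2L, 4L, 6L)] <- 0
  cfg <- config
  cfg$featureNames <- featNames
  cfg$blockAnnotation <- blockAnn
  cfg$positiveClass <- pos
  cfg$classes <- levels(f)
  new("RDCVResult", merits = as.data.frame(merits), meritSummary = ms,
      vip = vipMat, chosenA = chosenA,
      predictions = do.call(rbind, loop$predList), config = cfg)
}

# The double-CV loop shared by rdcv() and the permutation null: returns the
# per-repeat figures of merit, chosen component counts and (optionally) the
# pooled out-of-fold predictions, without building S4 objects.
rdcvLoop <- function(x, f, y01, config, folds, collectPred = FALSE) {
  n <- length(y01)
  pos <- levels(f)[2L]
  R <- config$repeats
  merits <- matrix(NA_real_, R, 3L,
                   dimnames = list(NULL, c("accuracy", "sensitivity",
                                           "specificity")))
  chosenA <- matrix(NA_integer_, R, config$outerFolds)
  predList <- if (collectPred) vector("list", R)

  for (r in seq_len(R)) {
    seedR <- deriveSeed(config$seed, r)
    outer <- if (is.null(folds)) stratifiedFolds(f, config$outerFolds, seedR)
             else folds
    predClass <- rep(NA_character_, n)
    predScore <- rep(NA_real_, n)
    for (fi in seq_along(outer)) {
      test <- outer[[fi]]
      train <- setdiff(seq_len(n), test)
      yTr <- y01[train]
      if (length(unique(yTr)) < 2L) {   # degenerate permuted fold: majority
        predClass[test] <- if (mean(yTr) >= 0.5) pos else levels(f)[1L]
        predScore[test] <- mean(yTr)
        chosenA[r, fi] <- 1L
        next
      }
      inner <- stratifiedFolds(f[train], config$innerFolds,
                               deriveSeed(seedR, fi))
      aCap <- min(config$maxComp, length(train) - 1L)
      poolPred <- matrix(NA_real_, length(train), aCap)
      for (ii in seq_along(inner)) {
        iTestLoc <- inner[[ii]]
        iTrainLoc <- setdiff(seq_along(train), iTestLoc)
        iTrain <- train[iTrainLoc]
        yIt <- y01[iTrain]
        if (length(unique(yIt)) < 2L) {
          poolPred[iTestLoc, ] <- mean(yIt)
          next
        }
        pp <- foldPreprocess(x, iTrain)
        xTe <- applyTransform(pp$transform, sliceRows(x, train[iTestLoc]))
        aFit <- min(aCap, nrow(pp$train) - 1L, ncol(pp$train))
        fit <- nipalsTrunc(pp$train, yIt - mean(yIt), aFit)
        if (is.null(fit)) { poolPred[iTestLoc, ] <- mean(yIt); next }
        pr <- predictAllComp(fit, mean(yIt), xTe)
        poolPred[iTestLoc, seq_len(ncol(pr))] <- pr
      }
      complete <- which(colSums(is.na(poolPred)) == 0L)
      if (!length(complete)) complete <- 1L
      errA <- colMeans((poolPred[, complete, drop = FALSE] >= 0.5) != yTr)
      bestA <- complete[which.min(errA)]   # which.min: ties -> smallest A

      pp <- foldPreprocess(x, train)
      aFit <- min(bestA, nrow(pp$train) - 1L, ncol(pp$train))
      fit <- nipalsTrunc(pp$train, yTr - mean(yTr), aFit)
      if (is.null(fit)) {
        predClass[test] <- if (mean(yTr) >= 0.5) pos else levels(f)[1L]
        predScore[test] <- mean(yTr)
        chosenA[r, fi] <- 1L
        next
      }
      xTe <- applyTransform(pp$transform, sliceRows(x, test))
      sc <- as.numeric(mean(yTr) +
        xTe %*% plsCoefficients(fit))
      predScore[test] <- sc
      predClass[test] <- ifelse(sc >= 0.5, pos, levels(f)[1L])
      chosenA[r, fi] <- length(fit$q)
    }
    merits[r, ] <- classificationMetrics(as.character(f), predClass, pos)
    if (collectPred)
      predList[[r]] <- data.frame(repeatId = r, sample = seq_len(n),
                                  truth = as.character(f),
                                  predicted = predClass, score = predScore)
  }
  list(merits = merits, chosenA = chosenA, predList = predList)
}

# Regression vector from a raw NIPALS fit (internal mirrors of the PLSModel
# methods, used inside the CV loops where no S4 object is built).
plsCoefficients <- function(fit) {
  as.numeric(fit$W %*% solve(crossprod(fit$P, fit$W), fit$q))
}

vipFromFit <- function(fit) {
  tot <- sum(fit$ssy)
  if (tot <= 0) return(rep(NA_real_, nrow(fit$W)))
  w2 <- sweep(fit$W, 2L, sqrt(colSums(fit$W^2)), "/")^2
  sqrt(nrow(fit$W) * as.numeric(w2 %*% fit$ssy) / tot)
}

#' VIP-consistency feature selection
#'
#' A feature is selected iff its VIP reaches `threshold` in at least
#' `consistency` of the repeats of an rDCV run. This is the first stage of
#' the two-stage biomarker rule; the second stage confirms the selected
#' features by Mann-Whitney tests with Bonferroni correction
#' (see [confirmSelectedFeatures()]).
#'
#' @param result an [RDCVResult-class].
#' @param threshold VIP threshold (default 1.15).
#' @param consistency minimum fraction of repeats (default 0.5).
#' @return data.frame: feature, block, meanVip, fractionAboveThreshold,
#'   selected.
#' @export
selectFeaturesVip <- function(result, threshold = 1.15, consistency = 0.5) {
  stopifnot(is(result, "RDCVResult"))
  v <- result@vip
  if (!ncol(v)) stop("empty VIP matrix", call. = FALSE)
  frac <- colMeans(v >= threshold, na.rm = TRUE)
  frac[colSums(!is.na(v)) == 0L] <- 0
  data.frame(feature = colnames(v),
             block = result@config$blockAnnotation,
             meanVip = colMeans(v, na.rm = TRUE),
             fractionAboveThreshold = frac,
             selected = frac >= consistency,
             row.names = NULL)
}

#' Confirm selected features by Mann-Whitney with Bonferroni correction
#'
#' @param x the matrix or block list the rDCV was run on.
#' @param labels the two-class labels.
#' @param features fused feature names to confirm (`block:feature` for block
#'   input).
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @return data.frame: feature, U, p, p_adj, significant.
#' @export
confirmSelectedFeatures <- function(x, labels, features, alpha = 0.05) {
  if (!length(features))
    return(data.frame(feature = character(0), U = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  pp <- foldPreprocess(x, seq_len(nRows(x)))
  m <- pp$train
  missing <- setdiff(features, colnames(m))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  f <- binaryLabels(labels)
  res <- t(vapply(features, function(ft) {
    mw <- mannWhitney(m[f == levels(f)[1L], ft], m[f == levels(f)[2L], ft])
    c(U = mw$U, p = mw$p)
  }, numeric(2L)))
  pAdj <- adjustPvalues(res[, "p"], "bonferroni")
  data.frame(feature = features, U = res[, "U"], p = res[, "p"],
             p_adj = pAdj, significant = pAdj <= alpha, row.names = NULL)
}

#' Permutation test of the classification figures of merit
#'
#' Builds the null distribution of accuracy, sensitivity and specificity by
#' permuting the class labels `nPerm` times and repeating the full rDCV
#' figure-of-merit computation at a reduced number of repeats
#' (`permRepeats`). To isolate label exchangeability, every permutation
#' reuses the outer-fold structure derived from the unpermuted labels.
#' `p = (1 + #\{null >= observed\}) / (1 + nPerm)` per metric.
#'
#' @param x matrix or named block list.
#' @param labels two-class labels.
#' @param config [rdcvConfig()] used for the observed run.
#' @param nPerm number of permutations (>= 1; default 1000).
#' @param permRepeats rDCV repeats per permutation (default 1).
#' @param positiveClass class coded 1.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(x, labels, config = rdcvConfig(), nPerm = 1000,
                            permRepeats = 1, positiveClass = NULL) {
  if (nPerm < 1L) stop("nPerm must be >= 1", call. = FALSE)
  f <- binaryLabels(labels, positiveClass)
  obs <- rdcv(x, f, config, positiveClass = levels(f)[2L])
  om <- rdcvMeritSummary(obs)
  observed <- c(accuracy = unname(om["accuracy_mean"]),
                sensitivity = unname(om["sensitivity_mean"]),
                specificity = unname(om["specificity_mean"]))
  foldsFixed <- stratifiedFolds(f, config$outerFolds,
                                deriveSeed(config$seed, 0L))
  permCfg <- config
  permCfg$repeats <- as.integer(permRepeats)
  null <- matrix(NA_real_, nPerm, 3L,
                 dimnames = list(NULL, names(observed)))
  for (i in seq_len(nPerm)) {
    permLab <- withSeed(deriveSeed(config$seed, 100000L + i), sample(f))
    permCfg$seed <- deriveSeed(config$seed, 200000L + i)
    pl <- rdcvLoop(x, permLab, as.numeric(permLab == levels(f)[2L]),
                   permCfg, folds = foldsFixed)
    null[i, ] <- colMeans(pl$merits)
  }
  p <- vapply(names(observed), function(m)
    (1 + sum(null[, m] >= observed[m] - 1e-12)) / (1 + nPerm), numeric(1L))
  new("PermutationResult", observed = observed, nullDistribution = null,
      p = p, nPerm = nPerm)
}
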