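#' @import methods
NULL

# ---------------------------------------------------------------------------
# FeatureTable
# ---------------------------------------------------------------------------

#' FeatureTable: samples x features non-negative matrix
#'
#' The canonical container for both the 16S count table (integer counts) and
#' the NMR metabolite concentration table (positive reals). Rows are samples,
#' columns are features; dimnames carry the sample and feature identifiers.
#' Optional per-feature annotation (e.g. a semicolon-delimited taxonomy
#' lineage) lives in `featureMeta`.
#'
#' @slot values numeric matrix, samples x features, non-negative, with unique
#'   row and column names.
#' @slot featureMeta data.frame with one row per feature (possibly 0 columns).
#'
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", featureMeta = "data.frame"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have sample (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated sample IDs")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated feature IDs")
  }
  if (is.numeric(v) && length(v) && any(!is.finite(v)))
    msg <- c(msg, "values must be finite")
  if (is.numeric(v) && length(v) && any(v < 0))
    msg <- c(msg, "values must be non-negative")
  if (nrow(object@featureMeta) > 0L && nrow(object@featureMeta) != ncol(v))
    msg <- c(msg, "featureMeta rows must match the number of features")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values samples x features numeric matrix with dimnames, or an
#'   unnamed matrix (IDs are then generated as `S1..Sn` / `F1..Fp`).
#' @param featureMeta optional data.frame of per-feature annotation.
#' @return A [FeatureTable-class] object.
#' @examples
#' ft <- featureTable(matrix(1:6, 2, 3))
#' dim(ft)
#' @export
featureTable <- function(values, featureMeta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  if (is.null(featureMeta))
    featureMeta <- data.frame(row.names = colnames(values))
  new("FeatureTable", values = values, featureMeta = featureMeta)
}

#' @describeIn featureTable matrix of values (samples x features)
#' @param x,object a FeatureTable.
#' @export
tableValues <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  x@values
}

#' @describeIn featureTable sample identifiers
#' @export
sampleIds <- function(x) rownames(tableValues(x))

#' @describeIn featureTable feature identifiers
#' @export
featureIds <- function(x) colnames(tableValues(x))

#' @describeIn featureTable per-feature annotation data.frame
#' @export
featureMeta <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  x@featureMeta
}

#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

#' @export
setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d samples x %d features\n",
              nrow(object@values), ncol(object@values)))
  if (ncol(object@featureMeta))
    cat("featureMeta:", paste(colnames(object@featureMeta), collapse = ", "),
        "\n")
})

#' Subset a FeatureTable
#'
#' @param x FeatureTable.
#' @param i,j sample / feature indices (any standard matrix index).
#' @param ... ignored.
#' @param drop ignored; the result is always a FeatureTable.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  fm <- x@featureMeta
  keepMeta <- if (ncol(fm)) fm[j, , drop = FALSE] else
    data.frame(row.names = colnames(v)[j])
  featureTable(v[i, j, drop = FALSE], keepMeta)
})

# ---------------------------------------------------------------------------
# StudyBundle
# ---------------------------------------------------------------------------

#' StudyBundle: linked count, metabolite and clinical tables
#'
#' The three tables share one ordered sample index; `truth` records the
#' planted effects (differential feature indices, effect sizes,
#' taxon-metabolite links) so simulations can be scored against ground truth.
#'
#' @slot counts FeatureTable of taxa counts.
#' @slot metabolites FeatureTable of metabolite concentrations.
#' @slot clinical data.frame of clinical variables incl. a `group` column.
#' @slot truth list describing planted effects.
#'
#' @exportClass StudyBundle
setClass("StudyBundle",
  representation(counts = "FeatureTable", metabolites = "FeatureTable",
                 clinical = "data.frame", truth = "list"))

setValidity("StudyBundle", function(object) {
  sc <- sampleIds(object@counts)
  msg <- character()
  if (!identical(sc, sampleIds(object@metabolites)))
    msg <- c(msg, "counts and metabolites sample indices differ")
  if (!identical(sc, rownames(object@clinical)))
    msg <- c(msg, "clinical sample index differs from counts")
  if (!"group" %in% colnames(object@clinical))
    msg <- c(msg, "clinical table must contain a 'group' column")
  if (any(rowSums(tableValues(object@counts)) <= 0))
    msg <- c(msg, "count row sums must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn generateStudy taxa count table of a bundle
#' @param x a StudyBundle.
#' @export
bundleCounts <- function(x) { stopifnot(is(x, "StudyBundle")); x@counts }

#' @describeIn generateStudy metabolite table of a bundle
#' @export
bundleMetabolites <- function(x) { stopifnot(is(x, "StudyBundle")); x@metabolites }

#' @describeIn generateStudy clinical table of a bundle
#' @export
bundleClinical <- function(x) { stopifnot(is(x, "StudyBundle")); x@clinical }

#' @describeIn generateStudy planted-truth record of a bundle
#' @export
bundleTruth <- function(x) { stopifnot(is(x, "StudyBundle")); x@truth }

#' @export
setMethod("show", "StudyBundle", function(object) {
  cat(sprintf("StudyBundle: %d samples | %d taxa | %d metabolites | %d clinical variables\n",
      nrow(tableValues(object@counts)), ncol(tableValues(object@counts)),
      ncol(tableValues(object@metabolites)), ncol(object@clinical) - 1L))
  cat("groups:", paste(sprintf("%s=%d", names(table(object@clinical$group)),
      table(object@clinical$group)), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# Chemometric models
# ---------------------------------------------------------------------------

#' PCAModel: SVD-based principal component analysis
#'
#' @slot loadings p x k orthonormal loading matrix (sign-fixed: the
#'   largest-magnitude entry of each column is positive).
#' @slot scores n x k score matrix.
#' @slot varianceFractions fraction of total variance per component.
#' @slot centers,scales the autoscaling transform used upstream (may be
#'   length 0 when the input was pre-scaled).
#' @exportClass PCAModel
setClass("PCAModel",
  representation(loadings = "matrix", scores = "matrix",
                 varianceFractions = "numeric",
                 centers = "numeric", scales = "numeric"))

setValidity("PCAModel", function(object) {
  G <- crossprod(object@loadings)
  msg <- character()
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    msg <- c(msg, "loading columns must be orthonormal")
  f <- object@varianceFractions
  if (any(f < -1e-12) || sum(f) > 1 + 1e-8)
    msg <- c(msg, "variance fractions must be in [0,1] and sum <= 1")
  if (is.unsorted(rev(f), strictly = FALSE) && any(diff(f) > 1e-12))
    msg <- c(msg, "variance fractions must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d components over %d variables\n",
      ncol(object@loadings), nrow(object@loadings)))
  cat("variance fractions:",
      paste(sprintf("%.1f%%", 100 * object@varianceFractions), collapse = " "),
      "\n")
})

#' PLSModel: NIPALS PLS1 discriminant model
#'
#' Binary PLS-DA fitted by NIPALS on a centered 0/1 class indicator. The
#' second element of `classes` is the positive class (coded 1).
#'
#' @slot weights p x A X-weight matrix W (unit columns).
#' @slot xloadings p x A X-loading matrix P.
#' @slot yloadings length-A y-loading vector q.
#' @slot scores n x A X-score matrix T (mutually orthogonal columns).
#' @slot coefficients length-p regression vector for the centered indicator.
#' @slot ssy explained response sum of squares per component.
#' @slot classes length-2 character, c(negative, positive).
#' @slot yMean training mean of the 0/1 indicator.
#' @slot transform parametric description of the preprocessing applied to raw
#'   feature rows before projection (see [applyTransform()]).
#' @exportClass PLSModel
setClass("PLSModel",
  representation(weights = "matrix", xloadings = "matrix",
                 yloadings = "numeric", scores = "matrix",
                 coefficients = "numeric", ssy = "numeric",
                 classes = "character", yMean = "numeric",
                 transform = "list"))

setValidity("PLSModel", function(object) {
  msg <- character()
  TT <- crossprod(object@scores)
  if (length(TT) > 1 && max(abs(TT - diag(diag(TT)))) >
      1e-8 * max(diag(TT)))
    msg <- c(msg, "score vectors must be mutually orthogonal")
  if (length(object@classes) != 2L)
    msg <- c(msg, "classes must have length 2")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d component(s), %d features; positive class '%s'\n",
      ncol(object@weights), nrow(object@weights), object@classes[2L]))
})

# ---------------------------------------------------------------------------
# Fusion / validation results
# ---------------------------------------------------------------------------

#' FusedBlockSet: Frobenius-normalized, row-wise concatenated blocks
#'
#' @slot fused samples x (sum of block widths) matrix.
#' @slot blockNorms Frobenius norm of each preprocessed block.
#' @slot blockMap named list mapping block name -> column indices in `fused`.
#' @slot transform parametric preprocessing record for out-of-sample rows.
#' @exportClass FusedBlockSet
setClass("FusedBlockSet",
  representation(fused = "matrix", blockNorms = "numeric",
                 blockMap = "list", transform = "list"))

setValidity("FusedBlockSet", function(object) {
  msg <- character()
  cols <- sort(unlist(object@blockMap, use.names = FALSE))
  if (!identical(cols, seq_len(ncol(object@fused))))
    msg <- c(msg, "blockMap must partition the fused columns")
  for (nm in names(object@blockMap)) {
    fn <- sqrt(sum(object@fused[, object@blockMap[[nm]], drop = FALSE]^2))
    if (abs(fn - 1) > 1e-12)
      msg <- c(msg, sprintf("block '%s' is not Frobenius-normalized", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "FusedBlockSet", function(object) {
  cat(sprintf("FusedBlockSet: %d samples x %d columns; blocks: %s\n",
      nrow(object@fused), ncol(object@fused),
      paste(sprintf("%s(%d)", names(object@blockMap),
                    lengths(object@blockMap)), collapse = ", ")))
})

#' RDCVResult: repeated double cross-validation output
#'
#' @slot merits data.frame with one row per repeat (accuracy, sensitivity,
#'   specificity in percent).
#' @slot meritSummary named numeric: mean and SD of each figure of merit.
#' @slot vip repeats x features VIP matrix from the per-repeat refits.
#' @slot chosenA repeats x outer-folds matrix of selected component counts.
#' @slot predictions data.frame of pooled out-of-fold predictions
#'   (repeat, sample, truth, predicted, score).
#' @slot config the RDCV configuration used.
#' @exportClass RDCVResult
setClass("RDCVResult",
  representation(merits = "data.frame", meritSummary = "numeric",
                 vip = "matrix", chosenA = "matrix",
                 predictions = "data.frame", config = "list"))

setValidity("RDCVResult", function(object) {
  msg <- character()
  if (nrow(object@merits) != nrow(object@vip))
    msg <- c(msg, "one VIP row per repeat required")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "RDCVResult", function(object) {
  s <- object@meritSummary
  cat(sprintf("RDCVResult: %d repeats, %d outer folds\n",
              nrow(object@merits), ncol(object@chosenA)))
  cat(sprintf("  accuracy    %.1f +/- %.1f\n", s["accuracy_mean"], s["accuracy_sd"]))
  cat(sprintf("  sensitivity %.1f +/- %.1f\n", s["sensitivity_mean"], s["sensitivity_sd"]))
  cat(sprintf("  specificity %.1f +/- %.1f\n", s["specificity_mean"], s["specificity_sd"]))
})

#' @describeIn rdcv per-repeat figures of merit
#' @export
rdcvMerits <- function(x) { stopifnot(is(x, "RDCVResult")); x@merits }

#' @describeIn rdcv mean/SD summary of the figures of merit
#' @export
rdcvMeritSummary <- function(x) { stopifnot(is(x, "RDCVResult")); x@meritSummary }

#' @describeIn rdcv repeats x features VIP matrix
#' @export
rdcvVip <- function(x) { stopifnot(is(x, "RDCVResult")); x@vip }

#' @describeIn rdcv repeats x outer-folds chosen component counts
#' @export
rdcvChosenA <- function(x) { stopifnot(is(x, "RDCVResult")); x@chosenA }

#' @describeIn rdcv pooled out-of-fold predictions
#' @export
rdcvPredictions <- function(x) { stopifnot(is(x, "RDCVResult")); x@predictions }

#' PermutationResult: label-permutation null of the figures of merit
#'
#' @slot observed named numeric (accuracy, sensitivity, specificity, percent).
#' @slot nullDistribution n_perm x 3 matrix of permuted figures of merit.
#' @slot p named numeric empirical p per metric (add-one estimator).
#' @slot nPerm number of permutations.
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(observed = "numeric", nullDistribution = "matrix",
                 p = "numeric", nPerm = "numeric"))

setValidity("PermutationResult", function(object) {
  msg <- character()
  lo <- 1 / (object@nPerm + 1)
  if (any(object@p < lo - 1e-12 | object@p > 1 + 1e-12))
    msg <- c(msg, "p must lie in [1/(n_perm+1), 1]")
  if (nrow(object@nullDistribution) != object@nPerm)
    msg <- c(msg, "null distribution must have n_perm rows")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %d permutations\n", object@nPerm))
  for (m in names(object@observed))
    cat(sprintf("  %-12s observed %.1f, p = %.4g\n", m, object@observed[m],
                object@p[m]))
})
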