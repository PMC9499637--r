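# Autoscaling, PCA, NIPALS PLS1-DA, VIP, classification figures of merit.

#' Autoscale a matrix
#'
#' Centers every column at its mean and scales it by its standard deviation
#' (n-1 denominator). Zero-variance columns are dropped with a warning (an
#' error if none remain). The returned transform is re-applied to
#' out-of-sample rows with [applyTransform()], never re-estimated.
#'
#' @param x numeric matrix.
#' @return list with `scaled` (matrix of kept columns, mean 0, SD 1),
#'   `centers`, `scales`, `kept` (column indices kept), and `transform`.
#' @examples
#' autoscale(cbind(a = c(1, 2, 3)))$scaled
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  centers <- colMeans(x)
  xc <- x - rep(centers, each = n)        # two-pass: exact 0 for constants
  scales <- sqrt(colSums(xc * xc) / (n - 1))
  kept <- which(scales > 1e-12)
  if (!length(kept))
    stop("every column has zero variance", call. = FALSE)
  if (length(kept) < ncol(x))
    warning(ncol(x) - length(kept), " zero-variance column(s) dropped")
  scaled <- xc[, kept, drop = FALSE] * rep(1 / scales[kept], each = n)
  tr <- list(type = "autoscale", centers = centers[kept],
             scales = scales[kept], kept = kept, p = ncol(x))
  list(scaled = scaled, centers = centers[kept], scales = scales[kept],
       kept = kept, transform = tr)
}

#' Apply a stored preprocessing transform to new rows
#'
#' Supports `"identity"`, `"autoscale"` (training centers/scales, training
#' column selection) and `"blocks"` (per-block autoscale then division by the
#' training-block Frobenius norm, then concatenation).
#'
#' @param transform transform record from [autoscale()], [fuseBlocks()] or a
#'   fitted model.
#' @param x new raw data: a matrix, or a named list of block matrices for the
#'   `"blocks"` type.
#' @return transformed matrix.
#' @export
applyTransform <- function(transform, x) {
  switch(transform$type,
    identity = as.matrix(x),
    autoscale = {
      x <- as.matrix(x)
      if (ncol(x) != transform$p)
        stop("expected ", transform$p, " columns, got ", ncol(x),
             call. = FALSE)
      n <- nrow(x)
      (x[, transform$kept, drop = FALSE] -
         rep(transform$centers, each = n)) *
        rep(1 / transform$scales, each = n)
    },
    blocks = {
      if (!is.list(x) || is.null(names(x)))
        stop("'blocks' transform needs a named list of matrices",
             call. = FALSE)
      parts <- lapply(names(transform$blocks), function(nm) {
        b <- transform$blocks[[nm]]
        applyTransform(b$inner, x[[nm]]) / b$fnorm
      })
      out <- do.call(cbind, parts)
      colnames(out) <- transform$colnames
      out
    },
    stop("unknown transform type '", transform$type, "'", call. = FALSE))
}

#' Principal component analysis (SVD)
#'
#' Expects pre-scaled input (see [autoscale()]). Scores are `X %*% loadings`;
#' variance fractions are the eigenvalue shares of the full spectrum. The
#' sign of each component is fixed by forcing its largest-magnitude loading
#' entry positive, so reruns are byte-identical.
#'
#' @param xScaled numeric matrix (columns centered).
#' @param k number of components, `k <= min(n-1, p)`.
#' @return a [PCAModel-class].
#' @export
pcaFit <- function(xScaled, k = 2) {
  x <- as.matrix(xScaled)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (k > kmax) stop("k must be <= min(n-1, p) = ", kmax, call. = FALSE)
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest |loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  scores <- x %*% load
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(k))
  new("PCAModel", loadings = load, scores = scores,
      varianceFractions = ev[seq_len(k)] / sum(ev),
      centers = numeric(0), scales = numeric(0))
}

# Core NIPALS PLS1: X (n x p, preprocessed), y centered response vector.
# Returns W, P (p x A), q (A), T (n x A), ssy (A).
nipalsPls1 <- function(x, y, ncomp) {
  n <- nrow(x); p <- ncol(x)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp); ssy <- numeric(ncomp)
  Xd <- x; yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("component ", a, " exceeds the rank of X", call. = FALSE)
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12)
      stop("component ", a, " exceeds the rank of X", call. = FALSE)
    pl <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - t * qa
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t
    q[a] <- qa; ssy[a] <- qa^2 * tt
  }
  list(W = W, P = P, q = q, T = Tm, ssy = ssy)
}

#' Fit a PLS-DA model (NIPALS PLS1 on a centered class indicator)
#'
#' The binary labels are coded 0/1 (positive class = 1) and centered; X is
#' expected already preprocessed (autoscaled, or Frobenius-fused blocks). A
#' transform record may be supplied so that [plsdaPredict()] can take raw
#' feature rows.
#'
#' @param xScaled preprocessed numeric matrix (n x p).
#' @param labels two-class labels, length n.
#' @param ncomp number of latent components A (>= 1, <= rank of X).
#' @param positiveClass which class is coded 1 (default: second factor
#'   level).
#' @param transform preprocessing record applied to new raw rows at
#'   prediction time (default `"identity"`: prediction input is expected
#'   already preprocessed).
#' @return a [PLSModel-class].
#' @export
plsdaFit <- function(xScaled, labels, ncomp, positiveClass = NULL,
                     transform = list(type = "identity")) {
  x <- as.matrix(xScaled)
  f <- binaryLabels(labels, positiveClass)
  if (length(f) != nrow(x)) stop("labels length must match rows",
                                 call. = FALSE)
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)
  y01 <- as.numeric(f == levels(f)[2L])
  yMean <- mean(y01)
  fit <- nipalsPls1(x, y01 - yMean, ncomp)
  # b = W (P'W)^-1 q  — regression vector for the centered indicator
  b <- as.numeric(fit$W %*% solve(crossprod(fit$P, fit$W), fit$q))
  rownames(fit$W) <- rownames(fit$P) <- colnames(x)
  new("PLSModel", weights = fit$W, xloadings = fit$P, yloadings = fit$q,
      scores = fit$T, coefficients = b, ssy = fit$ssy,
      classes = levels(f), yMean = yMean, transform = transform)
}

#' Predict classes from a PLS-DA model
#'
#' Applies the stored training transform to the raw rows, computes the
#' continuous predicted indicator, and assigns the positive class iff the
#' prediction is `>= threshold` (ties at the threshold go to the positive
#' class).
#'
#' @param model PLSModel.
#' @param xNew raw feature rows (matrix, or named block list when the model
#'   was fitted on fused blocks).
#' @param threshold decision threshold on the predicted indicator
#'   (default 0.5).
#' @return list with `class` (factor) and `score` (continuous prediction).
#' @export
plsdaPredict <- function(model, xNew, threshold = 0.5) {
  x <- applyTransform(model@transform, xNew)
  if (ncol(x) != nrow(model@weights))
    stop("feature count mismatch: model has ", nrow(model@weights),
         ", input has ", ncol(x), call. = FALSE)
  score <- as.numeric(model@yMean + x %*% model@coefficients)
  cls <- factor(ifelse(score >= threshold, model@classes[2L],
                       model@classes[1L]), levels = model@classes)
  list(class = cls, score = score)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * (w_ja / ||w_a||)^2 / sum_a SSY_a)`; the
#' squared VIPs always sum to p.
#'
#' @param model fitted PLSModel.
#' @return named numeric vector of per-feature VIP scores.
#' @export
vip <- function(model) {
  stopifnot(is(model, "PLSModel"))
  W <- model@weights
  ssy <- model@ssy
  tot <- sum(ssy)
  if (tot <= 0) stop("zero total explained response sum of squares",
                     call. = FALSE)
  w2 <- sweep(W, 2L, sqrt(colSums(W^2)), "/")^2
  v <- sqrt(nrow(W) * as.numeric(w2 %*% ssy) / tot)
  names(v) <- rownames(W)
  v
}

#' Classification figures of merit
#'
#' Accuracy, sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`, all in
#' percent.
#'
#' @param yTrue,yPred equal-length label vectors; `yTrue` must contain both
#'   classes.
#' @param positiveClass the class counted as positive.
#' @return named numeric: `accuracy`, `sensitivity`, `specificity` (percent).
#' @examples
#' classificationMetrics(c("a","a","b","b"), c("a","b","b","b"), "a")
#' @export
classificationMetrics <- function(yTrue, yPred, positiveClass) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch", call. = FALSE)
  if (length(unique(yTrue)) < 2L)
    stop("yTrue must contain both classes", call. = FALSE)
  pos <- yTrue == positiveClass
  tp <- sum(pos & yPred == positiveClass)
  fn <- sum(pos & yPred != positiveClass)
  tn <- sum(!pos & yPred != positiveClass)
  fp <- sum(!pos & yPred == positiveClass)
  c(accuracy = 100 * (tp + tn) / length(yTrue),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}
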