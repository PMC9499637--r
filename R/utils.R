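# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions never
#' disturb the caller's random-number stream.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic substream seed
#'
#' Expands one master seed into independent per-component seeds so adding a
#' generated table does not perturb the draws of the others. Linear
#' congruential step keeps results inside the 32-bit integer range.
#'
#' @param seed master seed.
#' @param stream small non-negative integer identifying the substream.
#' @noRd
deriveSeed <- function(seed, stream) {
  m <- 2147483647          # 2^31 - 1 (Mersenne prime modulus)
  s <- (abs(as.double(seed)) %% m)
  s <- (s * 48271 + (as.double(stream) %% m) + 11111) %% m
  s <- (s * 69621 + 11111) %% m
  as.integer(s)
}

assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# Two-level factor coercion with an explicit positive class. Returns a factor
# whose second level is the positive class.
binaryLabels <- function(labels, positiveClass = NULL) {
  f <- factor(labels)
  if (nlevels(f) != 2L)
    stop("labels must contain exactly two classes, got ",
         nlevels(f), call. = FALSE)
  if (is.null(positiveClass)) positiveClass <- levels(f)[2L]
  if (!positiveClass %in% levels(f))
    stop("positiveClass '", positiveClass, "' not among labels", call. = FALSE)
  factor(f, levels = c(setdiff(levels(f), positiveClass), positiveClass))
}

# rdirichlet via gamma draws; alpha a positive vector.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1   # degenerate underflow guard
  g / sum(g)
}
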