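# Synthetic study-bundle generator emulating a three-group paired
# microbiome/metabolome cohort design.

#' Default clinical-variable distribution settings
#'
#' Marginal distributions for the nine clinical variables (units: anti-GAD,
#' IAA, IA-2 in U/mL; HbA1c mmol/mol; cholesterol mg/dL; insulin need IU/kg;
#' blood pH unitless; age years; c-peptide ng/mL), parameterized from the
#' cohort means and SDs of a pediatric T1D-onset population, plus the target
#' pairwise Pearson correlations planted between them. Blood pH follows a
#' two-component normal mixture straddling the 7.32 acidosis cut-off
#' (components 7.18 (sd 0.08) and 7.38 (sd 0.04) with weights 0.54/0.46, the
#' observed below/at-or-above-7.32 strata proportions).
#'
#' @return list with `marginals` (named list of distribution specs) and
#'   `correlations` (data.frame var1, var2, r).
#' @export
defaultClinicalSpec <- function() {
  list(
    marginals = list(
      anti_GAD = list(dist = "lognormal", meanlog = 3.28, sdlog = 0.6),
      IAA = list(dist = "normal", mean = 6.38, sd = 3.56, min = 0),
      IA2 = list(dist = "lognormal", meanlog = 2.5, sdlog = 1.2),
      HbA1c = list(dist = "normal", mean = 102.4, sd = 22.7, min = 0),
      cholesterol = list(dist = "normal", mean = 155.7, sd = 49.9, min = 0),
      insulin_need = list(dist = "normal", mean = 0.84, sd = 0.25, min = 0),
      blood_pH = list(dist = "mixture", means = c(7.18, 7.38),
                      sds = c(0.08, 0.04), weights = c(0.54, 0.46)),
      age = list(dist = "normal", mean = 9.52, sd = 3.21, min = 2),
      c_peptide = list(dist = "lognormal", meanlog = -1.32, sdlog = 0.55)),
    correlations = data.frame(
      var1 = c("insulin_need", "insulin_need", "anti_GAD"),
      var2 = c("HbA1c", "blood_pH", "HbA1c"),
      r = c(0.33, -0.33, -0.36)))
}

# Default planted effects: a handful of abundant taxa shifted in the case
# and/or sibling groups and a few metabolites shifted in the case group,
# plus one strong negative taxon-metabolite link.
defaultPlantedTaxa <- function() {
  data.frame(
    taxon = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L, 5L, 6L),
    group = c(rep("T1D", 4L), rep("sibling", 4L), "T1D", "T1D"),
    log2fc = c(1, 1, -1, -1, 1, 1, -1, -1, 1, -1))
}

defaultPlantedMetabolites <- function() {
  data.frame(
    metabolite = c(1L, 2L, 3L, 4L, 5L, 6L),
    group = "T1D",
    shift = c(0.8, 0.8, -0.8, -0.8, -0.8, -0.8))
}

defaultLinks <- function() {
  data.frame(taxon = 4L, metabolite = 1L, r = -0.68)
}

#' Simulation parameters for a synthetic study bundle
#'
#' The defaults are the emulated study conditions: three groups of 52/17/57
#' samples, per-sample library sizes log-normal with mean 75,154 reads,
#' overdispersed Dirichlet-multinomial counts, 37 metabolites, planted
#' differential taxa/metabolites, one planted taxon-metabolite correlation
#' (r = -0.68), and the clinical table of [defaultClinicalSpec()].
#'
#' @param nPerGroup named integer vector of group sizes (each >= 2).
#' @param nTaxa number of taxa.
#' @param nMetabolites number of metabolites.
#' @param librarySizeMean mean reads per sample.
#' @param librarySizeCV coefficient of variation of the library size.
#' @param baselineConcentration Dirichlet concentration (total alpha) of the
#'   per-sample composition around its group composition; smaller values
#'   give stronger overdispersion.
#' @param plantedTaxa data.frame (taxon, group, log2fc) of planted log2 fold
#'   changes, or NULL for none.
#' @param plantedMetabolites data.frame (metabolite, group, shift) of
#'   standardized (log-scale SD units) mean shifts, or NULL.
#' @param taxonMetaboliteLinks data.frame (taxon, metabolite, r) of target
#'   Pearson correlations in \[-1, 1\], or NULL.
#' @param clinicalSpec see [defaultClinicalSpec()].
#' @param caseGroup group whose rows keep the disease-specific clinical
#'   variables (others are set missing).
#' @param seed master seed; independent substreams are derived per table.
#' @return validated parameter list of class `SimulationParams`.
#' @export
simulationParams <- function(nPerGroup = c(T1D = 52, sibling = 17, CTRL = 57),
                             nTaxa = 150, nMetabolites = 37,
                             librarySizeMean = 75154, librarySizeCV = 0.3,
                             baselineConcentration = 200,
                             plantedTaxa = defaultPlantedTaxa(),
                             plantedMetabolites = defaultPlantedMetabolites(),
                             taxonMetaboliteLinks = defaultLinks(),
                             clinicalSpec = defaultClinicalSpec(),
                             caseGroup = names(nPerGroup)[1L],
                             seed = 1) {
  if (is.null(names(nPerGroup)) || any(!nzchar(names(nPerGroup))))
    stop("'nPerGroup' must be a named vector", call. = FALSE)
  if (any(nPerGroup < 2)) stop("group sizes must be >= 2", call. = FALSE)
  assertScalarNumber(librarySizeMean, "librarySizeMean", positive = TRUE)
  assertScalarNumber(librarySizeCV, "librarySizeCV", positive = TRUE)
  assertScalarNumber(baselineConcentration, "baselineConcentration",
                     positive = TRUE)
  groups <- names(nPerGroup)
  checkPlanted <- function(df, idxCol, idxMax, valCol) {
    if (is.null(df)) return(invisible(NULL))
    if (any(df[[idxCol]] < 1L | df[[idxCol]] > idxMax))
      stop("planted ", idxCol, " index out of range", call. = FALSE)
    if (!all(df$group %in% groups))
      stop("planted effect references unknown group", call. = FALSE)
    if (any(!is.finite(df[[valCol]])))
      stop("planted ", valCol, " must be finite", call. = FALSE)
  }
  checkPlanted(plantedTaxa, "taxon", nTaxa, "log2fc")
  checkPlanted(plantedMetabolites, "metabolite", nMetabolites, "shift")
  if (!is.null(taxonMetaboliteLinks)) {
    lk <- taxonMetaboliteLinks
    if (any(lk$taxon < 1L | lk$taxon > nTaxa) ||
        any(lk$metabolite < 1L | lk$metabolite > nMetabolites))
      stop("link references a missing taxon or metabolite", call. = FALSE)
    if (any(abs(lk$r) > 1)) stop("|target r| must be <= 1", call. = FALSE)
  }
  R <- clinicalTargetMatrix(clinicalSpec)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("clinical target correlation matrix is not positive semidefinite",
         call. = FALSE)
  structure(list(nPerGroup = nPerGroup, nTaxa = as.integer(nTaxa),
                 nMetabolites = as.integer(nMetabolites),
                 librarySizeMean = librarySizeMean,
                 librarySizeCV = librarySizeCV,
                 baselineConcentration = baselineConcentration,
                 plantedTaxa = plantedTaxa,
                 plantedMetabolites = plantedMetabolites,
                 taxonMetaboliteLinks = taxonMetaboliteLinks,
                 clinicalSpec = clinicalSpec, caseGroup = caseGroup,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

# Assemble the symmetric unit-diagonal target correlation matrix.
clinicalTargetMatrix <- function(spec) {
  vars <- names(spec$marginals)
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  cr <- spec$correlations
  if (!is.null(cr) && nrow(cr)) {
    if (!all(c(cr$var1, cr$var2) %in% vars))
      stop("correlation references unknown clinical variable", call. = FALSE)
    if (any(abs(cr$r) > 1)) stop("|target r| must be <= 1", call. = FALSE)
    for (i in seq_len(nrow(cr)))
      R[cr$var1[i], cr$var2[i]] <- R[cr$var2[i], cr$var1[i]] <- cr$r[i]
  }
  R
}

groupVector <- function(params)
  factor(rep(names(params$nPerGroup), params$nPerGroup),
         levels = names(params$nPerGroup))

sampleIdVector <- function(params) {
  g <- groupVector(params)
  ave <- stats::ave(seq_along(g), g, FUN = seq_along)
  sprintf("%s_%02d", as.character(g), ave)
}

# Group-level compositions: baseline (rank-abundance ordered log-normal
# draws) with planted log2 fold changes applied and renormalized.
groupCompositions <- function(params) {
  base <- withSeed(deriveSeed(params$seed, 1L), {
    w <- exp(stats::rnorm(params$nTaxa, 0, 1.5))
    sort(w, decreasing = TRUE) / sum(w)
  })
  comps <- list()
  for (g in names(params$nPerGroup)) {
    pg <- base
    pt <- params$plantedTaxa
    if (!is.null(pt)) {
      sel <- pt$group == g
      if (any(sel))
        pg[pt$taxon[sel]] <- pg[pt$taxon[sel]] * 2^pt$log2fc[sel]
    }
    comps[[g]] <- pg / sum(pg)
  }
  comps
}

#' Generate a synthetic taxa count table
#'
#' Per sample: a library size drawn from a log-normal with the requested
#' mean and CV (rounded, floor 1), and counts drawn multinomially from a
#' Dirichlet draw around the group composition
#' (`alpha = baselineConcentration * composition`), giving overdispersed
#' (Dirichlet-multinomial) counts. The baseline composition is a
#' rank-abundance-ordered normalized log-normal profile; group compositions
#' apply the planted log2 fold changes and renormalize. Deterministic given
#' the seed.
#'
#' @param params [simulationParams()].
#' @return FeatureTable of counts with taxa `taxon_001`, ...
#' @export
generateCounts <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  comps <- groupCompositions(params)
  g <- groupVector(params)
  n <- length(g)
  sdlog <- sqrt(log(1 + params$librarySizeCV^2))
  meanlog <- log(params$librarySizeMean) - sdlog^2 / 2
  counts <- withSeed(deriveSeed(params$seed, 2L), {
    libs <- pmax(1, round(stats::rlnorm(n, meanlog, sdlog)))
    t(vapply(seq_len(n), function(i) {
      p <- rdirichlet1(params$baselineConcentration *
                         comps[[as.character(g[i])]])
      as.numeric(stats::rmultinom(1L, size = libs[i], prob = p))
    }, numeric(params$nTaxa)))
  })
  dimnames(counts) <- list(sampleIdVector(params),
                           sprintf("taxon_%03d", seq_len(params$nTaxa)))
  # guard: every sample keeps at least one read
  featureTable(counts)
}

# Standardized log-scale CSS abundance of one taxon (the scale on which
# taxon-metabolite links are planted).
standardizedCssLog <- function(countsMat, taxon) {
  f <- cssFactors(countsMat, 0.5)
  v <- log1p(countsMat[, taxon] / f * 1000)
  s <- stats::sd(v)
  if (s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Generate a synthetic metabolite concentration table
#'
#' Log-normal marginals with per-metabolite location and spread; planted
#' group shifts are added on the log scale in SD units. For every
#' taxon-metabolite link the metabolite's standardized log value is the
#' blend `r * s + sqrt(1 - r^2) * noise` of the linked taxon's standardized
#' CSS-normalized log abundance `s` and independent noise, which attains the
#' target Pearson correlation `r` (on the log scale) in expectation.
#'
#' @param params [simulationParams()].
#' @param counts the generated count FeatureTable; required when links are
#'   planted.
#' @return FeatureTable of positive concentrations (umol/g semantics).
#' @export
generateMetabolites <- function(params, counts = NULL) {
  stopifnot(inherits(params, "SimulationParams"))
  lk <- params$taxonMetaboliteLinks
  if (!is.null(lk) && nrow(lk) && is.null(counts))
    stop("counts must be supplied when links are planted", call. = FALSE)
  g <- groupVector(params)
  n <- length(g)
  m <- params$nMetabolites
  vals <- withSeed(deriveSeed(params$seed, 3L), {
    meanlog <- stats::runif(m, log(0.5), log(20))
    sdlog <- stats::runif(m, 0.3, 0.8)
    z <- matrix(stats::rnorm(n * m), n, m)
    if (!is.null(lk) && nrow(lk)) {
      cm <- tableValues(counts)
      for (i in seq_len(nrow(lk))) {
        s <- standardizedCssLog(cm, lk$taxon[i])
        r <- lk$r[i]
        z[, lk$metabolite[i]] <- r * s + sqrt(1 - r^2) * z[, lk$metabolite[i]]
      }
    }
    pm <- params$plantedMetabolites
    if (!is.null(pm) && nrow(pm)) {
      for (i in seq_len(nrow(pm)))
        z[g == pm$group[i], pm$metabolite[i]] <-
          z[g == pm$group[i], pm$metabolite[i]] + pm$shift[i]
    }
    exp(rep(meanlog, each = n) + rep(sdlog, each = n) * z)
  })
  dimnames(vals) <- list(sampleIdVector(params),
                         sprintf("metab_%02d", seq_len(m)))
  featureTable(vals)
}

marginalQuantile <- function(spec, p) {
  switch(spec$dist,
    normal = {
      if (!is.null(spec$min)) {
        p0 <- stats::pnorm(spec$min, spec$mean, spec$sd)
        stats::qnorm(p0 + p * (1 - p0), spec$mean, spec$sd)
      } else stats::qnorm(p, spec$mean, spec$sd)
    },
    lognormal = stats::qlnorm(p, spec$meanlog, spec$sdlog),
    mixture = {
      cdf <- function(x) sum(spec$weights *
        stats::pnorm(x, spec$means, spec$sds))
      lo <- min(spec$means - 8 * spec$sds)
      hi <- max(spec$means + 8 * spec$sds)
      vapply(p, function(pp)
        stats::uniroot(function(x) cdf(x) - pp, c(lo, hi),
                       tol = 1e-10)$root, numeric(1L))
    },
    stop("unknown marginal distribution '", spec$dist, "'", call. = FALSE))
}

#' Generate a synthetic clinical table
#'
#' Gaussian copula: a multivariate normal draw with the target correlation
#' matrix is mapped through the normal CDF and each column is transformed by
#' the inverse CDF of its specified marginal. Disease-specific variables
#' (all but age and cholesterol) are set missing outside the case group when
#' several groups are present.
#'
#' @param params [simulationParams()].
#' @return data.frame with row names = sample IDs, a `group` factor column
#'   and the nine clinical variables.
#' @export
generateClinical <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  spec <- params$clinicalSpec
  R <- clinicalTargetMatrix(spec)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target correlation matrix is not positive semidefinite",
         call. = FALSE)
  g <- groupVector(params)
  n <- length(g)
  vars <- names(spec$marginals)
  X <- withSeed(deriveSeed(params$seed, 4L), {
    Z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = R)
    U <- stats::pnorm(Z)
    vapply(seq_along(vars), function(j)
      marginalQuantile(spec$marginals[[j]], U[, j]), numeric(n))
  })
  colnames(X) <- vars
  df <- data.frame(group = g, X, row.names = sampleIdVector(params))
  if (nlevels(g) > 1L) {
    diseaseVars <- setdiff(vars, c("age", "cholesterol"))
    diseaseVars <- intersect(diseaseVars, colnames(df))
    df[df$group != params$caseGroup, diseaseVars] <- NA_real_
  }
  df
}

#' Generate a complete synthetic study bundle
#'
#' Draws the count, metabolite and clinical tables from independent
#' substreams of the master seed (so regenerating one table never perturbs
#' the others) and records the planted truth.
#'
#' @param params [simulationParams()].
#' @return a [StudyBundle-class].
#' @export
generateStudy <- function(params = simulationParams()) {
  counts <- generateCounts(params)
  metabolites <- generateMetabolites(params, counts)
  clinical <- generateClinical(params)
  truth <- list(plantedTaxa = params$plantedTaxa,
                plantedMetabolites = params$plantedMetabolites,
                taxonMetaboliteLinks = params$taxonMetaboliteLinks,
                clinicalCorrelations = params$clinicalSpec$correlations,
                caseGroup = params$caseGroup)
  new("StudyBundle", counts = counts, metabolites = metabolites,
      clinical = clinical, truth = truth)
}

#' Write a study bundle to disk
#'
#' Counts, metabolites and clinical tables as TSV (samples as rows, first
#' column the sample ID); the planted-truth record as JSON.
#'
#' @param bundle StudyBundle.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudy <- function(bundle, dir) {
  stopifnot(is(bundle, "StudyBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metabolites = file.path(dir, "metabolites.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  writeFeatureTable(bundleCounts(bundle), paths["counts"])
  writeFeatureTable(bundleMetabolites(bundle), paths["metabolites"])
  cl <- bundleClinical(bundle)
  utils::write.table(data.frame(sample_id = rownames(cl), cl,
                                check.names = FALSE),
                     paths["clinical"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(bundleTruth(bundle), paths["truth"],
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}
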