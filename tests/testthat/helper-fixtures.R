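# Shared fixture builders; everything generated in code at test time.

noPlanted <- list(plantedTaxa = NULL, plantedMetabolites = NULL,
                  taxonMetaboliteLinks = NULL)

# Two-group parameter set with no planted effects (null condition).
nullParams <- function(n1 = 40, n2 = 40, nTaxa = 150, nMetabolites = 10,
                       libMean = 75154, seed = 1) {
  do.call(simulationParams,
          c(list(nPerGroup = c(A = n1, B = n2), nTaxa = nTaxa,
                 nMetabolites = nMetabolites, librarySizeMean = libMean,
                 caseGroup = "A", seed = seed),
            noPlanted))
}

# Gaussian-like feature matrix with planted standardized log-scale mean
# shifts: built from the metabolite generator, returned on the log scale so
# the planted shifts are exactly `shift` SDs. Labels: A (null) / B (shifted).
plantedMatrix <- function(nPerGroup = 60, p = 200, planted = 1:10,
                          shift = 1.5, seed = 1) {
  pm <- if (length(planted))
    data.frame(metabolite = planted, group = "B", shift = shift) else NULL
  params <- simulationParams(
    nPerGroup = c(A = nPerGroup, B = nPerGroup), nTaxa = 5,
    nMetabolites = p, plantedTaxa = NULL, plantedMetabolites = pm,
    taxonMetaboliteLinks = NULL, caseGroup = "B", seed = seed)
  tab <- generateMetabolites(params)
  labels <- factor(rep(c("A", "B"), each = nPerGroup))
  list(x = log(tableValues(tab)), labels = labels,
       planted = colnames(tableValues(tab))[planted])
}

# Small count table with hand-set values for filter/CSS oracles.
toyCounts <- function(values) {
  featureTable(matrix(values, nrow = length(values) / ncol(as.matrix(values)),
                      byrow = FALSE))
}

lightConfig <- function(seed = 1, repeats = 1, maxComp = 2)
  rdcvConfig(outerFolds = 3, innerFolds = 2, repeats = repeats,
             maxComp = maxComp, seed = seed)

# Tiny study bundle for pipeline tests.
tinyBundle <- function(seed = 1) {
  generateStudy(simulationParams(
    nPerGroup = c(T1D = 12, sibling = 4, CTRL = 12), nTaxa = 40,
    nMetabolites = 12, librarySizeMean = 5000, seed = seed))
}

tinyPipelineConfig <- function(outDir, seed = 1) {
  cfg <- defaultPipelineConfig(outDir = outDir, seed = seed)
  cfg$simulate <- list(nPerGroup = c(T1D = 12, sibling = 4, CTRL = 12),
                       nTaxa = 40, nMetabolites = 12, librarySizeMean = 5000)
  cfg$permanova$nPerm <- 99
  cfg$rdcv <- list(outerFolds = 3, innerFolds = 2, repeats = 2, maxComp = 3,
                   vipThreshold = 1.15, vipConsistency = 0.5)
  cfg
}
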