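# Synthetic study-bundle generator.

test_that("default cohort design produces 52 + 17 + 57 samples with shared index", {
  b <- generateStudy(simulationParams(seed = 3))
  expect_equal(nrow(tableValues(bundleCounts(b))), 126)
  expect_identical(sampleIds(bundleCounts(b)), sampleIds(bundleMetabolites(b)))
  expect_identical(sampleIds(bundleCounts(b)), rownames(bundleClinical(b)))
  expect_equal(as.vector(table(bundleClinical(b)$group)), c(52, 17, 57))
  expect_true(all(rowSums(tableValues(bundleCounts(b))) > 0))
})

test_that("generation is deterministic in the seed and varies across seeds", {
  p <- simulationParams(seed = 11)
  b1 <- generateStudy(p)
  b2 <- generateStudy(p)
  expect_identical(tableValues(bundleCounts(b1)), tableValues(bundleCounts(b2)))
  expect_identical(tableValues(bundleMetabolites(b1)),
                   tableValues(bundleMetabolites(b2)))
  expect_identical(bundleClinical(b1), bundleClinical(b2))
  b3 <- generateStudy(simulationParams(seed = 12))
  expect_false(identical(tableValues(bundleCounts(b1)),
                         tableValues(bundleCounts(b3))))
  expect_identical(dim(tableValues(bundleCounts(b1))),
                   dim(tableValues(bundleCounts(b3))))
})

test_that("library sizes realize the requested log-normal mean", {
  p <- nullParams(n1 = 250, n2 = 250, nTaxa = 50, seed = 5)
  libs <- rowSums(tableValues(generateCounts(p)))
  expect_lt(abs(mean(libs) / 75154 - 1), 0.05)
})

test_that("planted parameters are validated", {
  expect_error(simulationParams(nPerGroup = c(A = 1, B = 5)), "group sizes")
  expect_error(simulationParams(librarySizeMean = -1), "positive")
  expect_error(
    simulationParams(nPerGroup = c(A = 5, B = 5), nTaxa = 10,
                     nMetabolites = 5, plantedTaxa = NULL,
                     plantedMetabolites = NULL,
                     taxonMetaboliteLinks = data.frame(taxon = 99,
                                                       metabolite = 1,
                                                       r = 0.5)),
    "missing taxon")
  expect_error(
    do.call(simulationParams,
            c(list(nPerGroup = c(A = 5, B = 5), nTaxa = 10,
                   taxonMetaboliteLinks = data.frame(taxon = 1,
                                                     metabolite = 1, r = 1.5),
                   plantedTaxa = NULL, plantedMetabolites = NULL),
              list(seed = 1))),
    "target r")
})

test_that("planted taxon-metabolite link attains the target correlation", {
  lk <- data.frame(taxon = 2L, metabolite = 3L, r = -0.68)
  p <- do.call(simulationParams,
               c(list(nPerGroup = c(A = 150, B = 150), nTaxa = 40,
                      nMetabolites = 10, taxonMetaboliteLinks = lk,
                      plantedTaxa = NULL, plantedMetabolites = NULL,
                      caseGroup = "A", seed = 8)))
  b <- generateStudy(p)
  s <- scale(log1p(tableValues(cssNormalize(bundleCounts(b), 0.5))[, 2]))
  r <- cor(as.numeric(s), log(tableValues(bundleMetabolites(b))[, 3]))
  expect_lt(abs(r - (-0.68)), 0.1)
})

test_that("a zero-r link leaves the metabolite independent of the taxon", {
  lk0 <- data.frame(taxon = 1L, metabolite = 1L, r = 0)
  base <- list(nPerGroup = c(A = 100, B = 100), nTaxa = 20, nMetabolites = 5,
               plantedTaxa = NULL, plantedMetabolites = NULL, caseGroup = "A",
               seed = 21)
  pLink <- do.call(simulationParams, c(base, list(taxonMetaboliteLinks = lk0)))
  pFree <- do.call(simulationParams, c(base, list(taxonMetaboliteLinks = NULL)))
  counts <- generateCounts(pLink)
  expect_identical(tableValues(generateMetabolites(pLink, counts)),
                   tableValues(generateMetabolites(pFree, counts)))
})

test_that("clinical copula hits the planted pairwise correlations", {
  p <- do.call(simulationParams,
               c(list(nPerGroup = c(G = 1000), nTaxa = 10, seed = 42),
                 noPlanted))
  cl <- generateClinical(p)
  expect_lt(abs(cor(cl$insulin_need, cl$HbA1c) - 0.33), 0.07)
  expect_lt(abs(cor(cl$insulin_need, cl$blood_pH) - (-0.33)), 0.07)
  expect_lt(abs(cor(cl$anti_GAD, cl$HbA1c) - (-0.36)), 0.07)
})

test_that("identity target matrix gives near-independent clinical variables", {
  # n large enough that the max over the 36 variable pairs is a stable
  # statistic rather than a coin flip against the 0.1 bound
  spec <- defaultClinicalSpec()
  spec$correlations <- NULL
  p <- do.call(simulationParams,
               c(list(nPerGroup = c(G = 4000), clinicalSpec = spec,
                      seed = 4), noPlanted))
  cl <- generateClinical(p)
  cc <- cor(as.matrix(cl[, setdiff(colnames(cl), "group")]))
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.1)
})

test_that("blood pH is bimodal around 7.32 and within physiological range", {
  p <- do.call(simulationParams,
               c(list(nPerGroup = c(G = 1000), nTaxa = 10, seed = 13),
                 noPlanted))
  ph <- generateClinical(p)$blood_pH
  expect_true(all(ph > 6.5 & ph < 8.0))
  # both mixture components populated in roughly the design proportions
  expect_gt(mean(ph >= 7.32), 0.3)
  expect_gt(mean(ph < 7.32), 0.3)
})

test_that("non-case groups carry missing disease variables, shared age", {
  b <- generateStudy(simulationParams(seed = 2))
  cl <- bundleClinical(b)
  expect_true(all(is.na(cl$anti_GAD[cl$group != "T1D"])))
  expect_true(all(is.finite(cl$anti_GAD[cl$group == "T1D"])))
  expect_true(all(is.finite(cl$age)))
})

test_that("truth record passes through the planted design", {
  pt <- data.frame(taxon = c(3L, 7L), group = "A", log2fc = c(1, -1))
  p <- simulationParams(nPerGroup = c(A = 5, B = 5), nTaxa = 10,
                        nMetabolites = 4, plantedTaxa = pt,
                        plantedMetabolites = NULL,
                        taxonMetaboliteLinks = NULL, caseGroup = "A",
                        seed = 1)
  tr <- bundleTruth(generateStudy(p))
  expect_identical(tr$plantedTaxa, pt)
  expect_identical(tr$caseGroup, "A")
})

test_that("null bundles give uniform Kruskal-Wallis p values downstream", {
  pvals <- vapply(seq_len(200), function(i) {
    p <- do.call(simulationParams,
                 c(list(nPerGroup = c(A = 10, B = 10, C = 10), nTaxa = 20,
                        nMetabolites = 2, librarySizeMean = 2000,
                        caseGroup = "A", seed = 1000 + i), noPlanted))
    cm <- tableValues(generateCounts(p))
    rel <- cm[, 1] / rowSums(cm)
    kruskalWallis(rel, rep(c("A", "B", "C"), each = 10))$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("planted two-fold taxa are recovered by Mann-Whitney + Bonferroni", {
  hits <- vapply(seq_len(20), function(i) {
    pt <- data.frame(taxon = 3L, group = "B", log2fc = 1)
    p <- simulationParams(nPerGroup = c(A = 60, B = 60), nTaxa = 50,
                          nMetabolites = 2, plantedTaxa = pt,
                          plantedMetabolites = NULL,
                          taxonMetaboliteLinks = NULL, caseGroup = "B",
                          seed = 3000 + i)
    cm <- tableValues(generateCounts(p))
    rel <- cm / rowSums(cm)
    pv <- vapply(seq_len(50), function(j)
      mannWhitney(rel[1:60, j], rel[61:120, j])$p, numeric(1))
    adjustPvalues(pv, "bonferroni")[3] <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("writeStudy round-trips the tables as TSV + JSON", {
  b <- tinyBundle(seed = 9)
  dir <- withr::local_tempdir()
  paths <- writeStudy(b, dir)
  expect_true(all(file.exists(paths)))
  back <- readFeatureTable(paths[["counts"]])
  expect_equal(tableValues(back), tableValues(bundleCounts(b)))
  tr <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(tr$caseGroup, "T1D")
})
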