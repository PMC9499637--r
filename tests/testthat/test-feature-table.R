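# Feature-table IO, filtering, CSS normalization, aggregation.

test_that("TSV round trip preserves the table in either orientation", {
  m <- matrix(c(1, 0, 5, 2, 3, 4, 0, 7, 9, 1, 2, 6), nrow = 3,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
  ft <- featureTable(m)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(ft, f1)
  expect_equal(tableValues(readFeatureTable(f1)), m)
  # features-as-rows dialect
  f2 <- withr::local_tempfile(fileext = ".tsv")
  tm <- t(m)
  utils::write.table(data.frame(feature_id = rownames(tm), tm,
                                check.names = FALSE),
                     f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(tableValues(readFeatureTable(f2, orientation = "features")), m)
})

test_that("reader rejects duplicate IDs and names the offending negative cell", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t1\t2", "s1\t3\t4"), f)
  expect_error(readFeatureTable(f), "duplicate")
  writeLines(c("sample_id\tf1\tf2", "s1\t1\t-5", "s2\t3\t4"), f)
  expect_error(readFeatureTable(f), "s1.*f2")
})

test_that("abundance/prevalence filter applies both >= rules", {
  # totals 96, 3, 1, 0 of grand total 100; prevalences 1, 0.75, 0.25, 0
  m <- rbind(c(24, 0, 1, 0), c(24, 1, 0, 0), c(24, 1, 0, 0), c(24, 1, 0, 0))
  dimnames(m) <- list(paste0("s", 1:4), paste0("f", 1:4))
  kept <- filterFeatures(featureTable(m))
  expect_identical(featureIds(kept), c("f1", "f2", "f3"))
  expect_identical(attr(kept, "removed"), "f4")
  # no-op thresholds keep everything with positive prevalence rule relaxed
  expect_identical(featureIds(filterFeatures(featureTable(m), 0, 0)),
                   paste0("f", 1:4))
  # all-zero features are always removed at default thresholds
  expect_false("f4" %in% featureIds(kept))
})

test_that("filtering a filtered table is a no-op (idempotence)", {
  p <- nullParams(n1 = 15, n2 = 15, nTaxa = 60, libMean = 5000, seed = 6)
  ft <- generateCounts(p)
  once <- filterFeatures(ft)
  twice <- filterFeatures(once)
  expect_identical(tableValues(once), tableValues(twice))
  expect_length(attr(twice, "removed"), 0)
})

test_that("filtering everything raises an explicit error", {
  m <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(filterFeatures(featureTable(m), minPrevalence = 0.9),
               "every feature")
})

test_that("CSS factors match a brute-force quantile-sum oracle", {
  rows <- list(c(1, 2, 3, 100), c(2, 4, 6, 200, 0), c(5, 5, 5, 5))
  m <- matrix(0, 3, 6, dimnames = list(paste0("s", 1:3), paste0("f", 1:6)))
  for (i in 1:3) m[i, seq_along(rows[[i]])] <- rows[[i]]
  for (q in c(0.25, 0.5, 0.75)) {
    norm <- cssNormalize(featureTable(m), q)
    oracle <- vapply(1:3, function(i) {
      nz <- m[i, m[i, ] > 0]
      sum(m[i, ][m[i, ] <= quantile(nz, q)])
    }, numeric(1))
    expect_equal(unname(attr(norm, "factors")), oracle)
    expect_equal(tableValues(norm), m / oracle * 1000, ignore_attr = TRUE)
  }
})

test_that("CSS normalization is invariant to per-sample count scaling", {
  p <- nullParams(n1 = 5, n2 = 5, nTaxa = 30, libMean = 2000, seed = 2)
  m <- tableValues(generateCounts(p))
  m2 <- m
  m2[3, ] <- m2[3, ] * 7          # rescale one sample
  n1 <- tableValues(cssNormalize(featureTable(m), 0.5))
  n2 <- tableValues(cssNormalize(featureTable(m2), 0.5))
  expect_identical(n1[3, ], n2[3, ])
  expect_identical(n1, tableValues(cssNormalize(featureTable(m * 2), 0.5)))
})

test_that("adaptive CSS quantile reproduces a brute-force grid scan", {
  p <- nullParams(n1 = 10, n2 = 10, nTaxa = 50, libMean = 3000, seed = 14)
  ft <- generateCounts(p)
  got <- suppressWarnings(cssReferenceQuantile(ft))
  m <- tableValues(ft)
  oracle <- NA
  for (l in seq(0.05, 0.95, by = 0.05)) {
    s <- apply(m, 1, function(r) {
      nz <- r[r > 0]
      sum(r[r <= quantile(nz, l)])
    })
    if (median(abs(s - median(s)) / median(s)) > 0.1) { oracle <- l; break }
  }
  if (is.na(oracle)) oracle <- 0.5
  expect_equal(got, oracle)
  expect_lt(got, 0.95)            # heavy-tailed counts trigger early
})

test_that("identical samples trigger the 0.5 fallback with a warning", {
  m <- matrix(rep(c(5, 3, 2, 1), each = 3), nrow = 3,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
  expect_warning(q <- cssReferenceQuantile(featureTable(m)), "fall")
  expect_equal(q, 0.5)
})

test_that("CSS errors on all-zero samples and zero factors", {
  m <- matrix(c(0, 1, 0, 2), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(cssNormalize(featureTable(m), 0.5), "all-zero|factor")
})

test_that("taxonomy aggregation conserves per-sample totals", {
  m <- matrix(c(3, 1, 4, 2, 5, 9, 2, 6), nrow = 2,
              dimnames = list(c("s1", "s2"), paste0("asv", 1:4)))
  tax <- c(asv1 = "Firmicutes;Lachnospiraceae;Dorea",
           asv2 = "Firmicutes;Lachnospiraceae;Blautia",
           asv3 = "Verrucomicrobia;Akkermansiaceae;Akkermansia")
  fam <- aggregateTaxonomy(featureTable(m), tax, "family")
  expect_equal(tableValues(fam)[, "Firmicutes;Lachnospiraceae"],
               m[, 1] + m[, 2])
  expect_true("Unassigned" %in% featureIds(fam))   # asv4 unmapped
  for (rank in c("phylum", "family", "genus"))
    expect_equal(rowSums(tableValues(aggregateTaxonomy(featureTable(m), tax,
                                                       rank))),
                 rowSums(m))
  # two genera of one family: counts 3 + 4 = 7
  expect_equal(unname(tableValues(fam)["s1", "Firmicutes;Lachnospiraceae"]), 7)
})

test_that("greengenes-style rank prefixes are stripped by the taxonomy reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlineage",
               "asv1\tk__Bacteria;p__Firmicutes;f__Lachnospiraceae"), f)
  tax <- readTaxonomy(f)
  expect_identical(unname(tax["asv1"]),
                   "Bacteria;Firmicutes;Lachnospiraceae")
})

test_that("relative abundance normalizes rows to exactly one", {
  m <- matrix(c(2, 1, 2, 0, 4, 0), nrow = 2,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  ra <- tableValues(relativeAbundance(featureTable(m)))
  expect_equal(ra["a", ], c(x = 0.25, y = 0.25, z = 0.5))
  expect_true(all(abs(rowSums(ra) - 1) < 1e-12))
  single <- relativeAbundance(featureTable(matrix(7, 1, 1)))
  expect_equal(unname(tableValues(single)[1, 1]), 1)
  m0 <- matrix(c(0, 1, 0, 2), 2)
  expect_error(relativeAbundance(featureTable(m0)), "zero row sum")
})
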