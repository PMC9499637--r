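# Frobenius fusion, rDCV, VIP selection, permutation testing.

test_that("Frobenius norm follows its definition", {
  expect_equal(frobeniusNorm(matrix(c(3, 0, 4, 0), 2)), 5)
  expect_equal(frobeniusNorm(matrix(0, 3, 3)), 0)
  set.seed(1)
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(frobeniusNorm(-2.5 * x), 2.5 * frobeniusNorm(x))
  expect_error(frobeniusNorm(matrix(c(1, NA), 1)), "non-finite")
})

test_that("fused blocks are unit-norm, mapped, and width-additive", {
  set.seed(2)
  rn <- paste0("s", 1:20)
  mb <- matrix(rnorm(20 * 37), 20, 37, dimnames = list(rn, paste0("m", 1:37)))
  mg <- matrix(rexp(20 * 120), 20, 120, dimnames = list(rn, paste0("t", 1:120)))
  fs <- fuseBlocks(list(mb = mb, mg = mg))
  X <- fusedMatrix(fs)
  expect_equal(ncol(X), 157)                       # 37 + 120
  for (nm in names(blockMap(fs)))
    expect_lt(abs(frobeniusNorm(X[, blockMap(fs)[[nm]]]) - 1), 1e-12)
  # self-fusion: the two halves are identical
  fs2 <- fuseBlocks(list(a = mb, b = mb))
  X2 <- fusedMatrix(fs2)
  expect_equal(unname(X2[, blockMap(fs2)$a]), unname(X2[, blockMap(fs2)$b]))
  # sample-index mismatch is an error
  mg2 <- mg; rownames(mg2) <- rev(rn)
  expect_error(fuseBlocks(list(mb = mb, mg = mg2)), "sample index")
  expect_error(fuseBlocks(list(z = matrix(0, 3, 2,
                                          dimnames = list(letters[1:3],
                                                          NULL))),
                          preprocess = "none"), "zero Frobenius")
})

test_that("fusion absorbs any positive rescaling of a raw block", {
  set.seed(3)
  rn <- paste0("s", 1:15)
  a <- matrix(rnorm(150), 15, 10, dimnames = list(rn, NULL))
  b <- matrix(rnorm(75), 15, 5, dimnames = list(rn, NULL))
  for (pre in c("autoscale", "none")) {
    f1 <- fusedMatrix(fuseBlocks(list(a = a, b = b), preprocess = pre))
    f2 <- fusedMatrix(fuseBlocks(list(a = 1e3 * a, b = b), preprocess = pre))
    expect_lt(max(abs(f1 - f2)), 1e-12)
  }
})

test_that("stratified folds partition samples and balance classes", {
  lab <- rep(c("a", "b"), c(30, 18))
  folds <- stratifiedFolds(lab, 5, seed = 4)
  expect_equal(sort(unlist(folds)), 1:48)
  for (f in folds) {
    expect_gte(sum(lab[f] == "a"), 5)
    expect_gte(sum(lab[f] == "b"), 3)
  }
  expect_identical(folds, stratifiedFolds(lab, 5, seed = 4))
  expect_false(identical(folds, stratifiedFolds(lab, 5, seed = 5)))
  expect_error(stratifiedFolds(lab, 1), ">= 2")
})

test_that("rDCV is deterministic and rejects impossible configurations", {
  pm <- plantedMatrix(nPerGroup = 15, p = 30, planted = 1:3, shift = 1,
                      seed = 5)
  cfg <- lightConfig(seed = 7, repeats = 2)
  r1 <- rdcv(pm$x, pm$labels, cfg)
  r2 <- rdcv(pm$x, pm$labels, cfg)
  expect_identical(rdcvMeritSummary(r1), rdcvMeritSummary(r2))
  expect_identical(rdcvVip(r1), rdcvVip(r2))
  expect_identical(rdcvPredictions(r1), rdcvPredictions(r2))
  # every sample predicted exactly once per repeat
  pr <- rdcvPredictions(r1)
  expect_equal(unname(table(pr$repeatId)), rep(30L, 2), ignore_attr = TRUE)
  expect_false(anyNA(pr$predicted))
  # class smaller than the outer fold count
  expect_error(rdcv(pm$x[c(1:3, 16:30), ],
                    pm$labels[c(1:3, 16:30)],
                    rdcvConfig(outerFolds = 5, seed = 1)),
               "outerFolds")
  expect_error(rdcvConfig(vipConsistency = 0), "vipConsistency")
  expect_error(rdcvConfig(outerFolds = 1), ">= 2")
})

test_that("rDCV accuracy grows with the planted effect size", {
  shifts <- c(0, 0.5, 1.0, 1.5)
  acc <- vapply(shifts, function(s) {
    mean(vapply(1:20, function(i) {
      pm <- plantedMatrix(nPerGroup = 20, p = 50,
                          planted = if (s > 0) 1:5 else integer(0),
                          shift = s, seed = 7000 + 31 * i + round(100 * s))
      rdcvMeritSummary(rdcv(pm$x, pm$labels,
                            lightConfig(seed = i)))["accuracy_mean"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= -3))   # non-decreasing up to sampling error
  expect_gt(acc[4], acc[1] + 15)
})

test_that("VIP-consistency selection applies threshold and consistency rules", {
  pm <- plantedMatrix(nPerGroup = 20, p = 40, planted = 1:4, shift = 1.5,
                      seed = 8)
  res <- rdcv(pm$x, pm$labels, lightConfig(seed = 9, repeats = 10,
                                           maxComp = 3))
  all40 <- selectFeaturesVip(res, threshold = 0)
  expect_true(all(all40$selected))                  # degenerate threshold
  sel <- selectFeaturesVip(res, threshold = 1.15, consistency = 0.5)
  expect_true(all(c("feature", "block", "selected") %in% colnames(sel)))
  # consistency rule on a hand-built VIP matrix: 4 of 10 repeats is not half
  fake <- res
  vm <- rdcvVip(res)
  vm[, 1] <- c(rep(2, 4), rep(0.2, 6))
  fake@vip <- vm
  s2 <- selectFeaturesVip(fake, threshold = 1.15, consistency = 0.5)
  expect_false(s2$selected[1])
  expect_equal(s2$fractionAboveThreshold[1], 0.4)
})

test_that("selected features pass Mann-Whitney confirmation on strong signal", {
  pm <- plantedMatrix(nPerGroup = 30, p = 40, planted = 1:4, shift = 1.5,
                      seed = 10)
  res <- rdcv(pm$x, pm$labels, lightConfig(seed = 11, repeats = 5,
                                           maxComp = 3))
  sel <- selectFeaturesVip(res)
  conf <- confirmSelectedFeatures(pm$x, pm$labels, sel$feature[sel$selected])
  expect_true(all(conf$p_adj >= conf$p))
  expect_gt(mean(conf$significant), 0.5)
  expect_error(confirmSelectedFeatures(pm$x, pm$labels, "no_such_feature"),
               "unknown feature")
})

test_that("permutation test attains its minimum on strong signal and validates input", {
  pm <- plantedMatrix(nPerGroup = 20, p = 30, planted = 1:5, shift = 2,
                      seed = 12)
  cfg <- lightConfig(seed = 13, repeats = 2)
  pt <- permutationTest(pm$x, pm$labels, cfg, nPerm = 19, permRepeats = 1)
  expect_equal(unname(pt@p["accuracy"]), 1 / 20)
  expect_equal(nrow(pt@nullDistribution), 19)
  expect_true(all(pt@p >= 1 / 20 & pt@p <= 1))
  expect_error(permutationTest(pm$x, pm$labels, cfg, nPerm = 0), "nPerm")
})

test_that("multi-block rDCV annotates VIPs by source block", {
  set.seed(14)
  pm <- plantedMatrix(nPerGroup = 15, p = 30, planted = 1:3, shift = 1.5,
                      seed = 15)
  blocks <- list(mb = pm$x[, 1:10], mg = pm$x[, 11:30])
  res <- rdcv(blocks, pm$labels, lightConfig(seed = 16, repeats = 2))
  ann <- res@config$blockAnnotation
  expect_setequal(unique(ann), c("mb", "mg"))
  expect_equal(sum(ann == "mb"), 10)
  sel <- selectFeaturesVip(res)
  expect_true(all(sel$block %in% c("mb", "mg")))
})
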