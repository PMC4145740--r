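test_that("metrics reproduce the confusion-matrix formulas", {
  perfect <- evalMetrics(TP = 5, TN = 5, FP = 0, FN = 0)
  expect_equal(unname(perfect[c("SN", "SP", "ACC", "MCC")]), c(1, 1, 1, 1))

  inverted <- evalMetrics(TP = 0, TN = 0, FP = 5, FN = 5)
  expect_equal(unname(inverted["MCC"]), -1)

  # frozen hand evaluation: numerator 3*4 - 2*1 = 10,
  # denominator sqrt(5 * 4 * 5 * 6) = sqrt(600)
  m <- evalMetrics(TP = 3, TN = 4, FP = 1, FN = 2)
  expect_equal(unname(m["SN"]), 3 / 5)
  expect_equal(unname(m["SP"]), 4 / 5)
  expect_equal(unname(m["ACC"]), 7 / 10)
  expect_equal(unname(m["MCC"]), 10 / sqrt(600))

  # zero denominator factors fall back to MCC = 0
  expect_equal(unname(evalMetrics(TP = 0, TN = 5, FP = 0, FN = 5)["MCC"]), 0)
  expect_equal(unname(evalMetrics(TP = 3, TN = 0, FP = 7, FN = 0)["MCC"]), 0)
})

test_that("metrics stay in their bounds over random confusion tables", {
  set.seed(61)
  for (rep in 1:50) {
    cc <- sample(0:20, 4, replace = TRUE)
    m <- evalMetrics(cc[1], cc[2], cc[3], cc[4])
    expect_true(all(m[c("SN", "SP", "ACC")] >= 0 &
                      m[c("SN", "SP", "ACC")] <= 1))
    expect_gte(m[["MCC"]], -1)
    expect_lte(m[["MCC"]], 1)
  }
  # MCC hits +1 exactly when both error cells vanish with both classes seen
  expect_equal(unname(evalMetrics(2, 7, 0, 0)["MCC"]), 1)
  expect_lt(unname(evalMetrics(2, 7, 1, 0)["MCC"]), 1)
})

test_that("stratified folds balance classes and partition the samples", {
  labels <- rep(c(1, 0), c(20, 40))
  fold <- stratifiedKFold(labels, k = 10, seed = 3)
  expect_identical(sort(unique(fold)), 1:10)
  for (f in 1:10) {
    expect_identical(sum(fold == f & labels == 1), 2L)
    expect_identical(sum(fold == f & labels == 0), 4L)
  }
  expect_identical(stratifiedKFold(labels, k = 10, seed = 3), fold)
  expect_false(identical(stratifiedKFold(labels, k = 10, seed = 4), fold))
  expect_error(stratifiedKFold(rep(c(1, 0), c(5, 40)), k = 10), ">= 10")
})

test_that("cross-validation pools out-of-fold predictions", {
  fm <- makeFeatureData(nPos = 8, nNeg = 16, nInformative = 1, nNoise = 1,
                        seed = 31)
  oracle <- function(trainX, trainY, testX) {
    # cheat classifier: look the labels up by matching rows
    all <- featureValues(fm)
    apply(testX, 1, function(x) {
      siteLabels(fm)[which.min(colSums((t(all) - x)^2))]
    })
  }
  m <- crossValidate(fm, oracle, folds = 4, seed = 1)
  expect_equal(unname(m["MCC"]), 1)

  alwaysPos <- function(trainX, trainY, testX) rep(1L, nrow(testX))
  m <- crossValidate(fm, alwaysPos, folds = 4, seed = 1)
  expect_equal(unname(m["SN"]), 1)
  expect_equal(unname(m["SP"]), 0)
  expect_equal(unname(m["MCC"]), 0)
})

test_that("cross-validation agrees with manual fold bookkeeping on a toy", {
  values <- matrix(c(2.1, 1.9, 1.7, 2.3, -2.2, -1.8, -0.1, 0.1), ncol = 1,
                   dimnames = list(NULL, "f"))
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fs <- snoFeatureSet(values, labels)
  signClassifier <- function(trainX, trainY, testX) {
    as.integer(testX[, 1] > 0)
  }
  foldAssign <- c(1, 2, 1, 2, 1, 2, 1, 2)
  m <- crossValidate(fs, signClassifier, foldAssign = foldAssign)
  # manual: predictions are sign-based regardless of folds;
  # sample 7 (-0.1 -> 0 ok), sample 8 (0.1 -> predicted 1, FP)
  expect_equal(unname(m[c("TP", "TN", "FP", "FN")]), c(4, 3, 1, 0))
  expect_equal(unname(m["MCC"]),
               unname(evalMetrics(4, 3, 1, 0)["MCC"]))
})

test_that("IFS scans ranked prefixes and picks the MCC-optimal one", {
  set.seed(71)
  fm <- makeFeatureData(nPos = 20, nNeg = 40, nInformative = 2, nNoise = 6,
                        effect = 4, seed = 7)
  ranking <- mrmrRank(fm)
  spec <- classifierSpec(method = "ksrc", sparsity = 10, delta = NULL)
  res <- ifs(fm, ranking, spec, folds = 5, seed = 2, step = 2)
  curve <- ifsCurve(res)
  expect_identical(curve$size, c(2, 4, 6, 8))
  expect_identical(optimalSize(res),
                   as.integer(min(curve$size[curve$MCC == max(curve$MCC)])))
  expect_identical(optimalFeatures(res),
                   rankedNames(ranking)[seq_len(optimalSize(res))])

  # prefix determinism: a finer step agrees at shared sizes
  res1 <- ifs(fm, ranking, spec, folds = 5, seed = 2, step = 4)
  shared <- intersect(ifsCurve(res1)$size, curve$size)
  expect_gt(length(shared), 0)
  for (s in shared) {
    expect_equal(curve$MCC[curve$size == s],
                 ifsCurve(res1)$MCC[ifsCurve(res1)$size == s])
  }
  expect_error(ifs(fm, ranking, spec, step = 0), ">= 1")
})

test_that("a single-feature curve has one point", {
  values <- matrix(rep(c(2, -2), each = 10) + rnorm(20, sd = 0.1), ncol = 1,
                   dimnames = list(NULL, "only"))
  fs <- snoFeatureSet(values, rep(c(1, 0), each = 10))
  ranking <- new("RankedFeatures", order = 1L, scores = 0.5,
                 featureNames = "only")
  res <- ifs(fs, ranking, function(trX, trY, teX) as.integer(teX[, 1] > 0),
             folds = 5, seed = 1)
  expect_identical(nrow(ifsCurve(res)), 1L)
  expect_identical(optimalSize(res), 1L)
})

test_that("the optimal prefix generalizes to a held-out split", {
  fm <- makeFeatureData(nPos = 30, nNeg = 60, nInformative = 3, nNoise = 7,
                        effect = 3, seed = 17)
  holdout <- makeFeatureData(nPos = 15, nNeg = 30, nInformative = 3,
                             nNoise = 7, effect = 3, seed = 18)
  ranking <- mrmrRank(fm)
  spec <- classifierSpec(method = "ksrc", sparsity = 20, delta = NULL)
  res <- ifs(fm, ranking, spec, folds = 5, seed = 3, step = 2)
  keep <- optimalFeatures(res)
  model <- sparseModel(fm[keep, ], method = "ksrc", sparsity = 20)
  pred <- predict(model, holdout[keep, ])$predicted_label
  cc <- table(factor(siteLabels(holdout), c(0, 1)),
              factor(as.integer(pred), c(0, 1)))
  held <- evalMetrics(cc["1", "1"], cc["0", "0"], cc["0", "1"], cc["1", "0"])
  cvBest <- max(ifsCurve(res)$MCC)
  expect_lt(abs(held[["MCC"]] - cvBest), 0.35)
  expect_gt(held[["MCC"]], 0.5)
})
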