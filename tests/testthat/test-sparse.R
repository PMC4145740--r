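test_that("OMP recovers an exact atom and respects orthogonality", {
  set.seed(3)
  A <- matrix(rnorm(24), 4, 6)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  sol <- omp(A, A[, 4] * 2.5, sparsity = 3)
  expect_identical(sol$support, 4L)
  expect_equal(sol$alpha[4], 2.5, tolerance = 1e-10)
  expect_lt(sol$residualNorm, 1e-10)

  # b orthogonal to every column: projections remove nothing
  A <- diag(4)[, 1:2]
  b <- c(0, 0, 1, 1)
  sol <- omp(A, b, sparsity = 2, eps = 0)
  expect_equal(sol$residualNorm, sqrt(2))
  expect_true(all(abs(sol$alpha) < 1e-12))
})

test_that("OMP residuals are non-increasing and it handles rank deficiency", {
  set.seed(19)
  for (rep in 1:10) {
    A <- matrix(rnorm(8 * 12), 8, 12)
    b <- rnorm(8)
    sol <- omp(A, b, sparsity = 6, eps = 0)
    expect_true(all(diff(c(sqrt(sum(b^2)), sol$residualPath)) <= 1e-10))
  }
  # duplicated column: the second copy must be dropped, not crash
  A <- cbind(c(1, 0), c(1, 0))
  expect_warning(sol <- omp(A, c(2, 3), sparsity = 2, eps = 0),
                 "rank-deficient")
  expect_identical(sol$support, 1L)
  expect_equal(sol$residualNorm, 3)
  expect_error(omp(cbind(c(0, 0), c(1, 0)), c(1, 0)), "zero columns")
})

test_that("OMP matches exhaustive support search on planted 2-sparse systems", {
  set.seed(23)
  tried <- 0
  recovered <- 0
  for (rep in 1:40) {
    A <- makeLowCoherenceDictionary(4, 6)
    coh <- max(abs(crossprod(A) - diag(6)))
    support <- sort(sample(6, 2))
    b <- as.numeric(A[, support] %*% c(1.3, -0.9))
    sol <- omp(A, b, sparsity = 2, eps = 0)
    oracle <- oracleBestSupport(A, b, 2)
    if (coh < 0.5) {
      tried <- tried + 1
      if (identical(sort(sol$support), support)) recovered <- recovered + 1
    }
    # when OMP attains the optimum it must agree to solver precision
    if (any(vapply(oracle$supports, identical, logical(1),
                   sort(sol$support)))) {
      expect_equal(sol$residualNorm, oracle$residual, tolerance = 1e-8)
    }
    expect_gte(sol$residualNorm, oracle$residual - 1e-8)
  }
  expect_gte(tried, 20)
  expect_gte(recovered / tried, 0.95)
})

test_that("Laplacian Gram matrix is symmetric, unit-diagonal and PSD", {
  set.seed(29)
  for (rep in 1:20) {
    X <- matrix(rnorm(5 * 12), 5, 12)
    K <- gramMatrix(X, delta = 2)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_equal(unname(diag(K)), rep(1, 12))
    expect_true(all(K > 0 & K <= 1))
    expect_gte(min(eigen(K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
  # two points at distance delta have kernel value e^-1
  X <- cbind(c(0, 0), c(3, 4))
  K <- gramMatrix(X, delta = 5)
  expect_equal(K[1, 2], exp(-1))
  # l1 variant
  K1 <- gramMatrix(X, delta = 7, distance = "l1")
  expect_equal(K1[1, 2], exp(-1))
  expect_error(gramMatrix(X, delta = 0), "positive")
  expect_equal(kernelVector(X, c(3, 4), delta = 5), c(exp(-1), 1))
})

test_that("SRC assigns the class with the smallest masked residual", {
  # a test vector equal to a training sample is its own zero-residual code
  set.seed(31)
  train <- matrix(rnorm(10 * 6), 6, 10)
  labels <- rep(c(1, 0), each = 3)
  model <- sparseModel(train, labels, method = "src", sparsity = 3)
  out <- srcClassify(model, as.numeric(train[1, ]))
  expect_identical(out$class, "1")
  expect_lt(out$residuals[["1"]], 1e-10)

  # orthogonal one-atom classes: decision goes to the max-projection column
  dict <- diag(4)
  model <- sparseModel(dict, c(1, 1, 0, 0), method = "src", sparsity = 1)
  out <- srcClassify(model, c(0.1, 0, 0, 0.9))
  expect_identical(out$class, "0")

  # 2-class 6-sample toy: decision equals the hand-computed residual rule
  X <- rbind(c(1, 0), c(0.9, 0.1), c(0.8, 0.2),
             c(0, 1), c(0.1, 0.9), c(0.2, 0.8))
  model <- sparseModel(X, c(1, 1, 1, 0, 0, 0), method = "src",
                       sparsity = 2, normalize = FALSE)
  for (y in list(c(0.95, 0.05), c(0.05, 0.95), c(0.7, 0.3))) {
    out <- srcClassify(model, y)
    sol <- omp(t(X), y, 2)
    expected <- vapply(c("0", "1"), function(cl) {
      a <- sol$alpha
      a[as.character(c(1, 1, 1, 0, 0, 0)) != cl] <- 0
      sqrt(sum((y - t(X) %*% a)^2))
    }, numeric(1))
    expect_identical(out$class, names(which.min(expected)))
    expect_equal(out$residuals, expected[names(out$residuals)],
                 tolerance = 1e-10)
  }
})

test_that("masked per-class coefficients sum to the full coefficient vector", {
  set.seed(37)
  X <- matrix(rnorm(12 * 5), 12, 5)
  labels <- rep(c(0, 1, 2), each = 4)
  A <- t(X)
  sol <- omp(A, rnorm(5), sparsity = 4, eps = 0)
  masked <- lapply(sort(unique(labels)), function(cl) {
    a <- sol$alpha
    a[labels != cl] <- 0
    a
  })
  expect_equal(Reduce(`+`, masked), sol$alpha, tolerance = 1e-12)
})

test_that("KSRC treats a training sample as its own kernel atom", {
  set.seed(41)
  train <- matrix(rnorm(12 * 4), 12, 4)
  labels <- rep(c(1, 0), each = 6)
  model <- sparseModel(train, labels, method = "ksrc", delta = 3,
                       sparsity = 3)
  out <- ksrcClassify(model, as.numeric(train[8, ]))
  expect_identical(out$class, "0")
  expect_lt(out$residuals[["0"]], 1e-8)
})

test_that("KSRC stays numerically sane in the flat-kernel limit", {
  set.seed(43)
  train <- matrix(rnorm(10 * 3), 10, 3)
  labels <- rep(c(1, 0), each = 5)
  model <- sparseModel(train, labels, method = "ksrc", delta = 1e6,
                       sparsity = 5)
  out <- ksrcClassify(model, rnorm(3))
  expect_true(out$class %in% c("0", "1"))
  expect_true(all(is.finite(out$residuals)))
})

test_that("KSRC separates Gaussian blobs and matches the oracle rewrite", {
  set.seed(47)
  n <- 40
  d <- 5
  trainX <- rbind(matrix(rnorm(n / 2 * d, mean = 2), n / 2, d),
                  matrix(rnorm(n / 2 * d, mean = -2), n / 2, d))
  trainY <- rep(c(1, 0), each = n / 2)
  testX <- rbind(matrix(rnorm(10 * d, mean = 2), 10, d),
                 matrix(rnorm(10 * d, mean = -2), 10, d))
  testY <- rep(c(1, 0), each = 10)
  delta <- median(dist(trainX))
  model <- sparseModel(trainX, trainY, method = "ksrc", delta = delta,
                       sparsity = 10)
  pred <- predict(model, testX)$predicted_label
  expect_gte(mean(as.integer(pred) == testY), 0.9)
  oraclePred <- oracleKsrcPredict(trainX, trainY, testX, delta, k = 10)
  expect_gte(mean(as.integer(pred) == oraclePred), 0.9)
})

test_that("linear-kernel KSRC mostly agrees with SRC on separated data", {
  set.seed(53)
  agree <- 0
  total <- 0
  for (rep in 1:5) {
    n <- 20
    trainX <- rbind(matrix(rnorm(n / 2 * 4, mean = 1.5), n / 2, 4),
                    matrix(rnorm(n / 2 * 4, mean = -1.5), n / 2, 4))
    trainX <- trainX / sqrt(rowSums(trainX^2))
    trainY <- rep(c(1, 0), each = n / 2)
    testX <- rbind(matrix(rnorm(8 * 4, mean = 1.5), 8, 4),
                   matrix(rnorm(8 * 4, mean = -1.5), 8, 4))
    testX <- testX / sqrt(rowSums(testX^2))
    src <- sparseModel(trainX, trainY, method = "src", sparsity = 5,
                       normalize = FALSE)
    klin <- sparseModel(trainX, trainY, method = "ksrc", kernel = "linear",
                        sparsity = 5)
    pSrc <- predict(src, testX)$predicted_label
    pK <- predict(klin, testX)$predicted_label
    agree <- agree + sum(pSrc == pK)
    total <- total + length(pSrc)
  }
  expect_gte(agree / total, 0.9)
})

test_that("sparse models persist to a text directory and back", {
  set.seed(59)
  fm <- makeFeatureData(nPos = 10, nNeg = 20, nInformative = 3, nNoise = 2,
                        seed = 6)
  model <- sparseModel(fm, sparsity = 8, delta = 4)
  dir <- tempfile()
  writeSparseModel(model, dir)
  back <- readSparseModel(dir)
  expect_equal(back@dictionary, model@dictionary, tolerance = 1e-12)
  expect_identical(as.character(back@classes), as.character(model@classes))
  expect_identical(back@method, model@method)
  expect_equal(back@kernel$delta, model@kernel$delta)
  newdata <- featureValues(makeFeatureData(nPos = 4, nNeg = 4,
                                           nInformative = 3, nNoise = 2,
                                           seed = 7))
  expect_identical(predict(back, newdata)$predicted_label,
                   predict(model, newdata)$predicted_label)
  expect_error(readSparseModel(tempfile()), "model directory")
})
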