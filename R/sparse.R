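#' Orthogonal matching pursuit
#'
#' Greedy sparse approximation of `b` over the columns of `A`: at each
#' iteration the unselected column with the largest absolute normalized
#' correlation to the current residual joins the support (ties to the lowest
#' column index), `b` is least-squares projected onto the selected columns,
#' and the residual is updated. Iteration stops after `sparsity` atoms or
#' when the residual l2-norm drops to `eps`. A column whose addition makes
#' the selected set rank-deficient is dropped with a warning and never
#' revisited.
#'
#' @param A numeric matrix, d x n dictionary; columns must be nonzero.
#' @param b numeric length-d target vector.
#' @param sparsity maximum number of atoms (k), at least 1.
#' @param eps residual norm tolerance.
#' @return list with `alpha` (length-n coefficient vector, zero off-support),
#'   `support` (selected column indices in selection order), `residual`
#'   (final residual vector), `residualNorm`, and `residualPath` (norm after
#'   each projection; non-increasing).
#' @export
omp <- function(A, b, sparsity = 50L, eps = 1e-6) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (nrow(A) != length(b)) stop("dimensions of A and b do not match")
  sparsity <- as.integer(sparsity)
  if (sparsity < 1L) stop("sparsity must be >= 1")
  n <- ncol(A)
  colNorm <- sqrt(colSums(A^2))
  if (any(colNorm == 0)) stop("dictionary contains zero columns")

  support <- integer(0)
  unavailable <- logical(n)
  G <- matrix(0, 0, 0)          # crossprod of selected columns
  Atb <- numeric(0)
  coef <- numeric(0)
  r <- b
  residualPath <- numeric(0)

  while (length(support) < sparsity && !all(unavailable) &&
         sqrt(sum(r^2)) > eps) {
    corr <- abs(as.numeric(crossprod(A, r))) / colNorm
    corr[unavailable] <- -Inf
    j <- which.max(corr)
    cross <- as.numeric(crossprod(A[, support, drop = FALSE], A[, j]))
    Gnew <- rbind(cbind(G, cross), c(cross, sum(A[, j]^2)))
    ch <- tryCatch(chol(Gnew), error = function(e) NULL)
    if (is.null(ch)) {
      warning("dropping rank-deficient dictionary column ", j)
      unavailable[j] <- TRUE
      next
    }
    G <- Gnew
    support <- c(support, j)
    unavailable[j] <- TRUE
    Atb <- c(Atb, sum(A[, j] * b))
    coef <- backsolve(ch, backsolve(ch, Atb, transpose = TRUE))
    r <- b - as.numeric(A[, support, drop = FALSE] %*% coef)
    residualPath <- c(residualPath, sqrt(sum(r^2)))
  }

  alpha <- numeric(n)
  alpha[support] <- coef
  list(alpha = alpha, support = support, residual = r,
       residualNorm = sqrt(sum(r^2)), residualPath = residualPath)
}

#' Kernel evaluations
#'
#' `gramMatrix()` returns the n x n matrix of pairwise kernel values over
#' the sample columns of `X`; `kernelVector()` the kernel values between
#' every column of `X` and a single vector `y`. The Laplacian kernel is
#' `exp(-dist(x, y) / delta)` with `dist` the Euclidean (default) or
#' Manhattan distance; the linear kernel is the plain inner product.
#'
#' @param X numeric matrix, d x n, samples in columns.
#' @param y numeric length-d vector.
#' @param kind `"laplacian"` or `"linear"`.
#' @param delta positive kernel bandwidth (Laplacian only).
#' @param distance `"l2"` or `"l1"` (Laplacian only).
#' @return `gramMatrix()`: n x n symmetric matrix with unit diagonal for the
#'   Laplacian kernel; `kernelVector()`: length-n vector.
#' @export
gramMatrix <- function(X, kind = c("laplacian", "linear"), delta = 100,
                       distance = c("l2", "l1")) {
  kind <- match.arg(kind)
  distance <- match.arg(distance)
  if (kind == "linear") return(crossprod(X))
  if (delta <= 0) stop("kernel bandwidth delta must be positive")
  method <- if (distance == "l2") "euclidean" else "manhattan"
  D <- as.matrix(stats::dist(t(X), method = method))
  exp(-D / delta)
}

#' @rdname gramMatrix
#' @export
kernelVector <- function(X, y, kind = c("laplacian", "linear"), delta = 100,
                         distance = c("l2", "l1")) {
  kind <- match.arg(kind)
  distance <- match.arg(distance)
  if (kind == "linear") return(as.numeric(crossprod(X, y)))
  if (delta <= 0) stop("kernel bandwidth delta must be positive")
  d <- if (distance == "l2") {
    sqrt(colSums((X - y)^2))
  } else {
    colSums(abs(X - y))
  }
  exp(-d / delta)
}

#' Median pairwise distance heuristic for the kernel bandwidth
#'
#' @param X numeric d x n matrix, samples in columns.
#' @param distance `"l2"` or `"l1"`.
#' @param maxSamples subsample size used for large n.
#' @return positive numeric scalar.
#' @export
medianBandwidth <- function(X, distance = c("l2", "l1"), maxSamples = 500L) {
  distance <- match.arg(distance)
  n <- ncol(X)
  if (n > maxSamples) {
    # deterministic thinning, independent of the RNG state
    X <- X[, round(seq(1L, n, length.out = maxSamples)), drop = FALSE]
  }
  method <- if (distance == "l2") "euclidean" else "manhattan"
  d <- stats::median(stats::dist(t(X), method = method))
  if (!is.finite(d) || d <= 0) 1 else d
}

#' Fit a sparse-representation classifier
#'
#' Builds the training dictionary for SRC / KSRC classification. With
#' `method = "src"` test samples are sparsely coded directly over the
#' (optionally column-normalized) training matrix. With `method = "ksrc"`
#' coding happens in the Laplacian-kernel induced space through the Gram
#' linear system: the dictionary becomes the training Gram matrix `K` and a
#' test sample enters as its vector of kernel evaluations against the
#' training samples.
#'
#' @param x training samples: a [SnoFeatureSet-class], or a samples x
#'   features matrix together with `labels`.
#' @param labels class labels when `x` is a bare matrix.
#' @param method `"ksrc"` (default) or `"src"`.
#' @param sparsity OMP budget k; default 50.
#' @param eps OMP residual tolerance.
#' @param kernel `"laplacian"` or `"linear"` (KSRC only).
#' @param delta Laplacian bandwidth; `NULL` applies the median pairwise
#'   distance heuristic of [medianBandwidth()].
#' @param distance distance inside the Laplacian kernel, `"l2"` or `"l1"`.
#' @param normalize l2-normalize dictionary columns before SRC coding.
#' @return A [SparseModel-class].
#' @export
sparseModel <- function(x, labels = NULL, method = c("ksrc", "src"),
                        sparsity = 50L, eps = 1e-6,
                        kernel = c("laplacian", "linear"), delta = NULL,
                        distance = c("l2", "l1"), normalize = TRUE) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  distance <- match.arg(distance)
  if (is(x, "SnoFeatureSet")) {
    labels <- siteLabels(x)
    x <- featureValues(x)
  }
  if (is.null(labels)) stop("labels are required with a bare matrix")
  dict <- t(as.matrix(x))          # features x samples
  classes <- factor(labels)
  if (method == "ksrc" && kernel == "laplacian" && is.null(delta)) {
    delta <- medianBandwidth(dict, distance)
  }
  kern <- list(kind = if (method == "ksrc") kernel else "linear",
               delta = delta, distance = distance)
  gram <- if (method == "ksrc") {
    gramMatrix(dict, kind = kernel, delta = if (is.null(delta)) 100 else delta,
               distance = distance)
  } else {
    matrix(0, 0, 0)
  }
  new("SparseModel", dictionary = dict, classes = classes, kernel = kern,
      method = method, sparsity = as.integer(sparsity), eps = eps,
      normalize = normalize, gram = gram,
      featureNames = if (is.null(rownames(dict))) character(0) else
        rownames(dict))
}

# Residual-rule decision shared by SRC and KSRC: per class, zero out the
# coefficients of the other classes and measure the reconstruction residual.
residualDecision <- function(A, b, alpha, classes) {
  lev <- levels(classes)
  residuals <- vapply(seq_along(lev), function(k) {
    alphaK <- alpha
    alphaK[as.integer(classes) != k] <- 0
    sqrt(sum((b - as.numeric(A %*% alphaK))^2))
  }, numeric(1))
  names(residuals) <- lev
  list(class = lev[which.min(residuals)], residuals = residuals)
}

#' Classify one sample by sparse representation
#'
#' `srcClassify()` codes `y` over the raw training dictionary with OMP and
#' assigns the class whose masked coefficient vector reconstructs `y` with
#' the smallest l2 residual. `ksrcClassify()` applies the same rule in the
#' kernel Gram system: the dictionary is the training Gram matrix and `y`
#' enters as its kernel vector against the training samples. Residual ties
#' resolve to the lowest class id.
#'
#' @param model a [SparseModel-class].
#' @param y numeric feature vector (length = number of dictionary rows).
#' @return list with `class` (character level) and `residuals` (named
#'   per-class residual norms).
#' @export
srcClassify <- function(model, y) {
  A <- model@dictionary
  if (model@normalize) {
    A <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
  }
  sol <- omp(A, y, model@sparsity, model@eps)
  residualDecision(A, y, sol$alpha, model@classes)
}

#' @rdname srcClassify
#' @export
ksrcClassify <- function(model, y) {
  K <- model@gram
  if (nrow(K) == 0L) stop("model holds no Gram matrix; fit with method ksrc")
  b <- kernelVector(model@dictionary, y, kind = model@kernel$kind,
                    delta = if (is.null(model@kernel$delta)) 100 else
                      model@kernel$delta,
                    distance = model@kernel$distance)
  sol <- omp(K, b, model@sparsity, model@eps)
  residualDecision(K, b, sol$alpha, model@classes)
}

#' Predict classes for new samples
#'
#' Runs [srcClassify()] or [ksrcClassify()] (per the model's `method`) on
#' every row of `newdata` and reports the decided class, the per-class
#' residuals, and `score_margin` = residual(negative) - residual(positive),
#' so larger margins favor the positive class.
#'
#' @param object a [SparseModel-class].
#' @param newdata samples x features matrix or [SnoFeatureSet-class].
#' @param ... ignored.
#' @return data.frame with one row per sample: `predicted_label`,
#'   `score_margin` and one `residual.<class>` column per class.
#' @export
setMethod("predict", "SparseModel", function(object, newdata, ...) {
  if (is(newdata, "SnoFeatureSet")) newdata <- featureValues(newdata)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object@dictionary)) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         nrow(object@dictionary))
  }
  classify <- if (object@method == "ksrc") ksrcClassify else srcClassify
  lev <- levels(object@classes)
  res <- t(vapply(seq_len(nrow(newdata)), function(i) {
    classify(object, as.numeric(newdata[i, ]))$residuals
  }, numeric(length(lev))))
  pred <- lev[apply(res, 1L, which.min)]
  margin <- if (all(c("0", "1") %in% lev)) {
    res[, "0"] - res[, "1"]
  } else {
    rep(NA_real_, nrow(res))
  }
  out <- data.frame(predicted_label = pred, score_margin = margin,
                    stringsAsFactors = FALSE)
  colnames(res) <- paste0("residual.", lev)
  cbind(out, as.data.frame(res))
})

#' Persist / load a sparse model directory
#'
#' The model is stored as plain text: `dictionary.tsv` (one training sample
#' per row with its class), and `config.txt` with `key=value` lines for the
#' method, kernel, bandwidth, distance, sparsity, eps and normalization.
#'
#' @param model a [SparseModel-class].
#' @param dir output directory (created if needed).
#' @return `writeSparseModel` returns `dir` invisibly; `readSparseModel`
#'   returns a [SparseModel-class].
#' @export
writeSparseModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- t(model@dictionary)
  colnames(vals) <- if (length(model@featureNames)) model@featureNames else
    paste0("f", seq_len(ncol(vals)))
  df <- cbind(data.frame(class = as.character(model@classes)),
              as.data.frame(vals, check.names = FALSE))
  utils::write.table(df, file.path(dir, "dictionary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- c(method = model@method,
           kernel = model@kernel$kind,
           delta = if (is.null(model@kernel$delta)) "NULL" else
             format(model@kernel$delta, digits = 17),
           distance = model@kernel$distance,
           sparsity = model@sparsity,
           eps = format(model@eps, digits = 17),
           normalize = model@normalize)
  writeLines(paste0(names(cfg), "=", unname(cfg)),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' @rdname writeSparseModel
#' @export
readSparseModel <- function(dir) {
  cfgPath <- file.path(dir, "config.txt")
  dictPath <- file.path(dir, "dictionary.tsv")
  if (!file.exists(cfgPath) || !file.exists(dictPath)) {
    stop("not a model directory (missing config.txt or dictionary.tsv): ",
         dir)
  }
  kv <- strsplit(readLines(cfgPath), "=", fixed = TRUE)
  cfg <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                         vapply(kv, `[`, character(1), 1L))
  df <- utils::read.table(dictPath, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, setdiff(colnames(df), "class"), drop = FALSE])
  sparseModel(vals, labels = df$class,
              method = cfg[["method"]],
              sparsity = as.integer(cfg[["sparsity"]]),
              eps = as.numeric(cfg[["eps"]]),
              kernel = cfg[["kernel"]],
              delta = if (cfg[["delta"]] == "NULL") NULL else
                as.numeric(cfg[["delta"]]),
              distance = cfg[["distance"]],
              normalize = as.logical(cfg[["normalize"]]))
}
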