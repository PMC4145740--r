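#' Classification metrics from confusion counts
#'
#' Sensitivity `SN = TP / (TP + FN)`, specificity `SP = TN / (TN + FP)`,
#' accuracy `ACC = (TP + TN) / n`, and the Matthews correlation coefficient
#' `MCC = (TP * TN - FN * FP) / sqrt((TP + FN)(TP + FP)(TN + FP)(TN + FN))`.
#' A zero factor in the MCC denominator yields `MCC = 0` (the usual
#' convention for degenerate confusion tables); an empty class likewise
#' gives `SN` or `SP` of `NaN`-free 0.
#'
#' @param TP,TN,FP,FN nonnegative confusion counts.
#' @return named numeric vector with TP, TN, FP, FN, SN, SP, ACC, MCC.
#' @examples
#' evalMetrics(TP = 3, TN = 4, FP = 1, FN = 2)
#' @export
evalMetrics <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  n <- TP + TN + FP + FN
  SN <- if (TP + FN > 0) TP / (TP + FN) else 0
  SP <- if (TN + FP > 0) TN / (TN + FP) else 0
  ACC <- if (n > 0) (TP + TN) / n else 0
  denom <- (TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)
  MCC <- if (denom > 0) (TP * TN - FN * FP) / sqrt(denom) else 0
  c(TP = TP, TN = TN, FP = FP, FN = FN, SN = SN, SP = SP, ACC = ACC,
    MCC = MCC)
}

# Confusion counts for binary 1/0 labels.
confusionCounts <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  c(TP = sum(truth == 1L & predicted == 1L),
    TN = sum(truth == 0L & predicted == 0L),
    FP = sum(truth == 0L & predicted == 1L),
    FN = sum(truth == 1L & predicted == 0L))
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds so that within every class the
#' fold sizes differ by at most one: class members are permuted with the
#' given seed and dealt round-robin over the folds.
#'
#' @param labels class label vector.
#' @param k number of folds; every class must have at least `k` members.
#' @param seed integer seed for the within-class permutation.
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
stratifiedKFold <- function(labels, k = 10L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  fold <- integer(length(labels))
  set.seed(as.integer(seed))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has ", length(idx), " members; need >= ", k)
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Classifier configuration for cross-validation
#'
#' Bundles the [sparseModel()] arguments used when a classifier has to be
#' refit inside each cross-validation fold.
#'
#' @inheritParams sparseModel
#' @return list of class `snoClassifierSpec`.
#' @export
classifierSpec <- function(method = c("ksrc", "src"), sparsity = 50L,
                           eps = 1e-6, kernel = c("laplacian", "linear"),
                           delta = NULL, distance = c("l2", "l1"),
                           normalize = TRUE) {
  spec <- list(method = match.arg(method), sparsity = as.integer(sparsity),
               eps = eps, kernel = match.arg(kernel), delta = delta,
               distance = match.arg(distance), normalize = normalize)
  if (spec$sparsity < 1L) stop("sparsity must be >= 1")
  if (!is.null(spec$delta) && spec$delta <= 0) stop("delta must be positive")
  class(spec) <- "snoClassifierSpec"
  spec
}

fitSpec <- function(spec, values, labels) {
  sparseModel(values, labels, method = spec$method, sparsity = spec$sparsity,
              eps = spec$eps, kernel = spec$kernel, delta = spec$delta,
              distance = spec$distance, normalize = spec$normalize)
}

#' Cross-validated evaluation of a classifier
#'
#' Runs stratified k-fold cross-validation: per fold the classifier is refit
#' on the training portion and applied to the held-out portion; the
#' out-of-fold predictions are pooled into a single confusion table from
#' which the metrics are computed once (pooling keeps the MCC stable when
#' positives are rare within folds).
#'
#' @param fs a [SnoFeatureSet-class].
#' @param spec a [classifierSpec()], or a function `(trainValues,
#'   trainLabels, testValues) -> predicted labels` for custom classifiers.
#' @param folds number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @param foldAssign optional precomputed fold assignment (overrides `folds`
#'   and `seed`), e.g. to reuse one partition across feature subsets.
#' @return named numeric vector as from [evalMetrics()].
#' @export
crossValidate <- function(fs, spec, folds = 10L, seed = 1L,
                          foldAssign = NULL) {
  values <- featureValues(fs)
  labels <- siteLabels(fs)
  if (is.null(foldAssign)) {
    foldAssign <- stratifiedKFold(labels, k = folds, seed = seed)
  }
  predicted <- integer(length(labels))
  for (f in sort(unique(foldAssign))) {
    test <- foldAssign == f
    if (is.function(spec)) {
      pred <- spec(values[!test, , drop = FALSE], labels[!test],
                   values[test, , drop = FALSE])
    } else {
      model <- fitSpec(spec, values[!test, , drop = FALSE], labels[!test])
      pred <- predict(model, values[test, , drop = FALSE])$predicted_label
    }
    predicted[test] <- as.integer(pred)
  }
  cc <- confusionCounts(labels, predicted)
  evalMetrics(cc[["TP"]], cc[["TN"]], cc[["FP"]], cc[["FN"]])
}

#' Incremental feature selection
#'
#' Evaluates nested prefixes of an mRMR ranking by cross-validation:
#' subsets of size `step, 2 * step, ...` (always including the full set) are
#' taken from the top of the ranking, each is scored with [crossValidate()]
#' using one shared fold assignment (so the curve isolates the effect of the
#' features), and the prefix with the highest MCC is declared optimal (ties
#' break toward the smaller prefix).
#'
#' @param fs a [SnoFeatureSet-class].
#' @param ranking a [RankedFeatures-class] covering all columns of `fs`.
#' @param spec classifier configuration, see [crossValidate()].
#' @param folds,seed cross-validation setup.
#' @param step subset-size increment, at least 1.
#' @return An [IFSResult-class].
#' @export
ifs <- function(fs, ranking, spec, folds = 10L, seed = 1L, step = 1L) {
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  p <- nrow(fs)
  if (length(rankedOrder(ranking)) != p) {
    stop("ranking covers ", length(rankedOrder(ranking)),
         " features but the data has ", p)
  }
  sizes <- unique(c(seq.int(step, p, by = step), p))
  foldAssign <- stratifiedKFold(siteLabels(fs), k = folds, seed = seed)
  rows <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    sub <- fs[rankedOrder(ranking)[seq_len(sizes[i])], ]
    m <- crossValidate(sub, spec, foldAssign = foldAssign)
    rows[[i]] <- c(size = sizes[i], m)
  }
  curve <- as.data.frame(do.call(rbind, rows))
  best <- min(curve$size[curve$MCC == max(curve$MCC)])
  new("IFSResult", curve = curve, optimalSize = as.integer(best),
      featureNames = rankedNames(ranking)[seq_len(best)])
}

#' Write an IFS curve table
#'
#' TSV with columns `size`, `SN`, `SP`, `ACC`, `MCC` (plus the confusion
#' counts); the companion file `<path>.optimal.txt` is written by
#' [writeOptimalFeatures()].
#'
#' @param result an [IFSResult-class].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeIfsCurve <- function(result, path) {
  utils::write.table(ifsCurve(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeIfsCurve
#' @export
writeOptimalFeatures <- function(result, path) {
  writeLines(optimalFeatures(result), path)
  invisible(path)
}
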