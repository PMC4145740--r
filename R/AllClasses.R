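#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show callNextMethod slot
#' @importFrom stats quantile sd rnorm runif median dist setNames predict
#' @importFrom utils read.table write.table head tail
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width subseq
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
NULL

# Residue alphabets used throughout. PSSM columns follow the PSI-BLAST
# query-profile order; all other per-residue channels are alphabetical.
AA_ALPHABETICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_PSSM_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
SS_CLASSES <- c("helix", "strand", "other")
ACC_CLASSES <- c("buried", "exposed")
WINDOW_WIDTH <- 21L
WINDOW_CENTER <- 11L

#' Set of cysteine-centered peptide windows
#'
#' Holds fixed-width (21-residue) peptide windows cut around candidate
#' S-nitrosylation cysteines, together with their provenance (protein id,
#' 1-based site position, protein length) and binary site label
#' (1 = nitrosylated, 0 = not). Windows that extend past the ends of the
#' protein are padded with `"X"`; with `padMode = "center"` (default) padding
#' is placed on the deficient side so the cysteine stays at position 11,
#' with `padMode = "end"` all padding is appended after the sequence.
#'
#' @slot windows [Biostrings::AAStringSet] of width-21 peptides.
#' @slot proteinId character, source protein of each window.
#' @slot sitePos integer, 1-based cysteine position in the source protein.
#' @slot protLength integer, length of the source protein.
#' @slot label integer, 1 (positive) or 0 (negative).
#' @slot padMode `"center"` or `"end"`.
#'
#' @seealso [extractWindows()], [stratifiedSplit()]
#' @export
setClass("PeptideWindowSet",
  slots = c(
    windows = "AAStringSet",
    proteinId = "character",
    sitePos = "integer",
    protLength = "integer",
    label = "integer",
    padMode = "character"
  )
)

setValidity("PeptideWindowSet", function(object) {
  n <- length(object@windows)
  msg <- character(0)
  if (length(object@proteinId) != n || length(object@sitePos) != n ||
      length(object@protLength) != n || length(object@label) != n) {
    msg <- c(msg, "provenance slots must have one entry per window")
  }
  if (n > 0 && any(Biostrings::width(object@windows) != WINDOW_WIDTH)) {
    msg <- c(msg, sprintf("all windows must have width %d", WINDOW_WIDTH))
  }
  if (!length(object@padMode) == 1L ||
      !object@padMode %in% c("center", "end")) {
    msg <- c(msg, "padMode must be \"center\" or \"end\"")
  }
  if (n > 0 && object@padMode == "center") {
    centers <- as.character(Biostrings::subseq(object@windows,
                                               WINDOW_CENTER, WINDOW_CENTER))
    if (any(centers != "C")) {
      msg <- c(msg, "centered windows must carry 'C' at position 11")
    }
  }
  if (n > 0 && !all(object@label %in% c(0L, 1L))) {
    msg <- c(msg, "labels must be 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' Per-residue annotation tracks for one protein
#'
#' Bundles the precomputed per-residue predictions consumed by the feature
#' encoders: a PSSM (one 20-number row per residue, PSI-BLAST column order),
#' a secondary-structure class per residue (helix/strand/other), a solvent
#' accessibility class per residue (buried/exposed), and a disorder score in
#' \[0, 1\] per residue. Any track may be absent (length 0 / 0 rows) when the
#' corresponding feature block is disabled.
#'
#' @slot proteinId character scalar.
#' @slot length integer, protein length all present tracks must match.
#' @slot pssm numeric matrix, length x 20, or 0-row when absent.
#' @slot ss character vector over helix/strand/other, or length 0.
#' @slot acc character vector over buried/exposed, or length 0.
#' @slot disorder numeric vector in \[0, 1\], or length 0.
#' @export
setClass("ResidueAnnotation",
  slots = c(
    proteinId = "character",
    length = "integer",
    pssm = "matrix",
    ss = "character",
    acc = "character",
    disorder = "numeric"
  )
)

setValidity("ResidueAnnotation", function(object) {
  msg <- character(0)
  L <- object@length
  if (length(object@proteinId) != 1L) msg <- c(msg, "proteinId must be scalar")
  if (length(L) != 1L || is.na(L) || L < 1L) {
    msg <- c(msg, "length must be a positive integer")
  }
  if (nrow(object@pssm) > 0) {
    if (nrow(object@pssm) != L) msg <- c(msg, "pssm rows must equal length")
    if (ncol(object@pssm) != 20L) msg <- c(msg, "pssm must have 20 columns")
  }
  if (length(object@ss) > 0) {
    if (length(object@ss) != L) msg <- c(msg, "ss length mismatch")
    if (!all(object@ss %in% SS_CLASSES)) {
      msg <- c(msg, "ss classes must be helix/strand/other")
    }
  }
  if (length(object@acc) > 0) {
    if (length(object@acc) != L) msg <- c(msg, "acc length mismatch")
    if (!all(object@acc %in% ACC_CLASSES)) {
      msg <- c(msg, "acc classes must be buried/exposed")
    }
  }
  if (length(object@disorder) > 0) {
    if (length(object@disorder) != L) msg <- c(msg, "disorder length mismatch")
    if (any(object@disorder < 0 | object@disorder > 1)) {
      msg <- c(msg, "disorder scores must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Labeled feature matrix for peptide samples
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay
#' `"features"` (features in rows, samples in columns), a mandatory integer
#' `label` column (1/0) in `colData`, and a `block` column in `rowData`
#' recording which feature block each row belongs to. Sample-level provenance
#' (`protein_id`, `position`) is carried in `colData` when available.
#'
#' @export
setClass("SnoFeatureSet", contains = "SummarizedExperiment")

setValidity("SnoFeatureSet", function(object) {
  msg <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay \"features\" is required")
  } else {
    a <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(a)) msg <- c(msg, "features assay must be numeric")
    if (anyNA(a)) msg <- c(msg, "features assay must not contain NA")
  }
  if (!"label" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must contain a label column")
  } else {
    lab <- SummarizedExperiment::colData(object)$label
    if (!all(lab %in% c(0L, 1L))) msg <- c(msg, "labels must be 0 or 1")
  }
  if (is.null(rownames(object)) && nrow(object) > 0) {
    msg <- c(msg, "features must be named")
  } else if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "feature names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' mRMR feature ranking
#'
#' The order in which greedy minimum-Redundancy-Maximum-Relevance selection
#' picked the features, with the value of the mRMR objective
#' (relevance minus mean redundancy against the already-selected set) at each
#' selection step.
#'
#' @slot order integer permutation of feature indices, best first.
#' @slot scores numeric, objective value at each step.
#' @slot featureNames character, names aligned with `order`.
#' @export
setClass("RankedFeatures",
  slots = c(order = "integer", scores = "numeric", featureNames = "character")
)

setValidity("RankedFeatures", function(object) {
  msg <- character(0)
  p <- length(object@order)
  if (length(object@scores) != p) msg <- c(msg, "one score per ranked feature")
  if (length(object@featureNames) != p) {
    msg <- c(msg, "one name per ranked feature")
  }
  if (p > 0 && !setequal(object@order, seq_len(p))) {
    msg <- c(msg, "order must be a permutation of 1..p")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse-representation classifier
#'
#' The dictionary of training samples (columns) with their class labels and
#' the kernel / solver configuration. With `kernel$kind == "linear"` and
#' `method = "src"` classification runs in the raw feature space; with the
#' Laplacian kernel it runs through the Gram-matrix linear system (KSRC).
#'
#' @slot dictionary numeric matrix, d features x n training samples.
#' @slot classes factor of length n, class of each column.
#' @slot kernel list with `kind` ("linear"/"laplacian"), `delta`, `distance`.
#' @slot method `"src"` or `"ksrc"`.
#' @slot sparsity integer OMP budget.
#' @slot eps numeric residual tolerance.
#' @slot normalize logical, l2-normalize dictionary columns (SRC only).
#' @slot gram numeric matrix, cached training Gram matrix (KSRC only).
#' @slot featureNames character, names of dictionary rows.
#' @export
setClass("SparseModel",
  slots = c(
    dictionary = "matrix",
    classes = "factor",
    kernel = "list",
    method = "character",
    sparsity = "integer",
    eps = "numeric",
    normalize = "logical",
    gram = "matrix",
    featureNames = "character"
  )
)

setValidity("SparseModel", function(object) {
  msg <- character(0)
  n <- ncol(object@dictionary)
  if (length(object@classes) != n) msg <- c(msg, "one class per column")
  if (nlevels(object@classes) < 2L) msg <- c(msg, "need at least two classes")
  if (!all(is.finite(object@dictionary))) {
    msg <- c(msg, "dictionary must be finite")
  }
  if (!object@method %in% c("src", "ksrc")) {
    msg <- c(msg, "method must be src or ksrc")
  }
  if (object@sparsity < 1L) msg <- c(msg, "sparsity must be >= 1")
  if (!is.null(object@kernel$delta) && object@kernel$kind == "laplacian" &&
      object@kernel$delta <= 0) {
    msg <- c(msg, "kernel bandwidth delta must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Incremental feature selection result
#'
#' Cross-validated performance of nested prefixes of an mRMR ranking, and the
#' prefix size with the best Matthews correlation coefficient (ties broken
#' toward the smaller prefix).
#'
#' @slot curve data.frame with columns size, TP, TN, FP, FN, SN, SP, ACC, MCC.
#' @slot optimalSize integer, MCC-argmax prefix size.
#' @slot featureNames character, names of the optimal prefix in rank order.
#' @export
setClass("IFSResult",
  slots = c(curve = "data.frame", optimalSize = "integer",
            featureNames = "character")
)

setValidity("IFSResult", function(object) {
  msg <- character(0)
  need <- c("size", "TP", "TN", "FP", "FN", "SN", "SP", "ACC", "MCC")
  if (!all(need %in% colnames(object@curve))) {
    msg <- c(msg, "curve must have size + confusion + metric columns")
  } else if (nrow(object@curve) > 0) {
    best <- max(object@curve$MCC)
    at <- object@curve$size[object@curve$MCC == best]
    if (!object@optimalSize %in% at || object@optimalSize != min(at)) {
      msg <- c(msg, "optimalSize must be the smallest MCC-argmax size")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PeptideWindowSet", function(object) {
  n <- length(object@windows)
  cat(sprintf("PeptideWindowSet with %d windows (width %d, pad mode \"%s\")\n",
              n, WINDOW_WIDTH, object@padMode))
  cat(sprintf("  positives: %d, negatives: %d\n",
              sum(object@label == 1L), sum(object@label == 0L)))
  if (n > 0) {
    k <- min(n, 3L)
    for (i in seq_len(k)) {
      cat(sprintf("  %s:%d %s [%d]\n", object@proteinId[i], object@sitePos[i],
                  as.character(object@windows[[i]]), object@label[i]))
    }
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})

setMethod("show", "ResidueAnnotation", function(object) {
  tracks <- c(
    if (nrow(object@pssm) > 0) "pssm",
    if (length(object@ss) > 0) "ss",
    if (length(object@acc) > 0) "acc",
    if (length(object@disorder) > 0) "disorder"
  )
  cat(sprintf("ResidueAnnotation for %s (%d residues): %s\n",
              object@proteinId, object@length,
              if (length(tracks)) paste(tracks, collapse = ", ") else "empty"))
})

setMethod("show", "RankedFeatures", function(object) {
  p <- length(object@order)
  cat(sprintf("RankedFeatures over %d features\n", p))
  k <- min(p, 5L)
  if (k > 0) {
    cat("  top:", paste(sprintf("%s (%.4f)", object@featureNames[seq_len(k)],
                                object@scores[seq_len(k)]), collapse = ", "),
        "\n")
  }
})

setMethod("show", "SparseModel", function(object) {
  cat(sprintf("SparseModel (%s): %d atoms x %d dims, %d classes\n",
              object@method, ncol(object@dictionary),
              nrow(object@dictionary), nlevels(object@classes)))
  if (object@kernel$kind == "laplacian") {
    cat(sprintf("  Laplacian kernel: delta = %g, %s distance\n",
                object@kernel$delta, object@kernel$distance))
  }
  cat(sprintf("  sparsity k = %d, eps = %g\n", object@sparsity, object@eps))
})

setMethod("show", "IFSResult", function(object) {
  cat(sprintf("IFSResult: %d subset sizes evaluated\n", nrow(object@curve)))
  i <- match(object@optimalSize, object@curve$size)
  cat(sprintf("  optimal size %d with MCC %.4f\n",
              object@optimalSize, object@curve$MCC[i]))
})
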