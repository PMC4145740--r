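#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname accessors
#' @export
setGeneric("windowSequences", function(x) standardGeneric("windowSequences"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("rankedOrder", function(x) standardGeneric("rankedOrder"))

#' @rdname accessors
#' @export
setGeneric("rankedNames", function(x) standardGeneric("rankedNames"))

#' @rdname accessors
#' @export
setGeneric("rankedScores", function(x) standardGeneric("rankedScores"))

#' @rdname accessors
#' @export
setGeneric("ifsCurve", function(x) standardGeneric("ifsCurve"))

#' @rdname accessors
#' @export
setGeneric("optimalSize", function(x) standardGeneric("optimalSize"))

#' @rdname accessors
#' @export
setGeneric("optimalFeatures", function(x) standardGeneric("optimalFeatures"))

#' Accessors for snoKSRC classes
#'
#' Small, read-only views onto the package's S4 containers:
#' `proteinIds()`, `sitePositions()`, `siteLabels()` and `windowSequences()`
#' for [PeptideWindowSet-class]; `featureValues()` (samples x features
#' matrix) and `siteLabels()` for [SnoFeatureSet-class]; `rankedOrder()`,
#' `rankedNames()` and `rankedScores()` for [RankedFeatures-class];
#' `ifsCurve()`, `optimalSize()` and `optimalFeatures()` for
#' [IFSResult-class].
#'
#' @param x an object of the documented class.
#' @return The requested component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("proteinIds", "PeptideWindowSet", function(x) x@proteinId)

#' @rdname accessors
#' @export
setMethod("sitePositions", "PeptideWindowSet", function(x) x@sitePos)

#' @rdname accessors
#' @export
setMethod("siteLabels", "PeptideWindowSet", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("windowSequences", "PeptideWindowSet",
          function(x) as.character(x@windows))

#' @rdname accessors
#' @export
setMethod("siteLabels", "SnoFeatureSet", function(x) {
  as.integer(SummarizedExperiment::colData(x)$label)
})

#' @rdname accessors
#' @export
setMethod("featureValues", "SnoFeatureSet", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' @rdname accessors
#' @export
setMethod("rankedOrder", "RankedFeatures", function(x) x@order)

#' @rdname accessors
#' @export
setMethod("rankedNames", "RankedFeatures", function(x) x@featureNames)

#' @rdname accessors
#' @export
setMethod("rankedScores", "RankedFeatures", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("ifsCurve", "IFSResult", function(x) x@curve)

#' @rdname accessors
#' @export
setMethod("optimalSize", "IFSResult", function(x) x@optimalSize)

#' @rdname accessors
#' @export
setMethod("optimalFeatures", "IFSResult", function(x) x@featureNames)

#' Subset a PeptideWindowSet
#'
#' @param x a [PeptideWindowSet-class].
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PeptideWindowSet", function(x, i, j, ..., drop = TRUE) {
  new("PeptideWindowSet",
      windows = x@windows[i],
      proteinId = x@proteinId[i],
      sitePos = x@sitePos[i],
      protLength = x@protLength[i],
      label = x@label[i],
      padMode = x@padMode)
})

#' Number of windows
#' @param x a [PeptideWindowSet-class].
#' @export
setMethod("length", "PeptideWindowSet", function(x) length(x@windows))
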