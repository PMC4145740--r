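#' Empirical mutual information between two discrete vectors
#'
#' Plug-in estimate from the joint empirical distribution, in nats:
#' `sum over cells of p(x, y) * log(p(x, y) / (p(x) p(y)))`, with
#' `0 * log 0` taken as 0. Inputs may be integer, factor or character; they
#' are coerced to category codes.
#'
#' @param x,y equal-length discrete vectors, at least 2 samples.
#' @return nonnegative numeric scalar.
#' @examples
#' mutualInformation(c(1, 1, 2, 2), c(1, 1, 2, 2))  # = log(2)
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 samples")
  xi <- as.integer(factor(x))
  yi <- as.integer(factor(y))
  miFromCodes(xi, max(xi), yi, max(yi))
}

# Fast path used by the ranker: x, y already small positive integer codes.
miFromCodes <- function(xi, nx, yi, ny) {
  joint <- tabulate(xi + nx * (yi - 1L), nbins = nx * ny)
  n <- length(xi)
  p <- joint / n
  px <- tabulate(xi, nbins = nx) / n
  py <- tabulate(yi, nbins = ny) / n
  denom <- as.vector(outer(px, py))
  keep <- p > 0
  sum(p[keep] * log(p[keep] / denom[keep]))
}

#' Discretize feature columns for mutual-information estimation
#'
#' Columns with at most `bins` distinct values (binary indicators, one-hot
#' channels) are passed through as categories; other columns are cut into
#' `bins` equal-width intervals over their observed range
#' (`strategy = "width"`) or into intervals holding equal sample counts at
#' the empirical quantiles (`strategy = "frequency"`).
#'
#' @param values numeric matrix, samples in rows.
#' @param bins number of bins, at least 2.
#' @param strategy `"width"` or `"frequency"`.
#' @return integer matrix of category codes (1-based), same shape.
#' @export
discretizeColumns <- function(values, bins = 3L,
                              strategy = c("width", "frequency")) {
  strategy <- match.arg(strategy)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  out <- matrix(1L, nrow(values), ncol(values),
                dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    ux <- unique(x)
    if (length(ux) <= bins) {
      out[, j] <- match(x, sort(ux))
    } else if (strategy == "width") {
      br <- seq(min(x), max(x), length.out = bins + 1L)
      out[, j] <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L),
                       bins)
    } else {
      br <- unique(stats::quantile(x, probs = seq(0, 1,
                                                  length.out = bins + 1L)))
      out[, j] <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L),
                       length(br) - 1L)
    }
  }
  out
}

#' Rank features by minimum-Redundancy-Maximum-Relevance
#'
#' Greedy first-order mRMR: the first feature maximizes mutual information
#' with the label (relevance); each subsequent step picks the unselected
#' feature maximizing relevance minus the mean mutual information with the
#' already-selected features (redundancy). Continuous features are
#' discretized first (see [discretizeColumns()]); ties break toward the
#' lower feature index, so the ranking is deterministic and invariant to
#' sample order.
#'
#' @param fs a [SnoFeatureSet-class], or a numeric samples x features matrix
#'   if `labels` is given.
#' @param labels 1/0 labels when `fs` is a bare matrix.
#' @param bins,strategy discretization, see [discretizeColumns()].
#' @return A [RankedFeatures-class].
#' @export
mrmrRank <- function(fs, labels = NULL, bins = 3L, strategy = "width") {
  if (is(fs, "SnoFeatureSet")) {
    values <- featureValues(fs)
    labels <- siteLabels(fs)
  } else {
    values <- as.matrix(fs)
    if (is.null(labels)) stop("labels are required with a bare matrix")
  }
  p <- ncol(values)
  if (p < 2L) stop("need at least 2 features to rank")
  if (length(unique(labels)) < 2L) stop("label vector is constant")
  disc <- discretizeColumns(values, bins = bins, strategy = strategy)
  nbin <- apply(disc, 2L, max)
  yi <- as.integer(factor(labels))
  ny <- max(yi)
  relevance <- vapply(seq_len(p), function(j) {
    miFromCodes(disc[, j], nbin[j], yi, ny)
  }, numeric(1))

  order <- integer(p)
  scores <- numeric(p)
  selected <- logical(p)
  redundancySum <- numeric(p)
  for (step in seq_len(p)) {
    if (step == 1L) {
      objective <- relevance
    } else {
      objective <- relevance - redundancySum / (step - 1L)
    }
    objective[selected] <- -Inf
    # lowest index wins among numerically tied maxima (MI sums of discrete
    # data tie exactly in real arithmetic but differ by float round-off)
    j <- which(objective >= max(objective) - 1e-10)[1]
    order[step] <- j
    scores[step] <- objective[j]
    selected[j] <- TRUE
    if (step < p) {
      rest <- which(!selected)
      redundancySum[rest] <- redundancySum[rest] +
        vapply(rest, function(i) {
          miFromCodes(disc[, i], nbin[i], disc[, j], nbin[j])
        }, numeric(1))
    }
  }
  new("RankedFeatures", order = order, scores = scores,
      featureNames = colnames(values)[order])
}

#' Write / read an mRMR ranking table
#'
#' TSV with columns `rank`, `feature_index`, `feature_name`, `score`.
#'
#' @param ranking a [RankedFeatures-class].
#' @param path TSV path.
#' @return `writeRankingTable` returns `path` invisibly; `readRankingTable`
#'   returns a [RankedFeatures-class].
#' @export
writeRankingTable <- function(ranking, path) {
  df <- data.frame(rank = seq_along(ranking@order),
                   feature_index = ranking@order,
                   feature_name = ranking@featureNames,
                   score = ranking@scores)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankingTable
#' @export
readRankingTable <- function(path) {
  if (!file.exists(path)) stop("ranking table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("rank", "feature_index", "feature_name", "score")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("ranking table missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[order(df$rank), ]
  new("RankedFeatures", order = as.integer(df$feature_index),
      scores = as.numeric(df$score),
      featureNames = as.character(df$feature_name))
}
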