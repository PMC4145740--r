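BLOCK_NAMES <- c("conservation", "aa_factor", "structure", "frequency",
                 "disorder")
BLOCK_WIDTHS <- c(conservation = 420L, aa_factor = 100L, structure = 105L,
                  frequency = 20L, disorder = 21L)

#' Amino-acid factor table
#'
#' Loads the 20 x 5 table of amino-acid factor scores used by the
#' `aa_factor` feature block. The shipped default is the five-factor
#' solution of the AAindex physicochemical property space (polarity,
#' secondary-structure propensity, molecular volume, codon diversity,
#' electrostatic charge). A user table may be supplied as TSV with columns
#' `aa`, `F1` ... `F5`, one row per standard residue.
#'
#' @param path optional path to a replacement table.
#' @return numeric 20 x 5 matrix with residue rownames.
#' @export
aaFactorTable <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_factors.tsv", package = "snoKSRC",
                        mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("aa", paste0("F", 1:5))
  if (!all(need %in% colnames(df))) {
    stop("factor table must have columns aa, F1..F5")
  }
  if (!setequal(df$aa, AA_ALPHABETICAL) || anyDuplicated(df$aa)) {
    stop("factor table must have exactly one row per standard residue")
  }
  m <- as.matrix(df[, paste0("F", 1:5)])
  if (anyNA(m)) stop("factor table contains missing values")
  rownames(m) <- df$aa
  m[AA_ALPHABETICAL, , drop = FALSE]
}

# Split a 21-char window into a character vector.
windowChars <- function(window) {
  chars <- strsplit(window, "")[[1]]
  if (length(chars) != WINDOW_WIDTH) {
    stop("window must have exactly ", WINDOW_WIDTH, " residues")
  }
  chars
}

#' Per-window feature encoders
#'
#' Each encoder turns one 21-residue window into one block of the numeric
#' representation. `map` is the window-to-protein position map from
#' [windowPositionMap()]; `NA` entries are padding and contribute zeros in
#' every block.
#'
#' * `encodeConservation()`: the 20-number PSSM row of each window position,
#'   concatenated; 21 x 20 = 420 values.
#' * `encodeAAFactor()`: the 5 amino-acid factor scores of each of the 20
#'   flank residues (the central cysteine is skipped, `X` gives zeros);
#'   20 x 5 = 100 values.
#' * `encodeStructure()`: per position, a one-hot over
#'   helix/strand/other followed by a one-hot over buried/exposed;
#'   21 x 5 = 105 values.
#' * `encodeFrequency()`: the count of each standard residue among the 20
#'   flank positions divided by 20 (`X` counts toward no channel); 20 values.
#' * `encodeDisorder()`: the per-position disorder score; 21 values.
#'
#' @param window character scalar, the 21-residue window.
#' @param ann a [ResidueAnnotation-class] covering the source protein.
#' @param map integer vector of length 21 mapping window slots to protein
#'   positions (NA = padding).
#' @param factorTable 20 x 5 matrix from [aaFactorTable()].
#' @return numeric vector of the block's width.
#' @name encoders
NULL

#' @rdname encoders
#' @export
encodeConservation <- function(window, ann, map) {
  chars <- windowChars(window)
  if (nrow(ann@pssm) == 0L) {
    stop("no PSSM available for protein ", ann@proteinId)
  }
  out <- matrix(0, WINDOW_WIDTH, 20L)
  ok <- !is.na(map)
  if (any(map[ok] < 1L | map[ok] > ann@length)) {
    stop("window map exceeds annotation for ", ann@proteinId)
  }
  out[ok, ] <- ann@pssm[map[ok], , drop = FALSE]
  as.numeric(t(out))
}

#' @rdname encoders
#' @export
encodeAAFactor <- function(window, factorTable) {
  chars <- windowChars(window)[-WINDOW_CENTER]
  out <- matrix(0, WINDOW_WIDTH - 1L, 5L)
  known <- chars %in% rownames(factorTable)
  out[known, ] <- factorTable[chars[known], , drop = FALSE]
  as.numeric(t(out))
}

#' @rdname encoders
#' @export
encodeStructure <- function(window, ann, map) {
  if (length(ann@ss) == 0L || length(ann@acc) == 0L) {
    stop("no secondary-structure/accessibility track for ", ann@proteinId)
  }
  out <- matrix(0, WINDOW_WIDTH, 5L)
  ok <- which(!is.na(map))
  ssIdx <- match(ann@ss[map[ok]], SS_CLASSES)
  accIdx <- match(ann@acc[map[ok]], ACC_CLASSES)
  if (anyNA(ssIdx) || anyNA(accIdx)) {
    stop("unknown structure class in annotation for ", ann@proteinId)
  }
  out[cbind(ok, ssIdx)] <- 1
  out[cbind(ok, 3L + accIdx)] <- 1
  as.numeric(t(out))
}

#' @rdname encoders
#' @export
encodeFrequency <- function(window) {
  chars <- windowChars(window)[-WINDOW_CENTER]
  counts <- vapply(AA_ALPHABETICAL, function(a) sum(chars == a), numeric(1))
  counts / (WINDOW_WIDTH - 1L)
}

#' @rdname encoders
#' @export
encodeDisorder <- function(window, ann, map) {
  if (length(ann@disorder) == 0L) {
    stop("no disorder track for ", ann@proteinId)
  }
  out <- numeric(WINDOW_WIDTH)
  ok <- !is.na(map)
  out[ok] <- ann@disorder[map[ok]]
  out
}

# Ordered feature names for one block.
blockFeatureNames <- function(block) {
  switch(block,
    conservation = as.vector(t(outer(seq_len(WINDOW_WIDTH), AA_PSSM_ORDER,
                                     function(i, a) sprintf("cons.%02d.%s",
                                                            i, a)))),
    aa_factor = as.vector(t(outer(seq_len(WINDOW_WIDTH)[-WINDOW_CENTER],
                                  paste0("F", 1:5),
                                  function(i, f) sprintf("aaf.%02d.%s",
                                                         i, f)))),
    structure = as.vector(t(outer(seq_len(WINDOW_WIDTH),
                                  c(SS_CLASSES, ACC_CLASSES),
                                  function(i, c) sprintf("struct.%02d.%s",
                                                         i, c)))),
    frequency = paste0("freq.", AA_ALPHABETICAL),
    disorder = sprintf("dis.%02d", seq_len(WINDOW_WIDTH)),
    stop("unknown feature block: ", block)
  )
}

#' Construct a SnoFeatureSet
#'
#' @param values numeric matrix, samples in rows, named features in columns.
#' @param labels integer vector of 1/0 sample labels.
#' @param proteinId,position optional sample provenance.
#' @param block optional character vector assigning each feature to a block;
#'   defaults to the prefix of the feature name.
#' @return A [SnoFeatureSet-class].
#' @export
snoFeatureSet <- function(values, labels, proteinId = NULL, position = NULL,
                          block = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("feature columns must be named")
  }
  if (nrow(values) != length(labels)) {
    stop("one label per sample row is required")
  }
  if (is.null(block)) block <- sub("\\..*$", "", colnames(values))
  cd <- S4Vectors::DataFrame(label = as.integer(labels))
  if (!is.null(proteinId)) cd$protein_id <- as.character(proteinId)
  if (!is.null(position)) cd$position <- as.integer(position)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)),
    rowData = S4Vectors::DataFrame(block = block, row.names = colnames(values)),
    colData = cd)
  new("SnoFeatureSet", se)
}

#' Assemble the full feature matrix for a window set
#'
#' Concatenates the enabled feature blocks for every window, in the fixed
#' order conservation, amino-acid factors, secondary structure +
#' accessibility, flank frequency, disorder. With all blocks enabled each
#' sample is a 666-dimensional vector (420 + 100 + 105 + 20 + 21); disabling
#' blocks shrinks the width accordingly. Feature names are
#' `<block>.<position>.<channel>`, so mRMR ranks remain attributable to
#' blocks and window positions.
#'
#' @param windows a [PeptideWindowSet-class].
#' @param annotations named list of [ResidueAnnotation-class], indexed by
#'   protein id; required for the conservation, structure and disorder
#'   blocks.
#' @param factorTable 20 x 5 matrix, defaults to [aaFactorTable()].
#' @param blocks character vector of blocks to enable.
#' @return A [SnoFeatureSet-class] of width `sum(widths of enabled blocks)`.
#' @export
assembleFeatures <- function(windows, annotations = NULL, factorTable = NULL,
                             blocks = BLOCK_NAMES) {
  blocks <- match.arg(blocks, BLOCK_NAMES, several.ok = TRUE)
  blocks <- BLOCK_NAMES[BLOCK_NAMES %in% blocks]
  needAnn <- c("conservation", "structure", "disorder")
  if (any(blocks %in% needAnn) && is.null(annotations)) {
    stop("annotations are required for block(s): ",
         paste(intersect(blocks, needAnn), collapse = ", "))
  }
  if ("aa_factor" %in% blocks && is.null(factorTable)) {
    factorTable <- aaFactorTable()
  }
  featNames <- unlist(lapply(blocks, blockFeatureNames), use.names = FALSE)
  blockOf <- rep(blocks, BLOCK_WIDTHS[blocks])
  n <- length(windows)
  seqs <- windowSequences(windows)
  vals <- matrix(0, nrow = n, ncol = length(featNames))
  for (i in seq_len(n)) {
    ann <- NULL
    if (any(blocks %in% needAnn)) {
      ann <- annotations[[windows@proteinId[i]]]
      if (is.null(ann)) {
        stop("missing annotation for protein ", windows@proteinId[i])
      }
    }
    map <- windowPositionMap(windows@sitePos[i], windows@protLength[i],
                             windows@padMode)
    vec <- unlist(lapply(blocks, function(b) {
      switch(b,
        conservation = encodeConservation(seqs[i], ann, map),
        aa_factor = encodeAAFactor(seqs[i], factorTable),
        structure = encodeStructure(seqs[i], ann, map),
        frequency = encodeFrequency(seqs[i]),
        disorder = encodeDisorder(seqs[i], ann, map))
    }), use.names = FALSE)
    if (length(vec) != length(featNames)) {
      stop("internal error: produced width ", length(vec),
           " does not match declared width ", length(featNames))
    }
    vals[i, ] <- vec
  }
  colnames(vals) <- featNames
  snoFeatureSet(vals, siteLabels(windows),
                proteinId = proteinIds(windows),
                position = sitePositions(windows),
                block = blockOf)
}

#' Write / read a labeled feature table
#'
#' TSV persistence for [SnoFeatureSet-class]: optional `protein_id` and
#' `position` columns, then `label`, then one named column per feature.
#'
#' @param fs a [SnoFeatureSet-class].
#' @param path TSV path.
#' @return `writeFeatureTable` returns `path` invisibly; `readFeatureTable`
#'   returns a [SnoFeatureSet-class].
#' @export
writeFeatureTable <- function(fs, path) {
  cd <- SummarizedExperiment::colData(fs)
  df <- data.frame(row.names = seq_len(ncol(fs)))
  if ("protein_id" %in% colnames(cd)) df$protein_id <- cd$protein_id
  if ("position" %in% colnames(cd)) df$position <- cd$position
  df$label <- cd$label
  vals <- featureValues(fs)
  out <- cbind(df, as.data.frame(vals, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"label" %in% colnames(df)) stop("feature table must have label column")
  meta <- intersect(c("protein_id", "position", "label"), colnames(df))
  featCols <- setdiff(colnames(df), meta)
  if (length(featCols) == 0L) stop("feature table has no feature columns")
  vals <- as.matrix(df[, featCols, drop = FALSE])
  if (!is.numeric(vals)) stop("feature columns must be numeric")
  snoFeatureSet(vals, df$label,
                proteinId = if ("protein_id" %in% meta) df$protein_id,
                position = if ("position" %in% meta) df$position)
}
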