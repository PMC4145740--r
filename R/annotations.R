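#' Construct a per-residue annotation bundle
#'
#' @param proteinId protein identifier.
#' @param length protein length in residues.
#' @param pssm optional length x 20 numeric matrix (PSI-BLAST column order
#'   `A R N D C Q E G H I L K M F P S T W Y V`).
#' @param ss optional character vector over `helix`/`strand`/`other`.
#' @param acc optional character vector over `buried`/`exposed`.
#' @param disorder optional numeric vector of per-residue disorder scores
#'   in \[0, 1\].
#' @return A [ResidueAnnotation-class].
#' @export
residueAnnotation <- function(proteinId, length, pssm = NULL, ss = NULL,
                              acc = NULL, disorder = NULL) {
  new("ResidueAnnotation",
      proteinId = as.character(proteinId),
      length = as.integer(length),
      pssm = if (is.null(pssm)) matrix(0, 0, 20) else as.matrix(pssm),
      ss = if (is.null(ss)) character(0) else as.character(ss),
      acc = if (is.null(acc)) character(0) else as.character(acc),
      disorder = if (is.null(disorder)) numeric(0) else as.numeric(disorder))
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the text profile written by `psiblast -out_ascii_pssm`. Data lines
#' carry a 1-based position, the query residue, 20 log-odds scores and 20
#' weighted observed percentages; header, blank and footer (K/Lambda) lines
#' are skipped. `scale` selects which section populates the matrix:
#' `"logodds"` (default) keeps the integer log-odds, `"percent"` rescales the
#' percentage section to \[0, 1\].
#'
#' @param path path to the ASCII PSSM file.
#' @param proteinId id recorded in the result; defaults to the file stem.
#' @param scale `"logodds"` or `"percent"`.
#' @return A [ResidueAnnotation-class] with only the PSSM track set.
#' @export
readPSSM <- function(path, proteinId = NULL,
                     scale = c("logodds", "percent")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(proteinId)) {
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  rows <- list()
  positions <- integer(0)
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) == 0L || !grepl("^[0-9]+$", tok[1])) next
    if (length(tok) < 42L) {
      stop(sprintf("PSSM line %d is truncated (%d fields, need >= 42): %s",
                   ln, length(tok), path))
    }
    vals <- suppressWarnings(as.numeric(tok[3:42]))
    if (anyNA(vals)) {
      stop(sprintf("PSSM line %d has non-numeric scores: %s", ln, path))
    }
    positions <- c(positions, as.integer(tok[1]))
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) stop("no PSSM rows found in ", path)
  if (!identical(positions, seq_along(positions))) {
    stop("PSSM positions are not consecutive from 1 in ", path)
  }
  m <- do.call(rbind, rows)
  m <- if (scale == "logodds") m[, 1:20, drop = FALSE] else
    m[, 21:40, drop = FALSE] / 100
  colnames(m) <- AA_PSSM_ORDER
  residueAnnotation(proteinId, nrow(m), pssm = m)
}

#' Write a PSI-BLAST-style ASCII PSSM
#'
#' Emits the dialect [readPSSM()] reads: two header lines, a column-label
#' line, then one row per residue with the 20 log-odds scores and 20
#' percentage scores. Used mainly by the synthetic-data generator.
#'
#' @param pssm length x 20 numeric matrix of log-odds scores.
#' @param residues character vector of residues (one letter per row).
#' @param path output path.
#' @param percent optional length x 20 matrix of percentages; defaults to 0.
#' @return `path`, invisibly.
#' @export
writePSSM <- function(pssm, residues, path, percent = NULL) {
  stopifnot(ncol(pssm) == 20L, length(residues) == nrow(pssm))
  if (is.null(percent)) percent <- matrix(0L, nrow(pssm), 20L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               paste("Last position-specific scoring matrix computed,",
                     "weighted observed percentages rounded down,",
                     "information per position, and relative weight of",
                     "gapless real matches to pseudocounts")), con)
  writeLines(paste0("            ",
                    paste(sprintf("%3s", c(AA_PSSM_ORDER, AA_PSSM_ORDER)),
                          collapse = " ")), con)
  for (i in seq_len(nrow(pssm))) {
    writeLines(paste0(sprintf("%5d %s ", i, residues[i]),
                      paste(sprintf("%3d", as.integer(pssm[i, ])),
                            collapse = " "), " ",
                      paste(sprintf("%3d", as.integer(percent[i, ])),
                            collapse = " "), "  0.00 0.00"), con)
  }
  invisible(path)
}

#' Read per-residue secondary structure / accessibility predictions
#'
#' TSV with a header and columns `position` (1-based, consecutive), `ss`
#' (`helix`/`strand`/`other`) and `acc` (`buried`/`exposed`). Lines starting
#' with `#` are skipped.
#'
#' @param path path to the TSV file.
#' @param proteinId id recorded in the result; defaults to the file stem.
#' @return A [ResidueAnnotation-class] with the ss and acc tracks set.
#' @export
readSSAcc <- function(path, proteinId = NULL) {
  if (!file.exists(path)) stop("ss/acc file not found: ", path)
  if (is.null(proteinId)) proteinId <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("position", "ss", "acc")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("ss/acc table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
    stop("ss/acc positions are not consecutive from 1 in ", path)
  }
  bad <- which(!df$ss %in% SS_CLASSES)
  if (length(bad)) {
    stop(sprintf("unknown secondary-structure class \"%s\" at line %d in %s",
                 df$ss[bad[1]], bad[1] + 1L, path))
  }
  bad <- which(!df$acc %in% ACC_CLASSES)
  if (length(bad)) {
    stop(sprintf("unknown accessibility class \"%s\" at line %d in %s",
                 df$acc[bad[1]], bad[1] + 1L, path))
  }
  residueAnnotation(proteinId, nrow(df), ss = df$ss, acc = df$acc)
}

#' Read per-residue disorder scores
#'
#' TSV with a header and columns `position` (1-based, consecutive) and
#' `score` (disorder probability in \[0, 1\]).
#'
#' @inheritParams readSSAcc
#' @return A [ResidueAnnotation-class] with the disorder track set.
#' @export
readDisorder <- function(path, proteinId = NULL) {
  if (!file.exists(path)) stop("disorder file not found: ", path)
  if (is.null(proteinId)) proteinId <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("position", "score"), colnames(df))
  if (length(miss)) {
    stop("disorder table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!identical(as.integer(df$position), seq_len(nrow(df)))) {
    stop("disorder positions are not consecutive from 1 in ", path)
  }
  residueAnnotation(proteinId, nrow(df), disorder = df$score)
}

# Merge annotation tracks for the same protein; lengths must agree.
mergeAnnotations <- function(...) {
  anns <- Filter(Negate(is.null), list(...))
  stopifnot(length(anns) >= 1L)
  L <- unique(vapply(anns, function(a) a@length, integer(1)))
  id <- unique(vapply(anns, function(a) a@proteinId, character(1)))
  if (length(L) != 1L) {
    stop("annotation tracks for ", paste(id, collapse = "/"),
         " disagree on protein length")
  }
  pick <- function(get, empty) {
    for (a in anns) {
      v <- get(a)
      if (NROW(v) > 0) return(v)
    }
    empty
  }
  residueAnnotation(id[1], L,
                    pssm = { m <- pick(function(a) a@pssm, NULL); m },
                    ss = pick(function(a) a@ss, NULL),
                    acc = pick(function(a) a@acc, NULL),
                    disorder = pick(function(a) a@disorder, NULL))
}

#' Read a directory of per-protein annotation files
#'
#' Expects the layout written by [writeSimulatedData()]: `pssm/<id>.pssm`
#' (PSI-BLAST ASCII), `ss_acc/<id>.tsv` and `disorder/<id>.tsv`. Any
#' subdirectory may be absent when the corresponding feature blocks are
#' disabled.
#'
#' @param dir annotation directory.
#' @param ids protein ids to load.
#' @param pssmScale passed to [readPSSM()].
#' @return Named list of [ResidueAnnotation-class], one per id.
#' @export
readAnnotationDir <- function(dir, ids, pssmScale = "logodds") {
  out <- list()
  for (id in ids) {
    tracks <- list()
    p <- file.path(dir, "pssm", paste0(id, ".pssm"))
    if (file.exists(p)) tracks$pssm <- readPSSM(p, id, scale = pssmScale)
    p <- file.path(dir, "ss_acc", paste0(id, ".tsv"))
    if (file.exists(p)) tracks$ss <- readSSAcc(p, id)
    p <- file.path(dir, "disorder", paste0(id, ".tsv"))
    if (file.exists(p)) tracks$dis <- readDisorder(p, id)
    if (length(tracks) == 0L) stop("no annotation files found for ", id)
    out[[id]] <- do.call(mergeAnnotations, unname(tracks))
  }
  out
}
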