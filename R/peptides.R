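#' Read protein sequences from FASTA
#'
#' Reads a FASTA file, uppercases sequences and maps every character outside
#' the 20 standard amino-acid letters (including selenocysteine `U` and other
#' ambiguity codes) to `"X"`, since the feature encoders only define values
#' for the standard residues. Record ids are the first whitespace-delimited
#' token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::AAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MCK"), fa)
#' readFastaProteins(fa)
#' @export
readFastaProteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(aas))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate protein id(s) in FASTA: ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(aas))
  seqs <- gsub(sprintf("[^%s]", paste(AA_ALPHABETICAL, collapse = "")),
               "X", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ", path)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read a site annotation table
#'
#' The table is TSV with a header and columns `protein_id`, `position`
#' (1-based cysteine position) and `label` (1 = S-nitrosylated, 0 = not).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns protein_id (character), position (integer),
#'   label (integer).
#' @export
readSiteTable <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("site table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(df$label %in% c(0L, 1L))) stop("site labels must be 0 or 1")
  data.frame(protein_id = as.character(df$protein_id),
             position = as.integer(df$position),
             label = as.integer(df$label),
             stringsAsFactors = FALSE)
}

#' Window-to-protein position map
#'
#' For a site at `sitePos` in a protein of `protLength` residues, returns the
#' protein position covered by each of the 21 window slots; `NA` entries are
#' padding. Under `padMode = "center"` the map is `sitePos - 10 ... sitePos +
#' 10` with out-of-range entries `NA`; under `padMode = "end"` the available
#' residues are left-aligned and `NA` padding trails.
#'
#' @param sitePos 1-based cysteine position.
#' @param protLength protein length.
#' @param padMode `"center"` or `"end"`.
#' @return integer vector of length 21.
#' @export
windowPositionMap <- function(sitePos, protLength, padMode = "center") {
  if (padMode == "center") {
    pos <- seq.int(sitePos - 10L, sitePos + 10L)
    pos[pos < 1L | pos > protLength] <- NA_integer_
  } else {
    start <- max(1L, sitePos - 10L)
    end <- min(protLength, sitePos + 10L)
    pos <- c(seq.int(start, end),
             rep(NA_integer_, WINDOW_WIDTH - (end - start + 1L)))
  }
  pos
}

#' Extract cysteine-centered peptide windows
#'
#' Cuts a 21-residue window around each annotated cysteine: the site residue
#' plus 10 residues upstream and 10 downstream. Positions that fall outside
#' the protein are filled with `"X"`. With `padMode = "center"` the padding
#' sits on the deficient side so the cysteine is always the 11th residue;
#' `padMode = "end"` instead appends all padding after the available
#' residues (truncated windows are then left-aligned).
#'
#' @param proteins a named [Biostrings::AAStringSet], e.g. from
#'   [readFastaProteins()].
#' @param sites data.frame with columns `protein_id`, `position`, `label`
#'   (see [readSiteTable()]).
#' @param padMode `"center"` (default) or `"end"`.
#' @return A [PeptideWindowSet-class].
#' @examples
#' prot <- Biostrings::AAStringSet(c(p1 = "ACDEFGHIKLMNPQRSTVWYA"))
#' sites <- data.frame(protein_id = "p1", position = 2, label = 1)
#' windowSequences(extractWindows(prot, sites))
#' @export
extractWindows <- function(proteins, sites, padMode = c("center", "end")) {
  padMode <- match.arg(padMode)
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop("proteins must carry unique names")
  }
  seqs <- as.character(proteins)
  n <- nrow(sites)
  out <- character(n)
  protLength <- integer(n)
  for (i in seq_len(n)) {
    id <- sites$protein_id[i]
    pos <- sites$position[i]
    if (!id %in% names(seqs)) stop("unknown protein id: ", id)
    s <- seqs[[id]]
    L <- nchar(s)
    if (pos < 1L || pos > L) {
      stop(sprintf("site position out of range: %s position %d (length %d)",
                   id, pos, L))
    }
    if (substr(s, pos, pos) != "C") {
      stop(sprintf("site is not a cysteine: %s position %d", id, pos))
    }
    map <- windowPositionMap(pos, L, padMode)
    chars <- rep("X", WINDOW_WIDTH)
    ok <- !is.na(map)
    chars[ok] <- substring(s, map[ok], map[ok])
    out[i] <- paste(chars, collapse = "")
    protLength[i] <- L
  }
  new("PeptideWindowSet",
      windows = Biostrings::AAStringSet(out),
      proteinId = as.character(sites$protein_id),
      sitePos = as.integer(sites$position),
      protLength = protLength,
      label = as.integer(sites$label),
      padMode = padMode)
}

#' Stratified train/test split
#'
#' Splits windows into training and testing partitions so the
#' positive-to-negative ratio of each partition matches the whole set up to
#' integer rounding: per class, round-half-up of `n_class * trainFraction`
#' samples go to training and the remainder to testing, with the within-class
#' assignment drawn as a seeded permutation. For the canonical 827 positive /
#' 1689 negative corpus at `trainFraction = 0.8` this yields 662/1351 training
#' and 165/338 testing samples.
#'
#' @param windows a [PeptideWindowSet-class].
#' @param trainFraction fraction of each class assigned to training,
#'   in (0, 1). Default 0.8 (a 4:1 split).
#' @param seed integer seed for the within-class permutation.
#' @return list with elements `train` and `test`, both
#'   [PeptideWindowSet-class].
#' @export
stratifiedSplit <- function(windows, trainFraction = 0.8, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  lab <- siteLabels(windows)
  classes <- sort(unique(lab))
  if (length(classes) < 2L) stop("both classes must be present")
  set.seed(as.integer(seed))
  trainIdx <- integer(0)
  testIdx <- integer(0)
  for (cl in classes) {
    idx <- which(lab == cl)
    if (length(idx) < 2L) stop("class ", cl, " has fewer than 2 members")
    perm <- sample(idx)
    nTrain <- floor(length(idx) * trainFraction + 0.5)
    trainIdx <- c(trainIdx, perm[seq_len(nTrain)])
    testIdx <- c(testIdx, perm[-seq_len(nTrain)])
  }
  list(train = windows[sort(trainIdx)], test = windows[sort(testIdx)])
}

#' Write / read a window table
#'
#' Serializes a [PeptideWindowSet-class] as TSV with columns `protein_id`,
#' `position`, `window` and `label` (plus a `prot_length` column so the
#' window-to-protein position map survives the round trip).
#'
#' @param x a [PeptideWindowSet-class].
#' @param path output TSV path.
#' @return `writeWindowTable` returns `path` invisibly; `readWindowTable`
#'   returns a [PeptideWindowSet-class].
#' @export
writeWindowTable <- function(x, path) {
  df <- data.frame(protein_id = x@proteinId, position = x@sitePos,
                   window = as.character(x@windows), label = x@label,
                   prot_length = x@protLength, pad_mode = x@padMode,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowTable
#' @export
readWindowTable <- function(path) {
  if (!file.exists(path)) stop("window table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "window", "label", "prot_length",
            "pad_mode")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("window table missing column(s): ", paste(miss, collapse = ", "))
  }
  new("PeptideWindowSet",
      windows = Biostrings::AAStringSet(df$window),
      proteinId = as.character(df$protein_id),
      sitePos = as.integer(df$position),
      protLength = as.integer(df$prot_length),
      label = as.integer(df$label),
      padMode = unique(df$pad_mode))
}
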