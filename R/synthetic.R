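#' Synthetic labeled feature matrix
#'
#' Generates a two-class numeric dataset with a controllable number of
#' informative and pure-noise features. Informative columns are drawn
#' `Normal(+effect / 2, 1)` in the positive class and `Normal(-effect / 2,
#' 1)` in the negative class; noise columns are `Normal(0, 1)` everywhere.
#' Column names flag the ground truth (`inf.*` vs `noise.*`) and
#' `rowData(fs)$informative` records it, so feature-selection recovery can
#' be scored. Defaults give the 1:2 class imbalance (67 positives, 133
#' negatives, n = 200) with 5 informative features shifted by 3 SD among 45
#' noise features.
#'
#' @param nPos,nNeg class sample counts.
#' @param nInformative,nNoise feature counts (at least one feature total).
#' @param effect between-class mean shift of informative features, in SD
#'   units.
#' @param seed integer seed; the result is a deterministic function of the
#'   arguments.
#' @return A [SnoFeatureSet-class] with `label` 1 for positives.
#' @export
makeFeatureData <- function(nPos = 67L, nNeg = 133L, nInformative = 5L,
                            nNoise = 45L, effect = 3, seed = 1L) {
  stopifnot(nPos >= 0, nNeg >= 0, nInformative >= 0, nNoise >= 0,
            nInformative + nNoise >= 1)
  set.seed(as.integer(seed))
  n <- nPos + nNeg
  p <- nInformative + nNoise
  labels <- rep(c(1L, 0L), c(nPos, nNeg))
  values <- matrix(stats::rnorm(n * p), n, p)
  if (nInformative > 0) {
    shift <- ifelse(labels == 1L, effect / 2, -effect / 2)
    values[, seq_len(nInformative)] <-
      values[, seq_len(nInformative), drop = FALSE] + shift
  }
  colnames(values) <- c(
    if (nInformative > 0) sprintf("inf.%02d", seq_len(nInformative)),
    if (nNoise > 0) sprintf("noise.%02d", seq_len(nNoise)))
  fs <- snoFeatureSet(values, labels,
                      block = rep(c("informative", "noise"),
                                  c(nInformative, nNoise)))
  SummarizedExperiment::rowData(fs)$informative <-
    rep(c(TRUE, FALSE), c(nInformative, nNoise))
  fs
}

#' Random low-coherence dictionary
#'
#' Draws a d x n matrix of unit-norm columns and iteratively de-correlates
#' the worst pair until the mutual coherence (largest absolute pairwise
#' inner product) falls below `targetCoherence`, yielding a well-spread
#' frame. Such dictionaries are the standard benchmark setting for sparse
#' support recovery, where greedy pursuit is reliable once the coherence is
#' small.
#'
#' @param d ambient dimension; `n` number of columns (n > d allowed).
#' @param n number of dictionary columns.
#' @param targetCoherence coherence the de-correlation iterates toward.
#' @param maxIter iteration cap.
#' @return d x n numeric matrix with unit-norm columns.
#' @export
makeLowCoherenceDictionary <- function(d, n, targetCoherence = 0.35,
                                       maxIter = 3000L) {
  A <- matrix(stats::rnorm(d * n), d, n)
  A <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
  for (it in seq_len(maxIter)) {
    G <- crossprod(A)
    diag(G) <- 0
    if (max(abs(G)) < targetCoherence) break
    worst <- which(abs(G) == max(abs(G)), arr.ind = TRUE)[1, ]
    i <- worst[1]
    j <- worst[2]
    g <- G[i, j]
    ai <- A[, i] - 0.2 * g * A[, j]
    aj <- A[, j] - 0.2 * g * A[, i]
    A[, i] <- ai / sqrt(sum(ai^2))
    A[, j] <- aj / sqrt(sum(aj^2))
  }
  A
}

# Draw one flank residue alphabet with optional acidic enrichment.
sampleResidues <- function(n, acidicWeight) {
  w <- rep(1, 20)
  names(w) <- AA_ALPHABETICAL
  w[c("D", "E")] <- acidicWeight
  sample(AA_ALPHABETICAL, n, replace = TRUE, prob = w / sum(w))
}

#' Synthetic protein / site / annotation corpus
#'
#' Emulates the shape of an S-nitrosylation training corpus: random protein
#' sequences with one planted central cysteine site each, a 1:2
#' positive-to-negative default imbalance at the full corpus size (827
#' positives, 1689 negatives), and per-residue annotation tracks of
#' consistent length. Positive-site flanks are compositionally biased
#' (acidic residues D/E enriched by `acidicBias`), so the frequency and
#' amino-acid-factor blocks carry class signal; the synthetic PSSM adds a
#' fixed bonus on the observed residue's column, propagating the same
#' compositional signal into the conservation block. Structure,
#' accessibility and disorder tracks are uninformative noise. True
#' S-nitrosylation sequence motifs are not emulated.
#'
#' @param nPos,nNeg numbers of positive and negative sites (one protein per
#'   site).
#' @param minLength,maxLength protein length range.
#' @param acidicBias sampling weight of D and E in positive flanks relative
#'   to weight 1 for every other residue.
#' @param seed integer seed.
#' @return list with `proteins` ([Biostrings::AAStringSet]), `sites`
#'   (data.frame: protein_id, position, label) and `annotations` (named list
#'   of [ResidueAnnotation-class]).
#' @export
makePeptideData <- function(nPos = 827L, nNeg = 1689L, minLength = 60L,
                            maxLength = 120L, acidicBias = 6, seed = 1L) {
  stopifnot(nPos >= 0, nNeg >= 0, nPos + nNeg >= 1,
            minLength >= 21L, maxLength >= minLength)
  set.seed(as.integer(seed))
  n <- nPos + nNeg
  labels <- rep(c(1L, 0L), c(nPos, nNeg))
  ids <- sprintf("prot%04d", seq_len(n))
  seqs <- character(n)
  pos <- integer(n)
  annotations <- vector("list", n)
  names(annotations) <- ids
  for (i in seq_len(n)) {
    L <- sample(minLength:maxLength, 1L)
    chars <- sample(AA_ALPHABETICAL, L, replace = TRUE)
    p <- sample(seq_len(L), 1L)
    chars[p] <- "C"
    flank <- setdiff(seq.int(max(1L, p - 10L), min(L, p + 10L)), p)
    bias <- if (labels[i] == 1L) acidicBias else 1
    chars[flank] <- sampleResidues(length(flank), bias)
    seqs[i] <- paste(chars, collapse = "")
    pos[i] <- p

    pssm <- matrix(round(stats::rnorm(L * 20, 0, 2)), L, 20)
    colnames(pssm) <- AA_PSSM_ORDER
    pssm[cbind(seq_len(L), match(chars, AA_PSSM_ORDER))] <-
      pssm[cbind(seq_len(L), match(chars, AA_PSSM_ORDER))] + 6
    annotations[[i]] <- residueAnnotation(
      ids[i], L, pssm = pssm,
      ss = sample(SS_CLASSES, L, replace = TRUE),
      acc = sample(ACC_CLASSES, L, replace = TRUE),
      disorder = round(stats::runif(L), 3))
  }
  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- ids
  list(proteins = proteins,
       sites = data.frame(protein_id = ids, position = pos, label = labels,
                          stringsAsFactors = FALSE),
       annotations = annotations)
}

#' Write a simulated corpus to disk
#'
#' Writes the artifacts of [makePeptideData()] in the formats the pipeline
#' readers consume: `proteins.fasta`, `sites.tsv`, and an `annotations/`
#' directory with `pssm/<id>.pssm` (PSI-BLAST ASCII dialect),
#' `ss_acc/<id>.tsv` and `disorder/<id>.tsv`.
#'
#' @param pep list from [makePeptideData()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedData <- function(pep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(pep$proteins, file.path(dir, "proteins.fasta"))
  utils::write.table(pep$sites, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  annDir <- file.path(dir, "annotations")
  for (sub in c("pssm", "ss_acc", "disorder")) {
    dir.create(file.path(annDir, sub), recursive = TRUE,
               showWarnings = FALSE)
  }
  for (id in names(pep$annotations)) {
    ann <- pep$annotations[[id]]
    residues <- strsplit(as.character(pep$proteins[[id]]), "")[[1]]
    writePSSM(ann@pssm, residues,
              file.path(annDir, "pssm", paste0(id, ".pssm")))
    utils::write.table(
      data.frame(position = seq_len(ann@length), ss = ann@ss,
                 acc = ann@acc),
      file.path(annDir, "ss_acc", paste0(id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(position = seq_len(ann@length), score = ann@disorder),
      file.path(annDir, "disorder", paste0(id, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
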