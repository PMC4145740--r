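# Small fixture builders shared across test files.

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# A fully annotated toy protein: constant tracks make expected feature
# values easy to state by hand.
toyAnnotation <- function(id, L, pssmValue = 1, ss = "helix",
                          acc = "exposed", disorder = 0.5) {
  residueAnnotation(
    id, L,
    pssm = matrix(pssmValue, L, 20),
    ss = rep(ss, L),
    acc = rep(acc, L),
    disorder = rep(disorder, L))
}

# One window cut from an explicit protein sequence.
windowFromSeq <- function(seq, pos, label = 1L, id = "toy",
                          padMode = "center") {
  prot <- Biostrings::AAStringSet(stats::setNames(seq, id))
  extractWindows(prot, data.frame(protein_id = id, position = pos,
                                  label = label), padMode = padMode)
}
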