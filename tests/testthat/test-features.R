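test_that("conservation block copies PSSM rows and zeros padding", {
  # window near the N-terminus: first 9 positions are padding
  w <- windowFromSeq("ACDEFGHIKLMNPQRSTVWYA", 2)
  ann <- toyAnnotation("toy", 21, pssmValue = 1)
  map <- windowPositionMap(2L, 21L)
  v <- encodeConservation(windowSequences(w), ann, map)
  expect_length(v, 420L)
  expect_true(all(v[1:180] == 0))     # 9 padded positions x 20
  expect_true(all(v[181:420] == 1))   # 12 real positions x 20

  # fully interior window: row i equals the PSSM row at sitePos - 11 + i
  L <- 40L
  set.seed(17)
  pssm <- matrix(rnorm(L * 20), L, 20)
  ann <- residueAnnotation("toy", L, pssm = pssm)
  seq <- paste(c(sample(c("A", "G"), 19, TRUE), "C",
                 sample(c("A", "G"), L - 20, TRUE)), collapse = "")
  w <- windowFromSeq(seq, 20)
  map <- windowPositionMap(20L, L)
  v <- encodeConservation(windowSequences(w), ann, map)
  for (i in c(1L, 11L, 21L)) {
    expect_equal(v[(i - 1) * 20 + 1:20], pssm[20 - 11 + i, ])
  }
})

test_that("aa-factor block emits per-flank-residue factors, skipping center", {
  ft <- aaFactorTable()
  # all-X flanks give all zeros
  w <- windowFromSeq("MC", 2)
  v <- encodeAAFactor(windowSequences(w), ft)
  expect_length(v, 100L)
  expect_identical(sum(v[1:45] != 0), 0L)  # 9 leading X
  expect_equal(v[46:50], unname(ft["M", ]))
  expect_true(all(v[51:100] == 0))

  # constant alanine flanks repeat the alanine 5-vector 20 times
  w <- windowFromSeq(paste0(strrep("A", 10), "C", strrep("A", 10)), 11)
  v <- encodeAAFactor(windowSequences(w), ft)
  expect_equal(v, rep(unname(ft["A", ]), 20))

  # swapping two flank residues permutes exactly those 5-blocks
  s1 <- paste0("KR", strrep("A", 8), "C", strrep("A", 10))
  s2 <- paste0("RK", strrep("A", 8), "C", strrep("A", 10))
  v1 <- encodeAAFactor(windowSequences(windowFromSeq(s1, 11)), ft)
  v2 <- encodeAAFactor(windowSequences(windowFromSeq(s2, 11)), ft)
  expect_equal(v1[1:5], v2[6:10])
  expect_equal(v1[6:10], v2[1:5])
  expect_equal(v1[-(1:10)], v2[-(1:10)])
})

test_that("structure block is a valid double one-hot with zero padding", {
  w <- windowFromSeq("ACDEFGHIKLMNPQRSTVWYA", 2)
  ann <- toyAnnotation("toy", 21, ss = "helix", acc = "exposed")
  map <- windowPositionMap(2L, 21L)
  v <- encodeStructure(windowSequences(w), ann, map)
  expect_length(v, 105L)
  m <- matrix(v, ncol = 5, byrow = TRUE)
  expect_true(all(m[1:9, ] == 0))                   # padding rows
  expect_true(all(m[10:21, ] == rep(c(1, 0, 0, 0, 1), each = 12)))
  expect_true(all(rowSums(m[10:21, 1:3, drop = FALSE]) == 1))
  expect_true(all(rowSums(m[10:21, 4:5, drop = FALSE]) == 1))
  expect_true(all(v %in% c(0, 1)))
})

test_that("frequency block is the flank composition over 20, X excluded", {
  w <- windowFromSeq(paste0(strrep("A", 10), "C", strrep("A", 10)), 11)
  v <- encodeFrequency(windowSequences(w))
  expect_length(v, 20L)
  expect_equal(unname(v[names(v) == "A"]), 1)
  expect_equal(sum(v), 1)

  # 10 G + 10 X flanks: G channel 0.5, total 0.5
  w <- windowFromSeq(paste0(strrep("G", 10), "C"), 11)
  v <- encodeFrequency(windowSequences(w))
  expect_equal(unname(v[names(v) == "G"]), 0.5)
  expect_equal(sum(v), 0.5)
})

test_that("disorder block copies per-position scores with zero padding", {
  L <- 21L
  ann <- residueAnnotation("toy", L, disorder = seq(0, 1, length.out = L))
  w <- windowFromSeq("ACDEFGHIKLMNPQRSTVWYA", 2)
  map <- windowPositionMap(2L, L)
  v <- encodeDisorder(windowSequences(w), ann, map)
  expect_length(v, 21L)
  expect_true(all(v[1:9] == 0))
  expect_equal(v[10:21], seq(0, 1, length.out = L)[1:12])
})

test_that("assembled width is 666 with all blocks and shrinks per block", {
  pep <- makePeptideData(nPos = 4, nNeg = 8, seed = 21)
  win <- extractWindows(pep$proteins, pep$sites)
  fs <- assembleFeatures(win, pep$annotations)
  expect_identical(nrow(fs), 666L)
  expect_identical(ncol(fs), 12L)
  blocks <- SummarizedExperiment::rowData(fs)$block
  expect_identical(as.integer(table(blocks)[c("conservation", "aa_factor",
                                              "structure", "frequency",
                                              "disorder")]),
                   c(420L, 100L, 105L, 20L, 21L))
  expect_false(anyDuplicated(rownames(fs)) > 0)
  expect_true("freq.C" %in% rownames(fs))

  fs20 <- assembleFeatures(win, blocks = "frequency")
  expect_identical(nrow(fs20), 20L)
  fsNoCons <- assembleFeatures(win, pep$annotations,
                               blocks = c("aa_factor", "structure",
                                          "frequency", "disorder"))
  expect_identical(nrow(fsNoCons), 246L)
})

test_that("encoders are pure and assembly errors on missing annotation", {
  pep <- makePeptideData(nPos = 3, nNeg = 3, seed = 8)
  win <- extractWindows(pep$proteins, pep$sites)
  a <- featureValues(assembleFeatures(win, pep$annotations))
  b <- featureValues(assembleFeatures(win, pep$annotations))
  expect_identical(a, b)
  expect_error(assembleFeatures(win, pep$annotations[-1]),
               "missing annotation")
  expect_error(assembleFeatures(win, NULL), "required")
})

test_that("feature tables round-trip through TSV", {
  fm <- makeFeatureData(nPos = 6, nNeg = 12, nInformative = 2, nNoise = 3,
                        seed = 4)
  path <- tempfile(fileext = ".tsv")
  writeFeatureTable(fm, path)
  back <- readFeatureTable(path)
  expect_identical(rownames(back), rownames(fm))
  expect_identical(siteLabels(back), siteLabels(fm))
  expect_equal(featureValues(back), featureValues(fm), tolerance = 1e-12)
})
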