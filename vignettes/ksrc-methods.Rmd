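---
title: "Methods: S-nitrosylation site prediction by kernel sparse representation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S-nitrosylation site prediction by kernel sparse representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoKSRC)
```

# The problem and the model

Given a protein sequence and a candidate cysteine, the package predicts
whether the cysteine carries an S-nitrosylation modification. The unit of
analysis is a 21-residue peptide window — the cysteine plus ten residues on
each side — encoded as a 666-dimensional numeric vector, ranked-and-pruned
by mutual information, and classified by sparse representation over the
training samples.

## Windowing and splitting

Windows that would extend past a protein end are padded with `X`. The
default (`padMode = "center"`) places padding on the deficient side so the
cysteine is always the 11th residue; this is required for the positional
blocks (21 x per-residue channels) to be comparable across samples. A
compatibility mode (`padMode = "end"`) instead appends all padding after the
available residues, matching corpora prepared with trailing-only padding;
positional features of truncated N-terminal windows are then shifted, which
is why it is not the default.

`stratifiedSplit()` assigns round-half-up `n_class * trainFraction` samples
of each class to training. This rounding is what maps the canonical corpus
(827 positives, 1689 negatives, fraction 0.8) to 662/1351 training and
165/338 testing samples. Within a class the assignment is a seeded
permutation, so a split is reproducible from `(data, fraction, seed)`.

## The six encoder channels, 666 features

| block | width | content |
|---|---|---|
| `cons.*` | 420 | PSSM row (20 log-odds) per window position |
| `aaf.*` | 100 | 5 amino-acid factor scores per flank residue (center skipped) |
| `struct.*` | 105 | one-hot helix/strand/other + buried/exposed per position |
| `freq.*` | 20 | flank composition: counts / 20, `X` counts nowhere |
| `dis.*` | 21 | per-position disorder score |

Design choices a user may want to revisit:

* **Padding emits zeros in every block.** A padded position carries no
  evidence; zero is the neutral element for all channels (PSSM log-odds,
  one-hots, scores).
* **Frequencies are proportions** (counts divided by the flank size 20),
  not raw counts, keeping the block on a scale comparable with the one-hot
  channels.
* **The amino-acid factor table** ships as
  `inst/extdata/aa_factors.tsv` — the five-factor summary of the AAindex
  physicochemical space (polarity, secondary-structure propensity, volume,
  codon diversity, charge). Any 20 x 5 table can be substituted by file,
  since published predictors differ in the exact factor solution they use.
* **PSSM scale.** PSI-BLAST ASCII profiles carry a log-odds section and a
  percentage section; `readPSSM(scale = )` exposes both (default
  `"logodds"`), because corpora in this field have been built both ways.
* **Block order is fixed** (conservation, factors, structure, frequency,
  disorder) so that feature indices in a saved mRMR ranking stay citable.

## mRMR ranking

Features are discretized (default: 3 equal-width bins; columns with at most
3 distinct values — one-hots and binaries — pass through as categories) and
ranked by the greedy first-order mRMR rule: pick
`argmax_j MI(X_j, Y)` first, then repeatedly
`argmax_j [ MI(X_j, Y) − (1/|S|) Σ_{i ∈ S} MI(X_j, X_i) ]`.
Mutual information is the plug-in estimate in nats; the base only rescales
scores and cannot change the order. Three numerical notes:

* A literal reading of evaluating the subset score with `S` shrunk to a
  single feature makes the objective "relevance minus self-entropy", which
  penalizes high-entropy features regardless of their relevance; the greedy
  scheme above is the standard construction and is what the package uses.
* Ties are real: on small discrete data many candidate features have
  *exactly* equal objectives in real arithmetic, and float summation order
  would otherwise decide the winner. The implementation therefore takes the
  lowest index among maxima within `1e-10`, making rankings deterministic
  and invariant to column order.
* The bin count for continuous features is a free parameter (the original
  analysis does not state one); rankings of strongly informative features
  are insensitive to it, but exact orders of near-null features are not, so
  saved rankings record their provenance in the CLI run log.

## Incremental feature selection

`ifs()` evaluates ranked prefixes of sizes `step, 2*step, ..., p` with
stratified k-fold cross-validation, reusing one fold assignment across all
sizes so the curve varies only with the features. Out-of-fold predictions
are pooled into a single confusion table per size; with 10 folds and rare
positives, per-fold MCC is unstable and pooling is the defensible
aggregate (counts are additive, so pooling folds equals summing their
tables). The optimal size is the MCC argmax, ties to the smaller prefix.
`step = 1` reproduces a per-feature curve; larger steps trade resolution for
time since each evaluation refits the classifier `folds` times.

## Sparse representation classification

`omp()` is standard orthogonal matching pursuit with normalized-correlation
atom selection (sign-blind, ties to the lowest column index), incremental
Cholesky least squares, and two stopping rules: `sparsity` atoms (default
`k = 50`) or residual norm at `eps` (default `1e-6`). A column whose
addition would make the selected set singular is dropped with a warning and
never revisited; per-iteration residual norms are returned and are
non-increasing by construction.

SRC codes the test vector over the (by default column-normalized) training
matrix and assigns `argmin_c ‖y − X α_c‖₂`, where `α_c` zeroes all
coefficients outside class `c`; the masked vectors sum exactly to the full
coefficient vector. KSRC replaces the feature-space system by the kernel
Gram system: the dictionary becomes `K = [Ψ(x_i, x_j)]` and the target the
kernel vector `κ(y) = [Ψ(y, x_i)]`, with the Laplacian kernel
`Ψ(x, y) = exp(−‖x − y‖₂/δ)`. Decisions use the residual in that linear
system, `‖κ(y) − K α_c‖₂` — it is exactly the system being solved and needs
no `Ψ(y, y)` bookkeeping; a feature-space residual would require expanding
`‖Ψ(y) − Ψ(X) α‖²` through the kernel trick and changes decisions only via
a constant offset per test sample. Gram columns are used raw (kernel values
are already bounded in (0, 1]); dictionary normalization applies to SRC
only, and both are switches.

Two open choices are exposed as configuration rather than hard-coded:
`|x − y|` in the Laplacian kernel is read as the Euclidean norm (`distance =
"l1"` gives the Manhattan variant, which also appears in the kernel
literature), and the bandwidth default is `δ = 100` in the CLI — the
classical value for this 666-feature encoding, whose PSSM block dominates
pairwise distances at that scale. For other feature spaces `delta = NULL`
applies the median pairwise-distance heuristic; the synthetic experiments
below use it, since their 10–50-dimensional standardized features sit at
pairwise distances around 4–12 where `δ = 100` would flatten the kernel
toward an all-ones matrix.

Degenerate inputs behave as follows: a test vector equal to a training
sample selects its own kernel atom and classifies with zero residual; in
the `δ → ∞` limit the Gram matrix approaches all-ones and the classifier
still returns a valid (class-size-driven) decision; residual ties resolve
to the lowest class id and are logged.

## Metrics

`evalMetrics()` computes SN, SP, ACC and MCC from the confusion counts,
with MCC defined as 0 whenever a denominator factor vanishes (the standard
convention; such tables carry no correlation signal).

## What the synthetic generator does and does not show

`makeFeatureData()` emulates the *statistical* shape of the problem: a 1:2
class imbalance (defaults 67/133, n = 200), 5 informative columns whose
class means differ by 3 SD, 45 standard-normal noise columns. It validates
the selection-plus-classification machinery — mRMR must surface the
informative block, KSRC must convert it into cross-validated MCC — and the
zero-effect variant calibrates the null (pooled CV MCC has standard error
about `1/sqrt(n)` ≈ 0.07 at n = 200, so individual null runs of ±0.15 are
expected occasionally).

`makePeptideData()` emulates the *structural* shape: random proteins
(60–120 residues) with one planted cysteine site each, positive flanks
enriched for acidic residues (D/E weight 6, i.e. ~40% of positive flank
residues vs 10% background), and consistent PSSM/structure/disorder tracks
where only the PSSM reflects the sequence (a +6 bonus on the observed
residue column). Corpus-scale defaults are 827/1689.

Neither generator emulates true S-nitrosylation motifs, homology structure
between proteins, or informative structure/disorder tracks. Passing tests
therefore demonstrate that the pipeline recovers planted signal of a known
kind and size — not that it attains any particular accuracy on real
modification data, where signal is weaker (real-corpus MCCs for this model
family are in the 0.16–0.29 range) and redundancy filtering of homologous
sequences (e.g. CD-HIT at 40% identity) must be done before windowing.

## Problem sizes used by the checks

The shipped tests and the acceptance script run, per seed: OMP support
recovery on 200 systems of 6 x 10 low-coherence dictionaries (generated by
iterative pairwise de-correlation toward coherence 0.35 — random Gaussian
frames of this shape essentially never reach coherence below 0.5, while
greedy 2-sparse recovery is only guaranteed below 1/3); exact-order mRMR
agreement with a brute-force reimplementation on 50 datasets of 12 samples
x 5 binary features; synthetic recovery at n = 200 with 10-fold
cross-validation over 5 seeds; and a 36-sample end-to-end CLI pipeline run
twice for byte-identity. These sizes keep a full run around a minute while
leaving each statistical conclusion comfortably inside its band.

## Known limitations

* KSRC refits cost O(n²) kernel evaluations per fold, so IFS with `step =
  1` over 666 features is expensive at corpus scale; use `step` > 1 for
  exploration and refine around the optimum.
* mRMR uses first-order (pairwise) mutual information only; higher-order
  joint dependence is invisible to the ranking.
* The discretization underlying MI estimation is a modeling choice; saved
  rankings are comparable only across runs with the same binning.
* Site tables are taken as authoritative: non-site cysteines are negatives
  only if listed as such.
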