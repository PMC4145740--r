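# Drive all seven CLI stages over a small simulated corpus.
runPipeline <- function(root, seed = 11) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  sim <- file.path(root, "sim")
  snoCli(c("simulate", "--out", sim, "--n-pos", "12", "--n-neg", "24",
           "--fm-pos", "10", "--fm-neg", "20", "--seed", as.character(seed)))
  snoCli(c("windows", "--fasta", file.path(sim, "proteins.fasta"),
           "--sites", file.path(sim, "sites.tsv"),
           "--out", file.path(root, "windows.tsv")))
  snoCli(c("encode", "--windows", file.path(root, "windows.tsv"),
           "--annotations", file.path(sim, "annotations"),
           "--out", file.path(root, "features.tsv")))
  snoCli(c("rank", "--features", file.path(root, "features.tsv"),
           "--out", file.path(root, "ranking.tsv")))
  snoCli(c("select", "--features", file.path(root, "features.tsv"),
           "--ranking", file.path(root, "ranking.tsv"),
           "--out-curve", file.path(root, "ifs.tsv"),
           "--out-features", file.path(root, "optimal.txt"),
           "--folds", "3", "--step", "222",
           "--seed", as.character(seed)))
  snoCli(c("train", "--features", file.path(root, "features.tsv"),
           "--feature-list", file.path(root, "optimal.txt"),
           "--out", file.path(root, "model")))
  snoCli(c("predict", "--model", file.path(root, "model"),
           "--features", file.path(root, "features.tsv"),
           "--out", file.path(root, "predictions.tsv")))
  root
}
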