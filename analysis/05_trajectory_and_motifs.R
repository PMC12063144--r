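#!/usr/bin/env Rscript
# Evaluate the repression axis: separation of the planted repressed
# population (rank AUC), effect of diffusion smoothing, the
# pseudotime/repression relationship, and trajectory-differential motifs.
#
# Requires results/run/ (analysis/01_run_pipeline.R).
# Writes results/tables/trajectory_summary.json and
# trajectory_motifs_significant.tsv.

suppressPackageStartupMessages({
  library(persistATAC)
  library(data.table)
})

run <- file.path("results", "run")
dir.create(file.path("results", "tables"), showWarnings = FALSE,
           recursive = TRUE)

rs <- fread(file.path(run, "matrices", "repression.tsv"))
sm <- fread(file.path(run, "trajectory", "repression_smoothed.tsv"))
tr <- fread(file.path(run, "trajectory", "trajectory.tsv"))
truth <- jsonlite::read_json(file.path(run, "inputs", "ground_truth.json"),
                             simplifyVector = TRUE)
labels <- unlist(truth$labels)

rank_auc <- function(x, y) {
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}
auc_of <- function(v, bc) {
  lab <- labels[bc]
  rank_auc(v[lab == "baseline"], v[lab == "repressed"])
}

dm <- fread(file.path(run, "motifs", "trajectory_motifs.tsv"))
sig <- dm[differential == TRUE][order(fdr)]
fwrite(sig, file.path("results", "tables",
                      "trajectory_motifs_significant.tsv"), sep = "\t")

summary <- list(
  repression_auc_raw = auc_of(rs$repression, rs$barcode),
  repression_auc_smoothed = auc_of(sm$repression_smoothed, sm$barcode),
  pseudotime_repression_spearman = cor(
    tr$pseudotime,
    sm[match(tr$barcode, barcode)]$repression_smoothed,
    method = "spearman"),
  n_cells_on_path = nrow(tr),
  n_motifs_tested = nrow(dm),
  significant_trajectory_motifs = sig$motif
)
jsonlite::write_json(summary,
                     file.path("results", "tables",
                               "trajectory_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
str(summary)
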