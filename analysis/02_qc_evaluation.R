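#!/usr/bin/env Rscript
# Evaluate per-cell QC against the simulator's planted ground truth:
# retention per population, metric distributions, and whether the
# synthetic-doublet kNN enrichment ranks planted doublets highly.
#
# Requires results/run/ (analysis/01_run_pipeline.R).
# Writes results/tables/qc_by_population.tsv and qc_doublet_eval.json.

suppressPackageStartupMessages({
  library(persistATAC)
  library(data.table)
})

run <- file.path("results", "run")
dir.create(file.path("results", "tables"), showWarnings = FALSE,
           recursive = TRUE)

qc <- fread(file.path(run, "qc", "cell_qc.tsv"))
kept <- readLines(file.path(run, "qc", "kept_barcodes.txt"))
truth <- jsonlite::read_json(file.path(run, "inputs", "ground_truth.json"),
                             simplifyVector = TRUE)
labels <- unlist(truth$labels)
qc[, population := labels[barcode]]
qc[barcode %in% truth$doublets, population := "doublet"]
qc[, kept := barcode %in% kept]

by_pop <- qc[, .(
  n_cells = .N,
  n_kept = sum(kept),
  retention = round(mean(kept), 4),
  median_fragments = as.numeric(median(n_fragments)),
  median_tss = round(median(tss_enrichment), 3),
  median_doublet_enrichment = round(median(doublet_enrichment), 3)
), by = population][order(population)]
fwrite(by_pop, file.path("results", "tables", "qc_by_population.tsv"),
       sep = "\t")
print(by_pop)

# planted doublets should sit in the upper tail of the enrichment score
thr <- quantile(qc$doublet_enrichment, 0.9)
eval <- list(
  n_planted_doublets = length(truth$doublets),
  doublet_top_decile_rate =
    mean(qc[population == "doublet"]$doublet_enrichment >= thr),
  doublets_removed_by_qc = sum(!qc[population == "doublet"]$kept),
  singlet_retention = round(mean(qc[population != "doublet"]$kept), 4)
)
jsonlite::write_json(eval, file.path("results", "tables",
                                     "qc_doublet_eval.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
str(eval)
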