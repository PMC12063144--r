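#!/usr/bin/env Rscript
# Summarize the marker statistics and the network key-driver call:
# signature sizes, recovery of planted marker genes, the up/down signature
# overlap test, and planted-vs-called key drivers.
#
# Requires results/run/ (analysis/01_run_pipeline.R).
# Writes results/tables/marker_summary.json and keydriver_eval.tsv.

suppressPackageStartupMessages({
  library(persistATAC)
  library(data.table)
})

run <- file.path("results", "run")
dir.create(file.path("results", "tables"), showWarnings = FALSE,
           recursive = TRUE)

markers <- fread(file.path(run, "markers", "markers.tsv"))
up <- readLines(file.path(run, "markers", "signature_up.txt"))
dn <- readLines(file.path(run, "markers", "signature_down.txt"))
ov <- jsonlite::read_json(file.path(run, "markers", "overlap.json"),
                          simplifyVector = TRUE)
truth <- jsonlite::read_json(file.path(run, "inputs", "ground_truth.json"),
                             simplifyVector = TRUE)

# the planted markers of the two compared populations should dominate the
# signatures; pool all planted marker genes for the recall figure
planted <- unique(unlist(truth$marker_genes))
summary <- list(
  n_features_tested = nrow(markers),
  n_signature_up = length(up),
  n_signature_down = length(dn),
  planted_marker_recall_in_signatures =
    round(mean(c(up, dn) %in% planted), 4),
  up_down_overlap = ov$overlap,
  up_down_overlap_p = ov$p
)
jsonlite::write_json(summary,
                     file.path("results", "tables", "marker_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
str(summary)

kd <- fread(file.path(run, "network", "keydrivers.tsv"))
planted_net <- jsonlite::read_json(file.path(run, "network", "planted.json"),
                                   simplifyVector = TRUE)
kd[, planted_driver := node %in% planted_net$drivers]
eval <- kd[is_key_driver | planted_driver,
           .(node, n_downstream, overlap, fdr,
             is_key_driver, planted_driver)][order(fdr)]
fwrite(eval, file.path("results", "tables", "keydriver_eval.tsv"),
       sep = "\t")
print(eval)
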