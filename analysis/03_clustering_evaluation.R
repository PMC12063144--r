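#!/usr/bin/env Rscript
# Evaluate the LSI embedding and modularity clustering against the planted
# populations: cluster/population confusion table and adjusted Rand index.
#
# Requires results/run/ (analysis/01_run_pipeline.R).
# Writes results/tables/cluster_confusion.tsv and cluster_metrics.json.

suppressPackageStartupMessages({
  library(persistATAC)
  library(data.table)
})

run <- file.path("results", "run")
dir.create(file.path("results", "tables"), showWarnings = FALSE,
           recursive = TRUE)

cl <- fread(file.path(run, "cluster", "clusters.tsv"))
truth <- jsonlite::read_json(file.path(run, "inputs", "ground_truth.json"),
                             simplifyVector = TRUE)
labels <- unlist(truth$labels)
meta <- jsonlite::read_json(file.path(run, "cluster",
                                      "embedding_meta.json"),
                            simplifyVector = TRUE)

tab <- table(cluster = cl$cluster, population = labels[cl$barcode])
conf <- as.data.table(tab)
fwrite(dcast(conf, cluster ~ population, value.var = "N"),
       file.path("results", "tables", "cluster_confusion.tsv"), sep = "\t")
print(tab)

ari <- {
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  e <- b * cc / choose(sum(tab), 2)
  (a - e) / ((b + cc) / 2 - e)
}
metrics <- list(n_clusters = length(unique(cl$cluster)),
                adjusted_rand_index = ari,
                lsi_depth_correlated_components = sum(meta$flagged))
jsonlite::write_json(metrics,
                     file.path("results", "tables", "cluster_metrics.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
str(metrics)
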