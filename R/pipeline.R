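## Configuration-driven orchestration: simulate -> qc -> matrices ->
## embed/cluster -> markers -> network -> repression smoothing ->
## pseudotime -> motifs. Every stage reads its inputs from the run
## directory and writes artifacts plus a JSON provenance block, so a rerun
## with the same configuration resumes after the last valid stage and a
## full rerun is byte-identical.

pipeline_defaults <- function() {
  list(
    out_dir = NULL,
    simulate = TRUE,
    sim = NULL,                      # sim_config; built from seed if NULL
    inputs = NULL,                   # named paths when simulate = FALSE
    min_fragments = 100, min_tss = 4, doublet_threshold = 1,
    n_synthetic_doublets = 400, doublet_k = 30,
    tile_size = 500, flank_bp = 2000,
    lsi_rank = 30, lsi_iterations = 2, n_top_features = 5000,
    cluster_k = 15, resolution = 0.8,
    marker_max_fdr = 0.1, marker_min_lfc = 0.5,
    network_n_nodes = 200, network_n_drivers = 2,
    network_children = 8, net_layers = 2, driver_h = 2,
    driver_max_fdr = 0.05, min_downstream = 5,
    motif_permutations = 50, motif_deciles = 10,
    smooth_k = 15, smooth_t = 3,
    trajectory_path = NULL,          # NULL = order clusters by repression
    traj_bins = 50, traj_window = 7, traj_permutations = 200,
    traj_max_fdr = 0.05,
    seeds = list(sim = 1, doublet = 2, lsi = 3, cluster = 4, network = 5,
                 motif = 6, trajectory = 7)
  )
}

#' Pipeline configuration
#'
#' Builds a validated configuration for \code{\link{run_pipeline}}. All
#' stage parameters default to the study settings (QC thresholds 100/4/1,
#' 500 bp tiles, 2 kb flanks, clustering resolution 0.8, marker thresholds
#' FDR 0.1 and |log2FC| 0.5, two network layers); every stochastic stage
#' has an explicit seed. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see \code{pipeline_defaults})
#' @return a \code{pipeline_config} list
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0,
              paste("unknown configuration key(s):",
                    paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  if ("seeds" %in% names(over)) {
    base <- pipeline_defaults()$seeds
    base[names(over$seeds)] <- over$seeds
    cfg$seeds <- base
  }
  assert_that(!is.null(cfg$out_dir), "out_dir is required")
  if (cfg$simulate && is.null(cfg$sim)) {
    cfg$sim <- sim_config(seed = cfg$seeds$sim)
  }
  assert_that(cfg$simulate || !is.null(cfg$inputs),
              "either simulate = TRUE or input paths are required")
  structure(cfg, class = "pipeline_config")
}

## recursively drop S3 classes so stage parameters (which may contain
## sim_config/population_spec objects) serialize as plain JSON
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

stage_provenance <- function(run_dir, stage, params, inputs, outputs) {
  params <- strip_classes(params)
  prov <- list(
    stage = stage,
    params = params,
    package_version = as.character(utils::packageVersion("persistATAC")),
    input_md5 = as.list(tools::md5sum(inputs)[basename(inputs) != ""]),
    outputs = basename(outputs)
  )
  names(prov$input_md5) <- basename(inputs)
  jsonlite::write_json(prov, file.path(run_dir, "provenance",
                                       paste0(stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_is_done <- function(run_dir, stage, params, outputs) {
  pf <- file.path(run_dir, "provenance", paste0(stage, ".json"))
  if (!file.exists(pf) || !all(file.exists(outputs))) return(FALSE)
  prev <- jsonlite::read_json(pf)
  identical(
    jsonlite::toJSON(prev$params, auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(strip_classes(params), auto_unbox = TRUE, digits = NA))
}

run_stage <- function(run_dir, stage, params, inputs, outputs, fn,
                      quiet = FALSE) {
  if (stage_is_done(run_dir, stage, params, outputs)) {
    if (!quiet) message(sprintf("[%s] up to date, skipping", stage))
    return(invisible(FALSE))
  }
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    abort(sprintf("stage '%s': missing upstream artifact(s): %s",
                  stage, paste(basename(missing_in), collapse = ", ")))
  }
  if (!quiet) {
    message(sprintf("[%s] running (seed %s)", stage,
                    params$seed %||% "none"))
  }
  fn()
  stage_provenance(run_dir, stage, params, inputs, outputs)
  invisible(TRUE)
}

read_embedding_artifacts <- function(dir) {
  emb <- fread(file.path(dir, "embedding.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "embedding_meta.json"),
                              simplifyVector = TRUE)
  E <- as.matrix(emb[, -1])
  rownames(E) <- emb[[1]]
  structure(list(embedding = E, depth_cor = meta$depth_cor,
                 flagged = meta$flagged, seed = meta$seed, features = NULL),
            class = "lsi_embedding")
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order inside \code{config$out_dir},
#' writing artifacts and per-stage provenance JSON (parameters, seed, input
#' checksums). A rerun with an identical configuration skips stages whose
#' provenance matches and whose outputs exist; a full rerun reproduces
#' byte-identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param quiet suppress stage messages
#' @return the run directory, invisibly
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  run_dir <- config$out_dir
  for (d in c("", "inputs", "qc", "matrices", "cluster", "markers",
              "network", "trajectory", "motifs", "provenance")) {
    dir.create(file.path(run_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  inp <- file.path(run_dir, "inputs")
  in_path <- function(f) file.path(inp, f)

  ## ---- stage: inputs ---------------------------------------------------
  input_files <- c("fragments.tsv.gz", "genes.tsv", "peaks.bed",
                   "peaks_annotated.tsv", "domains.bed", "motifs.bed",
                   "chrom_sizes.tsv")
  if (config$simulate) {
    run_stage(run_dir, "simulate",
              params = list(sim = unclass(config$sim),
                            seed = config$sim$seed),
              inputs = character(0),
              outputs = in_path(c(input_files, "ground_truth.json")),
              fn = function() simulate_experiment(config$sim, out_dir = inp),
              quiet = quiet)
  } else {
    map <- c(fragments = "fragments.tsv.gz", genes = "genes.tsv",
             peaks = "peaks.bed", peaks_annotated = "peaks_annotated.tsv",
             domains = "domains.bed", motifs = "motifs.bed",
             chrom_sizes = "chrom_sizes.tsv")
    assert_that(all(names(config$inputs) %in% names(map)),
                "unknown input name(s) in config$inputs")
    run_stage(run_dir, "ingest", params = list(paths = config$inputs),
              inputs = unlist(config$inputs),
              outputs = in_path(unname(map[names(config$inputs)])),
              fn = function() {
                for (k in names(config$inputs)) {
                  file.copy(config$inputs[[k]], in_path(map[[k]]),
                            overwrite = TRUE)
                }
              }, quiet = quiet)
  }

  ## ---- stage: qc -------------------------------------------------------
  qc_out <- file.path(run_dir, "qc",
                      c("cell_qc.tsv", "kept_barcodes.txt",
                        "filter_report.json"))
  run_stage(run_dir, "qc",
            params = list(min_fragments = config$min_fragments,
                          min_tss = config$min_tss,
                          doublet_threshold = config$doublet_threshold,
                          n_synthetic = config$n_synthetic_doublets,
                          k = config$doublet_k, tile_size = config$tile_size,
                          seed = config$seeds$doublet),
            inputs = in_path(c("fragments.tsv.gz", "genes.tsv",
                               "chrom_sizes.tsv")),
            outputs = qc_out, quiet = quiet, fn = function() {
    sizes <- read_chrom_sizes(in_path("chrom_sizes.tsv"))
    frags <- read_fragments(in_path("fragments.tsv.gz"), sizes)
    genes <- read_gene_annotation(in_path("genes.tsv"))
    qc <- compute_cell_qc(frags, genes)
    tiles_all <- build_tile_matrix(frags, sizes, config$tile_size)
    dbl <- doublet_enrichment(tiles_all,
                              n_synthetic = config$n_synthetic_doublets,
                              k = config$doublet_k,
                              seed = config$seeds$doublet)
    qc[, "doublet_enrichment" := dbl[qc$barcode]]
    filt <- apply_qc_filters(qc, config$min_fragments, config$min_tss,
                             config$doublet_threshold)
    fwrite(qc, qc_out[1], sep = "\t")
    writeLines(filt$kept, qc_out[2])
    jsonlite::write_json(as.list(filt$report), qc_out[3],
                         auto_unbox = TRUE, digits = NA)
  })

  ## ---- stage: matrices -------------------------------------------------
  mdir <- file.path(run_dir, "matrices")
  mat_out <- file.path(mdir, c("tiles.mtx", "gene_scores.mtx", "peaks.mtx",
                               "repression.tsv"))
  run_stage(run_dir, "matrices",
            params = list(tile_size = config$tile_size,
                          flank_bp = config$flank_bp),
            inputs = c(in_path(c("fragments.tsv.gz", "genes.tsv", "peaks.bed",
                                 "domains.bed", "chrom_sizes.tsv")),
                       qc_out[2]),
            outputs = mat_out, quiet = quiet, fn = function() {
    sizes <- read_chrom_sizes(in_path("chrom_sizes.tsv"))
    frags <- read_fragments(in_path("fragments.tsv.gz"), sizes)
    kept <- readLines(qc_out[2])
    genes <- read_gene_annotation(in_path("genes.tsv"))
    tiles <- build_tile_matrix(frags, sizes, config$tile_size, kept)
    write_matrix(tiles, mat_out[1])
    write_matrix(gene_scores(tiles, genes), mat_out[2])
    write_matrix(build_peak_matrix(frags, read_intervals(in_path("peaks.bed")),
                                   kept), mat_out[3])
    ds <- repressive_domain_set(read_intervals(in_path("domains.bed")),
                                sizes, config$flank_bp)
    rs <- repression_score(frags, ds, kept)
    fwrite(data.table(barcode = names(rs), repression = rs), mat_out[4],
           sep = "\t")
  })

  ## ---- stage: cluster --------------------------------------------------
  cdir <- file.path(run_dir, "cluster")
  cl_out <- file.path(cdir, c("embedding.tsv", "embedding_meta.json",
                              "clusters.tsv"))
  run_stage(run_dir, "cluster",
            params = list(rank = config$lsi_rank,
                          iterations = config$lsi_iterations,
                          n_top_features = config$n_top_features,
                          k = config$cluster_k,
                          resolution = config$resolution,
                          seed = config$seeds$lsi,
                          cluster_seed = config$seeds$cluster),
            inputs = mat_out[1], outputs = cl_out, quiet = quiet,
            fn = function() {
    tiles <- read_matrix(mat_out[1])
    emb <- tfidf_lsi(tiles, rank = config$lsi_rank,
                     n_top_features = min(config$n_top_features, ncol(tiles)),
                     iterations = config$lsi_iterations,
                     seed = config$seeds$lsi)
    cl <- snn_cluster(emb, k = config$cluster_k,
                      resolution = config$resolution,
                      seed = config$seeds$cluster)
    fwrite(data.table(barcode = rownames(emb$embedding), emb$embedding),
           cl_out[1], sep = "\t")
    jsonlite::write_json(list(depth_cor = emb$depth_cor,
                              flagged = emb$flagged, seed = emb$seed),
                         cl_out[2], digits = NA)
    fwrite(cl, cl_out[3], sep = "\t")
  })

  ## ---- stage: markers --------------------------------------------------
  kdir <- file.path(run_dir, "markers")
  mk_out <- file.path(kdir, c("markers.tsv", "signature_up.txt",
                              "signature_down.txt", "overlap.json"))
  run_stage(run_dir, "markers",
            params = list(max_fdr = config$marker_max_fdr,
                          min_lfc = config$marker_min_lfc),
            inputs = c(mat_out[2], cl_out[3]), outputs = mk_out,
            quiet = quiet, fn = function() {
    gs <- read_matrix(mat_out[2])
    cl <- fread(cl_out[3])
    top2 <- as.integer(names(sort(table(cl$cluster), decreasing = TRUE))[1:2])
    g1 <- cl$barcode[cl$cluster == top2[1]]
    g2 <- cl$barcode[cl$cluster == top2[2]]
    rec <- marker_features(gs, g1, g2)
    up <- select_signature(rec, config$marker_max_fdr, config$marker_min_lfc,
                           "up", sprintf("cluster%d_up", top2[1]))
    dn <- select_signature(rec, config$marker_max_fdr, config$marker_min_lfc,
                           "down", sprintf("cluster%d_vs%d_down",
                                           top2[1], top2[2]))
    ov <- hypergeom_overlap(up$genes, dn$genes, ncol(gs))
    fwrite(rec, mk_out[1], sep = "\t")
    writeLines(up$genes, mk_out[2])
    writeLines(dn$genes, mk_out[3])
    jsonlite::write_json(list(groups = top2, overlap = ov$overlap,
                              p = ov$p, universe = ncol(gs)),
                         mk_out[4], auto_unbox = TRUE, digits = NA)
  })

  ## ---- stage: network --------------------------------------------------
  ndir <- file.path(run_dir, "network")
  net_out <- file.path(ndir, c("edges.tsv", "planted.json", "keydrivers.tsv",
                               "components.json"))
  run_stage(run_dir, "network",
            params = list(n_nodes = config$network_n_nodes,
                          n_drivers = config$network_n_drivers,
                          children = config$network_children,
                          layers = config$net_layers, h = config$driver_h,
                          max_fdr = config$driver_max_fdr,
                          min_downstream = config$min_downstream,
                          seed = config$seeds$network),
            inputs = character(0), outputs = net_out, quiet = quiet,
            fn = function() {
    sim <- simulate_network(config$network_n_nodes, config$network_n_drivers,
                            config$network_children,
                            seed = config$seeds$network)
    write_network(sim$network, net_out[1])
    jsonlite::write_json(list(signature = sim$signature,
                              drivers = sim$drivers),
                         net_out[2], digits = NA)
    rep <- project_signature(sim$network, sim$signature,
                             layers = config$net_layers)
    kd <- key_drivers(sim$network, sim$signature, h = config$driver_h,
                      max_fdr = config$driver_max_fdr,
                      min_downstream = config$min_downstream)
    fwrite(kd, net_out[3], sep = "\t")
    jsonlite::write_json(
      list(layers = rep$layers,
           component_sizes = vapply(rep$components, `[[`, numeric(1), "size"),
           components = lapply(rep$components, `[[`, "nodes")),
      net_out[4], digits = NA)
  })

  ## ---- stage: trajectory (smoothing + pseudotime) ---------------------
  tdir <- file.path(run_dir, "trajectory")
  tr_out <- file.path(tdir, c("repression_smoothed.tsv", "trajectory.tsv"))
  run_stage(run_dir, "trajectory",
            params = list(smooth_k = config$smooth_k,
                          smooth_t = config$smooth_t,
                          path = config$trajectory_path),
            inputs = c(mat_out[4], cl_out[1], cl_out[2], cl_out[3]),
            outputs = tr_out, quiet = quiet, fn = function() {
    emb <- read_embedding_artifacts(cdir)
    cl <- fread(cl_out[3])
    rs <- fread(mat_out[4])
    v <- stats::setNames(rs$repression, rs$barcode)[rownames(emb$embedding)]
    sm <- impute_smooth(emb, v, k = config$smooth_k, t = config$smooth_t)
    fwrite(data.table(barcode = names(sm), repression_smoothed = sm),
           tr_out[1], sep = "\t")
    path <- config$trajectory_path
    if (is.null(path)) {
      ## order clusters from open to repressed chromatin (the biological
      ## direction of persister progression); ties broken by label
      cl_mean <- tapply(sm[cl$barcode], cl$cluster, mean)
      path <- as.integer(names(sort(cl_mean, decreasing = TRUE)))
      keep <- as.integer(names(table(cl$cluster)))[table(cl$cluster) >= 10]
      path <- path[path %in% keep]
    }
    tr <- pseudotime(emb, cl, path)
    fwrite(tr, tr_out[2], sep = "\t")
  })

  ## ---- stage: motifs ---------------------------------------------------
  odir <- file.path(run_dir, "motifs")
  mo_out <- file.path(odir, c("motif_z.tsv", "trajectory_motifs.tsv"))
  run_stage(run_dir, "motifs",
            params = list(n_permutations = config$motif_permutations,
                          n_deciles = config$motif_deciles,
                          bins = config$traj_bins,
                          window = config$traj_window,
                          traj_permutations = config$traj_permutations,
                          max_fdr = config$traj_max_fdr,
                          seed = config$seeds$motif,
                          trajectory_seed = config$seeds$trajectory),
            inputs = c(mat_out[3], in_path(c("motifs.bed", "peaks.bed")),
                       tr_out[2]),
            outputs = mo_out, quiet = quiet, fn = function() {
    pm <- read_matrix(mat_out[3])
    peaks <- read_intervals(in_path("peaks.bed"))
    hits <- read_intervals(in_path("motifs.bed"))
    ann <- motif_annotation_matrix(hits, peaks)
    z <- motif_deviation(pm, ann, n_permutations = config$motif_permutations,
                         n_deciles = config$motif_deciles,
                         seed = config$seeds$motif)
    fwrite(data.table(barcode = rownames(z), as.data.table(z)), mo_out[1],
           sep = "\t")
    tr <- fread(tr_out[2])
    data.table::setattr(tr, "class",
                        c("trajectory_result", class(tr)))
    dm <- trajectory_differential_motifs(
      z, tr, n_bins = config$traj_bins, window = config$traj_window,
      n_permutations = config$traj_permutations,
      max_fdr = config$traj_max_fdr, seed = config$seeds$trajectory)
    fwrite(dm, mo_out[2], sep = "\t")
  })

  invisible(run_dir)
}
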