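# TSS-enrichment fixture: one gene, insertions placed by hand. Each
# fragment contributes insertions at start and end-1; the second event is
# parked 5 kb downstream, outside both the centre and the background bands.
one_tss_genes <- function(tss = 5000L) {
  data.table::data.table(gene_id = "G1", symbol = "G1", chrom = "chr1",
                         strand = "+", tss = tss, body_start = tss,
                         body_end = tss + 2000L)
}

test_that("TSS enrichment matches direct evaluation of the density ratio", {
  tss <- 5000L
  starts <- seq(tss - 50L, tss + 50L)   # one insertion per centre base
  frags <- data.table::data.table(
    chrom = "chr1", start = starts, end = tss + 5001L,
    barcode = "CELLA", count = 1L)
  qc <- compute_cell_qc(frags, one_tss_genes(tss))
  # 101 centre events, 0 background events: (101/101) / ((0+1)/200) = 200
  expect_equal(qc$tss_enrichment, 200)
  expect_equal(qc$n_fragments, 101L)
})

test_that("cells with no TSS-proximal signal get zero enrichment", {
  frags <- data.table::data.table(chrom = "chr1", start = 100000L,
                                  end = 100200L, barcode = "FAR", count = 1L)
  qc <- compute_cell_qc(frags, one_tss_genes())
  expect_equal(qc$tss_enrichment, 0)
})

test_that("TSS enrichment is invariant to uniform depth scaling when the
           background dominates the pseudocount", {
  set.seed(1)
  tss <- 50000L
  n <- 2000
  pos <- c(sample(seq(tss - 50L, tss + 50L), n / 2, replace = TRUE),
           sample(seq(tss - 2000L, tss - 1901L), n / 2, replace = TRUE))
  frags <- data.table::data.table(chrom = "chr1", start = pos,
                                  end = pos + 1L, barcode = "C1", count = 1L)
  frags3x <- data.table::data.table(
    chrom = "chr1", start = rep(pos, 3), end = rep(pos + 1L, 3),
    barcode = "C3", count = 1L)
  g <- one_tss_genes(tss)
  e1 <- compute_cell_qc(frags, g)$tss_enrichment
  e3 <- compute_cell_qc(frags3x, g)$tss_enrichment
  expect_lt(abs(e3 / e1 - 1), 0.01)
})

test_that("the three-way filter keeps exactly the passing cells", {
  rec <- data.table::data.table(
    barcode = c("pass_boundary", "deep_doublet", "shallow", "low_tss", "ok"),
    n_fragments = c(100L, 5000L, 99L, 500L, 300L),
    tss_enrichment = c(4, 12, 8, 3.99, 6),
    doublet_enrichment = c(0.99, 1.0, 0.5, 0.2, 0.3))
  res <- apply_qc_filters(rec)
  # >= on fragments and TSS (boundary kept), < on doublet (boundary removed)
  expect_setequal(res$kept, c("pass_boundary", "ok"))
  expect_equal(unname(res$report["doublet"]), 1L)
  expect_equal(unname(res$report["low_fragments"]), 1L)
  expect_equal(unname(res$report["low_tss"]), 1L)

  empty <- apply_qc_filters(rec[0])
  expect_length(empty$kept, 0)
  expect_equal(unname(empty$report["n_input"]), 0L)
})

test_that("the filter is monotone in its thresholds", {
  set.seed(2)
  rec <- data.table::data.table(
    barcode = sprintf("b%03d", 1:200),
    n_fragments = as.integer(rpois(200, 150)),
    tss_enrichment = rgamma(200, 4), doublet_enrichment = rgamma(200, 1))
  base <- length(apply_qc_filters(rec)$kept)
  for (args in list(list(min_fragments = 160), list(min_tss = 5),
                    list(doublet_threshold = 0.8))) {
    expect_lte(length(do.call(apply_qc_filters, c(list(rec), args))$kept),
               base)
  }
})

test_that("doublet enrichment rejects degenerate inputs", {
  m <- feature_matrix(
    Matrix::Matrix(matrix(rpois(400, 1), 40, 10,
                          dimnames = list(sprintf("c%02d", 1:40),
                                          sprintf("t%02d", 1:10))),
                   sparse = TRUE), "tile")
  expect_error(doublet_enrichment(m, n_synthetic = 0), "n_synthetic")
  expect_error(doublet_enrichment(m, n_synthetic = 10, k = 60), "k must be")
})

test_that("planted doublets rank in the top decile of enrichment", {
  top_decile_hits <- 0
  n_rep <- 6
  for (s in seq_len(n_rep)) {
    cfg <- small_sim_config(seed = 100 + s, n_cells = 100, n_doublets = 10)
    sim <- simulate_experiment(cfg)
    tiles <- build_tile_matrix(sim$fragments, sim$chrom_sizes, 500)
    enr <- doublet_enrichment(tiles, seed = 100 + s)
    cut <- quantile(enr, 0.9)
    planted <- sim$ground_truth$doublets
    top_decile_hits <- top_decile_hits + mean(enr[planted] >= cut)
  }
  expect_gte(top_decile_hits / n_rep, 0.8)
})

test_that("enrichment centres near 1 on an exchangeable doublet-free null", {
  # with a single population there is no between-cluster void for synthetic
  # doublets to concentrate in, so the mean neighbourhood enrichment of real
  # cells matches the global synthetic fraction. (With multiple separated
  # populations the doublet-free mean is structurally pulled below 1 --
  # heterotypic synthetic doublets fall between the clusters; that
  # depression is exactly the signal the detector exploits.)
  mns <- vapply(1:6, function(s) {
    cfg <- sim_config(
      populations = list(population_spec("only", 250, marker_fold = 8,
                                         n_marker_genes = 40)),
      n_doublets = 0, genome = c(chr1 = 2e6, chr2 = 2e6),
      n_peaks = 1200, n_domains = 4, domain_width = 5e4,
      depth_log_mean = log(800), seed = 70 + s)
    sim <- simulate_experiment(cfg)
    tiles <- build_tile_matrix(sim$fragments, sim$chrom_sizes, 500)
    mean(doublet_enrichment(tiles, seed = 70 + s))
  }, numeric(1))
  expect_lt(abs(mean(mns) - 1), 0.15)
})
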