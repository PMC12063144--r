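toy_fragments <- function() {
  data.table::data.table(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(100L, 499L, 700L), end = c(250L, 501L, 900L),
    barcode = c("A", "A", "B"), count = 1L)
}

test_that("tile counting follows the two-insertion convention", {
  tiles <- build_tile_matrix(toy_fragments(), c(chr1 = 2000L), 500)
  m <- as.matrix(tiles)
  # chr1:100-250 -> insertions 100 and 249, both in tile 0-500
  expect_equal(unname(m["A", "chr1:0-500"]), 3)  # +1 from the 499 insertion
  # chr1:499-501 straddles the boundary: 499 -> tile 0-500, 500 -> 500-1000
  expect_equal(unname(m["A", "chr1:500-1000"]), 1)
  expect_equal(unname(m["B", "chr1:500-1000"]), 2)
  expect_equal(sum(m), 2 * nrow(toy_fragments()))
  expect_error(build_tile_matrix(toy_fragments(), c(chr1 = 2000L), 0),
               "tile_size")
})

test_that("tile-matrix conservation holds on a simulated dataset", {
  sim <- simulate_experiment(small_sim_config(seed = 4, n_cells = 40))
  tiles <- build_tile_matrix(sim$fragments, sim$chrom_sizes, 500)
  expect_equal(sum(tiles), 2 * nrow(sim$fragments))
  kept <- names(sim_truth_labels(sim))[1:50]
  sub <- build_tile_matrix(sim$fragments, sim$chrom_sizes, 500, kept)
  expect_equal(sum(sub),
               2 * sum(sim$fragments$barcode %in% kept))
})

test_that("gene-score weights: body weight 1, exponential tail, depth
           invariance", {
  genes <- data.table::data.table(
    gene_id = "G1", symbol = "G1", chrom = "chr1", strand = "+",
    tss = 10000L, body_start = 10000L, body_end = 12000L)
  # cell X: one fragment inside the body; cell Y: one fragment in the tile
  # whose nearest edge sits exactly 5000 bp from the body end
  frags <- data.table::data.table(
    chrom = "chr1",
    start = c(10100L, 17000L), end = c(10300L, 17050L),
    barcode = c("X", "Y"), count = 1L)
  tiles <- build_tile_matrix(frags, c(chr1 = 100000L), 500)
  gs <- gene_scores(tiles, genes)
  # both cells have 2 insertions total -> depth factor 1e4/2 each
  # X: weight 1 * 2 insertions; Y: weight exp(-5000/5000) * 2 insertions
  expect_equal(unname(gs["X", "G1"]), 1e4)
  expect_equal(unname(gs["Y", "G1"]), 1e4 * exp(-1), tolerance = 1e-12)

  # doubling depth with identical placement leaves normalized scores fixed
  frags2 <- rbind(frags, frags)[, "barcode" := c("X", "Y", "X", "Y")]
  gs2 <- gene_scores(build_tile_matrix(frags2, c(chr1 = 100000L), 500), genes)
  expect_equal(as.matrix(gs2), as.matrix(gs))
})

test_that("gene scores are linear in tile counts before normalization", {
  sim <- simulate_experiment(small_sim_config(seed = 6, n_cells = 20))
  tiles <- build_tile_matrix(sim$fragments, sim$chrom_sizes, 500)
  gs1 <- gene_scores(tiles, sim$genes)
  gs3 <- gene_scores(tiles * 3, sim$genes)
  # tripling all counts triples the raw score and the depth: ratio cancels
  expect_equal(as.matrix(gs3), as.matrix(gs1), tolerance = 1e-12)
})

test_that("repression score reproduces the direct arithmetic example", {
  # L_dom = 10,000 with 100 insertions; L_fl = 4,000 with 40 insertions
  domains <- data.table::data.table(chrom = "chr1", start = 20000L,
                                    end = 30000L)
  ds <- repressive_domain_set(domains, c(chr1 = 100000L), flank_bp = 2000)
  expect_equal(ds$L_dom, 10000)
  expect_equal(ds$L_fl, 4000)
  # 50 fragments in the domain (100 insertions), 20 in flanks (40)
  dom_pos <- as.integer(seq(21000, 29000, length.out = 50))
  fl_pos <- as.integer(c(seq(18100, 19800, length.out = 10),
                         seq(30100, 31800, length.out = 10)))
  frags <- data.table::data.table(
    chrom = "chr1", start = c(dom_pos, fl_pos),
    end = c(dom_pos, fl_pos) + 50L, barcode = "C", count = 1L)
  rs <- repression_score(frags, ds)
  expect_equal(unname(rs["C"]), (101 / 10000) / (41 / 4000),
               tolerance = 1e-9)
})

test_that("a fragment-free cell scores the pseudocount-only limit", {
  domains <- data.table::data.table(chrom = "chr1", start = 20000L,
                                    end = 30000L)
  ds <- repressive_domain_set(domains, c(chr1 = 100000L))
  frags <- data.table::data.table(chrom = "chr1", start = 90000L,
                                  end = 90100L, barcode = "FAR", count = 1L)
  rs <- repression_score(frags, ds, kept_barcodes = c("FAR", "EMPTY"))
  expect_equal(unname(rs["EMPTY"]), (1 / ds$L_dom) / (1 / ds$L_fl))
})

test_that("flanks are clipped against domains and chromosome ends", {
  domains <- data.table::data.table(chrom = "chr1",
                                    start = c(0L, 5000L), end = c(3000L, 9000L))
  ds <- repressive_domain_set(domains, c(chr1 = 10000L), flank_bp = 2000)
  fl <- as.data.frame(ds$flanks)
  # left flank of the first domain falls off-chromosome entirely;
  # the 3000-5000 gap serves both domains but is counted once
  expect_equal(ds$L_fl, 2000 + 1000)
  expect_true(all(fl$start >= 1 & fl$end <= 10000))
})

test_that("repression separates planted depletion from baseline", {
  aucs <- vapply(1:3, function(s) {
    sim <- simulate_experiment(small_sim_config(seed = 20 + s, n_cells = 60))
    truth <- sim_truth_labels(sim)
    ds <- repressive_domain_set(sim$domains, sim$chrom_sizes)
    rs <- repression_score(sim$fragments, ds, names(truth))
    rank_auc(rs[names(truth)[truth == "baseline"]],
             rs[names(truth)[truth == "repressed"]])
  }, numeric(1))
  expect_true(all(aucs >= 0.9))
})

test_that("motif deviation: saturation, planted bias and permuted null", {
  sim <- simulate_experiment(small_sim_config(seed = 8, n_cells = 60))
  truth <- sim_truth_labels(sim)
  pm <- build_peak_matrix(sim$fragments, sim$peaks, names(truth))
  ann <- motif_annotation_matrix(sim$motif_hits, sim$peaks)

  # a motif on every peak has obs = exp exactly -> deviation 0 for all cells
  all_ann <- Matrix::Matrix(TRUE, ncol(pm), 1,
                            dimnames = list(colnames(pm), "ALL"))
  z_all <- motif_deviation(pm, all_ann, n_permutations = 10, seed = 1)
  expect_true(all(z_all == 0))

  z <- motif_deviation(pm, ann, seed = 2)
  alv <- names(truth)[truth == "alveolar"]
  expect_gt(mean(z[alv, "MOTIF_A"]),
            mean(z[setdiff(rownames(z), alv), "MOTIF_A"]))

  # a random relabelling of peak membership carries no per-motif signal
  set.seed(3)
  perm_ann <- ann[sample(nrow(ann)), , drop = FALSE]
  rownames(perm_ann) <- rownames(ann)
  zp <- motif_deviation(pm, perm_ann, seed = 4)
  expect_lt(max(abs(colMeans(zp))), 0.2)

  # zero-member motifs are dropped with a message
  ann0 <- cbind(ann, EMPTY = FALSE)
  expect_message(z0 <- motif_deviation(pm, ann0, n_permutations = 5,
                                       seed = 1),
                 "zero member")
  expect_false("EMPTY" %in% colnames(z0))
})
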