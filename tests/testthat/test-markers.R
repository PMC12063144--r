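mat_from <- function(cols, barcodes) {
  m <- do.call(cbind, cols)
  rownames(m) <- barcodes
  m
}

test_that("exact Wilcoxon matches full enumeration on the worked case", {
  m <- mat_from(list(f1 = c(5, 6, 7, 1, 2, 3)),
                c("a1", "a2", "a3", "b1", "b2", "b3"))
  rec <- marker_features(m, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  # all C(6,3) = 20 rank splits: only the observed split is as extreme,
  # so two-sided p = 2/20
  expect_equal(rec$p, 0.1)
  expect_equal(rec$log2fc, log2(7 / 3))
  # independent oracle: stats::wilcox.test on the same data
  ref <- wilcox.test(c(5, 6, 7), c(1, 2, 3))$p.value
  expect_equal(rec$p, ref)
})

test_that("vectorised p-values agree with stats::wilcox.test across regimes", {
  set.seed(11)
  n1 <- 30; n2 <- 25
  X <- cbind(cont = rnorm(n1 + n2),
             ties = sample(0:3, n1 + n2, replace = TRUE),
             shift = c(rnorm(n1, 1), rnorm(n2)))
  rownames(X) <- c(sprintf("a%02d", 1:n1), sprintf("b%02d", 1:n2))
  rec <- marker_features(X, rownames(X)[1:n1], rownames(X)[-(1:n1)])
  for (j in 1:3) {
    # the oracle itself warns about ties (it falls back to the same normal
    # approximation the package uses)
    ref <- suppressWarnings(wilcox.test(X[1:n1, j], X[-(1:n1), j]))$p.value
    expect_equal(rec$p[j], ref, tolerance = 1e-10, info = colnames(X)[j])
  }
})

test_that("identical groups give zero fold change and p = 1 for constants", {
  set.seed(12)
  vals <- rnorm(6)
  m <- mat_from(list(f1 = rep(vals[1:3], 2), f2 = rep(1, 6)),
                sprintf("c%d", 1:6))
  rec <- marker_features(m, sprintf("c%d", 1:3), sprintf("c%d", 4:6))
  expect_equal(rec$log2fc, c(0, 0))
  expect_equal(rec$p[2], 1)  # constant feature
  expect_error(marker_features(m, sprintf("c%d", 1:3), sprintf("c%d", 3:6)),
               "disjoint")
})

test_that("null simulation controls the false-signature rate", {
  set.seed(13)
  rates <- vapply(1:5, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(60 * 1000), 60, 1000,
                dimnames = list(sprintf("c%02d", 1:60),
                                sprintf("f%04d", 1:1000)))
    rec <- marker_features(X, rownames(X)[1:30], rownames(X)[31:60])
    sig <- select_signature(rec, max_fdr = 0.1, min_abs_log2fc = 0,
                            direction = "both")
    length(sig$genes) / 1000
  }, numeric(1))
  se <- sqrt(0.1 * 0.9 / 1000)
  expect_lte(mean(rates), 0.1 + 3 * se)
})

test_that("signature selection applies the FDR and fold-change thresholds", {
  rec <- data.table::data.table(
    feature = c("kept_up", "weak_fdr", "down_gene", "small_fc"),
    mean_g1 = 1, mean_g2 = 1,
    log2fc = c(0.6, 2.0, -0.8, 0.3),
    p = c(0.001, 0.05, 0.001, 0.001),
    fdr = c(0.05, 0.2, 0.05, 0.05))
  expect_equal(select_signature(rec, direction = "up")$genes, "kept_up")
  expect_equal(select_signature(rec, direction = "down")$genes, "down_gene")
  expect_setequal(select_signature(rec, direction = "both")$genes,
                  c("kept_up", "down_gene"))
  expect_length(select_signature(rec[0])$genes, 0)
})

test_that("planted two-fold markers are recovered with high sensitivity", {
  sens <- vapply(1:3, function(s) {
    sim <- simulate_experiment(small_sim_config(seed = 60 + s, n_cells = 100))
    truth <- sim_truth_labels(sim)
    tiles <- build_tile_matrix(sim$fragments, sim$chrom_sizes, 500,
                               names(truth))
    gs <- gene_scores(tiles, sim$genes)
    rec <- marker_features(gs, names(truth)[truth == "alveolar"],
                           names(truth)[truth == "baseline"])
    sig <- select_signature(rec, 0.1, 0.5, "up")
    planted <- sim$ground_truth$marker_genes$alveolar
    mean(planted %in% sig$genes)
  }, numeric(1))
  expect_gte(mean(sens), 0.8)
})

test_that("volcano tables restrict, order and report missing genes", {
  rec <- data.table::data.table(
    feature = sprintf("g%d", 1:5), mean_g1 = 1, mean_g2 = 1,
    log2fc = c(0.1, -2, 1, 0.5, -0.2), p = 0.01, fdr = 0.02)
  v <- signature_volcano(rec, c("g2", "g3", "g4", "absent"))
  expect_equal(v$feature, c("g2", "g3", "g4"))
  expect_equal(attr(v, "missing"), "absent")
  all_v <- signature_volcano(rec, rec$feature)
  expect_equal(nrow(all_v), 5)
  expect_equal(all_v$feature[1], "g2")
})

test_that("hypergeometric overlap matches enumeration and edge cases", {
  # worked instance: N = 10, |A| = 4, |B| = 5, k = 3 -> 66/252
  got <- hypergeom_overlap(sprintf("x%d", 1:4),
                           c("x1", "x2", "x3", "y1", "y2"), 10)
  expect_equal(got$overlap, 3)
  expect_equal(got$p, 66 / 252, tolerance = 1e-12)
  expect_equal(got$p, hypergeom_enum_oracle(10, 4, 5, 3), tolerance = 1e-12)

  expect_equal(hypergeom_overlap(c("a"), c("b"), 10)$p, 1)  # k = 0
  u <- sprintf("u%d", 1:7)
  expect_equal(hypergeom_overlap(u, u, 7, universe = u)$p, 1)
  expect_error(hypergeom_overlap(sprintf("x%d", 1:5), "x1", 3), "universe")
})

test_that("hypergeometric equals exhaustive enumeration for all N <= 12", {
  for (N in 2:12) {
    for (nA in 1:(N - 1)) {
      for (nB in 1:(N - 1)) {
        k_obs <- sample(0:min(nA, nB), 1)
        got <- hypergeom_overlap(
          sprintf("e%d", 1:nA),
          sprintf("e%d", c(seq_len(k_obs), nA + seq_len(nB - k_obs))), N)
        expect_equal(got$p, hypergeom_enum_oracle(N, nA, nB, got$overlap),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BH adjustment is monotone after step-up", {
  set.seed(14)
  rec <- data.table::data.table(
    feature = sprintf("f%d", 1:50), mean_g1 = 1, mean_g2 = 1,
    log2fc = 0, p = runif(50))
  rec[, "fdr" := p.adjust(p, "BH")]
  o <- order(rec$p)
  expect_true(all(diff(rec$fdr[o]) >= -1e-15))
  expect_true(all(rec$fdr >= rec$p))
})

test_that("trajectory motif statistics: constants, planted trends,
           permutation floor", {
  set.seed(15)
  n <- 300
  pt <- sort(runif(n, 0, 100))
  bc <- sprintf("c%03d", 1:n)
  Z <- cbind(FLAT = rep(1.3, n),
             RISING = pt / 20 + rnorm(n, 0, 0.5),
             NOISE = rnorm(n))
  rownames(Z) <- bc
  tr <- data.table::data.table(barcode = bc, cluster = 0, pseudotime = pt)
  res <- trajectory_differential_motifs(Z, tr, n_bins = 50, window = 7,
                                        n_permutations = 200, seed = 15)
  expect_equal(res$statistic[res$motif == "FLAT"], 0)
  expect_equal(res$p[res$motif == "FLAT"], 1)
  expect_true(res$differential[res$motif == "RISING"])
  expect_false(res$differential[res$motif == "NOISE"])
  # permutation p floor: (1 + 0) / (1 + 200)
  expect_gte(min(res$p), 1 / 201)
  expect_error(
    trajectory_differential_motifs(Z, tr[1:10], n_bins = 50),
    "n_bins")
})

test_that("permutation p-values are valid under the null", {
  set.seed(16)
  n <- 150
  pt <- runif(n, 0, 100)
  bc <- sprintf("c%03d", 1:n)
  Z <- matrix(rnorm(n * 40), n, 40,
              dimnames = list(bc, sprintf("m%02d", 1:40)))
  tr <- data.table::data.table(barcode = bc, cluster = 0, pseudotime = pt)
  res <- trajectory_differential_motifs(Z, tr, n_bins = 30, window = 5,
                                        n_permutations = 100, seed = 16)
  for (alpha in c(0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / 40)
    expect_lte(mean(res$p <= alpha), alpha + 3 * se)
  }
})
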