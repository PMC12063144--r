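random_tile_matrix <- function(n = 60, p = 300, seed = 1) {
  set.seed(seed)
  m <- Matrix::Matrix(matrix(rpois(n * p, 0.4), n, p,
                             dimnames = list(sprintf("c%03d", seq_len(n)),
                                             sprintf("t%03d", seq_len(p)))),
                      sparse = TRUE)
  feature_matrix(m, "tile")
}

test_that("LSI: identical profiles embed identically and runs are
           deterministic", {
  m <- random_tile_matrix()
  mm <- as.matrix(m)
  mm[2, ] <- mm[1, ]  # duplicate binarized profile
  m2 <- feature_matrix(Matrix::Matrix(mm, sparse = TRUE), "tile")
  emb <- tfidf_lsi(m2, rank = 10, iterations = 1, seed = 5)
  expect_equal(emb$embedding[1, ], emb$embedding[2, ], tolerance = 1e-10)

  emb2 <- tfidf_lsi(m2, rank = 10, iterations = 1, seed = 5)
  expect_identical(emb$embedding, emb2$embedding)
  expect_error(tfidf_lsi(m2, rank = 500), "rank")
})

test_that("a rank-1 binarized structure is captured by one component", {
  # block matrix: 30 cells open exactly in the first 100 tiles, 30 in the
  # rest; after TF-IDF the spectrum has one dominant direction of variation
  block <- matrix(0, 60, 300)
  block[1:30, 1:100] <- 1
  block[31:60, 101:300] <- 1
  dimnames(block) <- list(sprintf("c%02d", 1:60), sprintf("t%03d", 1:300))
  m <- feature_matrix(Matrix::Matrix(block, sparse = TRUE), "tile")
  emb <- tfidf_lsi(m, rank = 5, iterations = 1, seed = 1,
                   depth_cor_threshold = 1.01)
  en <- colSums(emb$embedding^2)
  # component 1 is the constant TF-IDF direction; the block split must be
  # fully explained by the first two components
  expect_gte(sum(en[1:2]) / sum(en), 0.99)
})

test_that("depth-correlated components are flagged and excluded", {
  sim <- simulate_experiment(small_sim_config(seed = 2, n_cells = 50))
  tiles <- build_tile_matrix(sim$fragments, sim$chrom_sizes, 500,
                             names(sim_truth_labels(sim)))
  emb <- tfidf_lsi(tiles, rank = 20, seed = 2)
  depth <- Matrix::rowSums(tiles)
  flagged_cor <- abs(cor(emb$embedding, depth))[emb$flagged]
  expect_true(all(flagged_cor > 0.75))
  E <- embedding_coords(emb)
  expect_equal(ncol(E), 20 - sum(emb$flagged))
})

test_that("two separated blobs cluster exactly; resolution limit gives one
           cluster", {
  set.seed(3)
  E <- rbind(matrix(rnorm(40 * 5), 40, 5),
             matrix(rnorm(40 * 5, mean = 12), 40, 5))
  rownames(E) <- sprintf("c%02d", 1:80)
  cl <- snn_cluster(E, k = 10, resolution = 0.8, seed = 3)
  truth <- rep(1:2, each = 40)
  expect_equal(ari_from_table(table(cl$cluster, truth)), 1)

  # resolution -> 0 merges everything that is connected; with two distant
  # blobs the SNN graph has two components, so use one connected cloud
  set.seed(33)
  E1 <- matrix(rnorm(80 * 5), 80, 5)
  rownames(E1) <- sprintf("s%02d", 1:80)
  cl0 <- snn_cluster(E1, k = 10, resolution = 1e-4, seed = 3)
  expect_equal(length(unique(cl0$cluster)), 1)
  expect_error(snn_cluster(E, k = 100), "k must be")
})

test_that("cluster count is non-increasing as resolution decreases", {
  set.seed(4)
  E <- matrix(rnorm(120 * 6), 120, 6)
  rownames(E) <- sprintf("c%03d", 1:120)
  ladder <- c(2, 1.2, 0.8, 0.4, 0.1, 1e-3)
  ks <- vapply(ladder, function(r) {
    length(unique(snn_cluster(E, k = 12, resolution = r, seed = 4)$cluster))
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("diffusion smoothing preserves constants and t = 0 is identity", {
  set.seed(5)
  E <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(sprintf("c%02d", 1:50), NULL))
  v <- stats::setNames(rnorm(50), rownames(E))
  expect_identical(impute_smooth(E, v, t = 0), v)
  const <- stats::setNames(rep(2.5, 50), rownames(E))
  expect_equal(impute_smooth(E, const, t = 3), const, tolerance = 1e-12)
  expect_error(impute_smooth(E, v, t = -1), "t must be")
})

test_that("smoothing does not degrade planted repression separation", {
  ok <- vapply(1:3, function(s) {
    sim <- simulate_experiment(small_sim_config(seed = 40 + s, n_cells = 60))
    truth <- sim_truth_labels(sim)
    tiles <- build_tile_matrix(sim$fragments, sim$chrom_sizes, 500,
                               names(truth))
    emb <- tfidf_lsi(tiles, rank = 20, seed = s)
    ds <- repressive_domain_set(sim$domains, sim$chrom_sizes)
    rs <- repression_score(sim$fragments, ds, names(truth))
    rs <- rs[rownames(emb$embedding)]
    sm <- impute_smooth(emb, rs)
    base <- names(truth)[truth == "baseline"]
    repr <- names(truth)[truth == "repressed"]
    rank_auc(sm[base], sm[repr]) >= rank_auc(rs[base], rs[repr]) - 0.01
  }, logical(1))
  expect_true(all(ok))
})

test_that("pseudotime is exact at true centroids and monotone along a
           planted gradient", {
  # deterministic layout: clusters at x = 0, 5, 10 with symmetric offsets,
  # so cluster means are exactly the design centroids
  offs <- c(-1, 1)
  E <- cbind(c(0 + offs, 5 + offs, 10 + offs, 0, 5, 10), 0)
  rownames(E) <- sprintf("c%d", 1:9)
  cl <- data.table::data.table(barcode = rownames(E),
                               cluster = c(0, 0, 1, 1, 2, 2, 0, 1, 2))
  tr <- pseudotime(E, cl, path = 0:2)
  got <- tr$pseudotime[match(sprintf("c%d", 7:9), tr$barcode)]
  expect_equal(got, 100 * (0:2) / 3)

  set.seed(7)
  x <- runif(200, 0, 30)
  E2 <- cbind(x + rnorm(200, 0, .3), rnorm(200, 0, .3))
  rownames(E2) <- sprintf("g%03d", 1:200)
  cl2 <- data.table::data.table(barcode = rownames(E2),
                                cluster = pmin(2, x %/% 10))
  tr2 <- pseudotime(E2, cl2, path = 0:2)
  rho <- cor(tr2$pseudotime, x[match(tr2$barcode, rownames(E2))],
             method = "spearman")
  expect_gte(rho, 0.9)
  # off-path cells are excluded
  cl3 <- data.table::data.table(barcode = rownames(E2),
                                cluster = c(3, cl2$cluster[-1]))
  tr3 <- pseudotime(E2, cl3, path = 0:2)
  expect_true(rownames(E2)[1] %in% attr(tr3, "excluded"))
})
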