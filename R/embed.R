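## Iterative LSI embedding, SNN modularity clustering, Markov graph-
## diffusion smoothing and cluster-path pseudotime.

#' Iterative LSI (TF-IDF + truncated SVD)
#'
#' The matrix is binarized; the first iteration runs TF-IDF
#' (\code{TF}: row-normalized, \code{IDF_j = ln(1 + N/(1 + df_j))}) and a
#' rank-\code{rank} truncated SVD on the \code{n_top_features} most
#' frequently open tiles. A coarse clustering (resolution 0.2) of that
#' embedding defines pseudobulks, and the second iteration re-selects the
#' tiles most variable across pseudobulk log-CPM before repeating TF-IDF +
#' SVD. Components whose absolute Pearson correlation with per-cell depth
#' exceeds \code{depth_cor_threshold} are flagged and excluded from all
#' downstream geometry.
#'
#' @param tile_matrix cell x feature count matrix
#' @param rank number of singular components (default 30)
#' @param n_top_features features used per iteration (default
#'   \code{min(5000, ncol)})
#' @param iterations 1 or 2 (default 2)
#' @param seed integer seed (SVD initialization, coarse clustering)
#' @param depth_cor_threshold flag components with |r| above this (0.75)
#' @param coarse_resolution,coarse_k coarse-clustering parameters for the
#'   feature re-selection step
#' @return \code{lsi_embedding}: list(embedding, depth_cor, flagged, seed,
#'   features)
#' @export
tfidf_lsi <- function(tile_matrix, rank = 30, n_top_features = NULL,
                      iterations = 2, seed = 1, depth_cor_threshold = 0.75,
                      coarse_resolution = 0.2, coarse_k = 15,
                      binarize = TRUE) {
  n <- nrow(tile_matrix)
  n_top_features <- n_top_features %||% min(5000L, ncol(tile_matrix))
  assert_that(n >= rank + 1 && n_top_features >= rank + 1,
              "rank must be smaller than both matrix dimensions")
  B <- tile_matrix
  if (binarize) B@x <- rep(1, length(B@x))
  depth <- Matrix::rowSums(tile_matrix)

  run_svd <- function(feat_idx) {
    X <- B[, feat_idx, drop = FALSE]
    rs <- Matrix::rowSums(X)
    tf <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% X
    df <- Matrix::colSums(X)
    idf <- log(1 + n / (1 + df))
    M <- tf %*% Matrix::Diagonal(x = idf)
    set.seed(seed)
    sv <- irlba::irlba(M, nv = rank)
    fx <- fix_svd_signs(sv$u, sv$v)
    emb <- fx$u %*% diag(sv$d, rank, rank)
    rownames(emb) <- rownames(tile_matrix)
    colnames(emb) <- sprintf("LSI%02d", seq_len(rank))
    emb
  }

  feats <- order(Matrix::colSums(B), decreasing = TRUE)[seq_len(n_top_features)]
  emb <- run_svd(feats)

  if (iterations >= 2) {
    coarse <- snn_cluster(new_lsi(emb, depth, depth_cor_threshold, seed),
                          k = min(coarse_k, n - 1),
                          resolution = coarse_resolution, seed = seed)
    groups <- coarse$cluster[match(rownames(tile_matrix), coarse$barcode)]
    if (length(unique(groups)) >= 2) {
      glev <- sort(unique(groups))
      G <- Matrix::sparseMatrix(i = match(groups, glev), j = seq_len(n),
                                x = 1, dims = c(length(glev), n))
      pb <- as.matrix(G %*% tile_matrix)
      cpm <- log2(sweep(pb, 1, pmax(rowSums(pb), 1), "/") * 1e6 + 1)
      v <- apply(cpm, 2, var)
      feats <- order(v, decreasing = TRUE)[seq_len(n_top_features)]
      emb <- run_svd(feats)
    }
  }
  new_lsi(emb, depth, depth_cor_threshold, seed,
          features = colnames(tile_matrix)[feats])
}

new_lsi <- function(emb, depth, threshold, seed, features = NULL) {
  dcor <- suppressWarnings(as.numeric(cor(emb, depth)))
  dcor[is.na(dcor)] <- 0
  structure(list(embedding = emb, depth_cor = dcor,
                 flagged = abs(dcor) > threshold, seed = seed,
                 features = features),
            class = "lsi_embedding")
}

#' @rdname tfidf_lsi
#' @param emb an \code{lsi_embedding}
#' @param drop_flagged exclude depth-correlated components (default TRUE)
#' @export
embedding_coords <- function(emb, drop_flagged = TRUE) {
  assert_that(inherits(emb, "lsi_embedding"), "not an lsi_embedding")
  E <- emb$embedding
  if (drop_flagged && any(emb$flagged) && !all(emb$flagged)) {
    E <- E[, !emb$flagged, drop = FALSE]
  }
  E
}

#' @export
print.lsi_embedding <- function(x, ...) {
  cat(sprintf("lsi_embedding: %d cells x %d components (%d depth-flagged)\n",
              nrow(x$embedding), ncol(x$embedding), sum(x$flagged)))
  invisible(x)
}

#' Shared-nearest-neighbour modularity clustering
#'
#' kNN by Euclidean distance on the unflagged LSI components; edges are
#' weighted by the Jaccard overlap of the two cells' neighbour sets (pruned
#' below 1/15); communities are found by Leiden modularity optimization at
#' the given resolution. Labels are dense integers from 0, ordered by
#' decreasing cluster size.
#'
#' @param embedding an \code{lsi_embedding} (or bare numeric matrix)
#' @param k neighbours (default 15)
#' @param resolution modularity resolution (default 0.8, the study setting)
#' @param seed integer seed
#' @return \code{cluster_assignment}: data.table(barcode, cluster) with
#'   attributes resolution, k, seed
#' @export
snn_cluster <- function(embedding, k = 15, resolution = 0.8, seed = 1) {
  E <- if (inherits(embedding, "lsi_embedding")) embedding_coords(embedding)
       else embedding
  n <- nrow(E)
  assert_that(k < n, "k must be smaller than the number of cells")
  nn <- RANN::nn2(E, k = k + 1)$nn.idx  # includes self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)
  S@x <- S@x / (2 * (k + 1) - S@x)      # Jaccard on neighbour sets
  S@x[S@x < 1 / 15] <- 0
  S <- Matrix::drop0(S)
  Matrix::diag(S) <- 0
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(cl)
  ## dense labels from 0, largest cluster first
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  out <- data.table(barcode = rownames(E),
                    cluster = as.integer(relabel[as.character(memb)]))
  data.table::setattr(out, "resolution", resolution)
  data.table::setattr(out, "k", k)
  data.table::setattr(out, "seed", seed)
  data.table::setattr(out, "class", c("cluster_assignment", class(out)))
  out
}

#' Graph-diffusion smoothing of per-cell scores
#'
#' MAGIC-style imputation: an adaptive Gaussian kernel (bandwidth = distance
#' to the ceil(k/3)-th neighbour) truncated to each cell's k nearest
#' neighbours is symmetrized and row-normalized into a Markov matrix M, and
#' the values are diffused as \eqn{M^t v}. The kNN truncation keeps the
#' diffusion local: in an embedding with many near-noise components the
#' untruncated Gaussian tail carries substantial mass across unrelated
#' cells. Constant vectors are preserved exactly; \code{t = 0} returns the
#' input.
#'
#' @param embedding \code{lsi_embedding} or numeric matrix
#' @param values named numeric vector or matrix (rows = cells)
#' @param k neighbourhood size (default 15)
#' @param t diffusion steps (default 3, >= 0)
#' @return smoothed values, same shape and names as input
#' @export
impute_smooth <- function(embedding, values, k = 15, t = 3) {
  assert_that(t >= 0, "t must be >= 0")
  E <- if (inherits(embedding, "lsi_embedding")) embedding_coords(embedding)
       else embedding
  vec <- is.null(dim(values))
  V <- if (vec) matrix(values, ncol = 1,
                       dimnames = list(names(values), NULL))
       else as.matrix(values)
  assert_that(nrow(V) == nrow(E) &&
                (is.null(rownames(V)) || all(rownames(V) == rownames(E))),
              "values must align with embedding cells")
  if (t == 0) return(values)
  n <- nrow(E)
  k_use <- min(k, n - 1)
  nn <- RANN::nn2(E, k = k_use + 1)  # first neighbour is self
  kk <- max(1L, as.integer(ceiling(k / 3)))
  sigma <- nn$nn.dists[, min(kk, k_use) + 1]
  sigma[sigma == 0] <- min(c(sigma[sigma > 0], 1))
  K <- matrix(0, n, n)
  w <- exp(-(nn$nn.dists / sigma)^2)
  K[cbind(rep(seq_len(n), k_use + 1), as.vector(nn$nn.idx))] <- as.vector(w)
  K <- (K + t(K)) / 2
  M <- K / rowSums(K)
  for (i in seq_len(t)) V <- M %*% V
  if (vec) stats::setNames(as.numeric(V), names(values)) else V
}

#' Cluster-path pseudotime
#'
#' Cells are ordered along a user-specified path of clusters. A cell in the
#' i-th path cluster is positioned by the clamped scalar projection of its
#' offset from the cluster centroid onto the direction to the next
#' centroid (the last cluster reuses its incoming direction), giving
#' pseudotime \code{100 * (i - 1 + proj) / length(path)} in [0, 100]. Cells
#' in off-path clusters are excluded.
#'
#' @param embedding \code{lsi_embedding} or numeric matrix
#' @param clusters a \code{cluster_assignment}
#' @param path ordered vector of cluster labels (length >= 2)
#' @return \code{trajectory_result}: data.table(barcode, cluster,
#'   pseudotime) plus attributes path and excluded barcodes
#' @export
pseudotime <- function(embedding, clusters, path) {
  assert_that(length(path) >= 2, "path must contain at least 2 clusters")
  assert_that(all(path %in% clusters$cluster),
              "all path labels must exist in the cluster assignment")
  E <- if (inherits(embedding, "lsi_embedding")) embedding_coords(embedding)
       else embedding
  cl <- clusters$cluster[match(rownames(E), clusters$barcode)]
  centroids <- t(vapply(path, function(p) {
    colMeans(E[cl == p, , drop = FALSE])
  }, numeric(ncol(E))))
  L <- length(path)
  dirs <- centroids[c(2:L, L), , drop = FALSE] -
    centroids[c(1:(L - 1), L - 1), , drop = FALSE]
  assert_that(all(rowSums(dirs^2) > 0),
              "degenerate path: identical consecutive centroids")
  on_path <- cl %in% path
  pt <- rep(NA_real_, nrow(E))
  for (i in seq_len(L)) {
    sel <- on_path & cl == path[i]
    if (!any(sel)) next
    off <- sweep(E[sel, , drop = FALSE], 2, centroids[i, ])
    proj <- as.numeric(off %*% dirs[i, ]) / sum(dirs[i, ]^2)
    pt[sel] <- 100 * (i - 1 + pmin(pmax(proj, 0), 1)) / L
  }
  out <- data.table(barcode = rownames(E)[on_path], cluster = cl[on_path],
                    pseudotime = pt[on_path])
  data.table::setattr(out, "path", path)
  data.table::setattr(out, "excluded", rownames(E)[!on_path])
  data.table::setattr(out, "class", c("trajectory_result", class(out)))
  out
}
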