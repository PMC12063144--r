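## Cell x feature matrices: genome tiles, distance-weighted gene
## accessibility scores, peak counts, per-cell repressive-domain scores and
## per-cell motif deviation z-scores.

intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(intervals$chrom,
                         IRanges::IRanges(intervals$start + 1L, intervals$end))
}

#' Tile-matrix construction
#'
#' Bins the genome into fixed-width tiles and counts Tn5 insertion events
#' (fragment start and end-1) per cell and tile. The grand total of the
#' matrix is exactly twice the number of fragment records of the kept
#' cells.
#'
#' @param fragments fragment data.table
#' @param chrom_sizes named vector of chromosome lengths covering all
#'   fragment chromosomes
#' @param tile_size tile width in bp (> 0, default 500)
#' @param kept_barcodes optional barcodes to retain (default: all)
#' @return feature matrix (cells x tiles), tile ids "chrom:start-end"
#' @export
build_tile_matrix <- function(fragments, chrom_sizes, tile_size = 500,
                              kept_barcodes = NULL) {
  assert_that(tile_size > 0, "tile_size must be > 0")
  assert_that(all(fragments$chrom %in% names(chrom_sizes)),
              "chrom_sizes must cover all fragment chromosomes")
  if (!is.null(kept_barcodes)) {
    fragments <- fragments[fragments$barcode %in% kept_barcodes]
  }
  barcodes <- if (is.null(kept_barcodes)) sort(unique(fragments$barcode))
              else kept_barcodes
  n_tiles_per <- stats::setNames(as.integer(ceiling(chrom_sizes / tile_size)),
                                 names(chrom_sizes))
  offsets <- stats::setNames(c(0L, cumsum(n_tiles_per))[seq_along(chrom_sizes)],
                             names(chrom_sizes))
  total_tiles <- sum(n_tiles_per)

  tile_ids <- unlist(lapply(names(chrom_sizes), function(ch) {
    s <- seq.int(0L, by = tile_size, length.out = n_tiles_per[[ch]])
    sprintf("%s:%d-%d", ch, s, pmin(s + tile_size, chrom_sizes[[ch]]))
  }), use.names = FALSE)

  ins <- fragment_insertions(fragments)
  tile_local <- pmin(ins$pos %/% tile_size,
                     n_tiles_per[ins$chrom] - 1L)
  j <- offsets[ins$chrom] + tile_local + 1L
  i <- match(ins$barcode, barcodes)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(barcodes), total_tiles),
                            dimnames = list(barcodes, tile_ids))
  feature_matrix(m, "tile")
}

#' Peak-count matrix
#'
#' Counts insertion events per cell in each supplied peak interval; peaks
#' may not overlap each other. Feature ids are the peak names (or
#' "chrom:start-end" when unnamed).
#'
#' @param fragments fragment data.table
#' @param peaks interval data.table (chrom, start, end[, name])
#' @param kept_barcodes optional barcodes to retain
#' @return feature matrix (cells x peaks)
#' @export
build_peak_matrix <- function(fragments, peaks, kept_barcodes = NULL) {
  if (!is.null(kept_barcodes)) {
    fragments <- fragments[fragments$barcode %in% kept_barcodes]
  }
  barcodes <- if (is.null(kept_barcodes)) sort(unique(fragments$barcode))
              else kept_barcodes
  ids <- if ("name" %in% names(peaks)) peaks$name
         else sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  assert_that(!anyDuplicated(ids), "duplicate peak ids")
  ins <- fragment_insertions(fragments)
  ins_gr <- GenomicRanges::GRanges(ins$chrom,
                                   IRanges::IRanges(ins$pos + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(ins_gr, intervals_to_granges(peaks))
  i <- match(ins$barcode[S4Vectors::queryHits(ov)], barcodes)
  m <- Matrix::sparseMatrix(i = i, j = S4Vectors::subjectHits(ov), x = 1,
                            dims = c(length(barcodes), nrow(peaks)),
                            dimnames = list(barcodes, ids))
  feature_matrix(m, "peak")
}

#' Distance-weighted gene accessibility scores
#'
#' For each gene, tiles within \code{max_distance} of the gene body
#' contribute their insertion counts with weight 1 when they overlap the
#' body and weight \eqn{e^{-d / decay}} when they lie d bp from the nearest
#' body edge. Scores are then depth-normalized per cell to
#' \code{1e4 / (total insertions)}, so cells with identical fragment
#' placement but different depth get identical scores.
#'
#' @param tile_matrix cell x tile feature matrix
#' @param genes gene annotation table
#' @param decay_bp exponential decay scale (default 5000)
#' @param max_distance maximum tile-to-body distance considered (default 1e5)
#' @return feature matrix (cells x genes), gene_id columns
#' @export
gene_scores <- function(tile_matrix, genes, decay_bp = 5000,
                        max_distance = 100000) {
  assert_that(nrow(genes) > 0, "gene annotation is empty")
  ids <- colnames(tile_matrix)
  parts <- data.table::tstrsplit(ids, "[:-]")
  tiles <- data.table(chrom = parts[[1]], start = as.integer(parts[[2]]),
                      end = as.integer(parts[[3]]))
  tile_gr <- intervals_to_granges(tiles)
  missing_chrom <- !(genes$chrom %in% unique(tiles$chrom))
  if (any(missing_chrom)) {
    warning(sprintf("%d gene(s) on chromosomes absent from the tile matrix",
                    sum(missing_chrom)))
  }
  body_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$body_start + 1L, genes$body_end))
  win <- GenomicRanges::resize(body_gr,
                               GenomicRanges::width(body_gr) + 2 * max_distance,
                               fix = "center")
  suppressWarnings(ov <- GenomicRanges::findOverlaps(tile_gr, win))
  ti <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  d <- suppressWarnings(GenomicRanges::distance(tile_gr[ti], body_gr[gi]))
  w <- exp(-as.numeric(d) / decay_bp)  # distance 0 includes body overlap
  keep <- !is.na(d) & d <= max_distance
  W <- Matrix::sparseMatrix(i = ti[keep], j = gi[keep], x = w[keep],
                            dims = c(ncol(tile_matrix), nrow(genes)),
                            dimnames = list(ids, genes$gene_id))
  raw <- tile_matrix %*% W
  depth <- Matrix::rowSums(tile_matrix)
  scale <- ifelse(depth > 0, 1e4 / depth, 0)
  out <- Matrix::Diagonal(x = scale) %*% raw
  dimnames(out) <- list(rownames(tile_matrix), genes$gene_id)
  feature_matrix(out, "gene")
}

#' Build the repressive-domain set with clipped flanks
#'
#' Flanks are \code{flank_bp} on each side of every (merged) domain, with
#' bases that overlap any domain or fall off-chromosome removed. Used to
#' normalize in-domain insertion density against the local background.
#'
#' @param domains interval data.table of ChIP-seq broad domains
#' @param chrom_sizes named chromosome lengths
#' @param flank_bp flank width each side (default 2000)
#' @return list(domains, flanks [GRanges], L_dom, L_fl [bp])
#' @export
repressive_domain_set <- function(domains, chrom_sizes, flank_bp = 2000) {
  gr <- GenomicRanges::reduce(intervals_to_granges(domains))
  lens <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  left <- GenomicRanges::flank(gr, flank_bp, start = TRUE)
  right <- GenomicRanges::flank(gr, flank_bp, start = FALSE)
  fl <- GenomicRanges::reduce(c(left, right))
  fl <- GenomicRanges::setdiff(fl, gr)
  ## clip to chromosome bounds
  GenomicRanges::start(fl) <- pmax(GenomicRanges::start(fl), 1L)
  GenomicRanges::end(fl) <- pmin(GenomicRanges::end(fl),
                                 lens[as.character(GenomicRanges::seqnames(fl))])
  fl <- fl[GenomicRanges::width(fl) > 0]
  L_fl <- sum(as.numeric(GenomicRanges::width(fl)))
  assert_that(L_fl > 0, "flank set is empty: domains cover their flanks")
  structure(list(domains = gr, flanks = fl,
                 L_dom = sum(as.numeric(GenomicRanges::width(gr))),
                 L_fl = L_fl, flank_bp = flank_bp),
            class = "repressive_domain_set")
}

count_positions_in_gr <- function(ins, gr, barcodes) {
  q <- GenomicRanges::GRanges(ins$chrom,
                              IRanges::IRanges(ins$pos + 1L, width = 1L))
  hit <- IRanges::overlapsAny(q, gr)
  out <- stats::setNames(rep(0L, length(barcodes)), barcodes)
  if (any(hit)) {
    tb <- table(ins$barcode[hit])
    common <- intersect(names(tb), barcodes)
    out[common] <- as.integer(tb[common])
  }
  out
}

#' Per-cell repressive-chromatin score
#'
#' For each cell, the insertion density inside the repressive domains
#' divided by the density in their clipped +/- 2 kb flanks, with a
#' pseudocount \code{alpha} on both counts:
#' \deqn{raw(c) = \frac{(n_{dom}(c)+\alpha)/L_{dom}}{(n_{fl}(c)+\alpha)/L_{fl}}}
#' Low scores mean few insertions in domains relative to their local
#' background, i.e. more compacted heterochromatin. \code{mode =
#' "per_domain"} averages the per-domain ratios (each domain against its
#' own flanks) instead of pooling counts and lengths.
#'
#' @param fragments fragment data.table
#' @param domainset a \code{\link{repressive_domain_set}}
#' @param kept_barcodes barcodes to score (default: all in fragments)
#' @param alpha pseudocount (default 1)
#' @param mode "pooled" (default) or "per_domain"
#' @return named numeric vector, barcode -> raw score
#' @export
repression_score <- function(fragments, domainset, kept_barcodes = NULL,
                             alpha = 1, mode = c("pooled", "per_domain")) {
  mode <- match.arg(mode)
  assert_that(inherits(domainset, "repressive_domain_set"),
              "domainset must be a repressive_domain_set")
  if (!is.null(kept_barcodes)) {
    fragments <- fragments[fragments$barcode %in% kept_barcodes]
  }
  barcodes <- kept_barcodes %||% sort(unique(fragments$barcode))
  ins <- fragment_insertions(fragments)
  if (mode == "pooled") {
    nd <- count_positions_in_gr(ins, domainset$domains, barcodes)
    nf <- count_positions_in_gr(ins, domainset$flanks, barcodes)
    return(((nd + alpha) / domainset$L_dom) /
             ((nf + alpha) / domainset$L_fl))
  }
  ## per-domain: each domain normalized by its own clipped flanks
  doms <- domainset$domains
  scores <- matrix(0, length(barcodes), length(doms),
                   dimnames = list(barcodes, NULL))
  for (d in seq_along(doms)) {
    fl_d <- IRanges::subsetByOverlaps(
      domainset$flanks,
      GenomicRanges::resize(doms[d],
                            GenomicRanges::width(doms[d]) +
                              2 * domainset$flank_bp, fix = "center"))
    if (length(fl_d) == 0) next
    nd <- count_positions_in_gr(ins, doms[d], barcodes)
    nf <- count_positions_in_gr(ins, fl_d, barcodes)
    Ld <- as.numeric(GenomicRanges::width(doms[d]))
    Lf <- sum(as.numeric(GenomicRanges::width(fl_d)))
    scores[, d] <- ((nd + alpha) / Ld) / ((nf + alpha) / Lf)
  }
  rowMeans(scores)
}

#' Motif membership from motif-hit intervals
#'
#' @param motif_hits interval data.table with a \code{name} column (motif id)
#' @param peaks peak interval data.table (named)
#' @return logical sparse matrix, peaks x motifs; every annotated peak must
#'   exist in the peak set
#' @export
motif_annotation_matrix <- function(motif_hits, peaks) {
  ids <- if ("name" %in% names(peaks)) peaks$name
         else sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  motifs <- sort(unique(motif_hits$name))
  ov <- GenomicRanges::findOverlaps(intervals_to_granges(motif_hits),
                                    intervals_to_granges(peaks))
  i <- S4Vectors::subjectHits(ov)                       # peak index
  j <- match(motif_hits$name[S4Vectors::queryHits(ov)], motifs)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(nrow(peaks), length(motifs)),
                            dimnames = list(ids, motifs))
  m > 0
}

#' Per-cell motif deviation z-scores
#'
#' For cell c and motif m, the observed count in motif-bearing peaks is
#' compared with the expectation under uniform usage,
#' \eqn{exp = tot_c \cdot \sum_{p \in m}\bar{a}_p / \sum_p \bar{a}_p}
#' (mean peak accessibility weights), giving a relative deviation
#' \eqn{(obs-exp)/exp}. The deviation is z-scored against
#' \code{n_permutations} backgrounds in which motif membership is permuted
#' among peaks within deciles of mean accessibility, preserving the
#' accessibility confound. Motifs with zero member peaks are dropped with a
#' message; a degenerate null (zero sd) yields z = 0.
#'
#' @param peak_matrix cell x peak feature matrix
#' @param annotation logical peaks x motifs matrix
#'   (\code{\link{motif_annotation_matrix}})
#' @param n_permutations background permutations (default 50)
#' @param n_deciles accessibility bins for matched permutation (default 10)
#' @param seed integer seed
#' @return dense base matrix (cells x motifs) of signed z-scores with
#'   attributes \code{feature_space = "motif"} and \code{degenerate_cells}
#' @export
motif_deviation <- function(peak_matrix, annotation, n_permutations = 50,
                            n_deciles = 10, seed = 1) {
  assert_that(ncol(annotation) >= 1, "at least one motif required")
  assert_that(all(rownames(annotation) %in% colnames(peak_matrix)),
              "annotated peak ids must all exist in the peak matrix")
  A <- methods::as(annotation[colnames(peak_matrix), , drop = FALSE],
                   "CsparseMatrix") * 1
  n_member <- Matrix::colSums(A)
  if (any(n_member == 0)) {
    message(sprintf("dropping %d motif(s) with zero member peaks: %s",
                    sum(n_member == 0),
                    paste(colnames(A)[n_member == 0], collapse = ", ")))
    A <- A[, n_member > 0, drop = FALSE]
  }
  assert_that(ncol(A) >= 1, "no motif has member peaks")
  set.seed(seed)
  colmean <- Matrix::colMeans(peak_matrix)
  tot <- Matrix::rowSums(peak_matrix)

  deviation <- function(Amat) {
    obs <- as.matrix(peak_matrix %*% Amat)
    frac <- as.numeric(Matrix::crossprod(Amat, colmean)) / sum(colmean)
    expc <- outer(tot, frac)
    dev <- (obs - expc) / expc
    dev[expc == 0] <- 0
    dev
  }

  dev_obs <- deviation(A)
  ## accessibility-decile-matched permutations of peak membership
  dec <- cut(rank(colmean, ties.method = "first"),
             breaks = n_deciles, labels = FALSE)
  perm_sum <- array(0, dim(dev_obs))
  perm_sq <- array(0, dim(dev_obs))
  for (p in seq_len(n_permutations)) {
    perm <- seq_along(colmean)
    for (d in unique(dec)) {
      idx <- which(dec == d)
      perm[idx] <- idx[sample.int(length(idx))]
    }
    dv <- deviation(A[perm, , drop = FALSE])
    perm_sum <- perm_sum + dv
    perm_sq <- perm_sq + dv^2
  }
  mu <- perm_sum / n_permutations
  sdv <- sqrt(pmax(perm_sq / n_permutations - mu^2, 0) *
                n_permutations / (n_permutations - 1))
  z <- (dev_obs - mu) / sdv
  ## a null that is constant up to floating-point accumulation error is
  ## degenerate; 1e-9 is far below any genuine permutation sd at this scale
  degenerate <- sdv < 1e-9
  if (any(degenerate)) z[degenerate] <- 0
  dimnames(z) <- list(rownames(peak_matrix), colnames(A))
  attr(z, "degenerate_cells") <- sum(degenerate)
  attr(z, "feature_space") <- "motif"
  z
}
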