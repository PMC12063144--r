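## Per-cell quality metrics and the three-way cell filter used in the
## persister study: fragment count >= 100, TSS enrichment >= 4, and
## synthetic-doublet kNN enrichment < 1.

## count, per barcode, insertion hits in a set of (possibly overlapping)
## windows; an insertion inside two windows counts twice (pooled windows)
count_window_hits <- function(insertions, windows) {
  hits <- rep(0L, length(unique(insertions$barcode)))
  names(hits) <- unique(insertions$barcode)
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch]
    sel <- insertions$chrom == ch
    if (!any(sel)) next
    q <- IRanges::IRanges(insertions$pos[sel] + 1L, width = 1L)
    s <- IRanges::IRanges(w$start + 1L, w$end)
    ov <- IRanges::countOverlaps(q, s)
    if (any(ov > 0)) {
      agg <- rowsum(ov, insertions$barcode[sel])
      hits[rownames(agg)] <- hits[rownames(agg)] + as.integer(agg[, 1])
    }
  }
  hits
}

#' Per-cell QC metrics: fragment count and TSS enrichment
#'
#' Each fragment contributes two Tn5 insertion events (its start and its
#' last base). TSS enrichment for a cell is the insertion density in the
#' pooled TSS-centred windows (TSS +/- \code{center_halfwidth}) divided by
#' the density in the pooled distal background bands
#' (\code{background_band} bp up- and downstream of each TSS, oriented by
#' gene strand), with a +1 pseudocount on the background count:
#' \deqn{E = \frac{c / (2h+1)}{(b + 1) / (2 w)}}
#' where c and b are pooled center/background insertion counts, h the
#' center halfwidth and w the band width.
#'
#' @param fragments fragment data.table
#' @param genes gene annotation (needs chrom, strand, tss)
#' @param center_halfwidth halfwidth of the TSS window (bp, default 50)
#' @param background_band distal band, bp from the TSS (default 1901-2000)
#' @return data.table(barcode, n_fragments, tss_enrichment)
#' @export
compute_cell_qc <- function(fragments, genes, center_halfwidth = 50,
                            background_band = c(1901, 2000)) {
  assert_that(nrow(genes) >= 1, "at least one gene with a TSS is required")
  ins <- fragment_insertions(fragments)
  centers <- data.table(chrom = genes$chrom,
                        start = pmax(0L, genes$tss - as.integer(center_halfwidth)),
                        end = genes$tss + as.integer(center_halfwidth) + 1L)
  ## both strand-oriented bands are used for every gene, so the pooled
  ## background is strand-symmetric: [tss-b2, tss-b1] and [tss+b1, tss+b2]
  band_starts <- c(genes$tss - background_band[2],
                   genes$tss + background_band[1])
  bands <- data.table(chrom = rep(genes$chrom, 2),
                      start = pmax(0L, as.integer(band_starts)))
  bands[, "end" := bands$start + as.integer(diff(background_band)) + 1L]

  center_hits <- count_window_hits(ins, centers)
  bg_hits <- count_window_hits(ins, bands)
  band_w <- diff(background_band) + 1L
  nfrag <- table(fragments$barcode)

  bc <- names(nfrag)
  dt <- data.table(
    barcode = bc,
    n_fragments = as.integer(nfrag),
    tss_enrichment = (center_hits[bc] / (2 * center_halfwidth + 1)) /
      ((bg_hits[bc] + 1) / (2 * band_w))
  )
  dt$tss_enrichment[is.na(dt$tss_enrichment)] <- 0
  dt[]
}

#' Synthetic-doublet kNN enrichment
#'
#' Builds \code{n_synthetic} synthetic doublets by averaging the binarized
#' tile profiles of random cell pairs, co-embeds real and synthetic cells
#' with iterative LSI, and scores each real cell by the fraction of
#' synthetic doublets among its k nearest co-embedded neighbours, divided by
#' the global synthetic fraction. A value of 1 means the neighbourhood
#' doublet fraction equals chance; planted doublets score high because they
#' sit between their parent populations, where synthetic doublets
#' concentrate.
#'
#' The co-embedding defaults are deliberately compact: a low rank (the
#' structure that separates doublets from singlets is population-scale, and
#' extra components only add isotropic noise to neighbour distances), the
#' strongest 2000 tiles, and a larger k than the clustering default to
#' reduce the binomial variance of the neighbour fraction.
#'
#' @param tile_matrix cell x tile feature matrix (all barcodes, pre-filter)
#' @param n_synthetic number of synthetic doublets (> 0, default 400)
#' @param k neighbours (default 30)
#' @param embedding_params list passed to \code{\link{tfidf_lsi}} (rank,
#'   n_top_features, iterations)
#' @param seed integer seed
#' @return named numeric vector, barcode -> enrichment ratio
#' @export
doublet_enrichment <- function(tile_matrix, n_synthetic = 400, k = 30,
                               embedding_params = list(rank = 8,
                                                       iterations = 1,
                                                       n_top_features = 2000),
                               seed = 1) {
  n_real <- nrow(tile_matrix)
  assert_that(n_synthetic > 0, "n_synthetic must be > 0")
  assert_that(k < n_real + n_synthetic, "k must be smaller than total cells")
  assert_that(n_real >= 2 * k, "tile matrix must come from at least 2k cells")
  set.seed(seed)
  B <- tile_matrix
  B@x <- rep(1, length(B@x))
  i1 <- sample.int(n_real, n_synthetic, replace = TRUE)
  i2 <- vapply(i1, function(i) {
    j <- sample.int(n_real, 1)
    while (j == i) j <- sample.int(n_real, 1)
    j
  }, integer(1))
  synth <- (B[i1, , drop = FALSE] + B[i2, , drop = FALSE]) / 2
  rownames(synth) <- sprintf("SYNTH%05d", seq_len(n_synthetic))
  combined <- feature_matrix(rbind(B, synth), feature_space(tile_matrix))
  ## binarize = FALSE: the real rows are already binarized and the averaged
  ## synthetic rows must keep their fractional weights, otherwise they
  ## collapse to union profiles with twice the breadth of any real cell
  emb <- do.call(tfidf_lsi, c(list(combined, seed = seed, binarize = FALSE),
                              embedding_params))
  E <- embedding_coords(emb)
  nn <- RANN::nn2(E, E[seq_len(n_real), , drop = FALSE], k = k + 1)
  idx <- nn$nn.idx[, -1, drop = FALSE]  # drop self
  frac <- rowMeans(idx > n_real)
  expected <- n_synthetic / (n_synthetic + n_real)
  stats::setNames(frac / expected, rownames(tile_matrix))
}

#' Apply the three-way cell filter
#'
#' Keeps cells with \code{n_fragments >= min_fragments},
#' \code{tss_enrichment >= min_tss} and
#' \code{doublet_enrichment < doublet_threshold} (boundaries inclusive on
#' the >= criteria, exclusive on the doublet criterion: a cell at exactly
#' the doublet threshold is removed). The report counts removals per
#' criterion; a cell failing several is counted under each.
#'
#' @param records data.table with barcode, n_fragments, tss_enrichment and
#'   doublet_enrichment columns
#' @param min_fragments minimum fragment count (default 100)
#' @param min_tss minimum TSS enrichment (default 4)
#' @param doublet_threshold doublet-enrichment cutoff; cells at or above it
#'   are removed (default 1)
#' @return list(kept = character barcodes, report = named counts)
#' @export
apply_qc_filters <- function(records, min_fragments = 100, min_tss = 4,
                             doublet_threshold = 1) {
  if (nrow(records) == 0) {
    return(list(kept = character(0),
                report = c(n_input = 0L, n_kept = 0L, low_fragments = 0L,
                           low_tss = 0L, doublet = 0L)))
  }
  fail_frag <- records$n_fragments < min_fragments
  fail_tss <- records$tss_enrichment < min_tss
  fail_dbl <- records$doublet_enrichment >= doublet_threshold
  pass <- !fail_frag & !fail_tss & !fail_dbl
  list(kept = records$barcode[pass],
       report = c(n_input = nrow(records), n_kept = sum(pass),
                  low_fragments = sum(fail_frag), low_tss = sum(fail_tss),
                  doublet = sum(fail_dbl)))
}
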