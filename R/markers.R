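## Two-group marker detection, signature selection at the study thresholds
## (FDR <= 0.1, |log2FC| >= 0.5), signature volcano tables, hypergeometric
## set overlap and trajectory-differential motif calling.

## Vectorised two-sided Wilcoxon rank-sum p-values over matrix columns.
## Exact (pwilcox) when both groups have < 50 observations and the column
## is tie-free; otherwise the normal approximation with tie correction and
## continuity correction. Both routes match stats::wilcox.test defaults.
wilcox_p_columns <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2); N <- n1 + n2
  vapply(seq_len(ncol(x1)), function(j) {
    v <- c(x1[, j], x2[, j])
    r <- rank(v)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    has_ties <- any(ties > 1)
    if (!has_ties && n1 < 50 && n2 < 50) {
      p <- if (U > n1 * n2 / 2) {
        2 * (1 - pwilcox(U - 1, n1, n2))
      } else {
        2 * pwilcox(U, n1, n2)
      }
      return(min(1, p))
    }
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)  # constant across both groups
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }, numeric(1))
}

#' Marker features between two cell groups
#'
#' Per feature: a two-sided Wilcoxon rank-sum test (exact when both groups
#' have fewer than 50 cells and no ties, normal approximation with tie
#' correction otherwise), a pseudocounted log2 fold change
#' \code{log2((mean1 + beta) / (mean2 + beta))}, and Benjamini-Hochberg FDR
#' across all tested features. Features constant across both groups get
#' p = 1.
#'
#' @param matrix cell x feature matrix of normalized scores
#' @param group1,group2 disjoint barcode vectors, each >= 3 cells
#' @param pseudocount fold-change pseudocount beta (default 1)
#' @return data.table(feature, mean_g1, mean_g2, log2fc, p, fdr)
#' @export
marker_features <- function(matrix, group1, group2, pseudocount = 1) {
  assert_that(length(intersect(group1, group2)) == 0,
              "groups must be disjoint")
  assert_that(length(group1) >= 3 && length(group2) >= 3,
              "each group needs at least 3 cells")
  assert_that(all(c(group1, group2) %in% rownames(matrix)),
              "all group barcodes must be matrix rows")
  x1 <- as.matrix(matrix[group1, , drop = FALSE])
  x2 <- as.matrix(matrix[group2, , drop = FALSE])
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  p <- wilcox_p_columns(x1, x2)
  data.table(feature = colnames(matrix), mean_g1 = m1, mean_g2 = m2,
             log2fc = log2((m1 + pseudocount) / (m2 + pseudocount)),
             p = p, fdr = p.adjust(p, "BH"))
}

#' Select a signature set at the study thresholds
#'
#' @param records output of \code{\link{marker_features}}
#' @param max_fdr FDR ceiling (default 0.1)
#' @param min_abs_log2fc minimum |log2FC| (default 0.5)
#' @param direction "up" (group1-enriched), "down", or "both"
#' @param name signature name
#' @return \code{signature_set}: list(name, genes, provenance)
#' @export
select_signature <- function(records, max_fdr = 0.1, min_abs_log2fc = 0.5,
                             direction = c("up", "down", "both"),
                             name = "signature") {
  direction <- match.arg(direction)
  keep <- records$fdr <= max_fdr & switch(
    direction,
    up = records$log2fc >= min_abs_log2fc,
    down = records$log2fc <= -min_abs_log2fc,
    both = abs(records$log2fc) >= min_abs_log2fc)
  structure(list(name = name, genes = unique(records$feature[keep]),
                 provenance = list(max_fdr = max_fdr,
                                   min_abs_log2fc = min_abs_log2fc,
                                   direction = direction,
                                   n_tested = nrow(records))),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set '%s': %d genes (FDR <= %g, |log2FC| >= %g, %s)\n",
              x$name, length(x$genes), x$provenance$max_fdr,
              x$provenance$min_abs_log2fc, x$provenance$direction))
  invisible(x)
}

#' Volcano table restricted to a gene list
#'
#' Rows ordered by descending |log2FC|; list members absent from the tested
#' features are reported in the \code{"missing"} attribute.
#'
#' @param records output of \code{\link{marker_features}}
#' @param gene_list character vector or \code{signature_set}
#' @return data.table restricted and reordered
#' @export
signature_volcano <- function(records, gene_list) {
  genes <- if (inherits(gene_list, "signature_set")) gene_list$genes
           else gene_list
  assert_that(length(genes) > 0, "gene list is empty")
  out <- records[records$feature %in% genes]
  out <- out[order(-abs(out$log2fc))]
  data.table::setattr(out, "missing", setdiff(genes, records$feature))
  out[]
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail inclusive: \eqn{p = P(X \ge k)} with
#' \eqn{X \sim Hypergeom(N, |A|, |B|)} and \eqn{k = |A \cap B|}.
#'
#' @param setA,setB character vectors
#' @param universe_size N, at least \code{max(|A|, |B|)}
#' @param universe optional explicit universe; both sets must be subsets
#' @return list(overlap = k, p = upper-tail p-value)
#' @export
hypergeom_overlap <- function(setA, setB, universe_size, universe = NULL) {
  setA <- unique(setA); setB <- unique(setB)
  if (!is.null(universe)) {
    assert_that(all(setA %in% universe) && all(setB %in% universe),
                "both sets must be subsets of the universe")
    universe_size <- length(unique(universe))
  }
  assert_that(length(setA) <= universe_size && length(setB) <= universe_size,
              "universe smaller than a set")
  k <- length(intersect(setA, setB))
  p <- phyper(k - 1, length(setA), universe_size - length(setA),
              length(setB), lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Trajectory-differential motif calling
#'
#' Cells are binned into pseudotime quantile bins; per motif the bin means
#' are smoothed with a centered moving average and the statistic is the
#' range (max - min) of the smoothed profile. Significance comes from a
#' permutation null that shuffles pseudotime across cells,
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (1 + n_{perm})}, with BH FDR across
#' motifs. A motif is called differential at \code{fdr <= max_fdr}.
#'
#' @param motif_z cell x motif matrix of deviation z-scores
#' @param trajectory a \code{trajectory_result}
#' @param n_bins pseudotime quantile bins (default 100)
#' @param window moving-average window in bins (default 11)
#' @param n_permutations permutations (default 200)
#' @param max_fdr differential threshold (default 0.05)
#' @param seed integer seed
#' @return data.table(motif, statistic, p, fdr, differential)
#' @export
trajectory_differential_motifs <- function(motif_z, trajectory, n_bins = 100,
                                           window = 11, n_permutations = 200,
                                           max_fdr = 0.05, seed = 1) {
  shared <- intersect(rownames(motif_z), trajectory$barcode)
  assert_that(length(shared) >= n_bins,
              "need at least n_bins cells shared with the trajectory")
  set.seed(seed)
  Z <- motif_z[shared, , drop = FALSE]
  pt <- trajectory$pseudotime[match(shared, trajectory$barcode)]
  bin_of <- function(ptv) {
    ceiling(rank(ptv, ties.method = "first") / length(ptv) * n_bins)
  }
  stat_for <- function(bins) {
    means <- rowsum(Z, bins) / as.integer(table(bins))
    apply(means, 2, function(col) {
      sm <- moving_average(col, window)
      max(sm) - min(sm)
    })
  }
  obs <- stat_for(bin_of(pt))
  exceed <- rep(0L, ncol(Z))
  for (i in seq_len(n_permutations)) {
    perm <- stat_for(bin_of(sample(pt)))
    exceed <- exceed + (perm >= obs)
  }
  p <- (1 + exceed) / (1 + n_permutations)
  p[obs == 0] <- 1  # constant profile carries no signal
  fdr <- p.adjust(p, "BH")
  data.table(motif = colnames(Z), statistic = obs, p = p, fdr = fdr,
             differential = fdr <= max_fdr)
}
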