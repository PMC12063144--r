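#' @import Matrix
#' @importFrom data.table data.table as.data.table fread fwrite setattr
#'   setkey setorder := .N .SD
#' @importFrom stats cor dist phyper p.adjust pnorm pwilcox quantile rbinom
#'   rlnorm rnorm runif sd var
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

#' Extract Tn5 insertion events from fragments
#'
#' Each fragment contributes two insertion events: one at its start and one
#' at its last covered base (end - 1, half-open convention). The duplicate
#' count column is intentionally ignored: fragments are deduplicated
#' evidence and every record counts once per end.
#'
#' @param fragments fragment data.table (chrom, start, end, barcode)
#' @return data.table with columns chrom, pos, barcode (two rows/fragment)
#' @keywords internal
fragment_insertions <- function(fragments) {
  data.table(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start, fragments$end - 1L),
    barcode = rep(fragments$barcode, 2L)
  )
}

#' Construct a cell-by-feature matrix
#'
#' Thin wrapper around a sparse \code{dgCMatrix} carrying the name of the
#' feature space (tile, gene, peak, motif or domain). Rows are cell
#' barcodes, columns feature identifiers; both must be unique.
#'
#' @param mat matrix-like object, rows = cells, cols = features
#' @param space one of "tile", "gene", "peak", "motif", "domain"
#' @return a \code{dgCMatrix} with attribute \code{feature_space}
#' @export
feature_matrix <- function(mat, space = c("tile", "gene", "peak", "motif",
                                          "domain")) {
  space <- match.arg(space)
  m <- methods::as(methods::as(methods::as(mat, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  assert_that(!is.null(rownames(m)) && !is.null(colnames(m)),
              "feature matrix needs row (barcode) and column (feature) names")
  assert_that(!anyDuplicated(rownames(m)), "duplicate barcodes in matrix")
  assert_that(!anyDuplicated(colnames(m)), "duplicate feature ids in matrix")
  assert_that(min(m@x %||% 0, 0) >= 0, "feature matrix must be nonnegative")
  attr(m, "feature_space") <- space
  m
}

#' @rdname feature_matrix
#' @param m a feature matrix
#' @export
feature_space <- function(m) attr(m, "feature_space")

## deterministic sign convention for SVD factors: the entry of largest
## magnitude in each left singular vector is made positive
fix_svd_signs <- function(u, v) {
  s <- vapply(seq_len(ncol(u)), function(j) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) -1 else 1
  }, numeric(1))
  list(u = sweep(u, 2, s, "*"), v = sweep(v, 2, s, "*"))
}

## moving average with edge truncation: mean over the part of the window
## that falls inside the vector, so every position is defined
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}
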