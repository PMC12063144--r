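## Readers and writers for every on-disk format the pipeline touches.
## Coordinates are 0-based half-open everywhere, matching the 10x
## fragments.tsv and BED dialects; nothing is shifted on read or write.

#' Read a chromosome-sizes table
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path file path
#' @return named integer vector of chromosome lengths
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "length"))
  assert_that(!anyDuplicated(dt$chrom), "duplicate chromosome names")
  assert_that(all(dt$length > 0), "chromosome lengths must be positive")
  stats::setNames(as.integer(dt$length), dt$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes named vector of chromosome lengths
#' @export
write_chrom_sizes <- function(sizes, path) {
  fwrite(data.table(chrom = names(sizes), length = as.integer(sizes)),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a 10x-style fragment file
#'
#' Tab-separated: chrom, start (0-based), end (half-open), barcode and an
#' optional duplicate count (defaults to 1). Lines starting with '#' are
#' skipped. Malformed lines (inverted or negative intervals, non-integer
#' coordinates, unknown chromosome when \code{chrom_sizes} is supplied) are
#' rejected individually and reported with their line numbers; the read
#' aborts when more than \code{max_bad} lines are rejected.
#'
#' @param path TSV path, optionally gzipped
#' @param chrom_sizes optional named vector of chromosome lengths
#' @param max_bad rejected-line tolerance before aborting (default 0)
#' @return data.table(chrom, start, end, barcode, count) in file order, with
#'   the rejection report in attribute \code{"bad_lines"}
#' @export
read_fragments <- function(path, chrom_sizes = NULL, max_bad = 0) {
  ## readLines via file() auto-detects gzip, so .tsv and .tsv.gz both work
  ## without external decompression helpers
  lines <- readLines(path)
  line_no <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  line_no <- line_no[keep]
  empty <- data.table(chrom = character(0), start = integer(0),
                      end = integer(0), barcode = character(0),
                      count = integer(0))
  if (!length(lines)) {
    setattr(empty, "bad_lines",
            data.table(line = integer(0), reason = character(0)))
    return(empty)
  }
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  assert_that(length(parts) >= 4, "fragment file needs at least 4 columns")

  chrom <- parts[[1]]
  start <- suppressWarnings(as.integer(parts[[2]]))
  end <- suppressWarnings(as.integer(parts[[3]]))
  barcode <- parts[[4]]
  count <- if (length(parts) >= 5) {
    cnt <- suppressWarnings(as.integer(parts[[5]]))
    cnt[is.na(parts[[5]]) | parts[[5]] == ""] <- 1L
    cnt
  } else rep(1L, length(lines))

  bad_reason <- rep(NA_character_, length(lines))
  bad_reason[is.na(barcode) | barcode == ""] <- "fewer than 4 fields"
  ok <- is.na(bad_reason)
  bad_reason[ok & (is.na(start) | is.na(end) | is.na(count))] <-
    "non-integer field"
  ok <- is.na(bad_reason)
  bad_reason[ok & (end <= start | start < 0)] <- "inverted or negative interval"
  ok <- is.na(bad_reason)
  if (!is.null(chrom_sizes)) {
    unknown <- ok & !(chrom %in% names(chrom_sizes))
    bad_reason[unknown] <- "unknown chromosome"
    ok <- is.na(bad_reason)
    over <- ok & end > chrom_sizes[chrom]
    over[is.na(over)] <- FALSE
    bad_reason[over] <- "interval beyond chromosome end"
    ok <- is.na(bad_reason)
  }

  bad <- data.table(line = line_no[!ok], reason = bad_reason[!ok])
  if (nrow(bad) > max_bad) {
    abort(sprintf(
      "%d malformed fragment line(s), first at line %d (%s); tolerance %d",
      nrow(bad), bad$line[1], bad$reason[1], max_bad))
  }
  out <- data.table(chrom = chrom[ok], start = start[ok], end = end[ok],
                    barcode = barcode[ok], count = count[ok])
  setattr(out, "bad_lines", bad)
  out
}

#' @rdname read_fragments
#' @param fragments fragment data.table
#' @export
write_fragments <- function(fragments, path) {
  fwrite(fragments[, c("chrom", "start", "end", "barcode", "count")],
         path, sep = "\t", col.names = FALSE,
         compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' Read/write BED interval files
#'
#' BED3/BED4, 0-based half-open, '#' comment lines permitted. Intervals are
#' returned sorted by (chrom, start) in byte order.
#'
#' @param path BED path
#' @return data.table(chrom, start, end[, name])
#' @export
read_intervals <- function(path) {
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE, quote = "")
  raw <- raw[!startsWith(as.character(raw[[1]]), "#")]
  dt <- data.table(chrom = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4) dt[, "name" := as.character(raw[[4]])]
  assert_that(!anyNA(dt$start) && !anyNA(dt$end), "non-integer BED coordinate")
  assert_that(all(dt$end > dt$start) && all(dt$start >= 0),
              "BED interval with end <= start or negative start")
  setorder(dt, chrom, start)  # data.table orders strings in C locale
  dt[]
}

#' @rdname read_intervals
#' @param intervals interval data.table
#' @export
write_intervals <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  fwrite(intervals[, cols, with = FALSE], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Read/write the flat gene-annotation table
#'
#' Columns: gene_id, symbol, chrom, strand (+/-), tss, body_start, body_end;
#' coordinates 0-based, body half-open, TSS within the body.
#'
#' @param path TSV path with header
#' @return data.table of gene annotations
#' @export
read_gene_annotation <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "symbol", "chrom", "strand", "tss", "body_start",
            "body_end")
  assert_that(all(need %in% names(dt)),
              paste("gene annotation must have columns:",
                    paste(need, collapse = ", ")))
  assert_that(all(dt$strand %in% c("+", "-")), "strand must be + or -")
  assert_that(all(dt$tss >= dt$body_start & dt$tss < dt$body_end),
              "TSS must lie within the gene body")
  assert_that(!anyDuplicated(dt$gene_id), "duplicate gene ids")
  dt[]
}

#' @rdname read_gene_annotation
#' @param genes gene annotation data.table
#' @export
write_gene_annotation <- function(genes, path) {
  fwrite(genes[, c("gene_id", "symbol", "chrom", "strand", "tss",
                   "body_start", "body_end")], path, sep = "\t")
  invisible(path)
}

#' Directed regulatory network
#'
#' A simple directed graph: unique node ids and parent -> child edges with
#' no duplicates; every edge endpoint must be a known node.
#'
#' @param edges data.table/data.frame with columns parent, child
#' @param nodes optional character vector of node ids; defaults to the set
#'   of edge endpoints
#' @return object of class \code{directed_network}
#' @export
directed_network <- function(edges, nodes = NULL) {
  edges <- data.table(parent = as.character(edges$parent),
                      child = as.character(edges$child))
  if (is.null(nodes)) nodes <- sort(unique(c(edges$parent, edges$child)))
  nodes <- as.character(nodes)
  assert_that(!anyDuplicated(nodes), "duplicate node ids")
  dangling <- setdiff(c(edges$parent, edges$child), nodes)
  if (length(dangling)) {
    abort(sprintf("edge endpoint(s) not in node list: %s",
                  paste(head(dangling, 5), collapse = ", ")))
  }
  assert_that(!anyDuplicated(edges, by = c("parent", "child")) &&
                !any(duplicated(paste(edges$parent, edges$child))),
              "duplicate edges: network must be a simple graph")
  structure(list(nodes = nodes, edges = edges), class = "directed_network")
}

#' @rdname directed_network
#' @param edge_path TSV edge list (header: parent, child)
#' @param node_path optional one-column node list
#' @export
read_network <- function(edge_path, node_path = NULL) {
  edges <- fread(edge_path, sep = "\t", header = TRUE)
  nodes <- if (!is.null(node_path)) fread(node_path, header = FALSE)[[1]]
  directed_network(edges, nodes)
}

#' @rdname directed_network
#' @param network a \code{directed_network}
#' @param path output TSV path (node list written to \code{path.nodes})
#' @export
write_network <- function(network, path) {
  fwrite(network$edges, path, sep = "\t")
  fwrite(data.table(node = network$nodes), paste0(path, ".nodes"),
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read/write a sparse feature matrix as MatrixMarket triplets
#'
#' The matrix body is MatrixMarket coordinate text; barcodes, feature ids
#' and the feature-space tag are written to \code{path.rows},
#' \code{path.cols} and \code{path.space} sidecars.
#'
#' @param m feature matrix (see \code{\link{feature_matrix}})
#' @param path output path for the triplet file
#' @export
write_matrix <- function(m, path) {
  Matrix::writeMM(m, path)
  writeLines(rownames(m), paste0(path, ".rows"))
  writeLines(colnames(m), paste0(path, ".cols"))
  writeLines(feature_space(m) %||% "tile", paste0(path, ".space"))
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  rows <- readLines(paste0(path, ".rows"))
  cols <- readLines(paste0(path, ".cols"))
  assert_that(!anyDuplicated(rows), "duplicate barcodes in matrix sidecar")
  assert_that(!anyDuplicated(cols), "duplicate feature ids in matrix sidecar")
  assert_that(nrow(m) == length(rows) && ncol(m) == length(cols),
              "matrix dimensions do not match id sidecars")
  dimnames(m) <- list(rows, cols)
  feature_matrix(m, readLines(paste0(path, ".space"))[1])
}

#' Read a gene-set list (one id per line, '#' comments allowed)
#' @param path text file
#' @return character vector of unique ids
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!startsWith(x, "#") & nzchar(x)])
  unique(x)
}
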