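## Projection of cluster signatures onto a directed regulatory network and
## hypergeometric key-driver calling.

network_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges,
                                vertices = network$nodes, directed = TRUE)
}

#' Project a signature onto a regulatory network
#'
#' The seed set is the intersection of the signature with the network
#' nodes; it is expanded by breadth-first search over edges treated as
#' undirected up to \code{layers} hops ("neighbouring nodes within two
#' layers" by default). Weakly connected components of the induced subgraph
#' with at least \code{min_component_size} nodes are reported, sorted by
#' size descending.
#'
#' @param network a \code{\link{directed_network}}
#' @param signature character vector or \code{signature_set}
#' @param layers undirected expansion hops (default 2; the figure-legend
#'   alternative is 1)
#' @param min_component_size smallest reported component (default 5)
#' @return \code{subnetwork_report}: list of components, each with nodes,
#'   edges, size and the signature nodes it contains
#' @export
project_signature <- function(network, signature, layers = 2,
                              min_component_size = 5) {
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else signature
  assert_that(length(network$nodes) > 0, "network is empty")
  seed <- intersect(genes, network$nodes)
  if (length(seed) == 0) {
    warning("no signature gene is present in the network")
    return(structure(list(components = list(), layers = layers,
                          seed = character(0)),
                     class = "subnetwork_report"))
  }
  g <- network_igraph(network)
  gu <- igraph::as_undirected(g, mode = "collapse")
  reach <- igraph::ego(gu, order = layers, nodes = seed)
  members <- unique(unlist(lapply(reach, names)))
  sub <- igraph::induced_subgraph(g, members)
  comp <- igraph::components(sub, mode = "weak")
  comps <- lapply(seq_len(comp$no), function(i) {
    nodes <- names(comp$membership)[comp$membership == i]
    sg <- igraph::induced_subgraph(sub, nodes)
    el <- igraph::as_data_frame(sg, "edges")
    list(nodes = sort(nodes), size = length(nodes),
         edges = data.table(parent = el$from, child = el$to),
         signature_nodes = sort(intersect(nodes, seed)))
  })
  comps <- comps[vapply(comps, `[[`, numeric(1), "size") >=
                   min_component_size]
  comps <- comps[order(-vapply(comps, `[[`, numeric(1), "size"))]
  structure(list(components = comps, layers = layers, seed = seed),
            class = "subnetwork_report")
}

#' @export
print.subnetwork_report <- function(x, ...) {
  cat(sprintf("subnetwork_report: %d component(s) at %d layer(s); sizes: %s\n",
              length(x$components), x$layers,
              paste(vapply(x$components, `[[`, numeric(1), "size"),
                    collapse = ", ")))
  invisible(x)
}

#' Key-driver analysis by downstream hypergeometric enrichment
#'
#' For each candidate node v, the downstream set D is everything reachable
#' from v along directed edges within \code{h} hops (excluding v). The
#' overlap of D with the signature is tested against
#' \eqn{X \sim Hypergeom(N, |signature \cap nodes|, |D|)} (upper tail,
#' inclusive), BH-adjusted across candidates. A node is a key driver when
#' \code{fdr <= max_fdr} and \code{|D| >= min_downstream}.
#'
#' @param network a \code{\link{directed_network}}
#' @param signature character vector or \code{signature_set}
#' @param candidates candidate nodes (default: all network nodes)
#' @param h directed reachability horizon (default 2, >= 1)
#' @param universe_size hypergeometric universe (default: number of network
#'   nodes; the full assayed-gene count can be supplied instead)
#' @param max_fdr driver FDR threshold (default 0.05)
#' @param min_downstream minimum downstream size (default 5)
#' @return data.table(node, n_downstream, overlap, p, fdr, is_key_driver)
#' @export
key_drivers <- function(network, signature, candidates = network$nodes,
                        h = 2, universe_size = length(network$nodes),
                        max_fdr = 0.05, min_downstream = 5) {
  assert_that(h >= 1, "h must be >= 1")
  assert_that(all(candidates %in% network$nodes),
              "candidates must be network nodes")
  genes <- if (inherits(signature, "signature_set")) signature$genes
           else signature
  sig <- intersect(genes, network$nodes)
  g <- network_igraph(network)
  reach <- igraph::ego(g, order = h, nodes = candidates, mode = "out",
                       mindist = 1)
  n_down <- lengths(reach)
  overlap <- vapply(reach, function(r) length(intersect(names(r), sig)),
                    integer(1))
  p <- phyper(overlap - 1, length(sig), universe_size - length(sig),
              n_down, lower.tail = FALSE)
  fdr <- p.adjust(p, "BH")
  data.table(node = candidates, n_downstream = n_down, overlap = overlap,
             p = p, fdr = fdr,
             is_key_driver = fdr <= max_fdr & n_down >= min_downstream)
}
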