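# Shared fixtures: small planted simulations and hand-rolled oracles used
# across the suite. Everything is generated in code at test time.

# small three-population experiment (same structure as the default study
# conditions, scaled down for unit tests). The scaled-down genome saturates
# binarized tiles more easily than the full-size default, so the planted
# fold is raised to keep the populations separable (ARI ~ 1 at 60 cells per
# population) -- a fixture must exhibit the phenomenon it is used to test.
small_sim_config <- function(seed = 1, n_cells = 80, n_doublets = 10,
                             depletion = 0.2) {
  sim_config(
    populations = list(
      population_spec("baseline", n_cells, marker_fold = 8,
                      n_marker_genes = 40),
      population_spec("alveolar", n_cells, marker_fold = 8,
                      n_marker_genes = 40, motif = "MOTIF_A",
                      motif_multiplier = 3),
      population_spec("repressed", n_cells, marker_fold = 8,
                      n_marker_genes = 40, domain_depletion = depletion)),
    n_doublets = n_doublets,
    genome = c(chr1 = 2e6, chr2 = 2e6),
    n_peaks = 1200, n_domains = 4, domain_width = 5e4,
    depth_log_mean = log(800), seed = seed)
}

sim_truth_labels <- function(sim) unlist(sim$ground_truth$labels)

# adjusted Rand index from a contingency table (closed form; independent of
# any clustering code in the package)
ari_from_table <- function(tab) {
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- b * cc / choose(n, 2)
  (a - e) / ((b + cc) / 2 - e)
}

# rank-based AUC for "values of x tend to exceed values of y"
rank_auc <- function(x, y) {
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}

# brute-force BFS oracle over an edge list (independent of igraph)
bfs_oracle <- function(edges, start, layers, directed = FALSE) {
  adj <- list()
  addedge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
  }
  for (i in seq_len(nrow(edges))) {
    addedge(edges$parent[i], edges$child[i])
    if (!directed) addedge(edges$child[i], edges$parent[i])
  }
  frontier <- start
  seen <- start
  for (l in seq_len(layers)) {
    nxt <- unique(unlist(adj[frontier]))
    frontier <- setdiff(nxt, seen)
    if (length(frontier) == 0) break
    seen <- union(seen, frontier)
  }
  sort(seen)
}

# exhaustive hypergeometric upper-tail oracle: enumerate all C(N, nB) draws
hypergeom_enum_oracle <- function(N, nA, nB, k) {
  draws <- utils::combn(N, nB)
  a_set <- seq_len(nA)
  overlaps <- apply(draws, 2, function(d) length(intersect(d, a_set)))
  mean(overlaps >= k)
}

# recount oracle: fraction of fragment midpoints inside domain intervals,
# computed directly from the emitted fragment table
in_domain_fraction <- function(fragments, domains, barcodes) {
  mids <- (fragments$start + fragments$end) / 2
  indom <- rep(FALSE, nrow(fragments))
  for (i in seq_len(nrow(domains))) {
    indom <- indom | (fragments$chrom == domains$chrom[i] &
                        mids >= domains$start[i] & mids < domains$end[i])
  }
  tapply(indom, fragments$barcode, mean)[barcodes]
}
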