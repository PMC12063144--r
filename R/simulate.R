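## Synthetic scATAC-seq experiment generator with planted, recorded ground
## truth. Emulates the contrasts the downstream stages must detect: cell
## populations that differ in accessibility at planted marker genes, in
## fragment depletion inside repressive ChIP-seq broad domains, and in
## motif-biased peak usage — plus lognormal per-cell depth, TSS pileup and
## pooled-pair doublets.

#' Describe one simulated cell population
#'
#' @param name unique population label
#' @param n_cells number of singlet cells (>= 1)
#' @param marker_fold accessibility multiplier applied to this population's
#'   planted marker-gene peaks (>= 1; 1 = no markers)
#' @param n_marker_genes number of marker genes planted for this population
#' @param domain_depletion multiplier in (0, 1] on the fragment rate inside
#'   repressive domains (1 = no depletion; lower = more repressed)
#' @param motif optional motif id whose peaks this population favours
#' @param motif_multiplier weight multiplier on peaks carrying \code{motif}
#' @param peak_weight_multipliers named numeric multipliers per peak class
#'   (classes: tss, marker, shared, motif)
#' @return a \code{population_spec} list
#' @export
population_spec <- function(name, n_cells, marker_fold = 1,
                            n_marker_genes = 0, domain_depletion = 1,
                            motif = NULL, motif_multiplier = 1,
                            peak_weight_multipliers = numeric()) {
  assert_that(n_cells >= 1, "n_cells must be >= 1")
  assert_that(domain_depletion > 0 && domain_depletion <= 1,
              "domain_depletion must be in (0, 1]")
  assert_that(marker_fold > 0 && motif_multiplier > 0,
              "multipliers must be > 0")
  structure(list(name = name, n_cells = as.integer(n_cells),
                 marker_fold = marker_fold,
                 n_marker_genes = as.integer(n_marker_genes),
                 domain_depletion = domain_depletion, motif = motif,
                 motif_multiplier = motif_multiplier,
                 peak_weight_multipliers = peak_weight_multipliers),
            class = "population_spec")
}

#' Simulation configuration
#'
#' The defaults define the study conditions used throughout the package's
#' tests and analyses: three populations of 300 cells — a baseline
#' (untreated-like) population, an alveolar-like population with planted
#' marker genes and a motif bias, and a repressed population whose fragment
#' rate inside repressive domains is depleted to 0.2 of background.
#'
#' @param populations list of \code{\link{population_spec}}s
#' @param n_doublets number of pooled-pair doublet barcodes to add
#' @param genome named vector of chromosome lengths (bp)
#' @param tile_size genome tile width (bp)
#' @param n_peaks number of non-overlapping peaks across the genome
#' @param peak_width peak width (bp)
#' @param n_domains number of repressive broad domains
#' @param domain_width repressive-domain width (bp)
#' @param tss_fraction fraction of fragments placed at TSS-proximal peaks
#' @param background_fraction fraction of fragments placed uniformly outside
#'   peaks
#' @param depth_log_mean,depth_log_sd lognormal per-cell fragment-count
#'   parameters
#' @param fragment_length_mixture list(means, sds, weights) of the fragment
#'   length mixture (bp; clipped at 20)
#' @param seed integer seed; all outputs are pure functions of (config, seed)
#' @return a \code{sim_config} list
#' @export
sim_config <- function(populations = default_populations(),
                       n_doublets = 30,
                       genome = c(chr1 = 5e6, chr2 = 5e6),
                       tile_size = 500,
                       n_peaks = 2000, peak_width = 300,
                       n_domains = 8, domain_width = 100000,
                       tss_fraction = 0.45, background_fraction = 0.25,
                       depth_log_mean = log(1500), depth_log_sd = 0.4,
                       fragment_length_mixture = list(
                         means = c(80, 200), sds = c(20, 30),
                         weights = c(0.6, 0.4)),
                       seed = 1) {
  assert_that(length(populations) > 0, "at least one population is required")
  nm <- vapply(populations, `[[`, character(1), "name")
  assert_that(!anyDuplicated(nm), "population names must be unique")
  assert_that(tile_size > 0, "tile_size must be > 0")
  assert_that(all(genome >= peak_width),
              "every chromosome must be at least peak_width long")
  assert_that(tss_fraction >= 0 && tss_fraction <= 1 &&
                background_fraction >= 0 && background_fraction <= 1 &&
                tss_fraction + background_fraction <= 1,
              "fractions must be in [0,1] and sum to at most 1")
  structure(list(populations = populations, n_doublets = as.integer(n_doublets),
                 genome = genome, tile_size = as.integer(tile_size),
                 n_peaks = as.integer(n_peaks),
                 peak_width = as.integer(peak_width),
                 n_domains = as.integer(n_domains),
                 domain_width = as.integer(domain_width),
                 tss_fraction = tss_fraction,
                 background_fraction = background_fraction,
                 depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
                 fragment_length_mixture = fragment_length_mixture,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_populations <- function() {
  list(
    population_spec("baseline", 300, marker_fold = 4, n_marker_genes = 40),
    population_spec("alveolar", 300, marker_fold = 4, n_marker_genes = 40,
                    motif = "MOTIF_A", motif_multiplier = 3),
    population_spec("repressed", 300, marker_fold = 4, n_marker_genes = 40,
                    domain_depletion = 0.2)
  )
}

## Place n non-overlapping windows of width w on the genome, avoiding the
## intervals in `avoid` (data.table chrom/start/end). Grid + jitter keeps
## placement trivially collision-free.
place_windows <- function(genome, n, w, avoid = NULL) {
  per_chrom <- diff(round(seq(0, n, length.out = length(genome) + 1)))
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    k <- per_chrom[i]
    if (k == 0) next
    len <- genome[i]
    slot <- floor(len / k)
    assert_that(slot >= w, "chromosome too short for requested windows")
    jitter <- floor(runif(k, 0, slot - w))
    start <- as.integer((seq_len(k) - 1) * slot + jitter)
    dt <- data.table(chrom = names(genome)[i], start = start,
                     end = as.integer(start + w))
    if (!is.null(avoid)) {
      av <- avoid[avoid$chrom == names(genome)[i]]
      if (nrow(av)) {
        bad <- vapply(seq_len(nrow(dt)), function(j) {
          any(dt$start[j] < av$end & dt$end[j] > av$start)
        }, logical(1))
        dt <- dt[!bad]
      }
    }
    out[[i]] <- dt
  }
  data.table::rbindlist(out)
}

draw_fragment_lengths <- function(n, mix) {
  comp <- sample.int(length(mix$weights), n, replace = TRUE,
                     prob = mix$weights)
  len <- round(rnorm(n, mix$means[comp], mix$sds[comp]))
  pmax(len, 20L)
}

#' Simulate a single-cell accessibility experiment
#'
#' Generates a sorted fragment table, gene annotation, peak/domain/motif
#' BED-style interval tables and the planted ground truth. Peaks are
#' partitioned round-robin into classes (TSS-proximal, marker, shared,
#' motif-bearing); each TSS-proximal and marker peak hosts a gene whose TSS
#' is the peak centre. Marker peaks are assigned round-robin to populations
#' with \code{n_marker_genes > 0} and up-weighted by \code{marker_fold} for
#' that population. Repressive domains never overlap peaks, so depletion
#' acts on background fragments only; a fragment landing in a domain is
#' kept with probability \code{domain_depletion} and redrawn otherwise, so
#' each cell's emitted fragment count equals its drawn depth exactly.
#' Doublets pool half the fragments of two random singlets from distinct
#' populations under a new barcode.
#'
#' @param config a \code{\link{sim_config}}
#' @param out_dir optional directory; when given, all artifacts are written
#'   (fragments.tsv.gz, genes.tsv, peaks.bed, domains.bed, motifs.bed,
#'   chrom_sizes.tsv, ground_truth.json)
#' @return list(fragments, genes, peaks, domains, motif_hits, chrom_sizes,
#'   ground_truth); ground_truth maps barcodes to populations and records
#'   doublets, planted markers, motifs and depletion factors
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  genome <- config$genome
  pops <- config$populations
  npop <- length(pops)

  ## --- genome layout: domains first, peaks outside domains -------------
  domains <- place_windows(genome, config$n_domains, config$domain_width)
  domains[, "name" := sprintf("DOM%03d", seq_len(.N))]
  peaks <- place_windows(genome, config$n_peaks, config$peak_width,
                         avoid = domains)
  classes <- c("tss", "marker", "shared", "motif")
  peaks[, "class" := rep_len(classes, nrow(peaks))]
  peaks[, "name" := sprintf("PEAK%04d", seq_len(.N))]

  ## marker peaks round-robin over populations that plant markers
  marker_pops <- which(vapply(pops, function(p) p$n_marker_genes > 0,
                              logical(1)))
  peaks[, "marker_pop" := NA_character_]
  if (length(marker_pops)) {
    idx <- which(peaks$class == "marker")
    owner <- rep_len(marker_pops, length(idx))
    peaks$marker_pop[idx] <- vapply(owner, function(i) pops[[i]]$name,
                                    character(1))
    ## cap each population at its n_marker_genes
    for (i in marker_pops) {
      mine <- which(peaks$marker_pop == pops[[i]]$name)
      if (length(mine) > pops[[i]]$n_marker_genes) {
        drop <- mine[-seq_len(pops[[i]]$n_marker_genes)]
        peaks$marker_pop[drop] <- NA_character_
      }
    }
    peaks$class[peaks$class == "marker" & is.na(peaks$marker_pop)] <- "shared"
  } else {
    peaks$class[peaks$class == "marker"] <- "shared"
  }

  ## motifs: MOTIF_A on odd motif-class peaks, MOTIF_B on even (neutral)
  midx <- which(peaks$class == "motif")
  motif_id <- rep(c("MOTIF_A", "MOTIF_B"), length.out = length(midx))
  motif_hits <- data.table(chrom = peaks$chrom[midx],
                           start = peaks$start[midx],
                           end = peaks$end[midx], name = motif_id)
  setorder(motif_hits, chrom, start)

  ## genes on tss-class and marker-class peaks; TSS = peak centre
  gidx <- which(peaks$class %in% c("tss", "marker"))
  tss <- as.integer((peaks$start[gidx] + peaks$end[gidx]) %/% 2)
  strand <- rep_len(c("+", "-"), length(gidx))
  body_start <- ifelse(strand == "+", tss, pmax(0L, tss - 2000L))
  body_end <- ifelse(strand == "+",
                     pmin(genome[peaks$chrom[gidx]], tss + 2000L), tss + 1L)
  genes <- data.table(
    gene_id = sprintf("GENE%04d", seq_along(gidx)),
    symbol = sprintf("Gene%04d", seq_along(gidx)),
    chrom = peaks$chrom[gidx], strand = strand, tss = tss,
    body_start = as.integer(body_start), body_end = as.integer(body_end))
  peaks[, "gene_id" := NA_character_]
  peaks$gene_id[gidx] <- genes$gene_id
  marker_genes <- lapply(pops, function(p) {
    genes$gene_id[match(peaks$name[which(!is.na(peaks$marker_pop) &
                                           peaks$marker_pop == p$name)],
                        peaks$name[gidx])]
  })
  names(marker_genes) <- vapply(pops, `[[`, character(1), "name")

  ## --- per-population peak weights -------------------------------------
  peak_weights <- function(p) {
    w <- rep(1, nrow(peaks))
    for (cls in names(p$peak_weight_multipliers)) {
      w[peaks$class == cls] <- w[peaks$class == cls] *
        p$peak_weight_multipliers[[cls]]
    }
    if (!is.null(p$motif)) {
      hit <- peaks$name %in% peaks$name[midx][motif_id == p$motif]
      w[hit] <- w[hit] * p$motif_multiplier
    }
    mine <- !is.na(peaks$marker_pop) & peaks$marker_pop == p$name
    w[mine] <- w[mine] * p$marker_fold
    w
  }

  ## --- fragment generation ---------------------------------------------
  chrom_cum <- c(0, cumsum(as.numeric(genome)))
  gen_fragments <- function(n, pop) {
    w <- peak_weights(pop)
    is_tss_peak <- peaks$class %in% c("tss", "marker")
    draw <- function(m) {
      u <- runif(m)
      cat_bg <- u < config$background_fraction
      cat_tss <- !cat_bg & u < config$background_fraction + config$tss_fraction
      chrom <- character(m); center <- numeric(m)
      ## background: uniform over the genome (depletion applied below)
      nbg <- sum(cat_bg)
      if (nbg) {
        g <- sample.int(length(genome), nbg, replace = TRUE,
                        prob = as.numeric(genome))
        chrom[cat_bg] <- names(genome)[g]
        center[cat_bg] <- floor(runif(nbg, 0, genome[g]))
      }
      ## TSS-proximal peaks (incl. marker peaks, so markers show at genes)
      nts <- sum(cat_tss)
      if (nts) {
        pk <- sample(which(is_tss_peak), nts, replace = TRUE,
                     prob = w[is_tss_peak])
        chrom[cat_tss] <- peaks$chrom[pk]
        center[cat_tss] <- peaks$start[pk] +
          floor(runif(nts, 0, config$peak_width))
      }
      ## remaining peaks (shared + motif classes)
      rest <- !cat_bg & !cat_tss
      nr <- sum(rest)
      if (nr) {
        pool <- which(!is_tss_peak)
        pk <- sample(pool, nr, replace = TRUE, prob = w[pool])
        chrom[rest] <- peaks$chrom[pk]
        center[rest] <- peaks$start[pk] +
          floor(runif(nr, 0, config$peak_width))
      }
      len <- draw_fragment_lengths(m, config$fragment_length_mixture)
      start <- pmax(0L, as.integer(floor(center - len / 2)))
      end <- pmin(as.integer(genome[chrom]), as.integer(start + len))
      start <- pmin(start, end - 1L)
      data.table(chrom = chrom, start = start, end = end)
    }
    frags <- draw(n)
    ## rejection-resample fragments inside repressive domains so that the
    ## in-domain rate is depleted while the total per cell stays exact
    if (pop$domain_depletion < 1) {
      repeat {
        mid <- (frags$start + frags$end) / 2
        in_dom <- in_intervals(frags$chrom, mid, domains)
        reject <- in_dom & runif(nrow(frags)) > pop$domain_depletion
        if (!any(reject)) break
        frags[reject, c("chrom", "start", "end") := draw(sum(reject))]
      }
    }
    frags
  }

  all_frags <- vector("list", npop)
  labels <- character(0)
  depths <- integer(0)
  cell_id <- 0L
  for (i in seq_len(npop)) {
    p <- pops[[i]]
    depth <- pmax(50L, as.integer(round(rlnorm(p$n_cells,
                                               config$depth_log_mean,
                                               config$depth_log_sd))))
    fr <- gen_fragments(sum(depth), p)
    bc <- sprintf("BC%05d", cell_id + seq_len(p$n_cells))
    cell_id <- cell_id + p$n_cells
    fr[, "barcode" := rep(bc, depth)]
    all_frags[[i]] <- fr
    labels <- c(labels, stats::setNames(rep(p$name, p$n_cells), bc))
    depths <- c(depths, stats::setNames(depth, bc))
  }
  frags <- data.table::rbindlist(all_frags)

  ## doublets: pooled pair from distinct populations at half depth each
  doublet_bc <- character(0)
  if (config$n_doublets > 0 && npop >= 2) {
    singlets <- names(labels)
    doublet_bc <- sprintf("DBLT%04d", seq_len(config$n_doublets))
    dbl <- vector("list", config$n_doublets)
    for (d in seq_len(config$n_doublets)) {
      repeat {
        pair <- sample(singlets, 2)
        if (labels[pair[1]] != labels[pair[2]]) break
      }
      half <- lapply(pair, function(b) {
        f <- frags[frags$barcode == b]
        f[sample.int(nrow(f), floor(nrow(f) / 2))]
      })
      dd <- data.table::rbindlist(half)
      dd[, "barcode" := doublet_bc[d]]
      dbl[[d]] <- dd
    }
    frags <- data.table::rbindlist(c(list(frags), dbl))
  }

  frags[, "count" := 1L]
  setorder(frags, chrom, start, end, barcode)
  peaks_out <- peaks[, c("chrom", "start", "end", "name", "class",
                         "marker_pop", "gene_id")]
  setorder(peaks_out, chrom, start)
  setorder(domains, chrom, start)

  truth <- list(
    labels = as.list(labels),
    doublets = doublet_bc,
    marker_genes = marker_genes,
    motifs = stats::setNames(lapply(pops, `[[`, "motif"), names(marker_genes)),
    domain_depletion = stats::setNames(
      vapply(pops, `[[`, numeric(1), "domain_depletion"), names(marker_genes)),
    depths = as.list(depths)
  )

  result <- list(fragments = frags[], genes = genes, peaks = peaks_out,
                 domains = domains[], motif_hits = motif_hits,
                 chrom_sizes = genome, ground_truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fragments(frags, file.path(out_dir, "fragments.tsv.gz"))
    write_gene_annotation(genes, file.path(out_dir, "genes.tsv"))
    write_intervals(peaks_out, file.path(out_dir, "peaks.bed"))
    write_intervals(domains, file.path(out_dir, "domains.bed"))
    write_intervals(motif_hits, file.path(out_dir, "motifs.bed"))
    write_chrom_sizes(genome, file.path(out_dir, "chrom_sizes.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    ## peak metadata beyond BED4 (class/ownership) for downstream tests
    fwrite(peaks_out, file.path(out_dir, "peaks_annotated.tsv"), sep = "\t")
  }
  result
}

## membership test: is position p on chrom inside any interval?
in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch]
    sel <- chrom == ch
    if (!any(sel)) next
    ir <- IRanges::IRanges(iv$start + 1L, iv$end)
    q <- IRanges::IRanges(as.integer(floor(pos[sel])) + 1L, width = 1L)
    out[sel] <- IRanges::overlapsAny(q, ir)
  }
  out
}

#' Simulate a directed regulatory network with planted key drivers
#'
#' Planted drivers each point at \code{children_per_driver} distinct
#' signature nodes; the remaining edges follow preferential attachment on
#' in-degree. The ambient attachment process is independent of the planted
#' structure: attachment in-degree starts at zero (planted driver edges do
#' not give signature children a head start that would otherwise
#' concentrate ambient edges on them and create genuine secondary
#' regulators), and attachment edges never target a planted driver (drivers
#' are upstream roots). With \code{n_drivers = 0} the signature is drawn at
#' random (\code{children_per_driver} nodes) and no enrichment is planted.
#'
#' @param n_nodes number of nodes
#' @param n_drivers number of planted key drivers
#' @param children_per_driver signature children per driver
#' @param attachment_parameter additive smoothing on in-degree for
#'   preferential attachment (> 0)
#' @param n_extra_edges number of preferential-attachment edges (default
#'   \code{n_nodes}, i.e. ambient mean out-degree 1)
#' @param seed integer seed
#' @return list(network = directed_network, signature = character,
#'   drivers = character)
#' @export
simulate_network <- function(n_nodes, n_drivers, children_per_driver,
                             attachment_parameter = 1,
                             n_extra_edges = n_nodes, seed = 1) {
  assert_that(n_drivers * children_per_driver < n_nodes,
              "n_drivers * children_per_driver must be < n_nodes")
  assert_that(attachment_parameter > 0, "attachment_parameter must be > 0")
  set.seed(seed)
  nodes <- sprintf("g%03d", seq_len(n_nodes))
  drivers <- if (n_drivers > 0) sample(nodes, n_drivers) else character(0)
  pool <- setdiff(nodes, drivers)
  if (n_drivers > 0) {
    children <- sample(pool, n_drivers * children_per_driver)
    signature <- children
    edges <- data.table(
      parent = rep(drivers, each = children_per_driver),
      child = children)
  } else {
    signature <- sample(pool, children_per_driver)
    edges <- data.table(parent = character(0), child = character(0))
  }
  ## preferential attachment on ambient in-degree only (planted edges do
  ## not seed the process), never into a driver
  indeg <- stats::setNames(rep(0, n_nodes), nodes)
  seen <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(edges))) {
    assign(paste(edges$parent[e], edges$child[e]), TRUE, envir = seen)
  }
  add <- vector("list", n_extra_edges)
  n_added <- 0L
  attempts <- 0L
  while (n_added < n_extra_edges && attempts < 50 * n_extra_edges) {
    attempts <- attempts + 1L
    src <- sample(nodes, 1)
    tgt <- sample(pool, 1, prob = indeg[pool] + attachment_parameter)
    key <- paste(src, tgt)
    if (src == tgt || exists(key, envir = seen)) next
    assign(key, TRUE, envir = seen)
    n_added <- n_added + 1L
    add[[n_added]] <- data.table(parent = src, child = tgt)
    indeg[tgt] <- indeg[tgt] + 1
  }
  edges <- data.table::rbindlist(c(list(edges), add[seq_len(n_added)]))
  list(network = directed_network(edges, nodes),
       signature = signature, drivers = drivers)
}
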