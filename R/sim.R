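#' Configuration for the synthetic three-population study
#'
#' Defines the simulated study: drift-differentiated allele frequencies for
#' three populations descended from a common ancestor, founder-mosaic
#' haplotypes with tunable linkage disequilibrium, selective sweeps planted
#' at chosen genes in one population, and a scale-free interaction network
#' in which sweep targets form network-adjacent clusters.
#'
#' Defaults give pairwise differentiation comparable to human continental
#' populations (drift parameter F = 0.05 per population, pairwise FST about
#' 2F/(1+F) = 0.095) and sample sizes of 200 haplotypes per population.
#'
#' @param n_genes number of genes.
#' @param genes_per_chrom genes placed per chromosome (non-overlapping,
#'   fixed spacing).
#' @param snps_per_gene SNPs per gene span.
#' @param snp_spacing_bp spacing between consecutive SNPs within a gene, bp.
#' @param flank_bp intergenic gap between consecutive gene spans, bp.
#' @param populations labels of the three populations.
#' @param n_haplotypes haplotypes per population (recycled to length 3).
#' @param drift_f per-population drift parameter F in (0,1) of the
#'   Balding-Nichols Beta model (recycled to length 3).
#' @param founders_k number of founder haplotypes per population (K >= 1;
#'   K = 1 is the degenerate case where all haplotypes are identical).
#' @param switch_rate founder switch rate per bp of the recombination
#'   mosaic.
#' @param match_freq flip a minimal number of random alleles per SNP so the
#'   realized sample frequency matches the drawn population frequency
#'   (skipped when `founders_k == 1` so the degenerate case stays exact).
#' @param sweep_gene_ids explicit gene ids to sweep, or NULL to plant
#'   network-adjacent clusters (see `n_sweep_genes`).
#' @param n_sweep_genes number of swept genes chosen as seed nodes plus
#'   their network neighborhoods; 0 for a null (no-sweep) study.
#' @param cluster_radius neighborhood radius (in network steps) around each
#'   planted seed.
#' @param sweep_population population receiving the sweeps.
#' @param sweep_beta final derived-allele frequency of the sweep, in (0,1].
#' @param neighbor_beta final derived-allele frequency of the partial
#'   sweeps planted at the one-step network neighbors of swept genes
#'   (parallel pathway selection); 0 disables them.
#' @param network_m edges added per node by preferential attachment.
#' @param coselection_sd strength (SD on the log scale) of the
#'   network-autocorrelated drift field that emulates pathway-level
#'   coselection: each gene's drift parameter is scaled by exp(u), where u
#'   is a Gaussian field smoothed over network neighbors, so
#'   network-adjacent genes share correlated divergence rates.  Applied
#'   only when coselection is planted (sweeps present); 0 disables it.
#' @param seed integer seed; every stochastic stage derives its stream
#'   from it.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_genes = 1000, genes_per_chrom = 100,
                       snps_per_gene = 150, snp_spacing_bp = 200,
                       flank_bp = 20000,
                       populations = c("EAS", "CEU", "YRI"),
                       n_haplotypes = 200, drift_f = 0.05,
                       founders_k = 8, switch_rate = 1e-5,
                       match_freq = TRUE,
                       sweep_gene_ids = NULL, n_sweep_genes = 20,
                       cluster_radius = 1,
                       sweep_population = "EAS", sweep_beta = 0.9,
                       neighbor_beta = 0.35,
                       network_m = 3, coselection_sd = 0.6, seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    genes_per_chrom = as.integer(genes_per_chrom),
    snps_per_gene = as.integer(snps_per_gene),
    snp_spacing_bp = as.integer(snp_spacing_bp),
    flank_bp = as.integer(flank_bp),
    populations = as.character(populations),
    n_haplotypes = rep_len(as.integer(n_haplotypes), length(populations)),
    drift_f = rep_len(as.numeric(drift_f), length(populations)),
    founders_k = as.integer(founders_k),
    switch_rate = as.numeric(switch_rate),
    match_freq = isTRUE(match_freq),
    sweep_gene_ids = sweep_gene_ids,
    n_sweep_genes = as.integer(n_sweep_genes),
    cluster_radius = as.integer(cluster_radius),
    sweep_population = as.character(sweep_population),
    sweep_beta = as.numeric(sweep_beta),
    neighbor_beta = as.numeric(neighbor_beta),
    network_m = as.integer(network_m),
    coselection_sd = as.numeric(coselection_sd),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_genes > 0, genes_per_chrom > 0, snps_per_gene > 0,
              snp_spacing_bp > 0, flank_bp > 0,
              length(populations) == 3, !anyDuplicated(populations),
              all(n_haplotypes >= 2),
              all(drift_f > 0), all(drift_f < 1),
              founders_k >= 1, switch_rate >= 0,
              sweep_beta > 0, sweep_beta <= 1,
              neighbor_beta >= 0, neighbor_beta <= 1,
              network_m >= 1, cluster_radius >= 0, n_sweep_genes >= 0,
              coselection_sd >= 0,
              sweep_population %in% populations)
  })
  if (!is.null(cfg$sweep_gene_ids)) {
    ids <- gene_layout(cfg)$genes$gene
    if (!all(cfg$sweep_gene_ids %in% ids)) {
      stop("sweep_gene_ids must be a subset of the simulated gene set")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Gene and SNP layout implied by a configuration
#'
#' One gene is one SNP block with flanks: genes are placed non-overlapping
#' at fixed spacing along chromosomes, so gene midpoints are well defined.
#'
#' @param config a `sim_config`.
#' @return list with `genes` (gene, chrom, start, end, midpoint) and `snps`
#'   (chrom, pos, gene) data frames.
#' @export
gene_layout <- function(config) {
  n <- config$n_genes
  gene <- sprintf("G%04d", seq_len(n))
  chrom <- as.character((seq_len(n) - 1L) %/% config$genes_per_chrom + 1L)
  idx_on_chrom <- (seq_len(n) - 1L) %% config$genes_per_chrom
  span <- (config$snps_per_gene - 1L) * config$snp_spacing_bp
  start <- config$flank_bp + idx_on_chrom * (span + config$flank_bp) + 1
  end <- start + span
  genes <- data.frame(gene = gene, chrom = chrom, start = start, end = end,
                      midpoint = (start + end) / 2,
                      stringsAsFactors = FALSE)
  snps <- data.frame(
    chrom = rep(chrom, each = config$snps_per_gene),
    pos = rep(start, each = config$snps_per_gene) +
      rep(seq_len(config$snps_per_gene) - 1L, n) * config$snp_spacing_bp,
    gene = rep(gene, each = config$snps_per_gene),
    stringsAsFactors = FALSE
  )
  list(genes = genes, snps = snps)
}

#' Draw ancestral and population allele frequencies
#'
#' Balding-Nichols drift: the ancestral frequency p0 of each SNP is
#' Uniform(0.05, 0.95); each population's frequency is an independent
#' Beta(p0(1-F)/F, (1-p0)(1-F)/F) draw, so two populations with the same F
#' show pairwise differentiation of roughly 2F/(1+F).
#'
#' @param config a `sim_config`.
#' @param seed seed for this stage (default derived from the config seed).
#' @param f_scale optional per-gene multiplier of the drift parameter
#'   (named by gene id), used to impose a coselection field on divergence
#'   rates; the scaled F is clamped to (0, 0.8].
#' @return list with the layout, `p0`, and a SNP x population frequency
#'   matrix `freq`.
#' @export
simulate_frequencies <- function(config, seed = config$seed,
                                 f_scale = NULL) {
  layout <- gene_layout(config)
  set.seed(seed)
  S <- nrow(layout$snps)
  p0 <- runif(S, 0.05, 0.95)
  scale_snp <- if (is.null(f_scale)) {
    rep(1, S)
  } else {
    unname(f_scale[layout$snps$gene])
  }
  freq <- matrix(NA_real_, S, length(config$populations),
                 dimnames = list(NULL, config$populations))
  for (k in seq_along(config$populations)) {
    f <- pmin(config$drift_f[k] * scale_snp, 0.8)
    freq[, k] <- rbeta(S, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }
  list(layout = layout, p0 = p0, freq = freq)
}

#' Build founder-mosaic haplotype panels matching target frequencies
#'
#' Haplotypes are recombination mosaics of K founder haplotypes (founder
#' switch probability `1 - exp(-switch_rate * gap_bp)` between adjacent
#' SNPs), which creates linkage disequilibrium that decays with distance.
#' Founder alleles are drawn so that the founder pool frequency tracks the
#' target population frequency; a final per-SNP perturbation flips the
#' minimal number of random alleles so the realized sample frequency equals
#' the target (disable with `match_freq = FALSE` in the config; always
#' skipped for K = 1, where all haplotypes are identical by construction).
#'
#' @param config a `sim_config`.
#' @param freqs result of [simulate_frequencies()].
#' @param seed seed for this stage.
#' @return named list (one per population) of lists of `haplotype_panel`
#'   objects keyed by chromosome.
#' @export
simulate_haplotypes <- function(config, freqs, seed = config$seed + 1L) {
  if (config$founders_k < 1L) stop("founders_k must be >= 1")
  set.seed(seed)
  K <- config$founders_k
  snps <- freqs$layout$snps
  panels <- list()
  for (k in seq_along(config$populations)) {
    pop <- config$populations[k]
    n <- config$n_haplotypes[k]
    panels[[pop]] <- list()
    for (ch in unique(snps$chrom)) {
      sel <- snps$chrom == ch
      pos <- snps$pos[sel]
      p <- freqs$freq[sel, k]
      S <- length(pos)
      # founder pool: number of derived founders tracks the target frequency
      n_derived <- pmin(K, pmax(0L, as.integer(round(K * p))))
      founders <- matrix(0L, K, S)
      for (j in seq_len(S)) {
        if (n_derived[j] > 0L) {
          founders[sample.int(K, n_derived[j]), j] <- 1L
        }
      }
      gap <- c(0, diff(pos))
      sw <- 1 - exp(-config$switch_rate * gap)
      H <- cpp_mosaic_haplotypes(founders, n, sw)
      if (config$match_freq && K >= 2L) {
        H <- cpp_match_freq(H, as.integer(round(n * p)))
      }
      panels[[pop]][[ch]] <- haplotype_panel(H, pos, population = pop,
                                             chrom = ch)
    }
  }
  panels
}

#' Plant a selective sweep at a gene in one panel
#'
#' A core haplotype carrying the derived allele at the gene's central SNP is
#' copied over randomly chosen haplotypes, within a window spanning the gene
#' plus `flank_bp` on each side, until the derived frequency at the central
#' SNP reaches `beta`.  This jointly elevates DAF, cross-population
#' frequency differences, FST and extended haplotype homozygosity in the
#' target population only ("star-like" sweep).
#'
#' The core SNP is the in-gene SNP nearest the gene center among those with
#' a current derived frequency of at most `max_core_freq` (a sweep models a
#' new advantageous derived allele rising from low frequency; planting on
#' an allele that is already common would create no signal).  If every
#' in-gene SNP is common, the lowest-frequency SNP is used; if the core has
#' no derived carrier yet, one haplotype receives the derived allele first
#' (the new mutation).
#'
#' @param panel `haplotype_panel` of the target population.
#' @param gene one-row data frame with `start`/`end` (from the layout).
#' @param beta target final derived-allele frequency in (0,1].
#' @param flank_bp half-width added to the gene span for the copied window.
#' @param max_core_freq highest current derived frequency eligible for the
#'   core SNP.
#' @param seed optional seed.
#' @return list with the modified `panel`, the `core_snp` index, and
#'   `planted` (FALSE when the sweep was a no-op).
#' @export
plant_sweep <- function(panel, gene, beta, flank_bp = 20000,
                        max_core_freq = 0.25, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), beta > 0, beta <= 1)
  if (!is.null(seed)) set.seed(seed)
  in_gene <- which(panel$positions >= gene$start & panel$positions <= gene$end)
  if (length(in_gene) == 0L) stop("gene has no SNP in this panel")
  freq <- colMeans(panel$H[, in_gene, drop = FALSE])
  centre <- (gene$start + gene$end) / 2
  rare <- which(freq <= max_core_freq)
  core <- if (length(rare)) {
    rare[which.min(abs(panel$positions[in_gene[rare]] - centre))]
  } else {
    which.min(freq)
  }
  core <- in_gene[core]
  window <- which(panel$positions >= gene$start - flank_bp &
                  panel$positions <= gene$end + flank_bp)
  n <- nrow(panel$H)
  target <- ceiling(beta * n)
  carriers <- which(panel$H[, core] == 1L)
  if (length(carriers) >= target) {
    warning("sweep target frequency below current frequency; panel unchanged")
    return(list(panel = panel, core_snp = core, planted = FALSE))
  }
  if (length(carriers) == 0L) {
    donor <- sample.int(n, 1L)
    panel$H[donor, core] <- 1L
    carriers <- donor
  }
  donor <- carriers[sample.int(length(carriers), 1L)]
  recipients <- setdiff(seq_len(n), which(panel$H[, core] == 1L))
  need <- target - sum(panel$H[, core])
  recipients <- recipients[sample.int(length(recipients), need)]
  panel$H[recipients, window] <- rep(panel$H[donor, window],
                                     each = length(recipients))
  list(panel = panel, core_snp = core, planted = TRUE)
}

#' Simulate a scale-free interaction network with planted clusters
#'
#' Preferential-attachment (Barabasi-Albert) graph over the gene ids, with
#' `m` edges per incoming node, giving the heavy-tailed degree distribution
#' of curated PPI networks.  When `n_sweep` > 0, seed nodes are drawn and
#' each seed plus part of its neighborhood within `radius` steps (at most 4
#' genes per cluster, so the sweeps spread over several small pathway-like
#' clusters rather than one or two large ones) is marked as a sweep target,
#' capped at `n_sweep` genes in total; planted coselection clusters are
#' network-adjacent by construction.
#'
#' @param config a `sim_config`.
#' @param gene_ids node labels (gene ids from the layout).
#' @param seed seed for this stage.
#' @return list with `graph` (igraph, named vertices) and `truth`
#'   (`swept_genes`, `clusters`).
#' @export
simulate_network <- function(config, gene_ids, seed = config$seed + 2L) {
  stopifnot(length(gene_ids) >= 10)
  set.seed(seed)
  g <- igraph::sample_pa(length(gene_ids), power = 1, m = config$network_m,
                         directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- gene_ids
  truth <- list(swept_genes = character(0), clusters = list())
  n_sweep <- config$n_sweep_genes
  if (!is.null(config$sweep_gene_ids)) {
    truth$swept_genes <- config$sweep_gene_ids
    truth$clusters <- list(config$sweep_gene_ids)
  } else if (n_sweep > 0L) {
    pool <- sample(gene_ids)  # deterministic candidate order under seed
    members <- character(0)
    for (s in pool) {
      if (length(members) >= n_sweep) break
      if (s %in% members) next
      nb <- names(igraph::ego(g, order = config$cluster_radius,
                              nodes = s)[[1]])
      nb <- setdiff(nb, members)
      nb <- c(s, setdiff(nb, s))
      keep <- nb[seq_len(min(length(nb), 4L, n_sweep - length(members)))]
      truth$clusters <- c(truth$clusters, list(keep))
      members <- c(members, keep)
    }
    truth$swept_genes <- members
  }
  list(graph = g, truth = truth)
}

#' Run the whole synthetic study
#'
#' Lays out genes, draws frequencies, builds haplotype panels for the three
#' populations, simulates the interaction network, chooses sweep targets
#' (explicit ids or planted network clusters), and plants the sweeps in the
#' target population.  Everything is deterministic given the config seed.
#'
#' @param config a `sim_config`.
#' @return object of class `cosel_sim`: `config`, `genes`, `snps`, `freqs`,
#'   `panels`, `network`, and `truth` (`swept_genes` per population,
#'   `planted_clusters`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- gene_layout(config)
  net <- simulate_network(config, layout$genes$gene)
  # pathway-level coselection: when coselection is planted, per-gene drift
  # is scaled by a network-smoothed Gaussian field so adjacent genes share
  # correlated divergence rates; null (no-sweep) studies have no field
  f_scale <- NULL
  if (length(net$truth$swept_genes) > 0 && config$coselection_sd > 0) {
    set.seed(config$seed + 4L)
    u <- stats::rnorm(igraph::vcount(net$graph))
    nbs <- igraph::adjacent_vertices(net$graph, igraph::V(net$graph))
    # two neighbor-averaging passes: the field correlates over one- and
    # two-step network neighborhoods, the scale of pathway coselection
    for (pass in 1:2) {
      nb_mean <- vapply(nbs, function(v) mean(u[as.integer(v)]), 0)
      u <- (u + nb_mean) / 2
    }
    u <- u / sd(u) * config$coselection_sd
    # bounded pathway effect: extreme drift multipliers are not realistic
    # and would let single genes dominate every rank-based statistic
    u <- pmin(pmax(u, -1), 1)
    f_scale <- stats::setNames(exp(u), igraph::V(net$graph)$name)
  }
  freqs <- simulate_frequencies(config, f_scale = f_scale)
  panels <- simulate_haplotypes(config, freqs)
  genes <- freqs$layout$genes
  swept <- net$truth$swept_genes
  truth <- list(swept_genes = stats::setNames(
                  list(swept), config$sweep_population),
                planted_clusters = net$truth$clusters)
  if (length(swept) > 0L) {
    set.seed(config$seed + 3L)
    pop <- config$sweep_population
    planted <- character(0)
    for (gid in swept) {
      grow <- genes[genes$gene == gid, ]
      res <- plant_sweep(panels[[pop]][[grow$chrom]], grow,
                         beta = config$sweep_beta,
                         flank_bp = config$flank_bp)
      panels[[pop]][[grow$chrom]] <- res$panel
      if (res$planted) planted <- c(planted, gid)
    }
    # parallel pathway selection: the one-step network neighbors of the
    # swept genes are themselves partially swept in the target population
    # ("proteins involved are all affected, to more or less extent"),
    # elevating all four selection statistics moderately there
    nbhd <- setdiff(unique(names(unlist(
      igraph::ego(net$graph, order = 1, nodes = swept)))), swept)
    cosel <- character(0)
    if (config$neighbor_beta > 0) {
      for (gid in nbhd) {
        grow <- genes[genes$gene == gid, ]
        res <- suppressWarnings(
          plant_sweep(panels[[pop]][[grow$chrom]], grow,
                      beta = config$neighbor_beta,
                      flank_bp = config$flank_bp))
        panels[[pop]][[grow$chrom]] <- res$panel
        if (res$planted) cosel <- c(cosel, gid)
      }
    }
    # ground truth records only genes where a sweep was actually planted
    truth$swept_genes[[config$sweep_population]] <- planted
    truth$planted_clusters <- lapply(net$truth$clusters, intersect, planted)
    truth$coselected_neighbors <- cosel
  }
  structure(list(config = config, genes = genes, snps = freqs$layout$snps,
                 freqs = freqs, panels = panels, network = net$graph,
                 truth = truth),
            class = "cosel_sim")
}

#' @export
print.cosel_sim <- function(x, ...) {
  cat(sprintf(paste0("<cosel_sim> %d genes, %d SNPs, populations %s; ",
                     "%d swept genes in %s; network: %d nodes / %d edges\n"),
              nrow(x$genes), nrow(x$snps),
              paste(x$config$populations, collapse = "/"),
              length(unlist(x$truth$swept_genes)),
              x$config$sweep_population,
              igraph::vcount(x$network), igraph::ecount(x$network)))
  invisible(x)
}
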