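# per-SNP WC components (numerator/denominator) for one pair of panels,
# summed per gene -> ratio-of-sums FST per gene
gene_fst_pair <- function(panel_a, panel_b, snp_gene) {
  p <- cbind(snp_daf(panel_a), snp_daf(panel_b))
  n <- c(nrow(panel_a$H), nrow(panel_b$H))
  r <- 2
  N <- sum(n)
  pbar <- as.vector(p %*% n) / N
  msp <- as.vector((p - pbar)^2 %*% n) / (r - 1)
  msg <- as.vector((p * (1 - p)) %*% n) / sum(n - 1)
  nc <- (N - sum(n^2) / N) / (r - 1)
  num <- rowsum(msp - msg, snp_gene)
  den <- rowsum(msp + (nc - 1) * msg, snp_gene)
  out <- ifelse(den[, 1] == 0, NA_real_, num[, 1] / den[, 1])
  stats::setNames(out, rownames(num))
}

#' Gene-level pairwise FST between populations
#'
#' Multi-SNP Weir-Cockerham ratio-of-sums over the SNPs within each gene
#' span, for every pair of the three populations.  Genes without a usable
#' (polymorphic) SNP are excluded.
#'
#' @param panels named list (population -> chromosome) of
#'   `haplotype_panel` objects.
#' @param genes gene annotation data frame (gene, chrom, start, end).
#' @return data frame: gene, fst_12, fst_13, fst_23 (populations in
#'   `names(panels)` order).
#' @export
gene_fst <- function(panels, genes) {
  pops <- names(panels)
  stopifnot(length(pops) == 3)
  out <- list()
  for (ch in names(panels[[1]])) {
    pos <- panels[[1]][[ch]]$positions
    g <- genes[genes$chrom == ch, ]
    snp_gene <- rep(NA_character_, length(pos))
    for (i in seq_len(nrow(g))) {
      snp_gene[pos >= g$start[i] & pos <= g$end[i]] <- g$gene[i]
    }
    keep <- !is.na(snp_gene)
    sub <- lapply(panels, function(pp) {
      haplotype_panel(pp[[ch]]$H[, keep, drop = FALSE], pos[keep],
                      population = pp[[ch]]$population, chrom = ch)
    })
    f12 <- gene_fst_pair(sub[[1]], sub[[2]], snp_gene[keep])
    f13 <- gene_fst_pair(sub[[1]], sub[[3]], snp_gene[keep])
    f23 <- gene_fst_pair(sub[[2]], sub[[3]], snp_gene[keep])
    out[[ch]] <- data.frame(gene = names(f12), fst_12 = unname(f12),
                            fst_13 = unname(f13), fst_23 = unname(f23),
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab <- tab[complete.cases(tab), ]
  rownames(tab) <- NULL
  tab
}

#' Branch lengths of the trifurcate divergence tree
#'
#' Three-point formula: D_i = (FST(i,j) + FST(i,k) - FST(j,k)) / 2, so that
#' D_i + D_j = FST(i,j) exactly.  Negative branch lengths are retained.
#'
#' @param fst_12,fst_13,fst_23 pairwise FST values (vectorized).
#' @return matrix with columns D1, D2, D3.
#' @export
trifurcate_tree <- function(fst_12, fst_13, fst_23) {
  cbind(D1 = (fst_12 + fst_13 - fst_23) / 2,
        D2 = (fst_12 + fst_23 - fst_13) / 2,
        D3 = (fst_13 + fst_23 - fst_12) / 2)
}

#' Per-gene divergence trees for three populations
#'
#' Computes gene-level pairwise FST and the trifurcate branch lengths, and
#' records the per-population genome median divergence rate D' and its SD
#' over the included genes (the cohort used by [rtd()] and [syn()]).
#'
#' @param panels named list (population -> chromosome) of
#'   `haplotype_panel` objects.
#' @param genes gene annotation data frame.
#' @param universe optional gene ids to restrict the cohort to (e.g., the
#'   network-mapped genes).
#' @return data frame of class `divergence_trees`: gene, fst_12/13/23,
#'   D1..D3, with attributes `populations`, `medians`, `sds`.
#' @export
divergence_trees <- function(panels, genes, universe = NULL) {
  tab <- gene_fst(panels, genes)
  if (!is.null(universe)) tab <- tab[tab$gene %in% universe, ]
  D <- trifurcate_tree(tab$fst_12, tab$fst_13, tab$fst_23)
  tab <- cbind(tab, D)
  rownames(tab) <- NULL
  attr(tab, "populations") <- names(panels)
  attr(tab, "medians") <- apply(D, 2, median)
  attr(tab, "sds") <- apply(D, 2, sd)
  class(tab) <- c("divergence_trees", "data.frame")
  tab
}

tree_matrix <- function(table) {
  as.matrix(table[, c("D1", "D2", "D3")])
}

#' Ranked tree distance (RTD) between two genes
#'
#' Genes are ranked by divergence rate within each population (average
#' ranks on ties); the raw RTD of a pair is the mean absolute rank
#' difference over the three populations.  By default the score is
#' normalized so that RTD over all pairs of the cohort has zero mean and
#' unit variance; low RTD means similar evolutionary paths.
#'
#' @param a,b gene ids.
#' @param table a `divergence_trees` data frame.
#' @param normalize return the cohort-normalized score (default) or the
#'   raw mean rank distance.
#' @return a single RTD value.
#' @export
rtd <- function(a, b, table, normalize = TRUE) {
  D <- tree_matrix(table)
  R <- apply(D, 2, rank)
  ia <- match(a, table$gene); ib <- match(b, table$gene)
  if (is.na(ia) || is.na(ib)) stop("gene not in the tree table")
  raw <- mean(abs(R[ia, ] - R[ib, ]))
  if (!normalize) return(raw)
  all_raw <- rtd_all_pairs(R)
  (raw - mean(all_raw)) / sd(all_raw)
}

# raw RTD for all unordered pairs of rows of a rank matrix
rtd_all_pairs <- function(R) {
  m <- nrow(R)
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  (abs(R[ut[, 1], 1] - R[ut[, 2], 1]) +
     abs(R[ut[, 1], 2] - R[ut[, 2], 2]) +
     abs(R[ut[, 1], 3] - R[ut[, 2], 3])) / 3
}

#' Synergy (Syn) score between two genes
#'
#' Mean over populations of the standardized cross-product of the two
#' genes' divergence-rate residuals from the cohort median:
#' Syn = (1/3) sum_i (D_ai - D'_i)(D_bi - D'_i) / SD_i^2.  Positive values
#' mean the two genes deviate from the genome median tree in the same
#' direction (synergic divergence).
#'
#' @param a,b gene ids.
#' @param table a `divergence_trees` data frame.
#' @return a single Syn value.
#' @export
syn <- function(a, b, table) {
  D <- tree_matrix(table)
  med <- attr(table, "medians")
  sds <- attr(table, "sds")
  if (any(sds == 0)) stop("degenerate cohort: zero SD in a population")
  ia <- match(a, table$gene); ib <- match(b, table$gene)
  if (is.na(ia) || is.na(ib)) stop("gene not in the tree table")
  mean((D[ia, ] - med) * (D[ib, ] - med) / sds^2)
}

#' Tree similarity (RTD and Syn) as a function of network distance
#'
#' Mean normalized RTD and mean Syn per SPL bin over all unordered pairs of
#' cohort genes that are network nodes, compared with a reshuffling null:
#' in each of `n_perm` permutations the divergence rates are reshuffled
#' across nodes independently within each population and the bin means are
#' recomputed.  Empirical p-values per bin use the add-one two-sided rank
#' rule; the Spearman trend of the observed bin means against SPL is
#' reported.
#'
#' @param table a `divergence_trees` data frame.
#' @param spl an `spl_index`.
#' @param n_perm number of reshuffles (default 1000; 0 skips the null and
#'   returns the observed profile and trends only).
#' @param seed optional seed.
#' @param pool_at pool SPL values >= this into one bin.
#' @return object of class `tree_similarity_profile`: `profile` data frame
#'   (spl, n_pairs, mean_rtd, mean_syn, null means/sds, p_rtd, p_syn,
#'   low_support), `trend_rtd`, `trend_syn`, and the normalization
#'   constants.
#' @export
tree_similarity_vs_spl <- function(table, spl, n_perm = 1000, seed = NULL,
                                   pool_at = 9) {
  stopifnot(inherits(spl, "spl_index"))
  if (!is.null(seed)) set.seed(seed)
  common <- intersect(table$gene, spl$nodes)
  tab <- table[match(common, table$gene), ]
  m <- length(common)
  stopifnot(m >= 10)
  D <- tree_matrix(tab)
  R <- apply(D, 2, rank)
  med <- apply(D, 2, median)
  sds <- apply(D, 2, sd)
  if (any(sds == 0)) stop("degenerate cohort: zero SD in a population")
  Zr <- sweep(sweep(D, 2, med), 2, sds, "/")
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  dsub <- spl$d[match(common, spl$nodes), match(common, spl$nodes)]
  bin <- pmin(dsub[ut], pool_at)
  n_pairs <- tabulate(bin, pool_at)
  keep <- which(n_pairs > 0)
  pair_means <- function(Rm, Zm) {
    rtd_raw <- (abs(Rm[i, 1] - Rm[j, 1]) + abs(Rm[i, 2] - Rm[j, 2]) +
                  abs(Rm[i, 3] - Rm[j, 3])) / 3
    synv <- (Zm[i, 1] * Zm[j, 1] + Zm[i, 2] * Zm[j, 2] +
               Zm[i, 3] * Zm[j, 3]) / 3
    s <- rowsum(cbind(rtd_raw, synv), bin)
    list(rtd = s[, 1] / n_pairs[sort(unique(bin))],
         syn = s[, 2] / n_pairs[sort(unique(bin))],
         rtd_raw = rtd_raw)
  }
  obs <- pair_means(R, Zr)
  # normalization: the all-pairs multiset of RTD_raw is invariant under
  # within-population reshuffling, so the constants are shared with the null
  mu <- mean(obs$rtd_raw); sdev <- sd(obs$rtd_raw)
  obs_rtd <- (obs$rtd - mu) / sdev
  lab <- c(as.character(seq_len(pool_at - 1)), paste0(pool_at, "+"))
  if (n_perm == 0) {
    profile <- data.frame(spl = lab[keep], n_pairs = n_pairs[keep],
                          mean_rtd = obs_rtd, mean_syn = obs$syn,
                          low_support = n_pairs[keep] < 10,
                          stringsAsFactors = FALSE)
    return(structure(list(profile = profile,
                          trend_rtd = spearman_trend(obs_rtd, keep),
                          trend_syn = spearman_trend(obs$syn, keep),
                          rtd_mean = mu, rtd_sd = sdev),
                     class = "tree_similarity_profile"))
  }
  null_rtd <- matrix(NA_real_, n_perm, length(keep))
  null_syn <- matrix(NA_real_, n_perm, length(keep))
  Rp <- R; Zp <- Zr
  for (r in seq_len(n_perm)) {
    # each population's divergence rates reshuffled with its own draw
    for (c3 in 1:3) {
      perm <- sample.int(m)
      Rp[, c3] <- R[perm, c3]
      Zp[, c3] <- Zr[perm, c3]
    }
    pm <- pair_means(Rp, Zp)
    null_rtd[r, ] <- (pm$rtd - mu) / sdev
    null_syn[r, ] <- pm$syn
  }
  p_rtd <- vapply(seq_along(keep), function(b) {
    resample_p(obs_rtd[b], null_rtd[, b], "two.sided")
  }, 0)
  p_syn <- vapply(seq_along(keep), function(b) {
    resample_p(obs$syn[b], null_syn[, b], "two.sided")
  }, 0)
  profile <- data.frame(
    spl = lab[keep], n_pairs = n_pairs[keep],
    mean_rtd = obs_rtd, mean_syn = obs$syn,
    null_rtd_mean = colMeans(null_rtd), null_rtd_sd = apply(null_rtd, 2, sd),
    null_syn_mean = colMeans(null_syn), null_syn_sd = apply(null_syn, 2, sd),
    p_rtd = p_rtd, p_syn = p_syn,
    low_support = n_pairs[keep] < 10,
    stringsAsFactors = FALSE)
  spl_num <- keep
  structure(list(profile = profile,
                 trend_rtd = spearman_trend(obs_rtd, spl_num),
                 trend_syn = spearman_trend(obs$syn, spl_num),
                 rtd_mean = mu, rtd_sd = sdev,
                 null_rtd = null_rtd, null_syn = null_syn),
            class = "tree_similarity_profile")
}

#' @export
print.tree_similarity_profile <- function(x, ...) {
  cat("<tree_similarity_profile>\n")
  cols <- intersect(c("spl", "n_pairs", "mean_rtd", "mean_syn",
                      "p_rtd", "p_syn"), names(x$profile))
  print(x$profile[, cols], row.names = FALSE)
  cat(sprintf("RTD~SPL: rho = %.3f (p = %.3g); Syn~SPL: rho = %.3f (p = %.3g)\n",
              x$trend_rtd$rho, x$trend_rtd$p,
              x$trend_syn$rho, x$trend_syn$p))
  invisible(x)
}
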