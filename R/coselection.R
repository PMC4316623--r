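# Shared helpers for resampling nulls ---------------------------------------

# add-one empirical p from a null vector; two-sided = doubled smaller tail,
# capped at 1
resample_p <- function(obs, null, alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  if (is.na(obs)) return(NA_real_)
  n <- length(null)
  p_hi <- (1 + sum(null >= obs)) / (n + 1)
  p_lo <- (1 + sum(null <= obs)) / (n + 1)
  switch(alternative,
         greater = p_hi, less = p_lo,
         two.sided = min(1, 2 * min(p_hi, p_lo)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement.
#'
#' @param p vector of p-values in `[0,1]` (NAs kept).
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Default centrality interval scheme
#'
#' Six degree intervals and seven betweenness intervals that split a
#' curated PPI network into roughly equally occupied bins; both are
#' right-closed and fully configurable.
#'
#' @return list with numeric break vectors `dc` and `bc` (usable with
#'   `cut(..., right = TRUE)`).
#' @export
interval_scheme <- function() {
  list(dc = c(0, 1, 3, 5, 9, 20, Inf),
       bc = c(-Inf, 0, 10, 100, 500, 2000, 20000, Inf))
}

bin_labels <- function(breaks) {
  lab <- character(length(breaks) - 1)
  for (i in seq_along(lab)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    lab[i] <- if (is.infinite(hi)) sprintf(">%g", lo)
      else if (lo + 1 == hi || (is.infinite(lo) && hi == 0)) sprintf("%g", hi)
      else sprintf("%g-%g", lo + 1, hi)
  }
  lab
}

#' Centrality-interval enrichment of candidate genes
#'
#' For each centrality interval, the proportion of the candidate set
#' falling in the interval is compared with `n_perm` random resamples of
#' node sets of the same size drawn uniformly without replacement from the
#' network: Z = (P_S - mean(P_N)) / sd(P_N), empirical p by rank of P_S
#' against the resamples (two-sided by default, add-one rule), BH-FDR
#' across intervals.
#'
#' @param candidates character vector of candidate genes (must be network
#'   nodes) or a `candidate_genes` data frame.
#' @param centralities data frame from [ppi_centralities()].
#' @param measure `"dc"` or `"bc"`.
#' @param breaks interval breaks (default from [interval_scheme()]).
#' @param n_perm number of resamples.
#' @param seed optional seed.
#' @param alternative sidedness of the empirical p.
#' @return data frame of class `enrichment_profile`: bin, n_nodes,
#'   p_obs, null_mean, null_sd, z, p, p_adj.
#' @export
centrality_enrichment <- function(candidates, centralities,
                                  measure = c("dc", "bc"), breaks = NULL,
                                  n_perm = 10000, seed = NULL,
                                  alternative = "two.sided") {
  measure <- match.arg(measure)
  if (is.data.frame(candidates)) candidates <- candidates$gene
  if (!all(candidates %in% centralities$gene)) {
    stop("all candidates must be nodes of the network")
  }
  if (is.null(breaks)) breaks <- interval_scheme()[[measure]]
  if (!is.null(seed)) set.seed(seed)
  x <- centralities[[measure]]
  bin <- cut(x, breaks, right = TRUE)
  nb <- nlevels(bin)
  k <- length(unique(candidates))
  idx <- match(unique(candidates), centralities$gene)
  obs <- tabulate(bin[idx], nb) / k
  null <- matrix(0, n_perm, nb)
  n <- nrow(centralities)
  for (r in seq_len(n_perm)) {
    null[r, ] <- tabulate(bin[sample.int(n, k)], nb) / k
  }
  null_mean <- colMeans(null)
  null_sd <- apply(null, 2, sd)
  z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd,
              ifelse(obs == null_mean, 0, NA_real_))
  p <- vapply(seq_len(nb), function(b) {
    resample_p(obs[b], null[, b], alternative)
  }, 0)
  out <- data.frame(bin = bin_labels(breaks),
                    n_nodes = as.integer(table(bin)),
                    p_obs = obs, null_mean = null_mean, null_sd = null_sd,
                    z = z, p = p, p_adj = bh_fdr(p),
                    stringsAsFactors = FALSE)
  attr(out, "measure") <- measure
  attr(out, "n_perm") <- n_perm
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Mann-Whitney comparison of centralities between candidates and the rest
#'
#' Two-sided Wilcoxon rank-sum test of DC and of BC between candidate and
#' non-candidate nodes (exact for small tie-free samples, otherwise the
#' normal approximation with tie correction).
#'
#' @param candidates candidate gene ids or a `candidate_genes` data frame.
#' @param centralities data frame from [ppi_centralities()].
#' @return named numeric vector with elements `dc` and `bc`.
#' @export
mw_test_centrality <- function(candidates, centralities) {
  if (is.data.frame(candidates)) candidates <- candidates$gene
  sel <- centralities$gene %in% candidates
  if (!any(sel) || all(sel)) stop("both groups must be nonempty")
  c(dc = suppressWarnings(
      wilcox.test(centralities$dc[sel], centralities$dc[!sel])$p.value),
    bc = suppressWarnings(
      wilcox.test(centralities$bc[sel], centralities$bc[!sel])$p.value))
}

# distances of all unordered pairs within a node index set, pooled at
# pool_at, tabulated per bin 1..pool_at
pair_dist_counts <- function(d, idx, pool_at) {
  sub <- d[idx, idx]
  v <- sub[upper.tri(sub)]
  tabulate(pmin(v, pool_at), pool_at)
}

#' SPL coselection proportions of a candidate set
#'
#' For every shortest-path length d, P_S,d = (pairs at distance d with both
#' genes candidate) / (all pairs at distance d).  The expected proportion
#' under no coselection is C(k,2)/C(n,2); the relative proportion is
#' P_S,d divided by it, so values above 1 mark overrepresented coselection.
#' Z-scores and empirical p-values per d come from `n_perm` resampled node
#' sets of size k; distances of `pool_at` and beyond are pooled into one
#' bin.  P-values are BH-FDR corrected across bins; bins with fewer than 10
#' pairs are flagged low-support.
#'
#' @param candidates candidate gene ids or a `candidate_genes` data frame.
#' @param spl an `spl_index` from [ppi_spl()].
#' @param n_perm number of resamples.
#' @param seed optional seed.
#' @param pool_at pool SPL values >= this into one bin (default 9).
#' @param alternative sidedness of the empirical p.
#' @return data frame of class `enrichment_profile`: spl, n_pairs,
#'   n_copairs, p_obs, expected, relative, null_mean, null_sd, z, p, p_adj,
#'   low_support.
#' @export
spl_coselection <- function(candidates, spl, n_perm = 10000, seed = NULL,
                            pool_at = 9, alternative = "two.sided") {
  if (is.data.frame(candidates)) candidates <- candidates$gene
  candidates <- unique(candidates)
  stopifnot(inherits(spl, "spl_index"))
  if (!all(candidates %in% spl$nodes)) {
    stop("all candidates must be nodes of the SPL index")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(spl$nodes)
  k <- length(candidates)
  stopifnot(k >= 2)
  all_counts <- tabulate(pmin(spl$d[upper.tri(spl$d)], pool_at), pool_at)
  keep <- which(all_counts > 0)
  idx <- match(candidates, spl$nodes)
  co <- pair_dist_counts(spl$d, idx, pool_at)
  obs <- co / all_counts
  expected <- choose(k, 2) / choose(n, 2)
  null <- matrix(0, n_perm, pool_at)
  for (r in seq_len(n_perm)) {
    null[r, ] <- pair_dist_counts(spl$d, sample.int(n, k), pool_at) /
      all_counts
  }
  null_mean <- colMeans(null)
  null_sd <- apply(null, 2, sd)
  z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd,
              ifelse(obs == null_mean, 0, NA_real_))
  p <- vapply(seq_len(pool_at), function(b) {
    resample_p(obs[b], null[, b], alternative)
  }, 0)
  lab <- c(as.character(seq_len(pool_at - 1)), paste0(pool_at, "+"))
  out <- data.frame(spl = lab, n_pairs = all_counts, n_copairs = co,
                    p_obs = obs, expected = expected,
                    relative = obs / expected,
                    null_mean = null_mean, null_sd = null_sd, z = z, p = p,
                    stringsAsFactors = FALSE)[keep, ]
  out$p_adj <- bh_fdr(out$p)
  out$low_support <- out$n_pairs < 10
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "k") <- k
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Mean shortest path length among candidate genes versus resampled sets
#'
#' Observed mean SPL over all unordered candidate pairs, compared with
#' `n_perm` equal-size random node sets; one-sided empirical
#' p = (1 + #{null <= observed}) / (n_perm + 1) for the clustering
#' direction (shorter than expected).
#'
#' @param candidates candidate gene ids or a `candidate_genes` data frame.
#' @param spl an `spl_index`.
#' @param n_perm number of resamples.
#' @param seed optional seed.
#' @return list: observed, null_mean, null (vector), p.
#' @export
mean_spl_test <- function(candidates, spl, n_perm = 10000, seed = NULL) {
  if (is.data.frame(candidates)) candidates <- candidates$gene
  candidates <- unique(candidates)
  stopifnot(inherits(spl, "spl_index"), length(candidates) >= 2)
  if (!all(candidates %in% spl$nodes)) {
    stop("all candidates must be nodes of the SPL index")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(spl$nodes)
  k <- length(candidates)
  idx <- match(candidates, spl$nodes)
  sub <- spl$d[idx, idx]
  observed <- mean(sub[upper.tri(sub)])
  null <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    s_idx <- sample.int(n, k)
    sub_r <- spl$d[s_idx, s_idx]
    null[r] <- mean(sub_r[upper.tri(sub_r)])
  }
  list(observed = observed, null_mean = mean(null), null = null,
       p = (1 + sum(null <= observed)) / (n_perm + 1))
}

#' Spearman trend between a profile and SPL
#'
#' Rank correlation (with the exact or approximate p-value as the sample
#' allows) between, e.g., relative coselection proportions and their SPL
#' values.
#'
#' @param values profile values (one per SPL bin).
#' @param spl_values corresponding SPL values.
#' @return list: rho, p.
#' @export
spearman_trend <- function(values, spl_values = seq_along(values)) {
  ok <- is.finite(values) & is.finite(spl_values)
  if (sum(ok) < 4) stop("need at least 4 usable bins")
  if (sd(values[ok]) == 0 || sd(spl_values[ok]) == 0) {
    warning("constant input: rho undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(values[ok], spl_values[ok],
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
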