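#' Derived allele frequency per SNP
#'
#' @param panel a `haplotype_panel`.
#' @return numeric vector, one DAF in `[0,1]` per SNP.
#' @export
snp_daf <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  colMeans(panel$H)
}

#' Difference in derived allele frequency
#'
#' Convention for three populations: the target's DAF minus the mean DAF of
#' the other populations, so a positive value means the derived allele rose
#' specifically in the target.
#'
#' @param daf_target DAF vector of the target population.
#' @param daf_others DAF vector, or matrix with one column per other
#'   population.
#' @return signed numeric vector.
#' @export
delta_daf <- function(daf_target, daf_others) {
  daf_others <- as.matrix(daf_others)
  stopifnot(nrow(daf_others) == length(daf_target), ncol(daf_others) >= 1)
  daf_target - rowMeans(daf_others)
}

#' Weir-Cockerham FST from haplotype counts
#'
#' Two-allele ANOVA estimator in the haploid (haplotype-count) formulation.
#' Per SNP: MSP = sum n_i (p_i - pbar)^2 / (r-1), MSG = sum n_i p_i (1-p_i)
#' / sum (n_i - 1), n_c = (N - sum n_i^2 / N) / (r-1), and theta-hat =
#' (MSP - MSG) / (MSP + (n_c - 1) MSG).  Negative estimates are retained;
#' SNPs monomorphic in all populations are undefined (NA).  With
#' `ratio_of_sums = TRUE` the numerator and denominator are summed over the
#' supplied SNPs first (the multi-SNP "molecular FST" used per gene).
#'
#' @param p matrix of allele frequencies, SNPs x populations.
#' @param n haplotype counts per population.
#' @param ratio_of_sums combine SNPs by ratio of sums instead of returning
#'   a per-SNP vector.
#' @return numeric vector (per SNP), or a single value when
#'   `ratio_of_sums = TRUE`.
#' @export
wc_fst <- function(p, n, ratio_of_sums = FALSE) {
  p <- as.matrix(p)
  r <- ncol(p)
  stopifnot(r >= 2, length(n) == r, all(n >= 2))
  N <- sum(n)
  pbar <- as.vector(p %*% n) / N
  msp <- as.vector((p - pbar)^2 %*% n) / (r - 1)
  msg <- as.vector((p * (1 - p)) %*% n) / sum(n - 1)
  nc <- (N - sum(n^2) / N) / (r - 1)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  if (ratio_of_sums) {
    if (sum(den) == 0) return(NA_real_)
    return(sum(num) / sum(den))
  }
  theta <- num / den
  theta[den == 0] <- NA_real_  # monomorphic in all populations
  theta
}

#' Per-SNP FST between two panels
#'
#' @param panel_a,panel_b `haplotype_panel` objects over the same sites.
#' @return per-SNP Weir-Cockerham theta-hat.
#' @export
fst_per_snp <- function(panel_a, panel_b) {
  stopifnot(identical(panel_a$positions, panel_b$positions))
  wc_fst(cbind(snp_daf(panel_a), snp_daf(panel_b)),
         c(nrow(panel_a$H), nrow(panel_b$H)))
}

#' Site-specific extended haplotype homozygosity (EHHS) profile
#'
#' From a core SNP, the probability that two random haplotypes are
#' identical over every SNP from the core out to distance d (core
#' included); 1 at the core by definition and non-increasing with d.
#'
#' @param panel a `haplotype_panel`.
#' @param core core SNP index (column).
#' @param direction +1 (rightward) or -1 (leftward).
#' @return numeric vector over the flanking SNPs in that direction.
#' @export
ehhs <- function(panel, core, direction = 1) {
  stopifnot(inherits(panel, "haplotype_panel"),
            core >= 1, core <= ncol(panel$H))
  cpp_ehhs_profile(panel$H, as.integer(core), as.integer(direction))
}

#' Integrated EHHS (iES) for every SNP
#'
#' Trapezoid integral of the EHHS profile over physical distance, both
#' directions from each core, truncated at the first SNP whose EHHS falls
#' below `decay` or at `max_ext` bp.
#'
#' @param panel a `haplotype_panel`.
#' @param decay EHHS decay cutoff (default 0.05).
#' @param max_ext maximum extension per side, bp (default 500 kb).
#' @return numeric vector of iES values, one per SNP.
#' @export
ies <- function(panel, decay = 0.05, max_ext = 5e5) {
  stopifnot(inherits(panel, "haplotype_panel"))
  cpp_ies(panel$H, panel$positions, decay, max_ext)
}

#' lnRsb: log-ratio of integrated EHHS between two panels
#'
#' ln(iES_target / iES_other) per SNP; sites where the denominator is zero
#' are missing.  By default the scores are genome-standardized (median
#' subtracted, divided by the standard deviation) so that elevated values
#' flag unusually long haplotypes in the target population.
#'
#' @param panel_target,panel_other `haplotype_panel` objects on the same
#'   sites.
#' @param decay,max_ext passed to [ies()].
#' @param standardize subtract the median and divide by the SD.
#' @return per-SNP lnRsb vector.
#' @export
ln_rsb <- function(panel_target, panel_other, decay = 0.05, max_ext = 5e5,
                   standardize = TRUE) {
  stopifnot(identical(panel_target$positions, panel_other$positions))
  a <- ies(panel_target, decay, max_ext)
  b <- ies(panel_other, decay, max_ext)
  x <- ifelse(b == 0, NA_real_, log(a / b))
  x[!is.finite(x)] <- NA_real_
  if (standardize) x <- (x - median(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  x
}

#' One-sided empirical p-values (large = extreme)
#'
#' p_i = rank-from-top / (N + 1) with average ranks on ties, over the
#' non-missing values, so p is strictly inside (0,1) and usable inside the
#' CMS factor.
#'
#' @param x numeric vector of statistics (NAs propagate).
#' @return p-values in (0,1).
#' @export
empirical_p <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  N <- sum(ok)
  p <- rep(NA_real_, length(x))
  p[ok] <- (N + 1 - rank(x[ok], ties.method = "average")) / (N + 1)
  p
}

#' Composite of multiple signals (CMS) score
#'
#' Combines the empirical p-values of several selection statistics under a
#' prior fraction `pi` of selected sites.  The per-test posterior factor is
#' f_i = (1 - p_i) pi / ((1 - p_i) pi + p_i (1 - pi)).  The default
#' `"odds"` form is the product over tests of the posterior odds
#' f_i / (1 - f_i), an unbounded, strictly monotone transform of the
#' bounded posterior product (`form = "posterior"`); `"log10"` returns
#' log10 of the odds product.  SNPs missing any p-value get NA.
#'
#' @param p matrix of p-values (SNPs x tests), each strictly in (0,1).
#' @param prior prior fraction of selected sites (default 0.01).
#' @param form score form.
#' @return per-SNP CMS score.
#' @export
cms_score <- function(p, prior = 0.01,
                      form = c("odds", "posterior", "log10")) {
  form <- match.arg(form)
  p <- as.matrix(p)
  stopifnot(prior > 0, prior < 1)
  if (any(p <= 0 | p >= 1, na.rm = TRUE)) {
    stop("p-values must lie strictly inside (0,1)")
  }
  log_odds <- log((1 - p) * prior) - log(p * (1 - prior))
  s <- rowSums(log_odds)  # NA if any test missing
  switch(form,
         odds = exp(s),
         log10 = s / log(10),
         posterior = {
           f <- 1 / (1 + exp(-log_odds))
           exp(rowSums(log(f)))
         })
}

#' Per-SNP selection statistics and CMS for a target population
#'
#' Computes DAF, the DAF difference against the mean of the other
#' populations, Weir-Cockerham FST of target versus the pooled others,
#' lnRsb of target versus the pooled others, their one-sided empirical
#' p-values, and the combined CMS score.
#'
#' @param panels named list of `haplotype_panel` lists (population ->
#'   chromosome), as produced by [simulate_haplotypes()].
#' @param target target population label.
#' @param prior CMS prior fraction.
#' @param decay,max_ext lnRsb internals, see [ies()].
#' @param form CMS score form, see [cms_score()].
#' @return data frame of class `snp_stats`: chrom, pos, daf, ddaf, fst,
#'   lnrsb, p_* columns and cms.
#' @export
snp_stats <- function(panels, target, prior = 0.01, decay = 0.05,
                      max_ext = 5e5, form = "odds") {
  stopifnot(target %in% names(panels))
  others <- setdiff(names(panels), target)
  out <- list()
  for (ch in names(panels[[target]])) {
    pt <- panels[[target]][[ch]]
    po <- lapply(others, function(p) panels[[p]][[ch]])
    pooled <- pool_panels(po, population = "OTHERS")
    daf_t <- snp_daf(pt)
    ddaf <- delta_daf(daf_t, vapply(po, snp_daf, numeric(ncol(pt$H))))
    fst <- fst_per_snp(pt, pooled)
    lnrsb <- ln_rsb(pt, pooled, decay = decay, max_ext = max_ext)
    out[[ch]] <- data.frame(chrom = ch, pos = pt$positions, daf = daf_t,
                            ddaf = ddaf, fst = fst, lnrsb = lnrsb,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  # empirical p-values are genome-wide (across chromosomes)
  tab$p_daf <- empirical_p(tab$daf)
  tab$p_ddaf <- empirical_p(tab$ddaf)
  tab$p_fst <- empirical_p(tab$fst)
  tab$p_lnrsb <- empirical_p(tab$lnrsb)
  tab$cms <- cms_score(as.matrix(tab[c("p_daf", "p_ddaf", "p_fst",
                                       "p_lnrsb")]),
                       prior = prior, form = form)
  attr(tab, "target") <- target
  attr(tab, "prior") <- prior
  attr(tab, "form") <- form
  class(tab) <- c("snp_stats", "data.frame")
  tab
}

#' Call candidate selection regions from CMS scores
#'
#' Top SNPs are those with CMS at or above `cms_threshold` (or, when
#' `top_fraction` is given, the top fraction of finite CMS scores -- the
#' scan is rank-based, so threshold semantics are configurable).  Top SNPs
#' less than `max_gap` bp apart on the same chromosome are chained into a
#' region; single-SNP regions are dropped; the peak SNP is the member with
#' the highest CMS (leftmost on ties).
#'
#' @param stats a `snp_stats` data frame.
#' @param cms_threshold absolute CMS cutoff (default 10).
#' @param top_fraction if non-NULL, rank cutoff instead: keep this top
#'   fraction of SNPs by CMS.
#' @param max_gap chaining distance in bp (strict inequality, default
#'   10 kb).
#' @return data frame of regions: chrom, start, end, n_snps, peak_pos,
#'   peak_cms.
#' @export
call_regions <- function(stats, cms_threshold = 10, top_fraction = NULL,
                         max_gap = 10000) {
  cms <- stats$cms
  if (!is.null(top_fraction)) {
    ok <- which(!is.na(cms))
    k <- max(1L, floor(length(ok) * top_fraction))
    cut <- sort(cms[ok], decreasing = TRUE)[k]
    top <- !is.na(cms) & cms >= cut
  } else {
    top <- !is.na(cms) & cms >= cms_threshold
  }
  regions <- list()
  for (ch in unique(stats$chrom)) {
    idx <- which(top & stats$chrom == ch)
    if (length(idx) < 2) next
    pos <- stats$pos[idx]
    o <- order(pos)
    idx <- idx[o]; pos <- pos[o]
    grp <- cumsum(c(1, diff(pos) >= max_gap))
    for (g in unique(grp)) {
      members <- idx[grp == g]
      if (length(members) < 2) next  # singletons removed
      mcms <- stats$cms[members]
      peak <- members[which.max(mcms)]  # leftmost on ties
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = min(stats$pos[members]),
        end = max(stats$pos[members]), n_snps = length(members),
        peak_pos = stats$pos[peak], peak_cms = stats$cms[peak],
        stringsAsFactors = FALSE)
    }
  }
  if (length(regions) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      peak_pos = numeric(0), peak_cms = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, regions)
}

#' Assign a candidate gene to each region peak
#'
#' The gene whose span contains the peak SNP wins; otherwise the gene with
#' the nearest boundary within `max_dist` bp (leftmost start on ties);
#' otherwise none (NA).
#'
#' @param regions region data frame from [call_regions()].
#' @param genes gene annotation data frame (gene, chrom, start, end).
#' @param max_dist maximum peak-to-boundary distance, bp (default 20 kb).
#' @return `regions` with a `gene` column added.
#' @export
assign_gene <- function(regions, genes, max_dist = 20000) {
  regions$gene <- NA_character_
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], ]
    if (nrow(g) == 0) next
    g <- g[order(g$start), ]
    peak <- regions$peak_pos[i]
    inside <- g$start <= peak & g$end >= peak
    if (any(inside)) {
      regions$gene[i] <- g$gene[which(inside)[1]]
      next
    }
    d <- pmax(g$start - peak, peak - g$end)  # distance to nearest boundary
    j <- which(d <= max_dist)
    if (length(j)) regions$gene[i] <- g$gene[j[which.min(d[j])]]
  }
  regions
}

#' Length-free candidate gene assignment (gene midpoints)
#'
#' Gene-length control: every gene is represented by its midpoint and every
#' region by its peak position; a region is assigned the gene whose
#' midpoint is nearest to the peak, if within `max_dist` bp.
#'
#' @param regions region data frame from [call_regions()].
#' @param genes gene annotation data frame with `midpoint`.
#' @param max_dist peak-to-midpoint threshold, bp (default 150 kb).
#' @return `regions` with a `gene` column added.
#' @export
assign_gene_lengthfree <- function(regions, genes, max_dist = 150000) {
  if (is.null(genes$midpoint)) genes$midpoint <- (genes$start + genes$end) / 2
  regions$gene <- NA_character_
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], ]
    if (nrow(g) == 0) next
    g <- g[order(g$start), ]
    d <- abs(g$midpoint - regions$peak_pos[i])
    if (min(d) <= max_dist) regions$gene[i] <- g$gene[which.min(d)]
  }
  regions
}

#' Deduplicated candidate gene set from assigned regions
#'
#' One entry per gene; when several regions hit the same gene the highest
#' peak CMS is kept.
#'
#' @param regions regions with a `gene` column (from [assign_gene()] or
#'   [assign_gene_lengthfree()]).
#' @param population optional population label carried as an attribute.
#' @return data frame of class `candidate_genes`: gene, peak_cms.
#' @export
candidate_genes <- function(regions, population = NULL) {
  keep <- regions[!is.na(regions$gene), , drop = FALSE]
  if (nrow(keep)) {
    keep <- keep[order(keep$gene, -keep$peak_cms), ]
    keep <- keep[!duplicated(keep$gene), c("gene", "peak_cms")]
    rownames(keep) <- NULL
  } else {
    keep <- data.frame(gene = character(0), peak_cms = numeric(0))
  }
  attr(keep, "population") <- population
  class(keep) <- c("candidate_genes", "data.frame")
  keep
}

#' Candidate genes by per-gene peak CMS rank
#'
#' Rank-based alternative candidate definition: each gene is scored by the
#' maximum CMS over its SNPs and the top `top_n` genes are returned.  Used
#' for calibration studies where the absolute CMS threshold is not
#' meaningful.
#'
#' @param stats a `snp_stats` data frame.
#' @param snp_gene gene id per SNP row of `stats` (layout `snps$gene`).
#' @param top_n number of genes to keep.
#' @return a `candidate_genes` data frame.
#' @export
candidate_genes_by_rank <- function(stats, snp_gene, top_n) {
  stopifnot(length(snp_gene) == nrow(stats))
  ok <- !is.na(stats$cms)
  peak <- tapply(stats$cms[ok], snp_gene[ok], max)
  peak <- sort(peak, decreasing = TRUE)
  top <- peak[seq_len(min(top_n, length(peak)))]
  out <- data.frame(gene = names(top), peak_cms = as.numeric(top),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("candidate_genes", "data.frame")
  out
}
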