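#' Run the selection scan and map regions to candidate genes
#'
#' Convenience driver: per-SNP statistics and CMS for the target
#' population, region calling, gene assignment (boundary rule or the
#' length-free midpoint rule), and deduplication into a candidate gene
#' set.
#'
#' @param panels named list (population -> chromosome) of
#'   `haplotype_panel` objects.
#' @param target target population label.
#' @param genes gene annotation data frame.
#' @param cms_threshold absolute CMS cutoff (used when `top_fraction` is
#'   NULL).
#' @param top_fraction rank cutoff: keep this top fraction of SNPs by CMS.
#' @param lengthfree use midpoint assignment within 150 kb instead of the
#'   containment / nearest-within-20-kb rule.
#' @param ... passed to [snp_stats()].
#' @return list of class `selection_scan`: `stats` (per-SNP table),
#'   `regions`, `candidates` (a `candidate_genes` data frame).
#' @export
scan_selection <- function(panels, target, genes, cms_threshold = 10,
                           top_fraction = NULL, lengthfree = FALSE, ...) {
  st <- snp_stats(panels, target, ...)
  reg <- call_regions(st, cms_threshold = cms_threshold,
                      top_fraction = top_fraction)
  reg <- if (lengthfree) {
    assign_gene_lengthfree(reg, genes)
  } else {
    assign_gene(reg, genes)
  }
  structure(list(stats = st, regions = reg,
                 candidates = candidate_genes(reg, population = target)),
            class = "selection_scan")
}

#' @export
print.selection_scan <- function(x, ...) {
  cat(sprintf(paste0("<selection_scan> %s: %d SNPs scanned, %d regions, ",
                     "%d candidate genes\n"),
              attr(x$stats, "target"), nrow(x$stats), nrow(x$regions),
              nrow(x$candidates)))
  invisible(x)
}
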