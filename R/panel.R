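#' Phased haplotype panel for one population and one chromosome
#'
#' The container used by every per-SNP statistic.  Alleles are coded
#' 0 = ancestral, 1 = derived; rows are haplotypes, columns are SNPs in
#' strictly increasing 1-based physical position.
#'
#' @param H integer matrix, haplotypes x SNPs, entries 0/1.
#' @param positions integer vector of 1-based bp positions, strictly
#'   increasing, one per SNP column.
#' @param population population label.
#' @param chrom chromosome label.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(H, positions, population = "POP", chrom = "1") {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  if (nrow(H) < 2L) stop("a haplotype panel needs at least 2 haplotypes")
  if (ncol(H) != length(positions)) {
    stop("positions must have one entry per SNP column")
  }
  if (any(is.na(H)) || !all(H %in% c(0L, 1L))) {
    stop("allele matrix entries must be 0 (ancestral) or 1 (derived)")
  }
  positions <- as.numeric(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  structure(
    list(H = H, positions = positions,
         population = as.character(population), chrom = as.character(chrom)),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s chr%s: %d haplotypes x %d SNPs (%s-%s bp)\n",
              x$population, x$chrom, nrow(x$H), ncol(x$H),
              format(min(x$positions), scientific = FALSE),
              format(max(x$positions), scientific = FALSE)))
  invisible(x)
}

#' @export
dim.haplotype_panel <- function(x) dim(x$H)

#' Pool several panels of the same chromosome into one
#'
#' Used for target-vs-pooled-others comparisons: haplotypes are stacked,
#' sites must agree.
#'
#' @param ... `haplotype_panel` objects sharing positions and chromosome.
#' @param population label for the pooled panel.
#' @return a `haplotype_panel`.
#' @export
pool_panels <- function(..., population = "POOLED") {
  panels <- list(...)
  if (length(panels) == 1L && is.list(panels[[1]]) &&
      !inherits(panels[[1]], "haplotype_panel")) {
    panels <- panels[[1]]
  }
  stopifnot(length(panels) >= 1L)
  pos <- panels[[1]]$positions
  for (p in panels) {
    if (!identical(p$positions, pos) || !identical(p$chrom, panels[[1]]$chrom)) {
      stop("panels to pool must share chromosome and positions")
    }
  }
  haplotype_panel(do.call(rbind, lapply(panels, `[[`, "H")), pos,
                  population = population, chrom = panels[[1]]$chrom)
}
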