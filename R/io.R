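#' Write haplotype panels as a phased VCF
#'
#' One multi-sample VCF over the shared sites of the panels: consecutive
#' haplotype pairs of each population become phased diploid samples
#' (`0|1`-style GT), the ancestral allele is recorded in the INFO field as
#' `AA=`.  The ancestral allele is written as REF (A) and the derived
#' allele as ALT (G).
#'
#' @param panels named list of `haplotype_panel` objects (one population
#'   each) over identical sites, or a population -> chromosome nested list.
#' @param path output path (plain text `.vcf`).
#' @param sample_map_path optional path for a two-column population/sample
#'   TSV.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(panels, path, sample_map_path = NULL) {
  if (inherits(panels[[1]], "haplotype_panel")) {
    panels <- lapply(panels, function(p) stats::setNames(list(p), p$chrom))
  }
  pops <- names(panels)
  samples <- character(0)
  pop_of <- character(0)
  for (pop in pops) {
    n <- nrow(panels[[pop]][[1]]$H)
    if (n %% 2 != 0) stop("need an even haplotype count to form diploids")
    s <- sprintf("%s_%03d", pop, seq_len(n / 2))
    samples <- c(samples, s)
    pop_of <- c(pop_of, rep(pop, length(s)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (ch in names(panels[[1]])) {
    pos <- panels[[pops[1]]][[ch]]$positions
    gt <- do.call(rbind, lapply(pops, function(pop) {
      H <- panels[[pop]][[ch]]$H
      odd <- seq(1, nrow(H), by = 2)
      matrix(paste(H[odd, , drop = FALSE], H[odd + 1, , drop = FALSE],
                   sep = "|"),
             nrow = nrow(H) / 2, byrow = FALSE)
    }))
    lines <- paste(ch, format(pos, scientific = FALSE, trim = TRUE), ".",
                   "A", "G", ".", "PASS", "AA=A", "GT",
                   apply(gt, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  if (!is.null(sample_map_path)) {
    write.table(data.frame(sample = samples, population = pop_of),
                sample_map_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read phased haplotype panels from a VCF
#'
#' Reads a phased VCF with `vcfR`, recodes alleles to 0 = ancestral / 1 =
#' derived using the `AA` INFO annotation (sites without AA, or where AA
#' matches neither allele, are dropped with a message), and splits samples
#' into populations.
#'
#' @param path VCF path.
#' @param pop_map either a named character vector (sample -> population) or
#'   the path of a two-column sample/population TSV.
#' @return named list (population -> chromosome) of `haplotype_panel`
#'   objects.
#' @export
read_panels_vcf <- function(path, pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1 && file.exists(pop_map)) {
    m <- read.table(pop_map, sep = "\t", stringsAsFactors = FALSE)
    pop_map <- stats::setNames(m[[2]], m[[1]])
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info <- vcfR::extract.info(v, "AA")
  keep <- !is.na(info) & (info == fix[, "REF"] | info == fix[, "ALT"])
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("dropped %d site(s) without usable AA annotation",
                    n_drop))
  }
  gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  info <- info[keep]
  derived_is_alt <- info == fix[, "REF"]
  samples <- colnames(gt)
  if (!all(samples %in% names(pop_map))) {
    stop("pop_map must cover every VCF sample")
  }
  panels <- list()
  for (pop in unique(pop_map[samples])) {
    smp <- samples[pop_map[samples] == pop]
    panels[[pop]] <- list()
    for (ch in unique(fix[, "CHROM"])) {
      rows <- fix[, "CHROM"] == ch
      sub <- gt[rows, smp, drop = FALSE]
      a1 <- substr(sub, 1, 1) == "1"
      a2 <- substr(sub, 3, 3) == "1"
      H <- matrix(0L, nrow = 2 * length(smp), ncol = sum(rows))
      H[seq(1, nrow(H), 2), ] <- t(a1) * 1L
      H[seq(2, nrow(H), 2), ] <- t(a2) * 1L
      flip <- !derived_is_alt[rows]  # derived allele is REF there
      if (any(flip)) H[, flip] <- 1L - H[, flip]
      panels[[pop]][[ch]] <- haplotype_panel(
        H, as.numeric(fix[rows, "POS"]), population = pop, chrom = ch)
    }
  }
  panels
}

#' Write gene annotations as BED
#'
#' 0-based half-open intervals with the gene id in the name column.
#'
#' @param genes annotation data frame (gene, chrom, start, end; 1-based
#'   inclusive).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(genes, path) {
  write.table(data.frame(genes$chrom,
                         format(genes$start - 1, scientific = FALSE,
                                trim = TRUE),
                         format(genes$end, scientific = FALSE, trim = TRUE),
                         genes$gene),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene annotations from BED or GFF
#'
#' Uses `rtracklayer` to import the file (BED's 0-based half-open
#' coordinates become 1-based inclusive) and returns the annotation data
#' frame used throughout the package.
#'
#' @param path BED or GFF path.
#' @param name_field attribute holding the gene id for GFF input.
#' @return data frame: gene, chrom, start, end, midpoint.
#' @export
read_genes <- function(path, name_field = "Name") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_genes() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  nm <- if ("name" %in% names(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)$name
  } else if (name_field %in% names(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)[[name_field]]
  } else {
    stop("no gene name column found")
  }
  out <- data.frame(gene = as.character(nm),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out$midpoint <- (out$start + out$end) / 2
  out
}

#' Write a network as a two-column tab-separated edge list
#'
#' @param g an igraph graph with named vertices.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_edgelist(g)
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a network in the HPRD flat-file dialect
#'
#' Tab-separated with the interactor symbols in columns 1 and 4 (the other
#' columns carry placeholder identifiers), matching the layout of the HPRD
#' binary protein-protein interaction flat file so round trips through
#' [read_ppi()] with `dialect = "hprd-flat"` are exact.
#'
#' @param g an igraph graph with named vertices.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_hprd_flat <- function(g, path) {
  el <- igraph::as_edgelist(g)
  write.table(data.frame(el[, 1], "-", "-", el[, 2], "-", "-", "in vivo",
                         "-"),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write per-SNP statistics, regions, or enrichment profiles as TSV
#'
#' @param x a data frame (e.g. `snp_stats`, region table, or
#'   `enrichment_profile`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
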