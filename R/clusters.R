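#' Connected subnetworks formed by candidate genes
#'
#' Induced subgraph of the network on the candidate genes; its connected
#' components (one-step interactions among candidates), sorted by size,
#' descending.
#'
#' @param candidates candidate gene ids or a `candidate_genes` data frame.
#' @param g an igraph graph with named vertices (typically the LCC).
#' @return list with `graph` (the induced subgraph) and `components`
#'   (list of sorted gene-id vectors, largest first).
#' @export
candidate_subnetworks <- function(candidates, g) {
  if (is.data.frame(candidates)) candidates <- candidates$gene
  candidates <- unique(candidates)
  if (!all(candidates %in% igraph::V(g)$name)) {
    stop("all candidates must be network nodes")
  }
  sub <- igraph::induced_subgraph(g, candidates)
  comp <- igraph::components(sub)
  comps <- split(igraph::V(sub)$name, comp$membership)
  comps <- lapply(comps, sort)
  comps <- comps[order(-lengths(comps),
                       vapply(comps, `[`, "", 1L))]
  names(comps) <- NULL
  list(graph = sub, components = comps)
}

#' Syn-thresholded coselection clusters
#'
#' Keeps the one-step edges among candidate genes whose Syn score is
#' strictly higher than `threshold`, and returns the connected components
#' of the filtered graph together with the fraction of coselection edges
#' retained.  Isolated candidates (no retained edge) are not reported as
#' clusters.
#'
#' @param g the network (igraph, named vertices).
#' @param candidates candidate gene ids or a `candidate_genes` data frame.
#' @param table a `divergence_trees` data frame supplying Syn scores.
#' @param threshold keep edges with Syn > threshold.
#' @return object of class `syn_clusters`: `clusters` (list; each has
#'   `members`, `edges` data frame with syn), `retained_fraction`,
#'   `threshold`.
#' @export
syn_clusters <- function(g, candidates, table, threshold) {
  if (is.data.frame(candidates)) candidates <- candidates$gene
  sub <- candidate_subnetworks(candidates, g)$graph
  el <- igraph::as_edgelist(sub)
  n_edges <- nrow(el)
  if (n_edges == 0) {
    return(structure(list(clusters = list(), retained_fraction = NA_real_,
                          threshold = threshold), class = "syn_clusters"))
  }
  D <- tree_matrix(table)
  med <- attr(table, "medians")
  sds <- attr(table, "sds")
  ia <- match(el[, 1], table$gene)
  ib <- match(el[, 2], table$gene)
  if (anyNA(ia) || anyNA(ib)) {
    stop("Syn scores unavailable for some candidate edges")
  }
  Z <- sweep(sweep(D, 2, med), 2, sds, "/")
  syn_edge <- rowMeans(Z[ia, , drop = FALSE] * Z[ib, , drop = FALSE])
  keep <- syn_edge > threshold  # strictly higher than the threshold
  fil <- igraph::delete_edges(sub, which(!keep))
  fil <- igraph::delete_vertices(fil, which(igraph::degree(fil) == 0))
  clusters <- list()
  if (igraph::vcount(fil) > 0) {
    comp <- igraph::components(fil)
    for (ci in seq_len(comp$no)) {
      members <- sort(igraph::V(fil)$name[comp$membership == ci])
      csub <- igraph::induced_subgraph(fil, members)
      cel <- igraph::as_edgelist(csub)
      es <- vapply(seq_len(nrow(cel)), function(e) {
        syn_edge[(el[, 1] == cel[e, 1] & el[, 2] == cel[e, 2]) |
                   (el[, 1] == cel[e, 2] & el[, 2] == cel[e, 1])][1]
      }, 0)
      clusters[[length(clusters) + 1L]] <- list(
        members = members,
        edges = data.frame(a = cel[, 1], b = cel[, 2], syn = es,
                           stringsAsFactors = FALSE))
    }
    clusters <- clusters[order(-vapply(clusters,
                                       function(cl) length(cl$members), 0L))]
  }
  structure(list(clusters = clusters,
                 retained_fraction = sum(keep) / n_edges,
                 threshold = threshold),
            class = "syn_clusters")
}

#' @export
print.syn_clusters <- function(x, ...) {
  cat(sprintf("<syn_clusters> %d cluster(s) at Syn > %g (%.0f%% of edges retained)\n",
              length(x$clusters), x$threshold,
              100 * x$retained_fraction))
  for (cl in x$clusters) {
    cat(sprintf("  [%d genes / %d edges] %s\n", length(cl$members),
                nrow(cl$edges),
                paste(utils::head(cl$members, 8), collapse = " ")))
  }
  invisible(x)
}

#' Annotate a coselection cluster with selection and topology information
#'
#' Attaches each member's CMS score and within-cluster degree, and flags
#' the hub(s) (maximal within-cluster degree; ties flag all) and the peak
#' (maximal CMS) member.
#'
#' @param cluster one element of `syn_clusters()$clusters` (list with
#'   `members` and `edges`).
#' @param cms named numeric vector of CMS scores (e.g., peak CMS per
#'   candidate gene).
#' @return the cluster with a `nodes` data frame added: gene, cms, degree,
#'   is_hub, is_peak.
#' @export
annotate_cluster <- function(cluster, cms) {
  stopifnot(length(cluster$members) >= 1)
  deg <- stats::setNames(numeric(length(cluster$members)), cluster$members)
  if (nrow(cluster$edges)) {
    t1 <- table(c(cluster$edges$a, cluster$edges$b))
    deg[names(t1)] <- as.numeric(t1)
  }
  node_cms <- cms[cluster$members]
  nodes <- data.frame(gene = cluster$members,
                      cms = as.numeric(node_cms),
                      degree = as.numeric(deg),
                      is_hub = deg == max(deg),
                      is_peak = FALSE,
                      stringsAsFactors = FALSE)
  if (all(is.na(nodes$cms))) {
    nodes$is_peak[1] <- TRUE
  } else {
    nodes$is_peak[which.max(nodes$cms)] <- TRUE
  }
  cluster$nodes <- nodes
  cluster
}

#' Export cluster gene lists for external enrichment tools
#'
#' Writes one plain-text symbol list per cluster (uppercased,
#' deduplicated) plus a summary TSV (cluster id, size, edge count, mean
#' Syn, hub, peak).  The lists are inputs for web enrichment services; the
#' enrichment itself is outside this package.
#'
#' @param clusters a `syn_clusters` object (clusters should be annotated
#'   for hub/peak columns; unannotated clusters get NA there).
#' @param dir output directory (created if needed).
#' @return invisibly, the summary data frame.
#' @export
export_gene_lists <- function(clusters, dir) {
  stopifnot(inherits(clusters, "syn_clusters"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (ci in seq_along(clusters$clusters)) {
    cl <- clusters$clusters[[ci]]
    symbols <- sort(unique(toupper(cl$members)))
    writeLines(symbols, file.path(dir, sprintf("cluster_%02d.txt", ci)))
    hub <- peak <- NA_character_
    if (!is.null(cl$nodes)) {
      hub <- paste(cl$nodes$gene[cl$nodes$is_hub], collapse = ",")
      peak <- cl$nodes$gene[cl$nodes$is_peak][1]
    }
    rows[[ci]] <- data.frame(cluster = ci, size = length(symbols),
                             n_edges = nrow(cl$edges),
                             mean_syn = mean(cl$edges$syn),
                             hub = hub, peak = peak,
                             stringsAsFactors = FALSE)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), size = integer(0), n_edges = integer(0),
               mean_syn = numeric(0), hub = character(0),
               peak = character(0), stringsAsFactors = FALSE)
  write.table(summary, file.path(dir, "clusters_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(summary)
}
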