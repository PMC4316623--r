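#' Read a protein-protein interaction network
#'
#' Supported dialects: `"edgelist"` (two tab-separated symbol columns),
#' `"sif"` (node, interaction type, partner nodes), and `"hprd-flat"` (the
#' HPRD binary-interaction flat file: tab-separated, interactor symbols in
#' columns 1 and 4).  Symbols are uppercased; self-loops and duplicate
#' edges are removed (counts reported via message).
#'
#' @param path file path.
#' @param dialect one of `"edgelist"`, `"sif"`, `"hprd-flat"`.
#' @return an undirected simple igraph graph with named vertices.
#' @export
read_ppi <- function(path, dialect = c("edgelist", "sif", "hprd-flat")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pairs <- switch(dialect,
    "edgelist" = {
      f <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(f) < 2)
      if (length(bad)) stop(sprintf("malformed edge-list line %d", bad[1]))
      cbind(vapply(f, `[`, "", 1L), vapply(f, `[`, "", 2L))
    },
    "sif" = {
      f <- strsplit(lines, "[\t ]+")
      bad <- which(lengths(f) < 3)
      if (length(bad)) stop(sprintf("malformed SIF line %d", bad[1]))
      do.call(rbind, lapply(f, function(x) {
        cbind(x[1], x[3:length(x)])
      }))
    },
    "hprd-flat" = {
      f <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(f) < 4)
      if (length(bad)) stop(sprintf("malformed HPRD flat-file line %d", bad[1]))
      cbind(vapply(f, `[`, "", 1L), vapply(f, `[`, "", 4L))
    })
  pairs <- matrix(toupper(trimws(pairs)), ncol = 2)
  self <- pairs[, 1] == pairs[, 2]
  n_self <- sum(self)
  pairs <- pairs[!self, , drop = FALSE]
  if (nrow(pairs) == 0) stop("empty graph after removing self-loops")
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  n_dup <- igraph::ecount(g)
  g <- igraph::simplify(g)
  n_dup <- n_dup - igraph::ecount(g)
  if (n_self + n_dup > 0) {
    message(sprintf("removed %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))
  }
  g
}

#' Largest connected component
#'
#' Node-maximal connected component; ties broken deterministically by the
#' lexicographically smallest sorted node-name set.
#'
#' @param g an igraph graph with named vertices.
#' @return the induced subgraph on the largest component, with graph
#'   attribute `is_lcc = TRUE`.
#' @export
ppi_lcc <- function(g) {
  stopifnot(igraph::vcount(g) > 0)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    keysets <- vapply(best, function(b) {
      paste(sort(igraph::V(g)$name[comp$membership == b]), collapse = "\r")
    }, "")
    best <- best[order(keysets)[1]]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  sub <- igraph::permute(sub, match(igraph::V(sub)$name,
                                    sort(igraph::V(sub)$name)))
  igraph::graph_attr(sub, "is_lcc") <- TRUE
  sub
}

#' Degree and betweenness centrality of every node
#'
#' Degree = number of first neighbors.  Betweenness follows the igraph
#' convention for undirected graphs: for each unordered node pair (s,t) the
#' transit count through v is split among equally short paths
#' (sigma_st(v) / sigma_st) and summed, unnormalized.
#'
#' @param g an igraph graph (typically an LCC).
#' @return data frame: gene, dc, bc (rows sorted by gene).
#' @export
ppi_centralities <- function(g) {
  out <- data.frame(gene = igraph::V(g)$name,
                    dc = as.numeric(igraph::degree(g)),
                    bc = igraph::betweenness(g, directed = FALSE,
                                             weights = NA),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

#' All-pairs shortest path lengths of a connected graph
#'
#' BFS from every node; the network mean SPL is the average over unordered
#' distinct pairs.
#'
#' @param g a connected igraph graph.
#' @return object of class `spl_index`: `d` (symmetric integer matrix with
#'   node-name dimnames), `mean_spl`, `nodes`.
#' @export
ppi_spl <- function(g) {
  if (!igraph::is_connected(g)) stop("SPL index requires a connected graph")
  nodes <- sort(igraph::V(g)$name)
  d <- igraph::distances(g, algorithm = "unweighted")
  d <- d[nodes, nodes]
  structure(list(d = d, mean_spl = mean(d[upper.tri(d)]), nodes = nodes),
            class = "spl_index")
}

#' @export
print.spl_index <- function(x, ...) {
  cat(sprintf("<spl_index> %d nodes, mean SPL %.3f, max SPL %d\n",
              length(x$nodes), x$mean_spl, max(x$d)))
  invisible(x)
}

#' Partition nodes into betweenness strata
#'
#' Peripheral (BC <= cuts[1]), intermediate (cuts[1] < BC <= cuts[2]) and
#' core (BC > cuts[2]) node sets; the default cuts (100, 20000) follow the
#' convention of splitting a curated PPI network into periphery,
#' intermediate shell, and core.  Downstream SPL analyses within a stratum
#' reuse the global distances.
#'
#' @param centralities data frame from [ppi_centralities()].
#' @param cuts two increasing BC cut points.
#' @return named list of gene-id vectors: peripheral, intermediate, core.
#' @export
bc_strata <- function(centralities, cuts = c(100, 20000)) {
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2])
  bc <- centralities$bc
  list(peripheral = centralities$gene[bc <= cuts[1]],
       intermediate = centralities$gene[bc > cuts[1] & bc <= cuts[2]],
       core = centralities$gene[bc > cuts[2]])
}

#' Remove network edges between genomically close genes
#'
#' Linkage-disequilibrium control: deletes every edge whose two endpoint
#' genes lie on the same chromosome with midpoints closer than `window` bp.
#' Nodes without coordinates keep their edges (their count is reported).
#' The graph may fragment; rerun [ppi_lcc()] downstream.
#'
#' @param g an igraph graph with named vertices.
#' @param genes annotation data frame (gene, chrom, start, end, optionally
#'   midpoint).
#' @param window midpoint-distance threshold in bp (default 500 kb).
#' @return the filtered graph, with attributes `n_removed` and
#'   `n_unlocated`.
#' @export
filter_ld_edges <- function(g, genes, window = 5e5) {
  if (is.null(genes$midpoint)) genes$midpoint <- (genes$start + genes$end) / 2
  el <- igraph::as_edgelist(g)
  i <- match(el[, 1], genes$gene)
  j <- match(el[, 2], genes$gene)
  unlocated <- unique(c(el[, 1][is.na(i)], el[, 2][is.na(j)]))
  located <- !is.na(i) & !is.na(j)
  drop <- located &
    genes$chrom[i] == genes$chrom[j] &
    abs(genes$midpoint[i] - genes$midpoint[j]) < window
  drop[is.na(drop)] <- FALSE
  out <- igraph::delete_edges(g, which(drop))
  igraph::graph_attr(out, "n_removed") <- sum(drop)
  igraph::graph_attr(out, "n_unlocated") <- length(unlocated)
  if (length(unlocated)) {
    message(sprintf("%d node(s) without coordinates kept all their edges",
                    length(unlocated)))
  }
  out
}
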