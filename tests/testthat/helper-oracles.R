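# Independent brute-force oracles.  These deliberately re-derive each
# quantity from first principles, without touching the package's code paths.

# --- graph oracles ---------------------------------------------------------

adj_matrix <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  dimnames(A) <- list(igraph::V(g)$name, igraph::V(g)$name)
  A
}

# all-pairs shortest path lengths by Floyd-Warshall
spl_floyd <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  D <- ifelse(A, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# betweenness by exhaustive enumeration of all shortest paths
bc_brute <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  D <- spl_floyd(g)
  bc <- stats::setNames(numeric(n), rownames(A))
  paths_to <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (w in which(A[, t] & D[s, ] == D[s, t] - 1)) {
      for (p in paths_to(s, w)) out <- c(out, list(c(p, t)))
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      ps <- paths_to(s, t)
      for (p in ps) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(ps)
      }
    }
  }
  bc
}

# connected components by union-find
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(match(edges[e, 1], nodes))
      rj <- find(match(edges[e, 2], nodes))
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(nodes), find, 0)
  split(nodes, roots)
}

# --- population-genetics oracles -------------------------------------------

# two-population haploid Weir-Cockerham theta-hat, written out longhand
wc_oracle <- function(p1, p2, n1, n2) {
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (2 - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / ((n1 - 1) + (n2 - 1))
  nc <- (N - (n1^2 + n2^2) / N) / (2 - 1)
  (msp - msg) / (msp + (nc - 1) * msg)
}

# EHHS by direct pair counting over all C(n,2) haplotype pairs
ehhs_brute <- function(H, core, direction) {
  n <- nrow(H)
  S <- ncol(H)
  idx <- if (direction == 1) core:S else core:1
  vapply(seq_len(length(idx) - 1), function(d) {
    cols <- idx[1:(d + 1)]
    cnt <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (all(H[i, cols] == H[j, cols])) cnt <- cnt + 1
      }
    }
    cnt / choose(n, 2)
  }, 0)
}

# iES by trapezoid integration of the brute-force EHHS profile
ies_brute <- function(H, pos, decay = 0.05, max_ext = 5e5) {
  S <- ncol(H)
  vapply(seq_len(S), function(core) {
    total <- 0
    for (dir in c(-1, 1)) {
      prof <- ehhs_brute(H, core, dir)
      eprev <- 1
      pprev <- pos[core]
      j <- core + dir
      d <- 1
      while (j >= 1 && j <= S && abs(pos[j] - pos[core]) <= max_ext) {
        e <- prof[d]
        total <- total + 0.5 * (eprev + e) * abs(pos[j] - pprev)
        eprev <- e
        pprev <- pos[j]
        if (e < decay) break
        j <- j + dir
        d <- d + 1
      }
    }
    total
  }, 0)
}

# Benjamini-Hochberg step-up, written out longhand
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in rev(seq_len(n - 1))) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# per-test CMS posterior factor and both score forms, one-liner arithmetic
cms_oracle <- function(p, prior, form = "odds") {
  f <- (1 - p) * prior / ((1 - p) * prior + p * (1 - prior))
  if (form == "posterior") prod(f) else prod(f / (1 - f))
}

# --- fixtures --------------------------------------------------------------

rand_panel <- function(n = 8, S = 12, seed = 1, spacing = 500,
                       population = "POP") {
  set.seed(seed)
  H <- matrix(rbinom(n * S, 1, runif(S, 0.2, 0.8)[rep(seq_len(S),
                                                      each = n)]),
              n, S)
  haplotype_panel(H, seq_len(S) * spacing, population = population)
}

# small deterministic study shared by several test files
small_study <- function(seed = 5, n_sweep = 0, n_genes = 80,
                        snps_per_gene = 9) {
  simulate_study(sim_config(n_genes = n_genes, genes_per_chrom = n_genes,
                            snps_per_gene = snps_per_gene,
                            n_haplotypes = 60, n_sweep_genes = n_sweep,
                            seed = seed))
}
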