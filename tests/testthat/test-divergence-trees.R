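# a hand-built tree table with known cohort constants
toy_tree_table <- function(D1, D2 = D1, D3 = D1, genes = NULL,
                           medians = NULL, sds = NULL) {
  tab <- data.frame(gene = genes %||% sprintf("g%02d", seq_along(D1)),
                    D1 = D1, D2 = D2, D3 = D3, stringsAsFactors = FALSE)
  attr(tab, "medians") <- medians %||% apply(tab[, c("D1", "D2", "D3")], 2,
                                             median)
  attr(tab, "sds") <- sds %||% apply(tab[, c("D1", "D2", "D3")], 2, sd)
  class(tab) <- c("divergence_trees", "data.frame")
  tab
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gene-level FST reduces to the per-SNP estimator and the oracle", {
  sim <- small_study(seed = 19, n_sweep = 0, n_genes = 15, snps_per_gene = 1)
  tab <- gene_fst(sim$panels, sim$genes)
  per_snp <- fst_per_snp(sim$panels$EAS[["1"]], sim$panels$CEU[["1"]])
  idx <- match(tab$gene, sim$snps$gene)
  expect_equal(tab$fst_12, per_snp[idx])
  # two SNPs with hand-set counts: ratio of per-SNP sums
  p1 <- c(0.9, 0.3); p2 <- c(0.1, 0.25)
  n1 <- 20; n2 <- 30
  num <- den <- 0
  for (s in 1:2) {
    N <- n1 + n2; pbar <- (n1 * p1[s] + n2 * p2[s]) / N
    msp <- n1 * (p1[s] - pbar)^2 + n2 * (p2[s] - pbar)^2
    msg <- (n1 * p1[s] * (1 - p1[s]) + n2 * p2[s] * (1 - p2[s])) / (N - 2)
    nc <- N - (n1^2 + n2^2) / N
    num <- num + msp - msg
    den <- den + msp + (nc - 1) * msg
  }
  expect_equal(wc_fst(cbind(p1, p2), c(n1, n2), ratio_of_sums = TRUE),
               num / den, tolerance = 1e-12)
  # permuting SNP order leaves the ratio of sums unchanged
  expect_equal(wc_fst(cbind(rev(p1), rev(p2)), c(n1, n2),
                      ratio_of_sums = TRUE),
               wc_fst(cbind(p1, p2), c(n1, n2), ratio_of_sums = TRUE))
})

test_that("trifurcate branch lengths follow the three-point formula", {
  D <- trifurcate_tree(0.10, 0.12, 0.08)
  expect_equal(unname(D[1, ]), c(0.07, 0.03, 0.05))
  # equal pairwise FST: all branches are half of it
  expect_equal(unname(trifurcate_tree(0.2, 0.2, 0.2)[1, ]),
               rep(0.1, 3))
  # additivity holds to machine precision for random inputs
  set.seed(14)
  f12 <- rnorm(50, 0.1, 0.05); f13 <- rnorm(50, 0.1, 0.05)
  f23 <- rnorm(50, 0.1, 0.05)
  D <- trifurcate_tree(f12, f13, f23)
  expect_equal(D[, "D1"] + D[, "D2"], f12, tolerance = 1e-15)
  expect_equal(D[, "D1"] + D[, "D3"], f13, tolerance = 1e-15)
  expect_equal(D[, "D2"] + D[, "D3"], f23, tolerance = 1e-15)
})

test_that("RTD is a normalized mean rank distance, symmetric and rank-based", {
  tab <- toy_tree_table(D1 = c(0.1, 0.5, 0.3),
                        D2 = c(0.2, 0.1, 0.6),
                        D3 = c(0.4, 0.2, 0.1))
  # ranks: D1 = (1,3,2), D2 = (2,1,3), D3 = (3,2,1)
  expect_equal(rtd("g01", "g02", tab, normalize = FALSE),
               (2 + 1 + 1) / 3)
  expect_equal(rtd("g01", "g03", tab, normalize = FALSE),
               (1 + 1 + 2) / 3)
  expect_equal(rtd("g01", "g01", tab, normalize = FALSE), 0)
  expect_equal(rtd("g02", "g01", tab), rtd("g01", "g02", tab))
  # invariant under any monotone transform of D within a population
  tab2 <- toy_tree_table(D1 = exp(c(0.1, 0.5, 0.3)),
                         D2 = c(0.2, 0.1, 0.6)^3,
                         D3 = 10 * c(0.4, 0.2, 0.1))
  expect_equal(rtd("g01", "g02", tab2, normalize = FALSE),
               rtd("g01", "g02", tab, normalize = FALSE))
})

test_that("Syn scores standardized residual products with hand values", {
  med <- c(D1 = 0.1, D2 = 0.2, D3 = 0.3)
  sds <- c(D1 = 0.05, D2 = 0.08, D3 = 0.02)
  tab <- toy_tree_table(D1 = c(0.1, 0.1 + 0.05, 0.1 - 0.05, 0.4),
                        D2 = c(0.2, 0.2 + 0.08, 0.2 - 0.08, 0.5),
                        D3 = c(0.3, 0.3 + 0.02, 0.3 - 0.02, 0.6),
                        medians = med, sds = sds)
  # both genes at the median tree: zero
  expect_equal(syn("g01", "g01", tab), 0)
  # both one SD above the median in every population: unit score
  expect_equal(syn("g02", "g02", tab), 1)
  # one SD above vs one SD below everywhere: minus one
  expect_equal(syn("g02", "g03", tab), -1)
  # symmetry
  expect_equal(syn("g02", "g04", tab), syn("g04", "g02", tab))
  tab0 <- toy_tree_table(D1 = c(0.1, 0.2), sds = c(D1 = 0, D2 = 1, D3 = 1))
  expect_error(syn("g01", "g02", tab0), "degenerate")
})

test_that("divergence trees from panels keep exact additivity per gene", {
  sim <- small_study(seed = 23, n_sweep = 0, n_genes = 30, snps_per_gene = 6)
  tab <- divergence_trees(sim$panels, sim$genes)
  expect_gt(nrow(tab), 20)
  expect_equal(tab$D1 + tab$D2, tab$fst_12, tolerance = 1e-12)
  expect_equal(tab$D1 + tab$D3, tab$fst_13, tolerance = 1e-12)
  expect_equal(tab$D2 + tab$D3, tab$fst_23, tolerance = 1e-12)
})

test_that("tree similarity profile is normalized and calibrated under the null", {
  sim <- small_study(seed = 27, n_sweep = 0, n_genes = 60,
                     snps_per_gene = 6)
  lcc <- ppi_lcc(sim$network)
  spl <- ppi_spl(lcc)
  tab <- divergence_trees(sim$panels, sim$genes, universe = spl$nodes)
  prof <- tree_similarity_vs_spl(tab, spl, n_perm = 300, seed = 3,
                                 pool_at = 6)
  # normalized RTD: pair-weighted mean 0, second moment 1 over all pairs
  w <- prof$profile$n_pairs
  expect_equal(sum(w * prof$profile$mean_rtd) / sum(w), 0, tolerance = 1e-8)
  # reshuffling null keeps Syn centred near zero: each bin's null mean sits
  # within 3 SE of the exact finite-population cross-pair expectation, which
  # is itself tiny (residuals are median-centred, not mean-centred)
  D <- as.matrix(tab[match(intersect(tab$gene, spl$nodes), tab$gene),
                     c("D1", "D2", "D3")])
  med <- apply(D, 2, median); sds <- apply(D, 2, sd)
  Z <- sweep(sweep(D, 2, med), 2, sds, "/")
  m <- nrow(Z)
  e_pair <- mean((colSums(Z)^2 - colSums(Z^2)) / (m * (m - 1)))
  expect_lt(abs(e_pair), 0.05)
  se <- apply(prof$null_syn, 2, sd) / sqrt(nrow(prof$null_syn))
  expect_true(all(abs(colMeans(prof$null_syn) - e_pair) < 3 * se))
  # RTD and Syn order pairs in opposite directions
  D <- as.matrix(tab[, c("D1", "D2", "D3")])
  R <- apply(D, 2, rank)
  med <- apply(D, 2, median); sds <- apply(D, 2, sd)
  Z <- sweep(sweep(D, 2, med), 2, sds, "/")
  m <- nrow(D)
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  rtd_raw <- rowMeans(abs(R[ut[, 1], ] - R[ut[, 2], ]))
  syn_v <- rowMeans(Z[ut[, 1], ] * Z[ut[, 2], ])
  expect_lt(cor(rtd_raw, syn_v, method = "spearman"), 0)
})
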