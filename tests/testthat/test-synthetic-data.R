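test_that("frequency model collapses to the ancestral frequency as drift vanishes", {
  cfg <- sim_config(n_genes = 50, genes_per_chrom = 50, snps_per_gene = 4,
                    drift_f = 1e-6, n_sweep_genes = 0, seed = 3)
  fr <- simulate_frequencies(cfg)
  for (pop in cfg$populations) {
    expect_lt(max(abs(fr$freq[, pop] - fr$p0)), 0.01)
  }
})

test_that("identical configs give byte-identical simulations", {
  cfg <- sim_config(n_genes = 30, genes_per_chrom = 30, snps_per_gene = 6,
                    n_haplotypes = 40, n_sweep_genes = 4, seed = 17)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$freqs$freq, b$freqs$freq)
  expect_identical(lapply(a$panels, function(p) p[["1"]]$H),
                   lapply(b$panels, function(p) p[["1"]]$H))
  expect_identical(igraph::as_edgelist(a$network),
                   igraph::as_edgelist(b$network))
  expect_identical(a$truth, b$truth)
})

test_that("pairwise differentiation matches the Monte-Carlo drift oracle", {
  # frequency-level oracle: Beta draws at F, frequencies rounded to counts
  F <- 0.02; n <- 200
  set.seed(71)
  p0 <- runif(40000, 0.05, 0.95)
  q1 <- round(n * rbeta(40000, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)) / n
  q2 <- round(n * rbeta(40000, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)) / n
  oracle <- mean(wc_oracle(q1, q2, n, n), na.rm = TRUE)
  cfg <- sim_config(n_genes = 2000, genes_per_chrom = 2000,
                    snps_per_gene = 5, drift_f = F, n_sweep_genes = 0,
                    seed = 42)
  sim <- simulate_study(cfg)
  got <- mean(fst_per_snp(sim$panels$EAS[["1"]], sim$panels$CEU[["1"]]),
              na.rm = TRUE)
  expect_lt(abs(got - oracle), 0.004)
})

test_that("K = 1 founder gives identical haplotypes and flat EHHS", {
  cfg <- sim_config(n_genes = 10, genes_per_chrom = 10, snps_per_gene = 8,
                    founders_k = 1, n_haplotypes = 20, n_sweep_genes = 0,
                    seed = 2)
  panels <- simulate_haplotypes(cfg, simulate_frequencies(cfg))
  H <- panels$EAS[["1"]]$H
  expect_true(all(apply(H, 2, function(col) length(unique(col)) == 1)))
  prof <- ehhs(panels$EAS[["1"]], core = 40, direction = 1)
  expect_true(all(prof == 1))
})

test_that("zero switch rate makes every haplotype an exact founder copy", {
  cfg <- sim_config(n_genes = 10, genes_per_chrom = 10, snps_per_gene = 8,
                    founders_k = 4, switch_rate = 0, match_freq = FALSE,
                    n_haplotypes = 30, n_sweep_genes = 0, seed = 8)
  panels <- simulate_haplotypes(cfg, simulate_frequencies(cfg))
  H <- panels$CEU[["1"]]$H
  expect_lte(nrow(unique(H)), 4)
})

test_that("linkage disequilibrium decays with distance under the defaults", {
  cfg <- sim_config(n_genes = 8, genes_per_chrom = 8, snps_per_gene = 120,
                    n_haplotypes = 120, n_sweep_genes = 0, seed = 2)
  panels <- simulate_haplotypes(cfg, simulate_frequencies(cfg))
  p <- panels$EAS[["1"]]
  # brute-force r^2 between sampled SNP pairs, binned by distance
  set.seed(1)
  i <- sample(ncol(p$H), 8000, replace = TRUE)
  j <- sample(ncol(p$H), 8000, replace = TRUE)
  keep <- i != j & apply(cbind(i, j), 1, function(ij) {
    sd(p$H[, ij[1]]) > 0 && sd(p$H[, ij[2]]) > 0
  })
  i <- i[keep]; j <- j[keep]
  r2 <- vapply(seq_along(i), function(k) {
    cor(p$H[, i[k]], p$H[, j[k]])^2
  }, 0)
  d <- abs(p$positions[i] - p$positions[j])
  bins <- cut(d, c(0, 6000, 24000, 80000, Inf))
  m <- tapply(r2, bins, mean)
  expect_true(all(diff(m) < 0))
})

test_that("a complete sweep fixes the core allele and maximizes FST against an ancestral population", {
  panel <- rand_panel(n = 40, S = 21, seed = 9)
  gene <- data.frame(start = 5000, end = 6000)
  # make the central SNP rare so it is eligible as the sweep core
  panel$H[, 11] <- 0L
  panel$H[1, 11] <- 1L
  res <- plant_sweep(panel, gene, beta = 1, seed = 4)
  expect_true(res$planted)
  expect_equal(unname(colMeans(res$panel$H)[res$core_snp]), 1)
  other <- rand_panel(n = 40, S = 21, seed = 10)
  other$H[, res$core_snp] <- 0L  # q = 0 in the unswept population
  expect_equal(fst_per_snp(res$panel, other)[res$core_snp], 1)
})

test_that("sweeping below the current frequency is a warned no-op", {
  panel <- rand_panel(n = 20, S = 11, seed = 3)
  panel$H[, 4:8] <- 1L  # every in-gene SNP already fixed derived
  gene <- data.frame(start = 2000, end = 4000)
  expect_warning(res <- plant_sweep(panel, gene, beta = 0.5),
                 "below current frequency")
  expect_false(res$planted)
  expect_identical(res$panel$H, panel$H)
})

test_that("a planted sweep pushes core lnRsb beyond the genome-wide 99th percentile", {
  # the extremeness threshold is calibrated once on the null (unswept)
  # panel, on the raw lnRsb scale: standardizing a swept scan by its own
  # sweep-inflated SD would compress the very signal under test
  hits <- 0
  for (s in 1:50) {
    cfg <- sim_config(n_genes = 120, genes_per_chrom = 120,
                      snps_per_gene = 15, n_haplotypes = 100,
                      n_sweep_genes = 0, seed = 100 + s)
    sim <- simulate_study(cfg)
    gene <- sim$genes[60, ]
    pooled <- pool_panels(sim$panels$CEU[["1"]], sim$panels$YRI[["1"]])
    q99 <- quantile(ln_rsb(sim$panels$EAS[["1"]], pooled,
                           standardize = FALSE), 0.99, na.rm = TRUE)
    res <- plant_sweep(sim$panels$EAS[["1"]], gene, beta = 0.9,
                       seed = 200 + s)
    x <- ln_rsb(res$panel, pooled, standardize = FALSE)
    hits <- hits + (x[res$core_snp] > q99)
  }
  expect_gte(hits, 45)
})

test_that("no planted sweeps means empty ground truth", {
  sim <- small_study(seed = 4, n_sweep = 0)
  expect_length(sim$truth$swept_genes$EAS, 0)
})

test_that("preferential attachment with m = 1 yields a tree", {
  cfg <- sim_config(n_genes = 200, genes_per_chrom = 200, network_m = 1,
                    n_sweep_genes = 0, seed = 6)
  net <- simulate_network(cfg, sprintf("G%04d", 1:200))
  expect_equal(igraph::ecount(net$graph), 199)
  expect_true(igraph::is_connected(net$graph))
})

test_that("planted radius-1 cluster members sit within two network steps", {
  cfg <- sim_config(n_genes = 300, genes_per_chrom = 300,
                    n_sweep_genes = 12, seed = 21)
  net <- simulate_network(cfg, sprintf("G%04d", 1:300))
  d <- igraph::distances(net$graph)
  for (cl in net$truth$clusters) {
    if (length(cl) < 2) next
    expect_lte(max(d[cl, cl]), 2)
  }
})

test_that("scale-free degree distribution is heavier-tailed than Poisson", {
  cfg <- sim_config(n_genes = 1000, genes_per_chrom = 1000, network_m = 3,
                    n_sweep_genes = 0, seed = 9)
  net <- simulate_network(cfg, sprintf("G%04d", 1:1000))
  deg <- igraph::degree(net$graph)
  expect_gt(var(deg) / mean(deg), 2)
})
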