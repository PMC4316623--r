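test_that("derived allele frequencies are simple column means", {
  H <- rbind(c(0, 1), c(0, 1), c(0, 1), c(0, 0))
  p <- haplotype_panel(H, c(100, 200))
  expect_equal(unname(snp_daf(p)), c(0, 0.75))
})

test_that("delta DAF follows the target-minus-mean-of-others convention", {
  expect_equal(delta_daf(0.5, cbind(0.5, 0.5)), 0)
  expect_equal(delta_daf(0.9, cbind(0.1, 0.3)), 0.7)
  # two populations: swapping roles flips the sign
  expect_equal(delta_daf(0.8, 0.3), -delta_daf(0.3, 0.8))
})

test_that("Weir-Cockerham FST matches the longhand oracle", {
  # fixed difference with large equal samples
  expect_equal(wc_fst(cbind(1, 0), c(50, 50)), 1)
  # equal frequencies: non-positive by construction
  expect_lte(wc_fst(cbind(0.4, 0.4), c(30, 30)), 0)
  # monomorphic in all populations: undefined
  expect_true(is.na(wc_fst(cbind(0, 0), c(30, 30))))
  # toy counts against the independent oracle, to 1e-12
  expect_equal(wc_fst(cbind(0.8, 0.2), c(10, 10)),
               wc_oracle(0.8, 0.2, 10, 10), tolerance = 1e-12)
  set.seed(20)
  p1 <- runif(50); p2 <- runif(50)
  expect_equal(wc_fst(cbind(p1, p2), c(14, 38)),
               wc_oracle(p1, p2, 14, 38), tolerance = 1e-12)
})

test_that("EHHS equals brute-force pair counting and never increases", {
  H <- rbind(c(1, 0, 1), c(1, 0, 1), c(0, 0, 1), c(0, 1, 1))
  p <- haplotype_panel(H, c(100, 200, 300))
  expect_equal(ehhs(p, 1, 1), ehhs_brute(H, 1, 1))
  expect_equal(ehhs(p, 3, -1), ehhs_brute(H, 3, -1))
  # identical haplotypes: profile stays 1
  pid <- haplotype_panel(matrix(1L, 5, 4), 1:4 * 10)
  expect_true(all(ehhs(pid, 2, 1) == 1))
  # non-increasing on random panels
  for (s in 1:5) {
    rp <- rand_panel(n = 12, S = 15, seed = s)
    prof <- ehhs(rp, 5, 1)
    expect_true(all(diff(prof) <= 1e-12))
    expect_equal(prof, ehhs_brute(rp$H, 5, 1))
  }
})

test_that("iES and lnRsb agree with the brute-force integration oracle", {
  # tiny worked panel: 6 haplotypes, 5 SNPs
  H <- rbind(c(1, 1, 0, 0, 1),
             c(1, 1, 0, 0, 1),
             c(1, 0, 0, 1, 0),
             c(0, 0, 1, 1, 0),
             c(0, 0, 1, 0, 0),
             c(0, 1, 1, 0, 1))
  pos <- c(1000, 1800, 2400, 3600, 5000)
  p <- haplotype_panel(H, pos, population = "A")
  expect_equal(ies(p), ies_brute(H, pos))
  q <- rand_panel(n = 6, S = 5, seed = 31)
  q$positions <- pos
  expect_equal(ies(q), ies_brute(q$H, pos))
  # identical panels: unstandardized lnRsb is 0 at every SNP
  expect_true(all(ln_rsb(p, p, standardize = FALSE) == 0))
  # standardized scores: median 0, SD 1
  big <- rand_panel(n = 30, S = 60, seed = 7)
  big2 <- rand_panel(n = 30, S = 60, seed = 8)
  x <- ln_rsb(big, big2)
  expect_equal(median(x, na.rm = TRUE), 0)
  expect_equal(sd(x, na.rm = TRUE), 1)
})

test_that("empirical p-values are top ranks over N + 1 with average ties", {
  x <- c(5, 1, 3, 2, 9, 8, 7, 6, 4)
  expect_equal(empirical_p(x)[x == 9], 0.1)
  expect_equal(empirical_p(rep(2, 6)), rep(0.5, 6))
  # a shuffled vector gets the same p-values, shuffled
  set.seed(2)
  y <- rnorm(25)
  perm <- sample(25)
  expect_equal(empirical_p(y)[perm], empirical_p(y[perm]))
  expect_error(empirical_p(c(NA, 1)), "non-missing")
})

test_that("CMS matches direct arithmetic and is monotone in each p-value", {
  # symmetry point: one test with p equal to the prior
  expect_equal(cms_score(matrix(0.01), prior = 0.01, form = "odds"), 1)
  expect_equal(cms_score(matrix(0.01), prior = 0.01, form = "posterior"),
               0.5)
  # prior to zero drives the score to zero
  expect_lt(cms_score(matrix(0.2), prior = 1e-9), 1e-6)
  # worked four-test example against the one-line oracle, both forms
  p4 <- c(0.001, 0.01, 0.05, 0.2)
  expect_equal(cms_score(matrix(p4, 1), prior = 0.01, form = "odds"),
               cms_oracle(p4, 0.01, "odds"))
  expect_equal(cms_score(matrix(p4, 1), prior = 0.01, form = "posterior"),
               cms_oracle(p4, 0.01, "posterior"))
  expect_equal(cms_score(matrix(p4, 1), prior = 0.01, form = "log10"),
               log10(cms_oracle(p4, 0.01, "odds")))
  # decreasing any single p strictly increases the score
  base <- cms_score(matrix(p4, 1), prior = 0.01)
  for (i in 1:4) {
    lower <- p4; lower[i] <- lower[i] / 2
    expect_gt(cms_score(matrix(lower, 1), prior = 0.01), base)
  }
  expect_error(cms_score(matrix(c(0, 0.5), 1)), "strictly inside")
  expect_true(is.na(cms_score(matrix(c(NA, 0.5), 1))))
})

test_that("region calling chains top SNPs under 10 kb and drops singletons", {
  mk <- function(pos, cms) {
    structure(data.frame(chrom = "1", pos = pos, cms = cms),
              class = c("snp_stats", "data.frame"))
  }
  st <- mk(c(100, 5000, 30000), c(12, 15, 20))
  reg <- call_regions(st, cms_threshold = 10)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 100)
  expect_equal(reg$end, 5000)
  expect_equal(reg$peak_pos, 5000)
  # a gap of exactly 10 kb does not connect
  st2 <- mk(c(1000, 11000), c(12, 12))
  expect_equal(nrow(call_regions(st2, cms_threshold = 10)), 0)
  st3 <- mk(c(1000, 10999), c(12, 12))
  expect_equal(nrow(call_regions(st3, cms_threshold = 10)), 1)
  # nothing above threshold: empty, not an error
  expect_equal(nrow(call_regions(mk(c(1, 2), c(1, 2)), cms_threshold = 10)),
               0)
  # peak tie: leftmost member wins
  st4 <- mk(c(1000, 2000, 3000), c(11, 15, 15))
  expect_equal(call_regions(st4, cms_threshold = 10)$peak_pos, 2000)
})

test_that("gene assignment follows the containment then nearest-within-20kb rule", {
  genes <- data.frame(gene = c("A", "B"), chrom = "1",
                      start = c(10000, 40000), end = c(20000, 50000))
  reg <- function(peak) data.frame(chrom = "1", start = peak - 100,
                                   end = peak + 100, n_snps = 2,
                                   peak_pos = peak, peak_cms = 12)
  expect_equal(assign_gene(reg(15000), genes)$gene, "A")   # inside A
  expect_equal(assign_gene(reg(25000), genes)$gene, "A")   # 5 kb from A, 15 kb from B
  expect_equal(assign_gene(reg(32001), genes)$gene, "B")   # 12 kb from A, 8 kb from B
  expect_true(is.na(assign_gene(reg(75000), genes)$gene))  # 25 kb away
})

test_that("length-free assignment uses midpoints within 150 kb and deduplicates", {
  genes <- data.frame(gene = c("A", "B"), chrom = "1",
                      start = c(100000, 600000), end = c(120000, 620000))
  genes$midpoint <- (genes$start + genes$end) / 2
  reg <- data.frame(chrom = "1", start = 0, end = 0, n_snps = 2,
                    peak_pos = c(210000, 350000, 150000),
                    peak_cms = c(5, 7, 9))
  out <- assign_gene_lengthfree(reg, genes)
  expect_equal(out$gene, c("A", NA, "A"))  # 100 kb ok, 240 kb not, 40 kb ok
  cand <- candidate_genes(out)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$peak_cms, 9)  # max CMS kept on duplicates
})

test_that("scan statistics round-trip through phased VCF unchanged", {
  sim <- small_study(seed = 12, n_sweep = 0, n_genes = 12, snps_per_gene = 6)
  vcf <- tempfile(fileext = ".vcf")
  map <- tempfile(fileext = ".tsv")
  write_vcf(sim$panels, vcf, sample_map_path = map)
  back <- read_panels_vcf(vcf, map)
  for (pop in names(sim$panels)) {
    expect_identical(back[[pop]][["1"]]$H, sim$panels[[pop]][["1"]]$H)
    expect_equal(snp_daf(back[[pop]][["1"]]),
                 snp_daf(sim$panels[[pop]][["1"]]))
  }
})
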