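# netcosel

Genome-wide scans for recent positive selection routinely return hundreds
of candidate genes per population — far more independent adaptive events
than the short time since human populations diverged can comfortably
explain.  One resolution is **coselection**: selection signals that
co-occur among genes that interact, either because a change in one
protein exerts compensatory pressure on its physical partners
(coevolution) or because a whole pathway responds to the same external
pressure in parallel.  `netcosel` provides a tested pipeline for asking
this question: scan phased haplotype data from three populations for
selection, map the candidate genes onto a protein–protein interaction
(PPI) network, and test whether the signals cluster on that network.

The package is aimed at population geneticists with phased genotype
panels (VCF), gene annotations (BED/GFF) and a PPI network (HPRD flat
file, SIF or edge list), and at methodologists who want the statistics
with a ground-truthed simulator attached.

## The statistics at its core

**CMS (composite of multiple signals).**  For each SNP, four selection
statistics are computed for a target population: derived allele
frequency (DAF), the DAF difference against the other populations
(ΔDAF), Weir–Cockerham F<sub>ST</sub> against the pooled others, and
lnRsb (log-ratio of integrated site-specific extended haplotype
homozygosity, iES).  Each is turned into a one-sided empirical p-value
p<sub>i</sub> = rank/(N+1), and combined under a prior fraction π = 0.01
of selected sites through the posterior factor

    f_i = (1 - p_i) π / ((1 - p_i) π + p_i (1 - π))

with the default score being the product over tests of the posterior
odds f<sub>i</sub>/(1−f<sub>i</sub>).  Top SNPs chained within 10 kb form
candidate regions; region peaks map to candidate genes (containment,
else nearest boundary within 20 kb; a length-free 150-kb midpoint rule
is available).

**Network coselection.**  On the network's largest connected component:
Mann–Whitney and interval-enrichment tests of candidate centrality
(degree and betweenness), the mean shortest path length (SPL) among
candidate pairs versus equal-size resampled node sets, and per-SPL
relative coselection proportions

    relative(d) = P(both ends candidate | SPL = d) / [C(k,2) / C(n,2)]

whose Spearman trend against SPL is the headline clustering statistic.

**Divergence trees.**  Per gene, pairwise gene-level F<sub>ST</sub>
between the three populations defines a trifurcate tree with branch
lengths D<sub>i</sub> = ½(F<sub>ij</sub> + F<sub>ik</sub> −
F<sub>jk</sub>).  Similarity of two genes' recent evolutionary paths is
measured by the ranked tree distance (RTD, mean absolute rank difference
of divergence rates, normalized) and the synergy score (Syn, mean
standardized residual cross-product), profiled over SPL against a
within-population reshuffling null.  Syn-thresholded one-step subnetworks
of candidate genes are the exported coselection clusters.

## A worked example

Simulate a small three-population study with ten planted
network-adjacent sweeps in EAS, scan it, and test for coselection:

```r
library(netcosel)

cfg <- sim_config(n_genes = 300, genes_per_chrom = 100, snps_per_gene = 30,
                  n_sweep_genes = 10, seed = 42)
sim <- simulate_study(cfg)
#> <cosel_sim> 300 genes, 9000 SNPs, populations EAS/CEU/YRI; 10 swept genes
#>   in EAS; network: 300 nodes / 894 edges

scan <- scan_selection(sim$panels, "EAS", sim$genes, top_fraction = 0.005)
#> <selection_scan> EAS: 9000 SNPs scanned, 8 regions, 8 candidate genes
mean(sim$truth$swept_genes$EAS %in% scan$candidates$gene)
#> [1] 0.8

lcc <- ppi_lcc(sim$network)
spl <- ppi_spl(lcc)
ms <- mean_spl_test(scan$candidates$gene, spl, n_perm = 1999, seed = 1)
#> mean SPL among candidate pairs: 2.21 (network 3.05), p = 0.0015

sp <- spl_coselection(scan$candidates$gene, spl, n_perm = 1999, seed = 1,
                      pool_at = 5)
sp[, c("spl", "n_pairs", "n_copairs", "relative", "z", "p_adj")]
#>   spl n_pairs n_copairs   relative          z     p_adj
#> 1   1     894         7 12.5419463  8.0280097 0.0050000
#> 2   2    7750        10  2.0668203  1.8662805 0.2283333
#> 3   3   24643         9  0.5849966 -2.0100346 0.1800000
#> 4   4   11322         2  0.2829510 -1.3863890 0.2637500
#> 5  5+     241         0  0.0000000 -0.3407101 1.0000000
```

The eight candidate genes recover 8 of the 10 planted sweeps; candidate
pairs sit much closer on the network than random sets (mean SPL 2.21
versus 3.05, resampling p = 0.0015), and the relative coselection
proportion is 12.5-fold enriched at one interaction step, decaying below
1 by three steps — the planted coselection signature.

Divergence-tree similarity shows the same structure, and Syn-thresholded
clusters recover the planted groups:

```r
tab <- divergence_trees(sim$panels, sim$genes, universe = spl$nodes)
ts <- tree_similarity_vs_spl(tab, spl, n_perm = 500, seed = 1, pool_at = 5)
#> RTD~SPL: rho = 0.900 (p = 0.0833); Syn~SPL: rho = -0.600 (p = 0.35)
#> (adjacent genes: mean RTD -0.264, mean Syn +0.357, both p = 0.004)

syn_clusters(lcc, scan$candidates$gene, tab, threshold = 1.5)
#> <syn_clusters> 2 cluster(s) at Syn > 1.5 (100% of edges retained)
#>   [4 genes / 4 edges] G0002 G0006 G0023 G0113
#>   [4 genes / 3 edges] G0043 G0104 G0156 G0201
```

Real data enter through `read_panels_vcf()` (phased VCF with `AA`
ancestral-allele annotation plus a sample–population map),
`read_genes()` (BED/GFF) and `read_ppi()` (HPRD flat file, SIF, or
two-column edge list); `export_gene_lists()` writes cluster gene lists
for external enrichment services.

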