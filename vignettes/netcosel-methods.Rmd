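---
title: "Methods: scanning for recent selection and testing network coselection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning for recent selection and testing network coselection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`netcosel` implements a genome-wide scan for recent positive selection in
three populations and a set of network analyses asking whether the
selected genes co-occur on a protein–protein interaction (PPI) network —
*coselection*, whether through compensatory coevolution of interacting
partners or parallel selection on a shared pathway.  The pipeline has
five stages:

1. **Selection scan.** Per-SNP statistics — derived allele frequency
   (DAF), the DAF difference against the other populations (ΔDAF),
   Weir–Cockerham FST of the target against the pooled others, and the
   long-haplotype statistic lnRsb — are converted to one-sided empirical
   p-values and combined into a composite-of-multiple-signals (CMS)
   score.  Top SNPs are chained into candidate regions and mapped to
   candidate genes.
2. **Network statistics.** Degree centrality (DC), betweenness
   centrality (BC) and all-pairs shortest path lengths (SPL) on the
   largest connected component (LCC) of the PPI network.
3. **Coselection tests.** Centrality-interval enrichment of candidates,
   SPL-resolved coselection proportions, and the mean SPL among
   candidate pairs, each against resampling nulls of equal-size random
   node sets; Benjamini–Hochberg FDR across bins.
4. **Divergence trees.** Per-gene trifurcate trees from pairwise
   gene-level FST, compared between genes through the ranked tree
   distance (RTD) and the synergy score (Syn), profiled over SPL against
   a within-population reshuffling null.
5. **Clusters.** Connected subnetworks of candidate genes and
   Syn-thresholded coselection clusters, with exports for external
   enrichment tools.

A synthetic-data generator produces three-population haplotype panels
with planted sweeps and a scale-free network with planted coselection
clusters, so that every stage can be checked against a known ground
truth.

# The selection scan

## Per-SNP statistics

For a target population against the two others:

* **DAF**: the fraction of haplotypes carrying the derived allele.
* **ΔDAF**: target DAF minus the mean DAF of the other populations.
  The source method does not state its multi-population convention; the
  mean-of-others form is symmetric and is used throughout.
* **FST**: the Weir–Cockerham (1984) two-allele ANOVA estimator in its
  haploid (haplotype-count) formulation, target versus the pooled other
  populations.  Negative estimates are retained for ranking; SNPs
  monomorphic everywhere are undefined and excluded.
* **lnRsb**: ln of the ratio of integrated site-specific extended
  haplotype homozygosity (iES) between target and pooled others.  The
  EHHS profile from a core SNP is the probability that two random
  haplotypes are identical over every SNP from the core outward; iES is
  its trapezoid integral over physical distance, truncated where EHHS
  falls below 0.05 or at 500 kb per side (both configurable; the cited
  method leaves these dialect choices open).  Scores are
  genome-standardized (median subtracted, SD divided).

## Empirical p-values and CMS

Each statistic is ranked genome-wide, large values extreme:
`p = rank-from-top / (N + 1)` with average ranks on ties, so p is
strictly inside (0, 1).  With a prior fraction `π = 0.01` of the genome
under selection, the per-test posterior factor is

$$f_i = \frac{(1 - p_i)\,\pi}{(1 - p_i)\,\pi + p_i\,(1 - \pi)}.$$

The literal product of the bounded factors $f_i$ cannot exceed 1, yet
the method's operating point is "CMS ≥ 10"; the default score is
therefore the product of the posterior *odds* $f_i/(1-f_i)$ — a strictly
monotone per-factor transform of the bounded product that makes such
thresholds attainable — with the bounded posterior product and a log10
variant available as options.  Ranking is identical under all three
forms, and the scan is fundamentally rank-based: `call_regions()`
accepts either an absolute threshold or a top-fraction rank cutoff.

## Regions and genes

Top SNPs closer than 10 kb (strict) are chained; single-SNP regions are
dropped; the peak is the member with the highest CMS (leftmost on
ties).  A region's candidate gene is the gene whose span contains the
peak, else the gene with the nearest boundary within 20 kb (leftmost on
ties), else none.  A length-free alternative maps each peak to the
nearest gene *midpoint* within 150 kb, removing gene-length bias.  Genes
hit by several regions keep their maximum peak CMS.

# Network statistics

DC, BC and SPL are computed with igraph, the toolchain also used by the
analyses this package reproduces; BC follows the igraph convention
(transit counts split among equally short paths, unordered pairs,
unnormalized).  The test suite checks both against brute-force oracles
(exhaustive shortest-path enumeration; Floyd–Warshall) on every fixture
graph.  BC strata (peripheral ≤ 100 < intermediate ≤ 20,000 < core) let
analyses be repeated inside centrality layers while reusing the global
distances, and `filter_ld_edges()` removes one-step interactions between
genes less than 500 kb apart on the same chromosome to control for
genomic linkage.

# Coselection tests

All nulls are resampling nulls: node sets of the same size as the
candidate list drawn uniformly without replacement, 10,000 draws by
default.  Empirical p-values use the add-one rule
`(1 + #extreme) / (1 + n_perm)` and are two-sided by default (doubled
smaller tail, capped at 1); Z-scores are (observed − null mean) / null
SD.  For the SPL profile, the proportion of pairs at distance d with
both ends in the candidate set is normalized by the no-coselection
expectation `C(k,2)/C(n,2)`, so relative proportions above 1 mark
overrepresented coselection; their pair-count-weighted average equals 1
exactly (a conservation identity the tests assert).  Distances are
pooled into a tail bin (default 9+, configurable — analyses on small
simulated networks pool at 5+ because those graphs have diameter ~6).

Default centrality intervals (six DC bins, seven BC bins) approximate an
equal-occupancy split of a curated human PPI network and are fully
configurable.

# Divergence trees, RTD and Syn

Gene-level pairwise FST uses the Weir–Cockerham ratio-of-sums over the
SNPs inside the gene span.  The trifurcate tree assigns branch lengths

$$D_i = \tfrac12\left(F_{ij} + F_{ik} - F_{jk}\right),$$

so that $D_i + D_j = F_{ij}$ exactly; negative branch lengths are kept
(RTD is rank-based, Syn uses residuals).  RTD between two genes is the
mean absolute rank difference of their divergence rates across the three
populations, normalized to zero mean and unit variance over all pairs;
Syn is the mean standardized cross-product of their residuals from the
cohort median tree,

$$\mathrm{Syn} = \tfrac13 \sum_i
  \frac{(D_{ai} - D'_i)(D_{bi} - D'_i)}{\mathrm{SD}_i^2}.$$

The cohort (median $D'_i$ and $\mathrm{SD}_i$) is the set of
network-mapped genes, matching the reshuffling universe.  The null
reshuffles each population's divergence rates independently across
nodes; because all-pairs rank-distance multisets are invariant under
relabeling, the RTD normalization constants are shared between observed
and null draws.

**Known limitation.** Independent within-population reshuffling
destroys the within-gene coupling of the three branch lengths imposed by
the three-point formula, so observed bin means over-disperse mildly
relative to their own permutation bands: on simulated panels the 95%
bands cover ~92% (RTD ~90%, Syn ~94%), while the band machinery itself
is exact on independent columns.  The null is therefore slightly
anti-conservative per bin; conclusions should lean on the trend across
bins rather than single-bin significance.

# Coselection clusters

Candidate genes induce one-step subnetworks; edges whose Syn score is
strictly above a threshold are kept and the surviving connected
components are the coselection clusters.  The retained-edge fraction is
reported so users can calibrate thresholds the way the original analyses
did (thresholds retaining roughly a quarter to a third of coselection
interactions).  Each cluster is annotated with per-gene CMS,
within-cluster degree, its hub(s) (maximal within-cluster degree) and
its peak (maximal CMS); raising the threshold only ever refines clusters
(a monotonicity the tests assert).

# The synthetic-data generator

The generator emulates the statistical structure the pipeline consumes,
not human demography:

* **Frequencies.** Balding–Nichols drift: ancestral frequencies are
  Uniform(0.05, 0.95); each population's frequency is
  Beta(p₀(1−F)/F, (1−p₀)(1−F)/F).  The default F = 0.05 per population
  gives pairwise differentiation near the human continental scale
  (mean per-SNP Weir–Cockerham FST ≈ F/(1−F/2); ≈ 0.0142 at F = 0.02
  under frequency-matched sampling, verified against a Monte-Carlo
  oracle in the tests).
* **Haplotypes.** Recombination mosaics of K = 8 founders with a founder
  switch rate of 1e-5 per bp, then a minimal per-SNP perturbation to
  match the drawn frequencies; this yields linkage disequilibrium that
  decays with distance, so the long-haplotype statistic is informative.
  K = 1 and a zero switch rate are supported as degenerate cases (with
  frequency matching disabled they reproduce founders exactly).
* **Layout.** One gene = one SNP block: 150 SNPs at 200-bp spacing
  (~30 kb genes, sequencing-era SNP density), 20-kb intergenic flanks,
  100 genes per chromosome, 1,000 genes by default.
* **Sweeps.** A sweep copies one carrier haplotype over random
  haplotypes within the gene ± flank window until the core derived
  frequency reaches β = 0.9 in the target population.  The core is the
  SNP nearest the gene centre among sites at derived frequency ≤ 0.25 —
  a sweep models a *new* advantageous allele rising from low frequency;
  planting on an already-common allele would create no signal.  Sweeps
  whose target frequency is already reached are warned no-ops and are
  not recorded as swept.
* **Network and planted coselection.** Preferential attachment with
  m = 3 over the gene ids (heavy-tailed degree, connected).  Planted
  coselection chooses seed nodes and marks each seed plus part of its
  one-step neighborhood, at most 4 genes per cluster, until 20 genes are
  planted — several small pathway-like clusters, as coselection
  manifests in curated networks.
* **Pathway-level coselection.** When sweeps are planted the generator
  also emulates the two coselection mechanisms downstream analyses look
  for: (i) each gene's drift parameter is scaled by exp(u), where u is a
  Gaussian field (SD 0.6, clamped to |u| ≤ 1) smoothed twice over
  network neighbors, so network-adjacent genes genome-wide share
  correlated divergence rates; (ii) the one-step neighbors of swept
  genes receive *partial* sweeps (β = 0.35) in the target population —
  parallel pathway selection, elevating all four statistics moderately
  without competing with the strong sweeps at stringent cutoffs.  Null
  (no-sweep) studies have neither, so calibration experiments stay null.

What passing tests on this generator do **not** show: robustness to real
demography (growth, bottlenecks, migration), recurrent mutation,
background selection, SNP ascertainment, phasing error, or the biases of
literature-curated interactomes.  The generator's purpose is ground
truth for the statistics, not realism of human history.

# Problem sizes used in validation

Validation experiments are scaled to desk hardware and their sizes are
fixed in the test code: null calibration uses 200 studies of 500 genes
(5 SNPs each) with 200 haplotypes per population, 199-draw resampling
nulls, and tree-similarity calibration on a 150-gene universe with
199 reshuffles across 100 of those studies; signal recovery uses 20
studies at the full default conditions (1,000 genes × 150 SNPs, 20
planted sweeps).  The SPL-trend check uses the top 250 genes by peak-CMS
rank as its relaxed candidate list (the scan is rank-based; ~25% of the
simulated gene universe, versus ~10% of network nodes in the full-scale
human analyses) and pools SPL at 5+ because the simulated networks have
diameter ~6 (full-scale curated networks, diameter ~12, pool at 9+).
`scripts/acceptance.R` re-runs smaller versions of both experiments
(5 recovery and 40 null studies) from scratch under a user-supplied
seed.

# Numerical choices and tie-breaks

* Empirical p-values can never be 0 or 1 (rank/(N+1) with average ties),
  so the CMS factors are always finite.
* Region chaining uses strict `< 10 kb`; a gap of exactly 10 kb breaks a
  region.  Peak SNPs and gene assignment break ties leftmost.
* Resampling p-values use the add-one rule; degenerate nulls (zero SD)
  give Z = 0 when the observed equals the null value and NA otherwise.
* Syn requires positive residual SD in every population; a degenerate
  cohort is an error, not a silent NaN.
* The EHHS trapezoid includes the first segment whose far end falls
  below the decay threshold, and truncates hard at the maximal
  extension; chromosome edges truncate the integral (no reflection).
* All iteration orders are deterministic (sorted node names), and every
  stochastic operation takes an explicit seed.
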