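# mangrovebarcodes

A tidyverse-native R package for evaluating candidate DNA barcode markers in
plant communities. It was built with mangrove floras in mind — communities of
tens of species sampled at multiple coastal sites, sequenced for the four
classic plant barcoding loci (*rbcL*, ITS2, *matK*, *trnH-psbA*) with uneven
amplification success, occasional natural F1 hybrids, and subspecies-level
haplotype structure — but every function works on any aligned multi-marker
dataset with specimen metadata.

## What it computes

Given per-marker alignments and a specimen table (`specimen_id`, `species`,
`site_id`, …), the package scores every candidate barcode — each single
marker plus all multi-marker concatenations (4 markers → 15 candidates) —
with the three standard method families:

* **Genetic distance.** Pairwise Kimura 2-parameter distances
  `d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` (P, Q = transition and transversion
  proportions, pairwise deletion of gaps/ambiguities), partitioned into
  intra- and interspecific classes. A species shows a **barcode gap** when
  its minimum interspecific distance strictly exceeds its maximum
  intraspecific distance; the percentage of species with a gap is the
  headline distance-based score.
* **Similarity.** Leave-one-out **Best Match** (BM) and **Best Close Match**
  (BCM) identification: a query succeeds if its nearest neighbour is
  conspecific, is ambiguous on mixed-species ties, incorrect otherwise; BCM
  additionally demotes queries whose best match lies above a threshold
  (default: the interpolated 95th percentile of intraspecific distances) to
  *unidentified*.
* **Phylogeny.** Neighbor-joining trees on the K2P matrix with nonparametric
  bootstrap; a species counts as monophyletic when one tree bipartition
  separates exactly its individuals with support > 50%. When trees from
  other methods are supplied (Newick), the reported monophyly is the minimum
  across methods.

Around that core: per-population Watterson's θ and nucleotide diversity π,
within- vs between-population distance partitions, paired Wilcoxon
signed-rank marker comparisons with a common-language effect size
`W⁻/(W⁻+W⁺)` (exact p-values up to N = 25), F1 hybrid diagnosis from
heterozygous IUPAC sites at parental diagnostic columns plus chloroplast
matriline assignment, and haplotype collapsing over SNVs and indel runs.

A fully seeded community simulator (`simulate_community()`) generates
study-shaped datasets — Yule species tree, K2P sequence evolution with
per-marker rates and GC content, per-population coalescent diversity,
marker-specific recovery rates and indel events, F1 hybrids — together with
a ground-truth manifest, so the entire pipeline is testable without any
sequence download.

## Worked example

```r
library(mangrovebarcodes)

sim <- simulate_community(sim_config(n_species = 8, n_populations = 2,
                                     individuals_per_population = 3,
                                     n_hybrids = 1), seed = 2027)
d <- sim$dataset
d
#> <barcode_dataset>
#>   specimens: 49 | 9 species | 7 sites
#>   rbcL         49 sequences x   570 bp
#>   ITS2         43 sequences x   679 bp
#>   matK         35 sequences x   902 bp
#>   trnH-psbA    35 sequences x  1411 bp

ev <- evaluate_barcodes(d, boot_reps = 100, seed = 1)
ev[, c("barcode", "length", "gap_pct", "threshold", "bm_pct", "bcm_pct",
       "nj_monophyly_pct")]
#>    barcode length gap_pct threshold bm_pct bcm_pct nj_monophyly_pct
#> 1        I    679     100   0.00446    100   100.0              100
#> 2        R    570     100   0.00370    100   100.0              100
#> 3        M    902     100   0.00232    100    97.1              100
#> ...
#> 15 I+R+M+T   3562     100   0.00322    100   100.0              100
```

One row per candidate barcode (`I` = ITS2, `R` = *rbcL*, `M` = *matK*,
`T` = *trnH-psbA*; `I+R` is their concatenation). `gap_pct` is the percent
of species with a barcode gap, `threshold` the data-driven BCM ceiling,
`bm_pct`/`bcm_pct` the identification success rates, and
`nj_monophyly_pct` the percent of species forming supported clades. On this
simulated community every species is cleanly separable (values near 100);
counts differ per row because specimens missing a constituent marker are
dropped from that concatenation.

```r
hybrid_report(d, nuclear = "ITS2",
              chloroplast = c("rbcL", "matK", "trnH-psbA"))
#>   hybrid_id    parent1    parent2 n_diagnostic n_heterozygous fraction   call maternal_parent
#> 1     HYB01 Species_07 Species_08          303            303        1 called      Species_08
```

The simulated F1 is heterozygous at all 303 parental diagnostic sites and
its chloroplast matches its designated mother — both agree with the
simulator's truth manifest.

```r
compare_markers(d, "ITS2", "rbcL")
#> <marker_comparison> ITS2 vs rbcL: N = 28, W- = 406.0, W+ = 0.0
#>   p = 4e-06, common-language effect = 1.00, verdict: ITS2 >> rbcL
```

Across all 28 shared species pairs the ITS2-like marker is the more
divergent one, giving rank sums 406/0 and an effect size of 1.

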