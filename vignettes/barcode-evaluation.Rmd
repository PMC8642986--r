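---
title: "Methods: evaluating DNA barcodes for plant communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating DNA barcodes for plant communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangrovebarcodes)
```

This vignette is the package's own account of the statistical machinery it
implements, the choices made where conventions diverge, and what the
simulation-based tests do and do not establish about real data.

## The problem

A DNA barcode is a short genomic region used to assign specimens to species
by sequence comparison. For land plants no single locus is universally
sufficient, so community studies sequence several candidates — typically the
plastid coding regions *rbcL* and *matK*, the plastid spacer *trnH-psbA*,
and the nuclear ribosomal spacer ITS2 — and ask which locus, or which
concatenation, best discriminates the species actually present. The package
operationalises that question for a community dataset: per-marker aligned
sequences keyed by specimen, a metadata table mapping specimens to species,
groups, and collection sites, and three families of discrimination scores
computed per candidate barcode.

## Distances

All distances are Kimura 2-parameter (K2P):
$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$, with $P$ and $Q$
the proportions of transition- and transversion-type mismatches among
comparable sites. K2P is the field's convention for barcoding distances, so
the simulator (below) evolves sequences under the same two-rate process —
which also makes distance recovery analytically checkable.

Choices that the formula itself does not fix:

* **Pairwise deletion.** A site enters a pair's comparison only if both
  sequences carry an unambiguous base (`A/C/G/T`) there. Gaps, `N` and IUPAC
  ambiguity codes are excluded — K2P has no defined treatment for ambiguous
  observations, and treating `N` as evidence would bias hybrids and
  low-quality records.
* **Minimum overlap.** An entry backed by fewer than `min_overlap`
  comparable sites (default 50) is reported missing (`NA`) rather than
  trusted; for several-hundred-bp markers this floor only triggers on
  pathological gap patterns.
* **Saturation sentinel.** When $1-2P-Q \le 0$ or $1-2Q \le 0$ the
  logarithm is undefined; such pairs are flagged `Inf` and excluded from
  every min/max summary, mirroring how distance software reports such pairs
  as undefined rather than inventing a number.

The all-pairs matrix is computed via cross-products of base indicator
matrices (a few dense matrix multiplications) so community-scale inputs are
cheap; the scalar `k2p_distance()` is an independent code path used as the
per-pair reference in the tests.

## Barcode gap

For each species, `barcode_gap()` compares its maximum intraspecific
distance with its minimum distance to any heterospecific specimen (the
per-species reading of the classic scatter plot; the per-species-pair
variant exists in the literature, but per-species is standard practice and
is what the 1:1 scatter plot encodes). A gap requires the strict inequality
`min_inter > max_intra` — a point *on* the 1:1 line is not above it.
Species with a single sequence have no defined maximum intraspecific
distance and are excluded from the percentage denominator, which parallels
the "valid conspecifics" filter used for identification. The percentage is
reported to one decimal.

## Similarity identification

`best_match()` implements leave-one-out nearest-neighbour identification:
every sequence is a query against all others (no train/test split —
the standard protocol for this analysis). The verdict is *success* if all
closest matches are conspecific, *ambiguous* if the tie set mixes the
query's species with others, and *incorrect* if every closest match belongs
to other species — including ties among several wrong species, since the
query still matches "mismatched species names". Ties are distances equal
within 1e-12, i.e. exact up to floating-point noise. Only queries with at
least one conspecific in the pool are scored; a singleton can never be
matched correctly, so scoring it would measure sampling depth, not marker
quality.

`best_close_match()` adds a distance ceiling: a query whose best match lies
strictly above the threshold is *unidentified*; otherwise the Best Match
rules apply among the matches under the ceiling. Because the nearest match
drives the verdict, BCM can only demote BM verdicts — the BM ≥ BCM
inequality is structural, and the tests assert it across simulated
datasets.

The conventional "95% pairwise distance threshold" is ambiguous between
(a) the 95th percentile of intraspecific distances and (b) a fixed 5%
distance cutoff. The package implements (a) as the default
(`bcm_threshold()`, type-7 linear interpolation between order statistics,
matching `stats::quantile()`'s default and the common implementation) and
accepts any fixed cutoff via the `threshold`/`bcm_cutoff` arguments for
(b). Threshold units are K2P distance (substitutions per site).

## Trees and monophyly

`nj_tree()` wraps Saitou–Nei neighbor joining on the K2P matrix. The input
must be complete: missing or saturated entries are refused rather than
imputed, and `complete_distance()` greedily drops the specimens responsible
until the matrix is finite. Negative NJ branch lengths — an artifact of the
algebra, not a biological statement — are clamped to zero with the deficit
moved onto the adjacent ancestral branch, the standard cosmetic repair.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds an NJ tree per replicate, and annotates the point-estimate tree
(not a consensus tree; both conventions exist, and annotating the point
tree keeps a single topology for all downstream scoring) with the
percentage of replicates containing each internal bipartition. Support
attaches to bipartitions — unordered splits of the tip set — so rooting is
irrelevant; the tests assert invariance under re-rooting at random edges.
A zero-length internal edge carries no signal and is reported unresolved
(`NA`), so an all-identical alignment yields no supports at all. In
replicate trees, missing or saturated entries are capped at 1.5× the
largest finite distance; this only affects replicates, never the reported
point distances.

`monophyly_assess()` marks a species monophyletic when some bipartition
separates exactly its individuals and, when supports are present, that
edge's support strictly exceeds `min_support` (default 50%). Singletons
count as monophyletic by convention. When several trees are supplied (e.g.
externally built likelihood or Bayesian trees read via `read_newick()` —
tree *search* is deliberately out of scope), the evaluation reports the
minimum monophyly percentage across methods, the conservative choice. A
`partition_by` column reproduces the fallback of scoring trees within
taxon partitions (e.g. per order) when a global tree is unavailable; a
species alone in its partition counts as monophyletic.

## Multi-marker barcodes

`enumerate_barcodes()` generates all non-empty marker subsets — 15
candidates for 4 markers — named with the conventional single letters
(I = ITS2, R = *rbcL*, M = *matK*, T = *trnH-psbA*) in the canonical order
I, R, M, T. `concatenate_markers()` joins each individual's sequences
end-to-end. The default is complete-case: specimens missing any constituent
marker are dropped, because padding absentees with gaps would mix
pairwise-deletion denominators across markers in a way no protocol
specifies. `pad_missing = TRUE` provides the gap-padding variant for
sensitivity analysis. A concatenated K2P distance pools sites across
markers; it is *not* the mean of per-marker distances, and a test documents
that semantic difference on a worked pair.

## Population diversity

Per species × population (populations default to collection sites),
`diversity_table()` reports Watterson's estimator
$\hat\theta_W = S / (a_{n-1} L)$ with $a_{n-1} = \sum_{i=1}^{n-1} 1/i$, and
nucleotide diversity $\hat\pi$, the mean pairwise per-site p-distance. Both
are per site. $S$ and $L$ use complete deletion within the subset (columns
free of gaps/ambiguities), while $\hat\pi$ uses pairwise deletion — the
respective conventions of the two estimators. $\hat\pi$ deliberately uses
the p-distance, not K2P: π is defined as heterozygosity, not an evolutionary
distance. Records with fewer than `min_n = 3` sequences are skipped
(diversity from two individuals estimates little and is conventionally
omitted). `population_distance_partition()` splits intraspecific pairs into
within- and between-population classes for range-structure scatter plots.

## Marker-versus-marker rank tests

`compare_markers()` tests whether one marker is systematically more
divergent than another. The pairing unit is the **species pair**: each
marker contributes one summary value (by default the mean of all
cross-species sequence-pair distances) per unordered species pair, and
pairs present in both markers are compared by a Wilcoxon signed-rank test.
This unit is the only one consistent with fully-crossed designs, where the
number of paired observations equals $\binom{\text{species}}{2}$.

Zero differences are dropped; midranks handle ties; the p-value is exact
for N ≤ 25 — the full sign-flip null distribution of $W^+$ computed by
convolution over doubled (hence integer) midranks — and a normal
approximation with continuity and tie corrections beyond. The
common-language effect size is defined from rank sums,
$W^-/(W^- + W^+)$, so it is 0 when the second marker dominates every pair
and 1 when the first does. The tests check the exact p against brute-force
$2^N$ enumeration and against `stats::wilcox.test()` on tie-free data.

## Hybrid diagnosis and haplotypes

An F1 hybrid carries both parental alleles at nuclear loci, so at every
column where the parents are fixed for different bases the hybrid should
show the two-base IUPAC code of exactly that pair (A/G → R, C/T → Y,
A/C → M, G/T → K, A/T → W, C/G → S). `diagnostic_sites()` formalises this;
parental consensus is the strict-majority base per column, with columns
lacking an unambiguous majority excluded. `infer_parent_pair()` scores
every candidate species pair by its heterozygous fraction and calls the
maximiser when it has at least 3 diagnostic columns and a fraction ≥ 0.8
(real F1s sit at or near 1; the threshold is configurable and exact ties
are reported unresolved). `maternal_parent()` assigns the matriline to the
parent whose chloroplast consensus is closer to the hybrid's chloroplast
sequence, requiring a margin of at least one substitution. The package
operates on IUPAC-coded consensus sequences only; reading heterozygous
double peaks from chromatograms is upstream of its inputs.

`haplotype_collapse()` extracts variant columns across one or more markers
— single-nucleotide variants plus indels, where a maximal contiguous run of
gap-discordant columns counts as one indel event — and groups individuals
with identical variant states into haplotypes, the route used to show that
infraspecific taxa carry distinct haplotypes. Note that the indel-run
definition makes the haplotype *count* invariant to individual order but
not to arbitrary column permutations (which would fragment runs); the SNV
part alone is permutation-invariant.

## The community simulator

`simulate_community()` generates datasets shaped like a multi-site
community barcode survey, with a truth manifest for testing:

1. a Yule species tree (`n_species`, default 24; root-to-tip depth
   `tree_depth = 0.35` expected substitutions per site at rate 1, which
   puts maximum interspecific K2P distances in the 0.3–0.7 range observed
   for plant barcodes);
2. per-marker root sequences drawn with the marker's GC content and evolved
   along the tree under a two-rate transition/transversion process
   (κ = 2) with per-marker rate multipliers — defaults 0.38 / 1.0 / 0.55 /
   1.10 for the rbcL/ITS2/matK/trnH-psbA-like markers, chosen to reproduce
   the observed divergence ordering (ITS2 fastest among comparably aligned
   markers, rbcL slowest) at realistic magnitudes;
3. per species, 1–`n_populations` sites with 3–6 individuals each
   (`individuals_per_population = 3:6`, the common field design), a
   population-private divergence step
   (`between_population_divergence = 0.001`) and a Kingman coalescent
   sample per population with per-site diversity `theta * rate`
   (`theta = 0.001`, matching the ~0.001/bp typical of ITS2 population
   diversity). The coalescent genealogy is used — rather than, say,
   independent mutations on a star genealogy — because only under the
   coalescent are *both* $\hat\pi$ and $\hat\theta_W$ unbiased for the
   nominal θ, which is what the parameter-recovery tests assert;
4. indel events (a contiguous 1–8-column gap assigned to a random clade)
   for the indel-rich markers, so alignments contain shared gap columns
   without any aligner involvement;
5. independent per-individual, per-marker dropout with one minus the
   marker's recovery probability (defaults 98.6/87.9/70.0/72.8%, the
   recovery rates typical of the four loci);
6. F1 hybrids: IUPAC-coded heterozygotes at all parental diagnostic sites
   of the nuclear marker, with the designated mother's chloroplast
   sequences. Parent pairs are drawn under the `"distinct"` rule by
   default: both parents must lie at patristic distance ≥
   `min_parent_divergence` (0.05) from each other and from every third
   species. F1 diagnosis is only well-posed for diagnosably distinct
   parents — real documented hybrids arise between well-differentiated
   congeners — and a `"random"` rule remains available for studying the
   breakdown.

What the simulator does **not** emulate: alignment uncertainty (alignments
are correct by construction, so realignment error — a genuine issue for
*trnH-psbA* across distant taxa — is invisible to these tests);
across-site rate heterogeneity and selection; linkage between the plastid
markers (each locus gets an independent genealogy); later-generation
hybrids and introgression; biogeography. Passing tests therefore establish
correctness of the *computations* under a favourable generative model, not
field performance of any marker.

## Problem sizes and numerical conventions

The test-suite and acceptance-script simulations are sized for quick,
repeatable runs: communities of 5–12 species, 1–2 populations of 3–6
individuals, single markers of 300–800 bp for estimator checks, 100–200
Monte-Carlo replicates for parameter recovery, and 100 bootstrap replicates
where the analysis default is 1000. These sizes keep Monte-Carlo standard
errors small relative to the tested tolerances while exercising every code
path; the defaults users see (`boot_reps = 1000`, `sim_config()`'s study
shape) are the analysis-scale settings.

Conventions collected in one place: sequences are stored uppercase and
case-insensitively read; `N` is missing data, never ambiguity evidence;
coordinates in metadata are carried but never used in computation; the
metadata table is authoritative over FASTA-header annotations; distance
ties use an absolute 1e-12 tolerance; all percentages are on the 0–100
scale; every stochastic entry point takes a seed, and
`evaluate_barcodes(seed = )` makes the entire 15-barcode evaluation
reproducible end to end.
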