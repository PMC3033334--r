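---
title: "Stage-comparative expression analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-comparative expression analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageset)
```

## The problem

Rat testis maturation offers a natural contrast for finding stem-cell and
niche genes. Before puberty (9 days post partum) spermatogonia are highly
enriched in cells with spermatogonial-stem-cell potential and the
still-immature Sertoli cells provide their niche; at puberty (22 dpp)
most germ cells have entered differentiation and Sertoli cells have
matured. Profiling purified germ (G) and Sertoli (S) cells at both stages
— four populations G9, S9, G22, S22, each in biological triplicate on a
probe-level microarray — lets one define, for each population, the genes
*selectively* up-regulated in it relative to both of its natural
comparators: the same cell type at the other stage, and the other cell
type at the same stage. The G9-selective set then reads out stemness, the
S9-selective set niche function, and ligand–receptor pairs split across
the two read out stem-cell-to-niche communication.

`stageset` implements that full analysis as a reusable, tested pipeline,
exercised end to end on synthetic data with planted structure.

## Concordance differential expression

The caller mirrors the replicate-pairwise strategy of probe-level
microarray comparison software. For an (experimental, reference)
condition pair, every experimental replicate is compared with every
reference replicate — nine pairwise comparisons for triplicates. Each
per-pair, per-gene comparison is a two-sided Wilcoxon signed-rank test of
the matched per-probe log2 ratios against zero; the direction is the sign
of the median log-ratio when p < `change_alpha` (default 0.05), else
`NoChange`. The rank-test family is what per-pair probe data affords: the
probes of one probe set are matched one-to-one between two arrays, so the
matched signed-rank form is the natural choice; an unmatched rank-sum
variant is available via `de_config(pair_test = "rank_sum")` for users
who prefer not to rely on probe matching.

A gene is then *selected* when

* at least `required_concordant_count(n_pairs, 0.77)` comparisons agree
  in direction — ceiling semantics, so 7 of 9 for the default 77% cutoff
  (a 60% cutoff, sometimes used as a first-pass screen in this family of
  methods, is available through the same parameter but is not the
  default), and
* the ratio of condition-mean gene-level signals is at least two-fold in
  the same direction.

Fisher's combination of the nine p-values is reported as a ranking aid
only; selection uses concordance plus fold change, which keeps the
procedure deliberately conservative (few false positives at the price of
sensitivity for weak effects).

Numerical choices for the signed-rank test: zero differences are dropped;
tied absolute differences get averaged ranks; the p-value is exact via
the classical distribution for untied samples up to n = 25, exact by
enumeration of all 2^n sign assignments when ties occur and n ≤ 12, and a
normal approximation with tie and continuity correction otherwise. With
the default 11 probes per gene the exact paths cover essentially every
real case; the tests verify both exact paths against an independent
enumeration oracle.

Gene-level signals come from a simple documented summarizer — per-gene
median of probe intensities (default) or a 10%-trimmed mean — standing
where a platform-specific probe-set signal computation would sit;
re-implementing a vendor signal algorithm is out of scope. Fold changes
divide condition means of these signals, with the denominator floored at
1 intensity unit so background-level denominators cannot blow up.

Present/Absent detection calls test each gene's probe log-intensities
against the array background with a one-sided signed-rank test; Present
means p < 0.05. Genes with fewer than three probes are conservatively
Absent with p = 1.

## Selective sets and their disjointness

For condition A with comparators B and C, the pairwise up-lists are the
selected, up-regulated genes of A-vs-B and A-vs-C; the A-selective set is
their intersection, and all 2^m − 1 Venn region counts are reported
(capped at m = 6 comparators). Because a gene two-fold up in A vs B
cannot be two-fold up in B vs A, the construction makes selective sets of
different conditions pairwise disjoint; `check_disjoint()` asserts this
theorem on every run rather than assuming it.

## Clustering

Heat-map ordering uses hierarchical clustering with 1 − Pearson
correlation distance and average linkage (UPGMA). Gene-axis profiles are
log2-transformed and per-gene standardized — the relative red/green
heat-map convention, under which correlation compares shapes, not levels;
the sample axis uses raw log2 profiles so overall expression structure
drives the sample tree. Zero-variance items are dropped with a warning
(correlation is undefined for them). Clustering is delegated to
`stats::hclust`, whose average-linkage agglomeration is deterministic for
a given input; ties in merge distance are resolved by its internal order
and have probability zero for continuous data. The test suite checks the
whole path against a hand-written O(n³) agglomeration oracle via
cophenetic matrices, which is insensitive to tied-merge permutation.
Trees export to Newick through `ape`, with merge heights as branch
lengths.

## Hypergeometric enrichment

For a cluster of n genes and a category of m genes inside a universe of N
annotated genes, the observed overlap k is compared with its random
expectation m·n/N, and one-sided tail probabilities are computed from the
exact hypergeometric distribution (inclusive tails: upper = P(X ≥ k),
lower = P(X ≤ k), so upper + lower = 1 + P(X = k)). A category is flagged
*enriched* when the upper tail P < 0.001 and k ≥ 4 ("observed > 3"), and
*depleted* when the lower tail P < 0.001. No multiple-testing correction
enters the flags — the stringent cutoff plus the minimum-observed filter
is the procedure's own guard — but a Benjamini–Hochberg column is emitted
as a modern diagnostic.

The default universe is `annotated_only`: genes appearing in at least one
category, matching the convention of counting expectations over the
annotated fraction of an array rather than all features; `full_array`
mode is available since either convention is defensible and the choice
is not always stated in published analyses. External gene lists (e.g. an
independently derived SSC signature, or tumor-associated ortholog lists)
go through the same machinery via `list_overlap()`, optionally translated
through a many-to-many ortholog map under which a gene counts once no
matter how many partners map to it.

## Ligand–receptor cross-talk

`find_crosstalk()` screens a curated two-column ligand–receptor table
against two selective sets and reports pairs whose ligand falls in one
set and whose receptor falls in the other, in both orientations. The
bundled demonstration table carries five canonical stem-cell/niche
couples (vegfc–kdr, edn1–ednrb, bdnf–ntrk1, cxcl12–cxcr4, kitl–kit). The
accompanying statistic — the upper-tail hypergeometric probability of
observing that many completed pairs given the candidate ligands already
in place — is this package's own extension for calibration purposes; the
original analysis style reports the pairs themselves without a
completion test.

## The synthetic-data generator

`generate_expression()` draws per-probe intensities as

    2 ^ (baseline + gene effect + block effect(condition) + probe affinity + noise)

with everything in log2 units. The defaults define the study conditions
used throughout the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | gene universe (scaled down from an array-sized universe for test-speed; all statistics scale with it) |
| `probes_per_gene` | 11 | probes per probe set |
| conditions × replicates | G9,S9,G22,S22 × 3 | the four-population triplicate design |
| `baseline_log2_mean` | 8 | expressed-gene baseline (intensity ≈ 256) |
| `gene_sd_log2` | 1.0 | between-gene baseline spread |
| `probe_sd_log2` | 0.5 | fixed per-probe affinity offsets, mimicking probe-set heterogeneity so probe-level rank tests face realistic within-set spread |
| `noise_sd_log2` | 0.35 | per-measurement noise, a typical between-replicate SD for biological triplicates on expression arrays |
| planted blocks | 4 × 50 genes, effect 2.0 log2 | one selective block per population at four-fold |
| shared block | 60 genes in {G9, S9} | the mitotic program co-elevated in both pre-pubertal populations |
| `absent_fraction` | 0.1 | genes emitted at background in every sample, giving the detection caller a real task |
| `background_level` | 32 | array background (log2 = 5) |
| categories | 4 spiked (size 40, fraction 0.5) + 20 null (size 40) | spiked categories draw half their members from one planted block |

A single integer seed governs all randomness with a documented draw
order (block membership, absent genes, gene effects, probe affinities,
noise, categories), so output is bit-reproducible. A few genes of the G9
and S9 blocks are renamed to the ligand/receptor symbols above so the
cross-talk demonstration has planted hits with known orientation.

What the generator deliberately does *not* emulate: scanner artifacts and
spatial effects, cross-array normalization needs, mismatch probes,
correlated gene-gene noise, and heavy-tailed outliers. Passing tests
therefore show that the pipeline recovers the structure it targets under
a clean log-normal noise model — not that it is robust to every artifact
of real hybridizations.

## Verification strategy and results

The test suite and `scripts/acceptance.R` check, among others:

* exactness of the signed-rank p-values against exhaustive enumeration of
  sign assignments (n ≤ 12, with and without ties) and of the
  hypergeometric tails against combinatorial enumeration (N ≤ 60);
* zero-noise limits: planted four-fold genes give 9/9 Increase calls and
  exactly recovered selective sets; probe summaries equal the planted
  baseline; identical profiles merge at height 0 and anti-correlated ones
  at distance 2;
* at the default (noisy) study conditions with a fixed seed: sensitivity
  ≥ 0.9 and false-discovery proportion ≤ 0.05 for every planted selective
  block, pairwise disjoint selective sets, contiguous replicate groups in
  the sample dendrogram, all four spiked categories flagged enriched with
  the null false-flag count inside its binomial bound, and exactly the
  planted ligand–receptor hits.

With the conservative 7-of-9 + two-fold rule and four-fold planted
effects, recovery at the default noise level is in fact complete
(sensitivity 1, FDP 0); the acceptance thresholds leave room for harder
settings.

## Known limitations

* The headline gene counts of the original rat study (6908 differential
  transcripts; selective sets of 445/314/1101/708; external-list overlaps
  such as 64 observed vs 17 expected) depend on its primary hybridization
  data, for which no public accession is printed; they are not
  reproducible here and the pipeline makes no attempt to match them.
  Structure and procedure, not dataset-specific numbers, are what this
  package reproduces.
* Vendor probe-set signal computation and cross-array normalization are
  intentionally replaced by a simple documented summarizer; absolute
  signal values are therefore not comparable to vendor pipelines.
* The concordance caller assumes matched probe indices between arrays of
  the same platform; data without probe-level structure falls back to
  gene-level fold-change and cannot use the rank tests.
* GO-style category relationships (parent/child propagation) are out of
  scope; categories are taken exactly as given in the GMT file.
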