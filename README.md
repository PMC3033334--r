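# stageset

Stage-comparative expression profiling of stem-cell and niche gene sets.

`stageset` re-implements, as a tested R pipeline, the analysis design used
to contrast purified rat spermatogonia (G) and Sertoli cells (S) at two
developmental stages — pre-pubertal (9 days post partum) and pubertal
(22 dpp) — giving four populations G9, S9, G22 and S22 profiled in
biological triplicate on a probe-level microarray. The pre-pubertal
spermatogonial fraction is enriched in spermatogonial stem cells (SSCs)
and the pre-pubertal Sertoli cells provide their niche, so the
population-selective gene sets read out stemness and niche programs, and
complementary ligand–receptor expression between them reads out
stem-cell-to-niche signaling.

The pipeline has six stages, each exposed as package functions and driven
by a numbered script under `analysis/`:

1. **Simulation** (`generate_expression`): a planted-structure generator
   emulating the study design — log-normal probe intensities, one
   selective gene block per population, a shared mitotic block co-elevated
   in both 9-dpp populations, absent genes at array background, and
   annotation categories spiked from the planted blocks — with a full
   ground-truth table, so every downstream stage is testable without any
   external download.
2. **Concordance differential expression** (`pairwise_change_calls`,
   `concordance_select`): each of the 3 experimental replicates is
   compared with each of the 3 reference replicates (9 pairwise
   comparisons per gene, exact Wilcoxon signed-rank tests on matched
   per-probe log-ratios); a gene is selected when at least 7 of 9
   comparisons agree in direction (the 77% concordance cutoff) *and* the
   condition-mean signal changes at least two-fold. Present/Absent
   detection calls (`detection_call`) test probe intensities against
   array background.
3. **Selective gene sets** (`build_selective`): for each population, the
   genes up-regulated against *both* comparators (same cell type at the
   other stage; other cell type at the same stage) — the Venn
   intersection construction, which makes the four sets pairwise
   disjoint.
4. **Hierarchical clustering** (`cluster_profiles`): 1 − Pearson
   correlation distance, average linkage, for heat-map ordering of genes
   and samples; trees export to Newick.
5. **Hypergeometric enrichment** (`enrich`, `list_overlap`): observed
   overlap k of a gene set with a category versus the random expectation
   m·n/N over the annotated universe; one-sided tail P-values; a category
   is *enriched* when P < 0.001 and k > 3, *depleted* when the lower tail
   P < 0.001. External gene lists can be translated through an ortholog
   map before intersection.
6. **Ligand–receptor cross-talk** (`find_crosstalk`): curated
   ligand–receptor pairs whose ligand falls in one population's selective
   set and whose receptor falls in the other's, in both orientations,
   with an upper-tail hypergeometric statistic for the number of
   completed pairs.

## Worked example

```r
library(stageset)

spec <- synthetic_spec(seed = 101)       # 1000 genes, 4 conditions x 3 reps
res  <- run_pipeline(pipeline_config(synthetic = spec))
pipeline_report(res)$recovery
#>   set_name n_planted n_called n_recovered sensitivity fdp
#> 1       G9        50       50          50           1   0
#> 2       S9        50       50          50           1   0
#> 3      G22        50       50          50           1   0
#> 4      S22        50       50          50           1   0

res$crosstalk$hits[, c("ligand_id", "receptor_id", "orientation")]
#>   ligand_id receptor_id orientation
#> 1     vegfc         kdr      G9->S9
#> 2      edn1       ednrb      G9->S9
#> 3      bdnf       ntrk1      G9->S9
#> 4    cxcl12       cxcr4      S9->G9
```

Each planted 50-gene selective block is recovered completely with no
false discoveries (sensitivity 1, false-discovery proportion 0), and the
bundled ligand–receptor demonstration table finds exactly the planted
stem-cell-to-niche couples: three ligands selective in the spermatogonial
set with receptors selective in the Sertoli set, plus the chemokine pair
in the reverse orientation.

The same run, stage by stage with all intermediate tables written under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_selective_sets.R
Rscript analysis/04_clustering.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_crosstalk.R
```

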