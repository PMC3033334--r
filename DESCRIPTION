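Package: stageset
Title: Stage-Comparative Expression Profiling of Stem-Cell and Niche Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stage-comparative microarray expression
    profiling of purified cell populations, modelled on pre-pubertal and
    pubertal rat spermatogonia and Sertoli cells (G9, S9, G22, S22).
    Implements replicate-pairwise concordance differential-expression calling
    with fold-change filtering, Present/Absent detection calls from
    probe-level intensities, construction of condition-"selective" gene sets
    by Venn cross-intersection of pairwise up-regulation lists, hierarchical
    clustering (Pearson correlation, average linkage) for heat-map ordering,
    one-sided hypergeometric enrichment and depletion of annotation
    categories and external gene lists, and ligand-receptor complementarity
    detection between two condition-selective sets. A synthetic-data
    generator with planted condition-selective blocks, a shared mitotic
    block, absent genes, and enrichment-spiked annotation categories makes
    every stage testable end to end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
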