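#!/usr/bin/env Rscript
# Stage 1: simulate the four-population experiment.
#
# Generates the default synthetic study: 1000 genes x 11 probes on a
# simulated array, four cell populations (G9, S9, G22, S22) in
# biological triplicate, five planted structures (one selective block
# per population plus a shared mitotic block in the two 9-dpp
# populations), 10% absent genes at array background, and 24 annotation
# categories of which 4 are spiked from a planted block. Writes the
# probe matrix, sample sheet, ground truth and categories under
# results/data/ for the downstream stages.

suppressPackageStartupMessages(library(stageset))

seed <- 101L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(seed = seed)
sim <- generate_expression(spec)

write_expression_matrix(sim$matrix, file.path(out, "matrix.tsv"),
                        file.path(out, "samples.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gmt(sim$categories, file.path(out, "categories.gmt"))

n_planted <- sum(!is.na(sim$truth$selective_condition))
cat(sprintf("simulated %d genes x %d probes, %d samples (seed %d)\n",
            spec$n_genes, spec$probes_per_gene, ncol(sim$matrix$values), seed))
cat(sprintf("planted: %d condition-selective genes, %d shared mitotic genes, %d absent genes\n",
            n_planted, sum(sim$truth$blocks == "mitotic_shared"),
            sum(sim$truth$absent)))
cat("wrote matrix.tsv, samples.tsv, truth.tsv, categories.gmt to", out, "\n")
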