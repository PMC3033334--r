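#!/usr/bin/env Rscript
# Stage 4: hierarchical clustering for heat-map ordering.
#
# Samples and the differentially expressed genes are clustered with
# 1 - Pearson correlation distance and average linkage. The sample tree
# should place the three replicates of each population in one subtree,
# with the two 9-dpp populations (which share the mitotic program) more
# alike than the two stages of either cell type. Trees are exported as
# Newick; the selected-gene signal matrix is written in heat-map row
# order.

suppressPackageStartupMessages(library(stageset))

out <- "results/clustering"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
mat <- read_expression_matrix("results/data/matrix.tsv", "results/data/samples.tsv")
signals <- summarize_signal(mat)

sample_tree <- cluster_profiles(signals, axis = "samples")
tree_newick(sample_tree, file.path(out, "sample_tree.nwk"))
groups <- split(signals$samples$sample_id, signals$samples$condition)
ok <- groups_contiguous(sample_tree, groups)
cat("sample order:", paste(heatmap_order(sample_tree), collapse = " "), "\n")
cat(sprintf("replicates contiguous for %d/%d conditions\n", sum(ok), length(ok)))

# re-cluster the union of the selective sets, the heat-map gene panel
sel_files <- list.files("results/selective", pattern = "^selective_.*\\.tsv$",
                        full.names = TRUE)
de_genes <- sort(unique(unlist(lapply(sel_files, function(f)
  read.delim(f, stringsAsFactors = FALSE)$feature_id))))
sub <- signals$values[match(de_genes, signals$feature_ids), , drop = FALSE]
rownames(sub) <- de_genes
gene_tree <- cluster_profiles(sub, axis = "genes")
tree_newick(gene_tree, file.path(out, "gene_tree.nwk"))

ordered <- data.frame(feature_id = heatmap_order(gene_tree),
                      log2(sub[heatmap_order(gene_tree), ]),
                      check.names = FALSE)
write.table(ordered, file.path(out, "heatmap_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("clustered %d selective genes; ordered log2 matrix and trees in %s\n",
            length(de_genes), out))
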