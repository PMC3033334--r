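#!/usr/bin/env Rscript
# Stage 6: ligand-receptor cross-talk between stem cells and niche.
#
# Screens the two pre-pubertal selective sets against a curated
# ligand-receptor table: a hit means a ligand selectively expressed in
# the spermatogonial set (G9) whose receptor is selectively expressed
# in the Sertoli/niche set (S9), or the reverse. With the default
# generator the planted couples are vegfc-kdr, edn1-ednrb and
# bdnf-ntrk1 in the G9->S9 direction and cxcl12-cxcr4 in S9->G9.

suppressPackageStartupMessages(library(stageset))

out <- "results/crosstalk"
g9 <- read.delim("results/selective/selective_G9.tsv",
                 stringsAsFactors = FALSE)$feature_id
s9 <- read.delim("results/selective/selective_S9.tsv",
                 stringsAsFactors = FALSE)$feature_id
universe <- unique(read.delim("results/data/matrix.tsv",
                              comment.char = "#")[, 1])

res <- find_crosstalk(g9, s9, demo_lr_pairs(), "G9", "S9", universe = universe)
for (i in seq_len(nrow(res$hits))) {
  cat(sprintf("%s: ligand %s (%s) -> receptor %s (%s)\n",
              res$hits$orientation[i], res$hits$ligand_id[i],
              res$hits$ligand_set[i], res$hits$receptor_id[i],
              res$hits$receptor_set[i]))
}
print(res$stats)
write_results(list(crosstalk_hits = res$hits, crosstalk_stats = res$stats), out)
cat("wrote crosstalk hits and statistics to", out, "\n")
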