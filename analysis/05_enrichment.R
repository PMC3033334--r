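#!/usr/bin/env Rscript
# Stage 5: hypergeometric category enrichment.
#
# Each selective set is tested against the annotation categories:
# observed overlap k versus the random expectation m*n/N over the
# annotated universe, one-sided tail P-values, and the publication's
# reporting filter (enriched when P < 0.001 and observed > 3; depleted
# when the lower tail P < 0.001). The spiked categories should light up
# exactly for their own population; null categories should stay dark.

suppressPackageStartupMessages(library(stageset))

out <- "results/enrichment"
categories <- read_gene_sets("results/data/categories.gmt", "gmt")
cfg <- enrich_config()  # P < 0.001, observed > 3, annotated universe

sel <- lapply(c("G9", "S9", "G22", "S22"), function(cc)
  read.delim(file.path("results/selective", paste0("selective_", cc, ".tsv")),
             stringsAsFactors = FALSE)$feature_id)
names(sel) <- c("G9", "S9", "G22", "S22")

enr <- do.call(rbind, lapply(names(sel), function(cc)
  enrich(sel[[cc]], categories, cfg = cfg, cluster_name = paste0(cc, "_sel"))))

flagged <- enr[enr$flag != "none", ]
for (i in seq_len(nrow(flagged))) {
  cat(sprintf("%-9s %-16s %s: %d observed vs %.1f expected (P = %.2g)\n",
              flagged$cluster_name[i], flagged$category_name[i],
              flagged$flag[i], flagged$k[i], flagged$expected[i],
              if (flagged$flag[i] == "enriched") flagged$p_enrich[i]
              else flagged$p_deplete[i]))
}
n_null_flagged <- sum(flagged$flag == "enriched" &
                        grepl("^GO_null", flagged$category_name))
cat(sprintf("%d categories flagged (%d spiked, %d null false flags)\n",
            nrow(flagged),
            sum(grepl("program$", flagged$category_name)), n_null_flagged))
write_results(list(enrichment = enr), out)
cat("wrote enrichment table to", out, "\n")
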