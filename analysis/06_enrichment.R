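#!/usr/bin/env Rscript
# Stage 6: gene-set over-representation of the consensus DEGs selected in
# at least two datasets, hypergeometric test against the network gene
# background with Benjamini-Hochberg FDR, significance at FDR < 0.01.

library(mitonet)

cons <- read.delim("results/de/consensus_degs.tsv", stringsAsFactors = FALSE)
sets <- read_gmt("results/study_inputs/annotations.gmt")
edges <- read.delim("results/coexpression/tissue_edges.tsv",
                    stringsAsFactors = FALSE)
background <- unique(c(edges$a, edges$b))
query <- cons$gene[cons$n_selected >= 2]

res <- enrich(query, sets, background, fdr_cutoff = 0.01)
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
write.table(res$records, "results/enrichment/enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Enrichment of", length(query), "multi-dataset DEGs against",
    length(sets), "terms (background:", length(background), "network genes):\n")
cat("  terms tested (overlap >= 1):", nrow(res$records), "\n")
cat("  significant at FDR < 0.01:", nrow(res$significant), "\n")
if (nrow(res$significant) > 0) {
  print(res$significant[, c("term", "k", "K", "p_value", "fdr")])
}
cat("Enrichment table written to results/enrichment/enrichment.tsv\n")
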