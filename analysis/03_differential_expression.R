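#!/usr/bin/env Rscript
# Stage 3: consensus differential expression. Every dataset is analysed
# under both normalization variants (fold change > 1.5 on the linear
# scale, pooled t-test p < 0.05, uncorrected); a gene enters the
# study-wide consensus when both variants agree in one dataset or
# complementary variants call it in two datasets, and is classified
# Up / Down / Mixed from its per-dataset direction counts.

library(mitonet)

datasets <- read_datasets_config("results/study_inputs")
res <- consensus_de(datasets)
cons <- res$consensus

dir.create("results/de", showWarnings = FALSE, recursive = TRUE)
write.table(cons, "results/de/consensus_degs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Consensus differential expression:\n")
cat("  study-wide DEGs:", nrow(cons), "\n")
print(table(cons$class))
cat("  selected in >= 2 datasets:", sum(cons$n_selected >= 2), "\n")
cat("  selected in >= 3 datasets:", sum(cons$n_selected >= 3), "\n")

# recovery against the planted truth
truth <- jsonlite::read_json("results/study_inputs/truth.json",
                             simplifyVector = TRUE)
up <- cons$gene[cons$class == "Up"]; down <- cons$gene[cons$class == "Down"]
tp <- sum(up %in% truth$planted_up) + sum(down %in% truth$planted_down)
cat(sprintf("  planted-direction precision %.3f, recall %.3f\n",
            tp / (length(up) + length(down)),
            tp / (length(truth$planted_up) + length(truth$planted_down))))
cat("Consensus table written to results/de/consensus_degs.tsv\n")
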