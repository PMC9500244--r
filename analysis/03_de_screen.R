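#!/usr/bin/env Rscript
# Screen differentially expressed genes on the training cohort:
# |log2 fold change| >= log2(1.5) and Welch p < 0.05 (raw, as in the
# original screening design).

library(mpsdiag)

labels <- read.delim("results/training_labels.tsv")
train <- read_matrix_tsv("results/training_matrix.tsv", labels$label)

deg <- screen_degs(train, fc_threshold = 1.5, p_threshold = 0.05)
write_deg_table(deg, "results/deg_table.tsv")
write.table(volcano_table(deg), "results/volcano.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

counts <- table(deg$group)
message(sprintf("%d differential genes of %d tested (%d up, %d down)",
                sum(counts[c("up", "down")]), nrow(deg),
                counts["up"], counts["down"]))

planted <- readLines("results/data/planted_genes.txt")
hits <- differential_genes(deg)
message(sprintf("planted genes recovered: %d / %d (plus %d false positives)",
                sum(planted %in% hits), length(planted),
                sum(!hits %in% planted)))
message("wrote results/deg_table.tsv and results/volcano.tsv")
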