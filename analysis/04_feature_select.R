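#!/usr/bin/env Rscript
# Narrow the differential genes to a consensus characteristic set:
# 10 independent cycles of importance-driven random-forest elimination
# (delete negative mean-decrease-accuracy genes until none remain negative),
# then keep genes appearing in more than three of the 10 terminal sets.

library(mpsdiag)

SEED <- 1L
labels <- read.delim("results/training_labels.tsv")
train <- read_matrix_tsv("results/training_matrix.tsv", labels$label)
deg <- read.delim("results/deg_table.tsv")
candidates <- as.character(deg$gene[deg$group != "stable"])
message(sprintf("starting from %d differential genes", length(candidates)))

z <- align_genes(zscore(train), candidates)$matrix
sel <- consensus_select(z, n_cycles = 10, min_appearances = 4,
                        n_trees = 500, base_seed = SEED * 101L)

write.table(data.frame(gene = names(sel$appearance_counts),
                       count = as.integer(sel$appearance_counts)),
            "results/appearance_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sel$final_genes, "results/characteristic_genes.txt")

planted <- readLines("results/data/planted_genes.txt")
tp <- sum(sel$final_genes %in% planted)
message(sprintf("%d characteristic genes; precision %.2f, recall %.2f vs planted truth",
                length(sel$final_genes), tp / length(sel$final_genes),
                tp / length(planted)))
message("wrote results/appearance_counts.tsv and results/characteristic_genes.txt")
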