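#!/usr/bin/env Rscript
# Collapse the probe-level training matrix to genes (highest-median probe per
# gene) and standardize both cohorts to per-gene Z-scores.

library(mpsdiag)

probes_raw <- read_series_matrix("results/data/training_probes_series_matrix.txt")
map <- read_probe_map("results/data/training_probe_map.tsv")
probes <- probe_matrix(probes_raw$values, map, as.character(probes_raw$labels))
train <- collapse_probes(probes)
message(sprintf("collapsed %d probes -> %d genes (%d unmapped probes removed)",
                nrow(probes$values), nrow(train$values),
                length(probes$unmapped)))

valid <- read_series_matrix("results/data/validation_series_matrix.txt")

write_matrix_tsv(train, "results/training_matrix.tsv")
write_matrix_tsv(valid, "results/validation_matrix.tsv")
write.table(data.frame(sample = colnames(train$values),
                       label = as.character(train$labels)),
            "results/training_labels.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = colnames(valid$values),
                       label = as.character(valid$labels)),
            "results/validation_labels.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ztrain <- zscore(train)
message(sprintf("Z-scores: per-gene |mean| <= %.2g, |sd - 1| <= %.2g",
                max(abs(rowMeans(ztrain$values))),
                max(abs(apply(ztrain$values, 1, sd) - 1))))
message("wrote results/{training,validation}_matrix.tsv and label tables")
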