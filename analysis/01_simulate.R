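#!/usr/bin/env Rscript
# Simulate the two cohorts of the study design and write them in the file
# dialects the pipeline reads.
#
# Training: 40 cases vs 40 controls, 500 genes, 20 of them shifted by
# 2 log2-units (half up, half down), unit noise — written at PROBE level
# (3 probes per gene) so the preprocessing stage has real work to do.
# Validation: an independent cohort from the same generative spec (same
# planted genes, fresh sampling noise), written at gene level.

library(mpsdiag)

SEED <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

spec_train <- synthetic_spec(n_genes = 500, n_case = 40, n_control = 40,
                             n_informative = 20, effect_size = 2,
                             noise_sd = 1, seed = SEED)
spec_valid <- synthetic_spec(n_genes = 500, n_case = 40, n_control = 40,
                             n_informative = 20, effect_size = 2,
                             noise_sd = 1, seed = SEED,
                             sampling_seed = SEED + 1000L)

train <- generate_expression(spec_train)
valid <- generate_expression(spec_valid)
stopifnot(identical(train$truth, valid$truth))

probes <- attach_probe_layer(train$matrix, probes_per_gene = 3, seed = SEED)
write_series_matrix(probes, "results/data/training_probes_series_matrix.txt")
write_probe_map(probes$probe_map, "results/data/training_probe_map.tsv")
write_series_matrix(valid$matrix, "results/data/validation_series_matrix.txt")
writeLines(train$truth$informative_genes, "results/data/planted_genes.txt")

message(sprintf("training: %d probes x %d samples (%d genes, %d planted)",
                nrow(probes$values), ncol(probes$values),
                nrow(train$matrix$values),
                length(train$truth$informative_genes)))
message(sprintf("validation: %d genes x %d samples, same planted structure",
                nrow(valid$matrix$values), ncol(valid$matrix$values)))
message("wrote results/data/{training_probes_series_matrix.txt, ",
        "training_probe_map.tsv, validation_series_matrix.txt, planted_genes.txt}")
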