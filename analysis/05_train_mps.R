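#!/usr/bin/env Rscript
# Train the single-hidden-node back-propagation network on characteristic-
# gene Z-scores and collapse it to the linear MPS gene-weight table.
# Genes absent from the validation cohort are dropped before training, as a
# signature can only be transferred on the genes both cohorts measure.

library(mpsdiag)

SEED <- 1L
tlab <- read.delim("results/training_labels.tsv")
vlab <- read.delim("results/validation_labels.tsv")
train <- read_matrix_tsv("results/training_matrix.tsv", tlab$label)
valid <- read_matrix_tsv("results/validation_matrix.tsv", vlab$label)
genes <- readLines("results/characteristic_genes.txt")

aligned <- align_genes(valid, genes)
if (length(aligned$missing) > 0) {
  message(sprintf("dropping %d gene(s) absent from validation: %s",
                  length(aligned$missing),
                  paste(aligned$missing, collapse = ", ")))
}
genes_used <- rownames(aligned$matrix$values)

ztrain <- align_genes(zscore(train), genes_used)$matrix
net <- train_network(ztrain, config = training_config(
  hidden_size = 1, max_iterations = 200, seed = SEED))
message(sprintf("trained in %d iterations, loss %.4f -> %.4f",
                length(net$loss_history) - 1, net$loss_history[1],
                net$loss_history[length(net$loss_history)]))
message(sprintf("gradient check (central, eps 1e-6): %.3g",
                gradient_check(net, ztrain, epsilon = 1e-6)))

weights <- extract_gene_weights(net)
write_gene_weights(weights, "results/gene_weights.tsv")
write_network(net, "results/network.txt")

mps_train <- compute_mps(weights, ztrain)
zvalid <- align_genes(zscore(valid), genes_used)$matrix
mps_valid <- compute_mps(weights, zvalid)
write_gene_weights(mps_train, "results/mps_training.tsv")
write_gene_weights(mps_valid, "results/mps_validation.tsv")

message(sprintf("weight range: [%.3f, %.3f] over %d genes",
                min(weights$weight), max(weights$weight), nrow(weights)))
message("wrote results/{gene_weights.tsv, network.txt, mps_training.tsv, mps_validation.tsv}")
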