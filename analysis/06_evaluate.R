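#!/usr/bin/env Rscript
# Evaluate the MPS score: ROC/AUC on both cohorts, agreement of the
# trapezoidal AUC with the Mann-Whitney statistic, and a TF-subnetwork
# extraction on a synthetic regulator edge table.

library(mpsdiag)

mps_train <- read.delim("results/mps_training.tsv")
mps_valid <- read.delim("results/mps_validation.tsv")

roc_t <- roc_curve(mps_train)
roc_v <- roc_curve(mps_valid)
write_roc_points(roc_t, "results/roc_training.tsv")
write_roc_points(roc_v, "results/roc_validation.tsv")

message(sprintf("training  AUC: %.4f (Mann-Whitney %.4f)",
                auc(roc_t), auc_mannwhitney(mps_train)))
message(sprintf("validation AUC: %.4f (Mann-Whitney %.4f)",
                auc(roc_v), auc_mannwhitney(mps_valid)))

# TF regulation of the characteristic genes, on a synthetic edge table:
# a few fake regulators pointing at characteristic genes, plus decoy edges.
genes <- readLines("results/characteristic_genes.txt")
edges <- rbind(
  data.frame(tf = paste0("TF", seq_along(genes) %% 5 + 1), target = genes,
             mode = rep(c("Activation", "Repression", "Unknown"),
                        length.out = length(genes)),
             reference = "synthetic"),
  data.frame(tf = "TF9", target = paste0("DECOY", 1:10),
             mode = "Activation", reference = "synthetic"))
sub <- tf_subnetwork(edges, genes)
write.table(sub, "results/tf_subnetwork.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
message(sprintf("TF subnetwork: kept %d of %d edges targeting characteristic genes",
                nrow(sub), nrow(edges)))
message("wrote results/{roc_training.tsv, roc_validation.tsv, tf_subnetwork.tsv}")
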