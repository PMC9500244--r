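# Shared fixtures, built in code.

# small labelled expression matrix with explicit values
make_expr <- function(values, labels, genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  dimnames(values) <- list(genes, paste0("s", seq_len(ncol(values))))
  expression_matrix(values, labels)
}

# random z-scored cohort with planted signal, via the generator
make_cohort <- function(n_genes = 60, n_case = 20, n_control = 20,
                        n_informative = min(5, n_genes), effect_size = 2,
                        seed = 1) {
  sim <- generate_expression(synthetic_spec(
    n_genes = n_genes, n_case = n_case, n_control = n_control,
    n_informative = n_informative, effect_size = effect_size, seed = seed))
  list(z = zscore(sim$matrix), raw = sim$matrix, truth = sim$truth)
}

# independent AUC oracle: exhaustive pairwise concordance count
auc_pairwise <- function(scores, labels) {
  cs <- scores[labels == "case"]; ks <- scores[labels == "control"]
  pairs <- outer(cs, ks, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

random_scores <- function(n_case, n_control, ties = FALSE) {
  s <- if (ties) {
    sample(seq_len(max(2, (n_case + n_control) %/% 2)),
           n_case + n_control, replace = TRUE) / 2
  } else {
    rnorm(n_case + n_control)
  }
  data.frame(mps = s,
             label = rep(c("case", "control"), c(n_case, n_control)))
}
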