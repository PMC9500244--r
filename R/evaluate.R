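#' ROC curve and trapezoidal AUC for MPS scores
#'
#' Case-positive orientation: a sample is predicted "case" when its score is
#' at or above the threshold. Thresholds sweep the unique score values in
#' descending order (plus an initial `Inf`), so tied scores contribute a
#' single curve vertex; the curve starts at (0, 0) and ends at (1, 1) and the
#' AUC is the trapezoidal integral. If the AUC falls below 0.5 the curve is
#' reported as-is with a warning — no silent score flipping.
#'
#' @param scores an `mps_scores` data.frame (columns `mps`, `label`), or any
#'   data.frame with a numeric score column named `mps` and a `label` column
#'   of case/control.
#' @return An object of class `roc_curve`: data.frame with columns
#'   `threshold`, `fpr`, `tpr`, plus attribute `auc`.
#' @export
roc_curve <- function(scores) {
  lab <- as.character(scores$label)
  s <- scores$mps
  n_case <- sum(lab == "case"); n_ctrl <- sum(lab == "control")
  if (n_case == 0L || n_ctrl == 0L) {
    mps_abort("need at least one case and one control",
              "mpsdiag_validation_error")
  }
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]; case_ord <- lab[ord] == "case"
  keep <- !duplicated(s_ord, fromLast = TRUE)   # last index of each tie block
  tpr <- c(0, cumsum(case_ord)[keep] / n_case)
  fpr <- c(0, cumsum(!case_ord)[keep] / n_ctrl)
  thr <- c(Inf, s_ord[keep])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  if (auc < 0.5) {
    mps_warn(sprintf("AUC = %.3f < 0.5; reporting the curve as-is", auc))
  }
  out <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  attr(out, "auc") <- auc
  class(out) <- c("roc_curve", class(out))
  out
}

#' @rdname roc_curve
#' @param x a `roc_curve`.
#' @return `auc()` returns the area under the curve as a single number.
#' @export
auc <- function(x) attr(x, "auc")

#' Mann-Whitney AUC (rank statistic)
#'
#' The probability that a random case outscores a random control, with ties
#' half-credited: `(#{case > control} + 0.5 #{case == control}) /
#' (n_case * n_control)`, computed via midranks. Serves as an independent
#' route to the trapezoidal [roc_curve()] AUC — the two agree to numerical
#' precision on any input.
#'
#' @inheritParams roc_curve
#' @return AUC as a single number.
#' @export
auc_mannwhitney <- function(scores) {
  lab <- as.character(scores$label)
  s <- scores$mps
  n_case <- sum(lab == "case"); n_ctrl <- sum(lab == "control")
  if (n_case == 0L || n_ctrl == 0L) {
    mps_abort("need at least one case and one control",
              "mpsdiag_validation_error")
  }
  r <- rank(s)                                  # midranks: ties half-credited
  (sum(r[lab == "case"]) - n_case * (n_case + 1) / 2) / (n_case * n_ctrl)
}

#' Subset a transcription-factor edge table to characteristic genes
#'
#' Keeps the regulatory edges relevant to a gene set: by default those whose
#' target is in the set (`mode = "target"`); `mode = "either"` also keeps
#' edges where the TF itself is a characteristic gene. Self-loops present in
#' the source table are kept and flagged via the `"self_loops"` attribute.
#' Output rows are sorted by (tf, target) for determinism.
#'
#' @param edges data.frame with columns `tf`, `target`, `mode`
#'   (Activation/Repression/Unknown), `reference` — as read by
#'   [read_tf_edges()].
#' @param genes character vector of characteristic genes.
#' @param mode `"target"` (default) or `"either"`.
#' @return The filtered, sorted edge data.frame (possibly empty).
#' @export
tf_subnetwork <- function(edges, genes, mode = c("target", "either")) {
  mode <- match.arg(mode)
  keep <- edges$target %in% genes
  if (mode == "either") keep <- keep | edges$tf %in% genes
  out <- edges[keep, , drop = FALSE]
  out <- out[order(out$tf, out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "self_loops") <- which(out$tf == out$target)
  out
}

#' Read a TRRUST-dialect transcription-factor edge table
#'
#' Four tab-separated columns, no header: TF, target gene, regulation mode
#' (Activation/Repression/Unknown), reference.
#'
#' @param path file path.
#' @return data.frame with columns `tf`, `target`, `mode`, `reference`.
#' @export
read_tf_edges <- function(path) {
  read.delim(path, header = FALSE,
             col.names = c("tf", "target", "mode", "reference"),
             colClasses = "character")
}

#' @rdname roc_curve
#' @param path file path.
#' @export
write_roc_points <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
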