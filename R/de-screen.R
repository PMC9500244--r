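#' Welch two-sample t-test (vectorised over genes)
#'
#' Computes the Welch t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value from the t distribution, for one gene (vectors) or
#' many (matrices with genes in rows). Degenerate inputs follow a documented
#' convention: if both groups have zero variance, p = 1 when the means are
#' equal and p = 0 when they differ (t is +/-Inf).
#'
#' @param case_values,control_values numeric vectors (one gene) or matrices
#'   with genes in rows and >= 2 samples per group.
#' @return A data.frame with columns `t`, `df`, `p_value` (one row per gene).
#' @examples
#' welch_t(c(3, 4, 5), c(1, 2, 3)) # t = 2.449, df = 4, p = 0.0705
#' @export
welch_t <- function(case_values, control_values) {
  if (is.null(dim(case_values))) case_values <- matrix(case_values, 1L)
  if (is.null(dim(control_values))) control_values <- matrix(control_values, 1L)
  n1 <- ncol(case_values); n2 <- ncol(control_values)
  if (n1 < 2L || n2 < 2L) {
    mps_abort("each group needs >= 2 values", "mpsdiag_validation_error")
  }
  m1 <- rowMeans(case_values); m2 <- rowMeans(control_values)
  v1 <- rowSums((case_values - m1)^2) / (n1 - 1L)
  v2 <- rowSums((control_values - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  # both groups constant: se2 == 0 -> t is +/-Inf or NaN
  degenerate <- se2 == 0
  if (any(degenerate)) {
    equal <- degenerate & (m1 == m2)
    t_stat[degenerate] <- sign(m1 - m2)[degenerate] * Inf
    t_stat[equal] <- 0
    df[degenerate] <- NA_real_
    p[degenerate] <- ifelse(equal[degenerate], 1, 0)
  }
  data.frame(t = t_stat, df = df, p_value = p,
             row.names = rownames(case_values))
}

#' Screen differentially expressed genes by fold change and p-value
#'
#' Per gene: `log2fc` = case mean - control mean (the data are already on the
#' log2 scale, so this is the log2 fold change), and a Welch two-sample
#' p-value. Classification: `up` if `log2fc >= log2(fc_threshold)` and
#' `p < p_threshold`; `down` if `log2fc <= -log2(fc_threshold)` and
#' `p < p_threshold`; otherwise `stable`. No multiple-testing correction is
#' applied by default (`adjust = "none"`); with `adjust = "BH"` the
#' Benjamini-Hochberg adjusted p-value is used for classification instead.
#'
#' @param x an `expr_matrix` with >= 2 samples per group.
#' @param fc_threshold fold-change threshold on the linear scale
#'   (default 1.5).
#' @param p_threshold significance threshold (default 0.05, strict `<`).
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return A data.frame of class `deg_table` with columns `gene`, `log2fc`,
#'   `p_value`, `group` and attribute `thresholds`.
#' @export
screen_degs <- function(x, fc_threshold = 1.5, p_threshold = 0.05,
                        adjust = "none") {
  stopifnot(inherits(x, "expr_matrix"))
  ci <- case_columns(x); ki <- control_columns(x)
  if (length(ci) < 2L || length(ki) < 2L) {
    mps_abort("need >= 2 samples per group", "mpsdiag_validation_error")
  }
  wt <- welch_t(x$values[, ci, drop = FALSE], x$values[, ki, drop = FALSE])
  log2fc <- rowMeans(x$values[, ci, drop = FALSE]) -
    rowMeans(x$values[, ki, drop = FALSE])
  p_class <- if (identical(adjust, "none")) wt$p_value else
    stats::p.adjust(wt$p_value, method = adjust)
  lfc_cut <- log2(fc_threshold)
  group <- ifelse(p_class < p_threshold & log2fc >= lfc_cut, "up",
           ifelse(p_class < p_threshold & log2fc <= -lfc_cut, "down",
                  "stable"))
  out <- data.frame(gene = rownames(x$values), log2fc = log2fc,
                    p_value = wt$p_value,
                    group = factor(group, c("up", "down", "stable")),
                    row.names = NULL)
  attr(out, "thresholds") <- list(fc_threshold = fc_threshold,
                                  p_threshold = p_threshold, adjust = adjust)
  class(out) <- c("deg_table", class(out))
  out
}

#' Genes classified as differential (up or down)
#' @param table a `deg_table` from [screen_degs()].
#' @return Character vector of gene ids.
#' @export
differential_genes <- function(table) {
  as.character(table$gene[table$group != "stable"])
}

#' Volcano-plot coordinate table
#'
#' The numeric content of a volcano plot: per gene, the log2 fold change and
#' `-log10(p)`, with p-values clipped at the smallest positive double so the
#' transform is finite.
#'
#' @param table a `deg_table`.
#' @return data.frame with columns `gene`, `log2fc`, `neg_log10_p`, `group`.
#' @export
volcano_table <- function(table) {
  p <- pmax(table$p_value, .Machine$double.xmin)
  data.frame(gene = table$gene, log2fc = table$log2fc,
             neg_log10_p = -log10(p), group = table$group)
}

#' @rdname screen_degs
#' @param table a `deg_table`.
#' @param path file path.
#' @export
write_deg_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
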