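#' Collapse probes to genes by highest median
#'
#' For every gene with mapped probes, the probe whose values have the highest
#' median across samples is selected and used, unchanged, as the gene's
#' expression row; unmapped probes are removed. Median ties between probes of
#' the same gene are broken by lexicographic probe id so the result is
#' deterministic and invariant to probe row order.
#'
#' @param probes a `probe_matrix`.
#' @return An `expr_matrix` with one row per mapped gene (genes sorted by id).
#' @export
collapse_probes <- function(probes) {
  stopifnot(inherits(probes, "probe_matrix"))
  map <- probes$probe_map
  map <- map[map$probe_id %in% rownames(probes$values), , drop = FALSE]
  if (nrow(map) == 0L) {
    mps_abort("no probe maps to any gene; nothing to collapse",
              "mpsdiag_empty_result_error")
  }
  med <- apply(probes$values[map$probe_id, , drop = FALSE], 1L, median)
  # order by gene, then descending median, then probe id (tie-break)
  ord <- order(map$gene_symbol, -med, map$probe_id)
  keep <- map[ord, ][!duplicated(map$gene_symbol[ord]), , drop = FALSE]
  vals <- probes$values[keep$probe_id, , drop = FALSE]
  rownames(vals) <- keep$gene_symbol
  expression_matrix(vals, as.character(probes$labels))
}

#' Standardize expression to per-gene Z-scores (Gene_Score)
#'
#' Each value becomes `(value - gene mean) / gene sd`, the model input
#' ("Gene_Score"). The standard deviation uses the sample (n - 1)
#' denominator. By default each dataset is standardized with its own
#' statistics; pass `reference_stats` (e.g. from a training cohort) to score
#' a new cohort on the training scale.
#'
#' @param x an `expr_matrix`.
#' @param reference_stats optional list with numeric vectors `mean` and `sd`
#'   named by gene, as found in the `"stats"` attribute of a previous
#'   `zscore()` result; used instead of `x`'s own statistics.
#' @return An `expr_matrix` (subclass `zmatrix`) of dimensionless Z-scores,
#'   with attribute `"stats"` holding the per-gene mean and sd used.
#' @export
zscore <- function(x, reference_stats = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(reference_stats)) {
    m <- rowMeans(x$values)
    s <- apply(x$values, 1L, sd)
  } else {
    if (!all(rownames(x$values) %in% names(reference_stats$mean))) {
      missing <- setdiff(rownames(x$values), names(reference_stats$mean))
      mps_abort(paste0("reference_stats lack genes: ",
                       paste(head(missing, 5), collapse = ", ")),
                "mpsdiag_validation_error")
    }
    m <- reference_stats$mean[rownames(x$values)]
    s <- reference_stats$sd[rownames(x$values)]
  }
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    mps_abort(paste0("zero-variance gene(s): ",
                     paste(head(rownames(x$values)[bad], 10), collapse = ", ")),
              "mpsdiag_zero_variance_error",
              genes = rownames(x$values)[bad])
  }
  z <- (x$values - m) / s
  out <- expression_matrix(z, as.character(x$labels))
  class(out) <- c("zmatrix", class(out))
  attr(out, "stats") <- list(mean = stats::setNames(as.numeric(m), rownames(z)),
                             sd = stats::setNames(as.numeric(s), rownames(z)))
  out
}

#' Restrict a matrix to a gene list, reporting absent genes
#'
#' Mirrors the validation-cohort alignment step of signature scoring: genes
#' of the signature absent from the new cohort are dropped (and reported)
#' rather than failing the run.
#'
#' @param x an `expr_matrix`.
#' @param gene_list character vector of requested gene ids (no duplicates).
#' @return A list with `matrix` (sub-`expr_matrix`, rows ordered as in
#'   `gene_list`) and `missing` (requested genes absent from `x`).
#' @export
align_genes <- function(x, gene_list) {
  stopifnot(inherits(x, "expr_matrix"))
  if (length(gene_list) == 0L) {
    mps_abort("'gene_list' is empty", "mpsdiag_validation_error")
  }
  if (anyDuplicated(gene_list)) {
    mps_abort("'gene_list' contains duplicated entries",
              "mpsdiag_validation_error", field = "gene_list")
  }
  present <- gene_list[gene_list %in% rownames(x$values)]
  missing <- setdiff(gene_list, present)
  if (length(present) == 0L) {
    mps_abort("none of the requested genes are present in the matrix",
              "mpsdiag_empty_result_error")
  }
  sub <- x$values[present, , drop = FALSE]
  out <- expression_matrix(sub, as.character(x$labels))
  if (inherits(x, "zmatrix")) {
    class(out) <- c("zmatrix", class(out))
    st <- attr(x, "stats")
    if (!is.null(st)) {
      attr(out, "stats") <- list(mean = st$mean[present], sd = st$sd[present])
    }
  }
  list(matrix = out, missing = missing)
}
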