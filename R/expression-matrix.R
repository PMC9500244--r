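#' Expression matrix with case/control labels
#'
#' The pipeline's universal currency: a numeric genes x samples matrix of
#' log2-scale expression values, with a binary case/control label per sample
#' column. Row names are gene identifiers (unique), column names sample
#' identifiers.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row names (gene ids) and column names (sample ids).
#' @param labels character or factor of length `ncol(values)` with values
#'   `"case"` or `"control"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `labels` (factor with levels case, control).
#' @examples
#' m <- expression_matrix(
#'   matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
#'   c("case", "case", "control")
#' )
#' case_columns(m)
#' @export
expression_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values)) {
    mps_abort("'values' must be a numeric matrix", "mpsdiag_validation_error")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    mps_abort("'values' must have unique row names (gene ids)",
              "mpsdiag_validation_error", field = "values")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    mps_abort(sprintf("length(labels) [%d] != number of sample columns [%d]",
                      length(labels), ncol(values)),
              "mpsdiag_validation_error", field = "labels")
  }
  if (!all(labels %in% c("case", "control"))) {
    mps_abort("labels must be 'case' or 'control'",
              "mpsdiag_validation_error", field = "labels")
  }
  if (anyNA(values)) {
    mps_abort("expression values contain missing entries",
              "mpsdiag_validation_error", field = "values")
  }
  if (max(values) > 30) {
    mps_warn(paste0("matrix maximum exceeds 30; values are expected on the ",
                    "log2 scale and are used untransformed"))
  }
  structure(list(values = values, labels = factor(labels, c("case", "control"))),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d genes x %d samples (%d case, %d control)\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
case_columns <- function(x) which(x$labels == "case")

#' @rdname expression_matrix
#' @export
control_columns <- function(x) which(x$labels == "control")

#' Probe-level matrix with a probe-to-gene map
#'
#' @param values numeric matrix, probes in rows (unique probe ids as row
#'   names), samples in columns.
#' @param probe_map data.frame with columns `probe_id` and `gene_symbol`;
#'   probes without a gene mapping may be absent from the map or carry an
#'   empty/NA gene symbol — they are flagged in `$unmapped`, never silently
#'   kept.
#' @param labels case/control per sample column.
#' @return An object of class `probe_matrix` with elements `values`,
#'   `probe_map` (mapped probes only), `labels`, `unmapped` (flagged probe
#'   ids without a gene).
#' @export
probe_matrix <- function(values, probe_map, labels) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      anyDuplicated(rownames(values))) {
    mps_abort("probe 'values' must be a matrix with unique probe-id row names",
              "mpsdiag_validation_error", field = "values")
  }
  if (!is.data.frame(probe_map) ||
      !all(c("probe_id", "gene_symbol") %in% names(probe_map))) {
    mps_abort("'probe_map' needs columns probe_id and gene_symbol",
              "mpsdiag_validation_error", field = "probe_map")
  }
  probe_map <- probe_map[, c("probe_id", "gene_symbol")]
  probe_map$probe_id <- as.character(probe_map$probe_id)
  probe_map$gene_symbol <- as.character(probe_map$gene_symbol)
  empty <- is.na(probe_map$gene_symbol) | probe_map$gene_symbol == ""
  mapped <- probe_map[!empty, , drop = FALSE]
  unmapped <- union(probe_map$probe_id[empty],
                    setdiff(rownames(values), mapped$probe_id))
  labels <- factor(as.character(labels), c("case", "control"))
  structure(list(values = values, probe_map = mapped, labels = labels,
                 unmapped = unmapped),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("<probe_matrix> %d probes x %d samples, %d mapped genes, %d unmapped probes\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$probe_map$gene_symbol)), length(x$unmapped)))
  invisible(x)
}

# ---- file formats ----------------------------------------------------------

#' Read and write the simplified series-matrix dialect
#'
#' Tab-separated text: comment lines start with `!`; one `!Sample_group` line
#' gives the case/control label per sample column; the table header is
#' `ID_REF` followed by sample names; one row per gene (or probe). Values are
#' written with 17 significant digits so a write/read round trip reproduces
#' the matrix exactly.
#'
#' @param x an `expr_matrix`.
#' @param path file path.
#' @return `write_series_matrix` returns `path` invisibly;
#'   `read_series_matrix` returns an `expr_matrix`.
#' @export
write_series_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix") || inherits(x, "probe_matrix"))
  if (nrow(x$values) == 0L || ncol(x$values) == 0L) {
    mps_abort("refusing to write an empty matrix", "mpsdiag_validation_error")
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) mps_abort(
                    sprintf("cannot open '%s' for writing: %s", path,
                            conditionMessage(e)), "mpsdiag_io_error"))
  on.exit(close(con))
  writeLines("!Series_matrix_dialect\tsimplified", con)
  writeLines(paste(c("!Sample_group", as.character(x$labels)),
                   collapse = "\t"), con)
  writeLines(paste(c("ID_REF", colnames(x$values)), collapse = "\t"), con)
  body <- cbind(rownames(x$values),
                matrix(sprintf("%.17g", x$values), nrow(x$values)))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_series_matrix
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) {
    mps_abort(sprintf("no such file: '%s'", path), "mpsdiag_io_error")
  }
  lines <- readLines(path)
  comments <- grepl("^!", lines)
  group_line <- lines[grepl("^!Sample_group\t", lines)]
  if (length(group_line) != 1L) {
    mps_abort("expected exactly one !Sample_group line", "mpsdiag_io_error")
  }
  labels <- strsplit(group_line, "\t", fixed = TRUE)[[1]][-1]
  tab <- lines[!comments]
  header <- strsplit(tab[1L], "\t", fixed = TRUE)[[1]]
  if (header[1L] != "ID_REF") {
    mps_abort("table header must start with ID_REF", "mpsdiag_io_error")
  }
  cells <- strsplit(tab[-1L], "\t", fixed = TRUE)
  ids <- vapply(cells, `[`, "", 1L)
  vals <- matrix(as.numeric(unlist(lapply(cells, `[`, -1L))),
                 nrow = length(cells), byrow = TRUE,
                 dimnames = list(ids, header[-1L]))
  expression_matrix(vals, labels)
}

#' Read and write plain TSV matrices and probe maps
#'
#' `write_matrix_tsv`/`read_matrix_tsv` handle a genes x samples table whose
#' first column (`gene_id`) holds gene identifiers; labels travel separately
#' (a two-column TSV sample/label) or are supplied by the caller.
#'
#' @param x an `expr_matrix`.
#' @param path file path.
#' @param labels for `read_matrix_tsv`, the case/control labels of the
#'   sample columns.
#' @return the read functions return an `expr_matrix` / data.frame.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, labels) {
  df <- read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- as.character(df[[1L]])
  expression_matrix(vals, labels)
}

#' @rdname write_matrix_tsv
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("probe_id", "gene_symbol") %in% names(df))) {
    mps_abort("probe map must have columns probe_id, gene_symbol",
              "mpsdiag_io_error")
  }
  df
}

#' @rdname write_matrix_tsv
#' @param probe_map data.frame with columns probe_id, gene_symbol.
#' @export
write_probe_map <- function(probe_map, path) {
  write.table(probe_map[, c("probe_id", "gene_symbol")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
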