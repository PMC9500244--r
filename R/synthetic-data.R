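#' Specification for a synthetic two-group expression dataset
#'
#' Describes a simulated case/control cohort on the log2 scale: per-gene
#' baseline means drawn uniformly from `baseline_mean_range`, i.i.d. normal
#' noise with standard deviation `noise_sd`, and `n_informative` genes whose
#' case-group mean is shifted by `effect_size` log2 units (half shifted up,
#' half down, mirroring the typical mix of up- and downregulated disease
#' genes; the split is configurable via `prop_up`).
#'
#' @param n_genes number of genes.
#' @param n_case,n_control samples per group.
#' @param n_informative number of genes with a true group-mean shift
#'   (0 for a null dataset).
#' @param effect_size absolute case-minus-control mean shift, log2 units;
#'   may be 0.
#' @param baseline_mean_range length-2 interval for per-gene baseline means,
#'   log2 units (default `c(4, 14)`, a typical microarray range).
#' @param noise_sd per-gene noise standard deviation, log2 units (> 0).
#' @param prop_up fraction of informative genes shifted upward (rounded).
#' @param probes_per_gene probes per gene when a probe layer is attached
#'   (1 = no probe layer).
#' @param seed integer seed; the same spec and seed reproduce the dataset
#'   bit for bit. The seed drives the cohort *structure* (baseline means,
#'   which genes are informative, shift directions).
#' @param sampling_seed integer seed for the noise draws; defaults to `seed`.
#'   Two specs sharing `seed` but differing in `sampling_seed` describe
#'   independent cohorts with the same planted structure — the usual
#'   training/validation design.
#' @return An object of class `synthetic_spec`.
#' @examples
#' sp <- synthetic_spec(n_genes = 100, n_case = 10, n_control = 10,
#'                      n_informative = 10, effect_size = 2, seed = 1)
#' sim <- generate_expression(sp)
#' sim$truth$informative_genes
#' @export
synthetic_spec <- function(n_genes, n_case, n_control,
                           n_informative = 0L,
                           effect_size = 0,
                           baseline_mean_range = c(4, 14),
                           noise_sd = 1,
                           prop_up = 0.5,
                           probes_per_gene = 1L,
                           seed = 1L,
                           sampling_seed = NULL) {
  stopifnot_count(n_genes, "n_genes")
  stopifnot_count(n_case, "n_case")
  stopifnot_count(n_control, "n_control")
  stopifnot_count(n_informative, "n_informative", min = 0L)
  stopifnot_count(probes_per_gene, "probes_per_gene")
  stopifnot_count(seed, "seed", min = -.Machine$integer.max)
  if (is.null(sampling_seed)) sampling_seed <- seed
  stopifnot_count(sampling_seed, "sampling_seed", min = -.Machine$integer.max)
  if (n_informative > n_genes) {
    mps_abort("'n_informative' cannot exceed 'n_genes'",
              "mpsdiag_validation_error", field = "n_informative")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    mps_abort("'noise_sd' must be a single value > 0",
              "mpsdiag_validation_error", field = "noise_sd")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      !is.finite(effect_size)) {
    mps_abort("'effect_size' must be a single finite number",
              "mpsdiag_validation_error", field = "effect_size")
  }
  if (length(baseline_mean_range) != 2L ||
      baseline_mean_range[1] > baseline_mean_range[2]) {
    mps_abort("'baseline_mean_range' must be an ordered length-2 interval",
              "mpsdiag_validation_error", field = "baseline_mean_range")
  }
  if (!is.numeric(prop_up) || prop_up < 0 || prop_up > 1) {
    mps_abort("'prop_up' must be in [0, 1]",
              "mpsdiag_validation_error", field = "prop_up")
  }
  structure(list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 baseline_mean_range = baseline_mean_range,
                 noise_sd = noise_sd, prop_up = prop_up,
                 probes_per_gene = as.integer(probes_per_gene),
                 seed = as.integer(seed),
                 sampling_seed = as.integer(sampling_seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-group expression dataset with known ground truth
#'
#' Values are drawn directly on the log2 scale: for gene g and sample j,
#' `x[g, j] = mu_g + shift_g * [j is a case] + N(0, noise_sd^2)`, where
#' `mu_g ~ U(baseline_mean_range)` and `shift_g = +/- effect_size` for the
#' `n_informative` planted genes (a random subset), 0 otherwise. The
#' structure draws (`mu_g`, the informative subset and its shift signs) come
#' from one generator stream seeded by `spec$seed`; the noise draws from a
#' stream seeded by `spec$sampling_seed` (equal to `seed` unless set).
#' Identical specs reproduce the matrix bit for bit.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `matrix` (an `expr_matrix`; case columns first) and
#'   `truth` (class `ground_truth`: `informative_genes`, plus `shift`, the
#'   named per-gene true case-minus-control mean difference, 0 for
#'   non-informative genes).
#' @export
generate_expression <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    mps_abort("'spec' must be a synthetic_spec", "mpsdiag_validation_error")
  }
  genes <- sprintf("GENE%05d", seq_len(spec$n_genes))
  samples <- c(sprintf("CASE%03d", seq_len(spec$n_case)),
               sprintf("CTRL%03d", seq_len(spec$n_control)))
  labels <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
  withr::with_seed(spec$seed, {
    mu <- runif(spec$n_genes, spec$baseline_mean_range[1],
                spec$baseline_mean_range[2])
    informative <- sort(sample.int(spec$n_genes, spec$n_informative))
    n_up <- round(spec$prop_up * spec$n_informative)
    sign_vec <- rep(c(1, -1), c(n_up, spec$n_informative - n_up))
    shift <- numeric(spec$n_genes)
    shift[informative] <- sign_vec * spec$effect_size
  })
  n <- spec$n_case + spec$n_control
  withr::with_seed(spec$sampling_seed, {
    vals <- matrix(rnorm(spec$n_genes * n, sd = spec$noise_sd),
                   spec$n_genes, n) + mu
    vals[, labels == "case"] <- vals[, labels == "case"] + shift
  })
  dimnames(vals) <- list(genes, samples)
  truth <- structure(list(informative_genes = genes[informative],
                          shift = stats::setNames(shift, genes)),
                     class = "ground_truth")
  list(matrix = expression_matrix(vals, labels), truth = truth)
}

#' Expand a gene-level matrix into a probe-level matrix
#'
#' Each gene becomes `probes_per_gene` probe rows; every probe row is the
#' gene's row plus independent probe-level normal noise (an extra offset per
#' probe plus per-cell jitter), emulating multiple array probes measuring
#' one transcript. A probe-to-gene map is emitted alongside.
#'
#' @param x an `expr_matrix` at gene level.
#' @param probes_per_gene probes per gene (>= 1). With 1, the probe values
#'   equal the input values and the map is one-to-one.
#' @param probe_noise_sd standard deviation of the probe-level jitter
#'   (log2 units); ignored when `probes_per_gene == 1`.
#' @param seed integer seed for the probe noise.
#' @return A `probe_matrix`.
#' @export
attach_probe_layer <- function(x, probes_per_gene, probe_noise_sd = 0.25,
                               seed = 1L) {
  stopifnot(inherits(x, "expr_matrix"))
  stopifnot_count(probes_per_gene, "probes_per_gene")
  genes <- rownames(x$values)
  k <- as.integer(probes_per_gene)
  probe_ids <- paste0(rep(genes, each = k), "_at", rep(seq_len(k), length(genes)))
  map <- data.frame(probe_id = probe_ids,
                    gene_symbol = rep(genes, each = k),
                    stringsAsFactors = FALSE)
  vals <- x$values[rep(seq_along(genes), each = k), , drop = FALSE]
  if (k > 1L) {
    withr::with_seed(as.integer(seed), {
      # per-probe additive offset (probe affinity) + per-cell jitter
      offset <- rnorm(length(probe_ids), sd = probe_noise_sd)
      vals <- vals + offset +
        matrix(rnorm(length(vals), sd = probe_noise_sd / 2), nrow(vals))
    })
  }
  rownames(vals) <- probe_ids
  probe_matrix(vals, map, x$labels)
}
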