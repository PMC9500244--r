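# Known configuration keys per block, used for validation and typo hints.
config_keys <- list(
  top = c("seed", "out_dir", "standardization", "de", "selection",
          "training_config", "training", "validation", "tf_edges"),
  de = c("fc_threshold", "p_threshold", "adjust"),
  selection = c("n_cycles", "min_appearances", "n_trees", "max_iterations"),
  training_config = c("hidden_size", "max_iterations", "learning_rate",
                      "l2_decay", "convergence_tol", "loss"),
  dataset = c("file", "labels", "synthetic"),
  synthetic = c("n_genes", "n_case", "n_control", "n_informative",
                "effect_size", "baseline_mean_range", "noise_sd", "prop_up",
                "probes_per_gene", "seed", "sampling_seed")
)

default_synthetic_block <- function() {
  list(n_genes = 500L, n_case = 40L, n_control = 40L, n_informative = 20L,
       effect_size = 2, noise_sd = 1, probes_per_gene = 1L)
}

#' Default pipeline configuration
#'
#' A fully synthetic run: training and validation cohorts of 40 cases vs 40
#' controls over 500 genes, 20 of them carrying a 2 log2-unit shift with unit
#' noise — a strong-signal design on which the pipeline is expected to
#' recover the planted genes and discriminate the validation cohort.
#'
#' @param seed master seed; every stage seed is derived from it.
#' @param out_dir output directory for the run's artifacts.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("mpsdiag_run")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    standardization = "own",
    de = list(fc_threshold = 1.5, p_threshold = 0.05, adjust = "none"),
    selection = list(n_cycles = 10L, min_appearances = 4L, n_trees = 500L,
                     max_iterations = 100L),
    training_config = list(hidden_size = 1L, max_iterations = 200L,
                           learning_rate = 0.1, l2_decay = 0,
                           convergence_tol = 1e-8, loss = "cross_entropy"),
    training = list(synthetic = default_synthetic_block()),
    validation = list(synthetic = default_synthetic_block()),
    tf_edges = NULL
  ), class = "run_config")
}

check_unknown_keys <- function(block, known, where) {
  unknown <- setdiff(names(block), known)
  if (length(unknown) > 0L) {
    hint <- agrep(unknown[1], known, max.distance = 2, value = TRUE)
    msg <- sprintf("unknown key '%s' in %s", unknown[1], where)
    if (length(hint) > 0L) msg <- paste0(msg, sprintf(" (did you mean '%s'?)", hint[1]))
    mps_abort(msg, "mpsdiag_config_error", key = unknown[1])
  }
}

merge_block <- function(defaults, user, known, where) {
  if (is.null(user)) return(defaults)
  check_unknown_keys(user, known, where)
  for (k in names(user)) defaults[[k]] <- user[[k]]
  defaults
}

#' Parse, default, and validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills every unset key from [default_config()],
#' and validates: unknown keys (with a closest-match hint), type and range
#' constraints, and that each dataset block names exactly one of a file input
#' or a synthetic block. An empty file yields the full-default synthetic
#' configuration. Every defaulted value is part of the returned object, so
#' the resolved configuration is self-describing.
#'
#' @param path path to a YAML configuration file.
#' @param seed master seed used when the file does not set one.
#' @return A validated `run_config`.
#' @export
validate_config <- function(path, seed = 1L) {
  if (!file.exists(path)) {
    mps_abort(sprintf("no such config file: '%s'", path), "mpsdiag_io_error")
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  check_unknown_keys(user, config_keys$top, "configuration")
  cfg <- default_config(seed = user$seed %||% seed)
  if (!is.null(user$out_dir)) cfg$out_dir <- user$out_dir
  if (!is.null(user$standardization)) {
    if (!user$standardization %in% c("own", "training")) {
      mps_abort("standardization must be 'own' or 'training'",
                "mpsdiag_config_error", key = "standardization")
    }
    cfg$standardization <- user$standardization
  }
  cfg$de <- merge_block(cfg$de, user$de, config_keys$de, "de")
  cfg$selection <- merge_block(cfg$selection, user$selection,
                               config_keys$selection, "selection")
  cfg$training_config <- merge_block(cfg$training_config, user$training_config,
                                     config_keys$training_config,
                                     "training_config")
  for (ds in c("training", "validation")) {
    blk <- user[[ds]]
    if (is.null(blk)) next
    check_unknown_keys(blk, config_keys$dataset, ds)
    has_file <- !is.null(blk$file); has_syn <- !is.null(blk$synthetic)
    if (has_file == has_syn) {
      mps_abort(sprintf("dataset '%s' must set exactly one of file/synthetic", ds),
                "mpsdiag_config_error", key = ds)
    }
    if (has_syn) {
      check_unknown_keys(blk$synthetic, config_keys$synthetic,
                         paste0(ds, "$synthetic"))
      blk$synthetic <- merge_block(default_synthetic_block(), blk$synthetic,
                                   config_keys$synthetic,
                                   paste0(ds, "$synthetic"))
    }
    if (has_file && !file.exists(blk$file)) {
      mps_abort(sprintf("dataset '%s' file does not exist: '%s'", ds, blk$file),
                "mpsdiag_config_error", key = ds)
    }
    cfg[[ds]] <- blk
  }
  if (!is.null(user$tf_edges)) {
    if (!file.exists(user$tf_edges)) {
      mps_abort(sprintf("tf_edges file does not exist: '%s'", user$tf_edges),
                "mpsdiag_config_error", key = "tf_edges")
    }
    cfg$tf_edges <- user$tf_edges
  }
  # range constraints
  sel <- cfg$selection
  for (k in names(sel)) stopifnot_count(sel[[k]], paste0("selection$", k))
  if (!is.numeric(cfg$de$fc_threshold) || cfg$de$fc_threshold < 1) {
    mps_abort("de$fc_threshold must be >= 1", "mpsdiag_config_error",
              key = "fc_threshold")
  }
  if (!is.numeric(cfg$de$p_threshold) || cfg$de$p_threshold <= 0 ||
      cfg$de$p_threshold > 1) {
    mps_abort("de$p_threshold must be in (0, 1]", "mpsdiag_config_error",
              key = "p_threshold")
  }
  do.call(training_config, c(cfg$training_config, list(seed = 1L))) # validates
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "mpsdiag_stage_error")) return()
    stop(structure(class = c(class(e)[1], "mpsdiag_stage_error",
                             "mpsdiag_error", "error", "condition"),
                   list(message = sprintf("[stage %s] %s", stage,
                                          conditionMessage(e)),
                        stage = stage)))
  })
}

load_dataset <- function(block, structure_seed, sampling_seed, probe_seed) {
  if (!is.null(block$synthetic)) {
    syn <- block$synthetic
    syn$seed <- syn$seed %||% structure_seed
    syn$sampling_seed <- syn$sampling_seed %||% sampling_seed
    spec <- do.call(synthetic_spec, syn)
    sim <- generate_expression(spec)
    mat <- sim$matrix
    if (spec$probes_per_gene > 1L) {
      probes <- attach_probe_layer(mat, spec$probes_per_gene,
                                   seed = probe_seed)
      mat <- collapse_probes(probes)
    }
    list(matrix = mat, truth = sim$truth)
  } else {
    mat <- if (is.null(block$labels)) {
      read_series_matrix(block$file)
    } else {
      lab <- read.delim(block$labels)
      read_matrix_tsv(block$file, lab[[2L]])
    }
    list(matrix = mat, truth = NULL)
  }
}

#' Run the full train/validate diagnostic-model workflow
#'
#' Executes, in order: data loading or simulation (with probe collapse when a
#' probe layer is present), differential-expression screening on the training
#' cohort, consensus random-forest feature selection on the differential
#' genes, alignment of the selected genes to the validation cohort (absent
#' genes are dropped and recorded), Z-scoring, single-hidden-node network
#' training, linearization to gene weights, MPS scoring and ROC/AUC on both
#' cohorts, and optional TF-subnetwork extraction. All artifacts are written
#' under `config$out_dir` as TSV/plain text, plus a JSON run manifest
#' sufficient to re-run the pipeline bit-identically. Progress goes to
#' standard error.
#'
#' @param config a `run_config` from [default_config()] or
#'   [validate_config()].
#' @param quiet suppress progress messages.
#' @return The manifest (class `run_manifest`), invisibly a list with the
#'   resolved config, per-stage seeds, output files, and stage summaries
#'   (gene counts, selected genes, AUCs).
#' @export
run_all <- function(config = default_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6L)
  names(seeds) <- c("training_data", "validation_data", "probe_layer",
                    "selection_base", "network", "spare")
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  say("stage data: loading/simulating cohorts (seed %d)", config$seed)
  # synthetic training and validation cohorts share one structure seed
  # (the same planted genes) and differ in their sampling seeds, giving an
  # independent validation cohort from the same generative spec
  structure_seed <- config$training$synthetic$seed %||% seeds[["training_data"]]
  train <- with_stage("data", load_dataset(config$training,
                                           structure_seed,
                                           seeds[["training_data"]],
                                           seeds[["probe_layer"]]))
  valid <- with_stage("data", load_dataset(config$validation,
                                           structure_seed,
                                           seeds[["validation_data"]],
                                           seeds[["probe_layer"]] + 1L))

  say("stage de_screen: fold-change %.2f, p < %g (adjust: %s)",
      config$de$fc_threshold, config$de$p_threshold, config$de$adjust)
  deg <- with_stage("de_screen",
    screen_degs(train$matrix, config$de$fc_threshold, config$de$p_threshold,
                config$de$adjust))
  candidates <- differential_genes(deg)
  if (length(candidates) == 0L) {
    mps_abort("[stage de_screen] no differential genes at these thresholds",
              "mpsdiag_empty_selection_error")
  }
  say("stage de_screen: %d differential genes (%d up, %d down)",
      length(candidates), sum(deg$group == "up"), sum(deg$group == "down"))
  emit("deg_table.tsv", function(p) write_deg_table(deg, p))
  emit("volcano.tsv", function(p) write.table(volcano_table(deg), p,
       sep = "\t", quote = FALSE, row.names = FALSE))

  ztrain <- with_stage("preprocess", zscore(train$matrix))
  zcand <- align_genes(ztrain, candidates)$matrix

  say("stage feature_select: %d cycles x elimination on %d genes (base seed %d)",
      config$selection$n_cycles, length(candidates), seeds[["selection_base"]])
  sel <- with_stage("feature_select",
    consensus_select(zcand, n_cycles = config$selection$n_cycles,
                     min_appearances = config$selection$min_appearances,
                     n_trees = config$selection$n_trees,
                     base_seed = seeds[["selection_base"]],
                     max_iterations = config$selection$max_iterations))
  say("stage feature_select: %d characteristic genes", length(sel$final_genes))
  emit("appearance_counts.tsv", function(p) write.table(
    data.frame(gene = names(sel$appearance_counts),
               count = as.integer(sel$appearance_counts)),
    p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("cycle_gene_sets.tsv", function(p) write.table(
    data.frame(cycle = rep(seq_along(sel$cycle_results),
                           lengths(sel$cycle_results)),
               gene = unlist(sel$cycle_results)),
    p, sep = "\t", quote = FALSE, row.names = FALSE))

  aligned <- with_stage("align", align_genes(valid$matrix, sel$final_genes))
  genes_used <- rownames(aligned$matrix$values)
  if (length(aligned$missing) > 0L) {
    say("stage align: %d selected gene(s) absent from validation, dropped: %s",
        length(aligned$missing), paste(aligned$missing, collapse = ", "))
  }
  emit("final_genes.txt", function(p) writeLines(genes_used, p))

  say("stage train: %d-gene network, hidden_size %d, maxit %d (seed %d); standardization: %s",
      length(genes_used), config$training_config$hidden_size,
      config$training_config$max_iterations, seeds[["network"]],
      config$standardization)
  tc <- do.call(training_config,
                c(config$training_config, list(seed = seeds[["network"]])))
  ztrain_sel <- align_genes(ztrain, genes_used)$matrix
  net <- with_stage("train", train_network(ztrain_sel, config = tc))
  weights <- extract_gene_weights(net)
  emit("gene_weights.tsv", function(p) write_gene_weights(weights, p))
  emit("network.txt", function(p) write_network(net, p))

  ref <- if (config$standardization == "training") {
    attr(ztrain, "stats")
  } else NULL
  zvalid <- with_stage("preprocess",
    align_genes(zscore(valid$matrix, reference_stats = ref),
                genes_used)$matrix)

  mps_train <- compute_mps(weights, ztrain_sel)
  mps_valid <- compute_mps(weights, zvalid)
  roc_train <- with_stage("evaluate", roc_curve(mps_train))
  roc_valid <- with_stage("evaluate", roc_curve(mps_valid))
  net_valid <- data.frame(mps = as.numeric(predict_network(net, zvalid)),
                          label = as.character(zvalid$labels))
  auc_net_valid <- auc_mannwhitney(net_valid)
  emit("mps_training.tsv", function(p) write_gene_weights(mps_train, p))
  emit("mps_validation.tsv", function(p) write_gene_weights(mps_valid, p))
  emit("roc_training.tsv", function(p) write_roc_points(roc_train, p))
  emit("roc_validation.tsv", function(p) write_roc_points(roc_valid, p))
  say("stage evaluate: training AUC %.3f, validation AUC %.3f (network output: %.3f)",
      auc(roc_train), auc(roc_valid), auc_net_valid)

  subnet_summary <- NULL
  if (!is.null(config$tf_edges)) {
    edges <- read_tf_edges(config$tf_edges)
    subnet <- tf_subnetwork(edges, genes_used)
    emit("tf_subnetwork.tsv", function(p) write.table(subnet, p, sep = "\t",
         quote = FALSE, row.names = FALSE, col.names = FALSE))
    subnet_summary <- nrow(subnet)
    say("stage tf_subnetwork: %d edge(s) retained", subnet_summary)
  }

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("mpsdiag")),
    config = unclass(config),
    seeds = as.list(seeds),
    files = files,
    summaries = list(
      n_genes_training = nrow(train$matrix$values),
      n_differential = length(candidates),
      n_up = sum(deg$group == "up"), n_down = sum(deg$group == "down"),
      n_selected = length(sel$final_genes),
      selected_genes = sel$final_genes,
      genes_used = genes_used,
      dropped_in_validation = aligned$missing,
      training_auc = auc(roc_train),
      validation_auc = auc(roc_valid),
      validation_auc_network = auc_net_valid,
      tf_subnetwork_edges = subnet_summary
    ),
    truth = list(training = train$truth, validation = valid$truth)
  ), class = "run_manifest")
  jsonlite::write_json(
    manifest[c("package_version", "config", "seeds", "files", "summaries")],
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  manifest$files <- c(files, "manifest.json")
  invisible(manifest)
}
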