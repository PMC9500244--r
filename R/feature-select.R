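#' Fit a random forest classifier on candidate genes
#'
#' Thin, seeded wrapper around [randomForest::randomForest()] that keeps what
#' the downstream importance machinery needs: the forest structure and the
#' per-tree bootstrap (in-bag) counts, from which each tree's out-of-bag
#' (OOB) sample set is derived. Defaults follow the field's conventions:
#' 500 trees, `floor(sqrt(p))` candidate variables per split, bootstrap with
#' replacement, Gini splitting, majority vote.
#'
#' @param z a `zmatrix` (genes x samples) restricted to the candidate genes.
#' @param labels case/control factor per sample (defaults to `z$labels`).
#' @param n_trees number of trees.
#' @param seed integer seed; the same seed reproduces the forest (including
#'   its OOB index sets) exactly.
#' @return An object of class `mps_forest`: list with `rf` (the randomForest
#'   fit), `genes`, `labels`, `oob` (per-tree integer vectors of OOB sample
#'   indices), `seed`.
#' @export
fit_forest <- function(z, labels = z$labels, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(z, "expr_matrix"))
  stopifnot_count(n_trees, "n_trees")
  labels <- factor(as.character(labels), c("case", "control"))
  if (nlevels(droplevels(labels)) < 2L) {
    mps_abort("labels contain a single class; need both case and control",
              "mpsdiag_validation_error", field = "labels")
  }
  if (min(table(labels)) < 2L) {
    mps_abort("need >= 2 samples per class", "mpsdiag_validation_error")
  }
  if (nrow(z$values) < 1L) {
    mps_abort("need >= 1 candidate gene", "mpsdiag_validation_error")
  }
  x <- t(z$values)
  rf <- withr::with_seed(as.integer(seed),
    randomForest::randomForest(x, labels, ntree = n_trees,
                               keep.inbag = TRUE, keep.forest = TRUE))
  oob <- lapply(seq_len(n_trees), function(t) which(rf$inbag[, t] == 0L))
  structure(list(rf = rf, genes = rownames(z$values), labels = labels,
                 oob = oob, seed = as.integer(seed)),
            class = "mps_forest")
}

#' Overall out-of-bag accuracy of a fitted forest
#' @param forest an `mps_forest`.
#' @return Fraction of samples whose OOB-aggregated prediction matches the
#'   label.
#' @export
oob_accuracy <- function(forest) {
  mean(forest$rf$predicted == forest$labels, na.rm = TRUE)
}

# Vectorised single-tree prediction for (tree, sample) pairs, walking the
# stored forest structure level by level. `override_var`, if given, replaces
# that variable's value for pair i with override_vals[i] (used for the
# within-OOB permutation). Returns the class index (1 = first level).
forest_pair_predict <- function(fr, X, tree_idx, sample_idx,
                                override_var = NULL, override_vals = NULL) {
  npair <- length(tree_idx)
  node <- rep(1L, npair)
  repeat {
    idx <- cbind(node, tree_idx)
    active <- which(fr$nodestatus[idx] == 1L)
    if (length(active) == 0L) break
    an <- node[active]; at <- tree_idx[active]
    aidx <- cbind(an, at)
    v <- fr$bestvar[aidx]
    xv <- X[cbind(sample_idx[active], v)]
    if (!is.null(override_var)) {
      ov <- v == override_var
      xv[ov] <- override_vals[active][ov]
    }
    goleft <- xv <= fr$xbestsplit[aidx]
    side <- ifelse(goleft, 1L, 2L)
    node[active] <- fr$treemap[cbind(an, side, at)]
  }
  fr$nodepred[cbind(node, tree_idx)]
}

#' Raw mean decrease in out-of-bag accuracy under per-gene permutation
#'
#' For each gene, and for every tree whose splits use that gene: the tree's
#' accuracy on its own out-of-bag samples is compared with the accuracy after
#' permuting the gene's values among those OOB samples. The importance is the
#' average decrease over all trees (trees that never split on the gene
#' contribute exactly 0). This is the raw (unscaled) mean decrease accuracy;
#' no standard-error normalization is applied.
#'
#' @param forest an `mps_forest` from [fit_forest()].
#' @param z the `zmatrix` the forest was fitted on (same genes).
#' @param labels sample labels (defaults to the forest's).
#' @param seed integer seed for the permutations.
#' @return Named numeric vector (class `importance_table`): one finite value
#'   per gene.
#' @export
mean_decrease_accuracy <- function(forest, z, labels = forest$labels,
                                   seed = 1L) {
  stopifnot(inherits(forest, "mps_forest"))
  if (!identical(forest$genes, rownames(z$values))) {
    mps_abort("forest was not fitted on the genes of 'z'",
              "mpsdiag_validation_error")
  }
  fr <- forest$rf$forest
  X <- t(z$values)
  ntree <- fr$ntree
  p <- length(forest$genes)
  y_int <- as.integer(factor(as.character(labels), forest$rf$classes))

  oob <- forest$oob
  len <- lengths(oob)
  with_oob <- which(len > 0L)
  tree_idx <- rep.int(seq_len(ntree), len)
  sample_idx <- unlist(oob, use.names = FALSE)
  pair_of_tree <- split(seq_along(tree_idx), tree_idx)

  base_pred <- forest_pair_predict(fr, X, tree_idx, sample_idx)
  base_correct <- as.integer(base_pred == y_int[sample_idx])
  acc0 <- numeric(ntree)
  acc0[with_oob] <- rowsum(base_correct, tree_idx)[, 1L] / len[with_oob]

  # which trees split on which variable
  split_nodes <- fr$nodestatus == 1L
  var_by_tree <- lapply(seq_len(ntree), function(t)
    unique(fr$bestvar[split_nodes[, t], t]))
  trees_of_var <- vector("list", p)
  tv <- rep.int(seq_len(ntree), lengths(var_by_tree))
  vv <- unlist(var_by_tree, use.names = FALSE)
  for (g in seq_len(p)) trees_of_var[[g]] <- tv[vv == g]

  imp <- numeric(p)
  withr::with_seed(as.integer(seed), {
    for (g in seq_len(p)) {
      trees_g <- trees_of_var[[g]]
      trees_g <- trees_g[len[trees_g] > 0L]
      if (length(trees_g) == 0L) next
      idx <- unlist(pair_of_tree[trees_g], use.names = FALSE)
      perm_samples <- unlist(lapply(trees_g, function(t) {
        s <- oob[[t]]
        if (length(s) > 1L) s[sample.int(length(s))] else s
      }), use.names = FALSE)
      perm_vals <- X[cbind(perm_samples, g)]
      pred <- forest_pair_predict(fr, X, tree_idx[idx], sample_idx[idx],
                                  override_var = g, override_vals = perm_vals)
      correct <- as.integer(pred == y_int[sample_idx[idx]])
      acc_g <- rowsum(correct, tree_idx[idx])[, 1L] / len[trees_g]
      imp[g] <- sum(acc0[trees_g] - acc_g) / ntree
    }
  })
  structure(stats::setNames(imp, forest$genes), class = "importance_table")
}

#' Iterative elimination of negative-importance genes
#'
#' Repeats fit-forest / compute-importance / delete-negative-importance-genes
#' until the importance table has no strictly negative values. Genes with
#' importance exactly 0 are kept. The full trace (per-iteration gene sets and
#' importance tables) is returned; gene sets strictly shrink between
#' iterations, so the loop always terminates within `gene count + 1`
#' iterations unless `max_iterations` cuts it short first.
#'
#' @param z a `zmatrix` of candidate genes.
#' @param labels case/control per sample.
#' @param n_trees trees per forest refit.
#' @param seed cycle seed; per-iteration forest and permutation seeds are
#'   derived from it deterministically.
#' @param max_iterations safety bound on refits.
#' @return An object of class `elimination_trace`: list with `iterations`
#'   (each: `genes`, `importance`), `terminal_genes`, `terminal_importance`.
#' @export
eliminate_until_nonnegative <- function(z, labels = z$labels, n_trees = 500L,
                                        seed = 1L, max_iterations = 100L) {
  stopifnot(inherits(z, "expr_matrix"))
  stopifnot_count(max_iterations, "max_iterations")
  seeds <- matrix(derive_seeds(seed, 2L * max_iterations), ncol = 2L)
  current <- rownames(z$values)
  iterations <- list()
  for (i in seq_len(max_iterations)) {
    zi <- align_genes(z, current)$matrix
    forest <- fit_forest(zi, labels, n_trees = n_trees, seed = seeds[i, 1L])
    imp <- mean_decrease_accuracy(forest, zi, labels, seed = seeds[i, 2L])
    iterations[[i]] <- list(genes = current, importance = imp)
    negative <- names(imp)[imp < 0]
    if (length(negative) == 0L) {
      return(structure(list(iterations = iterations,
                            terminal_genes = current,
                            terminal_importance = imp,
                            seed = as.integer(seed)),
                       class = "elimination_trace"))
    }
    current <- setdiff(current, negative)
    if (length(current) == 0L) {
      mps_abort("all genes eliminated: every importance went negative",
                "mpsdiag_empty_selection_error")
    }
  }
  mps_abort(sprintf("elimination did not reach a nonnegative fixed point in %d iterations",
                    max_iterations), "mpsdiag_iteration_limit_error")
}

#' Consensus characteristic-gene selection over repeated elimination cycles
#'
#' Runs `n_cycles` independent [eliminate_until_nonnegative()] cycles (cycle
#' seeds `base_seed + 0 ... + n_cycles - 1` unless `cycle_seeds` is given),
#' counts in how many terminal gene sets each gene appears, and keeps the
#' genes appearing in at least `min_appearances` cycles. The default of 4
#' out of 10 reads "appeared more than three times" literally.
#'
#' @param z a `zmatrix` of candidate genes (e.g. the differential genes).
#' @param labels case/control per sample.
#' @param n_cycles number of independent elimination cycles.
#' @param min_appearances minimum number of terminal sets a gene must appear
#'   in (>= 1).
#' @param n_trees trees per forest refit.
#' @param base_seed integer; cycle c uses seed `base_seed + c - 1`.
#' @param cycle_seeds optional explicit per-cycle seeds (overrides
#'   `base_seed`).
#' @param max_iterations per-cycle bound, see [eliminate_until_nonnegative()].
#' @return An object of class `consensus_selection`: `cycle_results` (the
#'   terminal gene set of each cycle), `appearance_counts` (named, every
#'   input gene, in `[0, n_cycles]`), `min_appearances`, `final_genes`.
#' @export
consensus_select <- function(z, labels = z$labels, n_cycles = 10L,
                             min_appearances = 4L, n_trees = 500L,
                             base_seed = 1L, cycle_seeds = NULL,
                             max_iterations = 100L) {
  stopifnot_count(n_cycles, "n_cycles")
  stopifnot_count(min_appearances, "min_appearances")
  if (is.null(cycle_seeds)) {
    cycle_seeds <- as.integer(base_seed) + seq_len(n_cycles) - 1L
  }
  stopifnot(length(cycle_seeds) == n_cycles)
  cycle_results <- lapply(cycle_seeds, function(s)
    eliminate_until_nonnegative(z, labels, n_trees = n_trees, seed = s,
                                max_iterations = max_iterations)$terminal_genes)
  genes <- rownames(z$values)
  counts <- stats::setNames(integer(length(genes)), genes)
  for (res in cycle_results) counts[res] <- counts[res] + 1L
  final <- genes[counts >= min_appearances]
  if (length(final) == 0L) {
    mps_abort(paste0("no gene reached min_appearances = ", min_appearances,
                     "; highest observed count: ", max(counts)),
              "mpsdiag_empty_selection_error", counts = counts)
  }
  structure(list(cycle_results = cycle_results,
                 appearance_counts = counts,
                 min_appearances = as.integer(min_appearances),
                 final_genes = final),
            class = "consensus_selection")
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf("<consensus_selection> %d cycles, threshold >= %d, %d final genes\n",
              length(x$cycle_results), x$min_appearances,
              length(x$final_genes)))
  invisible(x)
}
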