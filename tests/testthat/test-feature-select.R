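test_that("fit_forest is seeded, records OOB sets, and learns a separable gene", {
  co <- make_cohort(n_genes = 20, n_informative = 1, effect_size = 6,
                    seed = 2)
  f1 <- fit_forest(co$z, n_trees = 100, seed = 5)
  f2 <- fit_forest(co$z, n_trees = 100, seed = 5)
  expect_identical(f1$oob, f2$oob)
  expect_identical(f1$rf$forest, f2$rf$forest)
  expect_gte(oob_accuracy(f1), 0.9)
  expect_length(f1$oob, 100)
  # OOB sets are the complement of the bootstrap draws
  expect_true(all(vapply(seq_len(100), function(t)
    all(f1$rf$inbag[f1$oob[[t]], t] == 0), logical(1))))
})

test_that("single-class labels and empty gene sets are rejected", {
  co <- make_cohort(n_genes = 5, seed = 3)
  expect_error(fit_forest(co$z, labels = rep("case", ncol(co$z$values))),
               class = "mpsdiag_validation_error")
})

test_that("label-permuted data give chance-level OOB accuracy", {
  accs <- vapply(1:3, function(s) {
    co <- make_cohort(n_genes = 50, n_case = 30, n_control = 30,
                      n_informative = 5, effect_size = 2, seed = s)
    perm <- withr::with_seed(s, sample(as.character(co$z$labels)))
    oob_accuracy(fit_forest(co$z, labels = perm, n_trees = 200, seed = s))
  }, numeric(1))
  expect_true(all(accs >= 0.35 & accs <= 0.65))
})

test_that("hand-rolled tree traversal reproduces randomForest predictions", {
  co <- make_cohort(n_genes = 30, n_informative = 3, seed = 6)
  f <- fit_forest(co$z, n_trees = 50, seed = 1)
  X <- t(co$z$values)
  ind <- predict(f$rf, X, predict.all = TRUE)$individual
  ref <- matrix(as.integer(factor(ind, f$rf$classes)), nrow(X), 50)
  ti <- rep(seq_len(50), each = nrow(X))
  si <- rep(seq_len(nrow(X)), 50)
  mine <- mpsdiag:::forest_pair_predict(f$rf$forest, X, ti, si)
  expect_identical(mine, ref[cbind(si, ti)])
})

test_that("importance: informative gene dominates, noise centred at zero, unused gene exactly zero", {
  # sole informative gene among noise: strictly largest, positive (5 seeds)
  wins <- vapply(1:5, function(s) {
    co <- make_cohort(n_genes = 51, n_case = 25, n_control = 25,
                      n_informative = 1, effect_size = 3, seed = s)
    f <- fit_forest(co$z, n_trees = 200, seed = s)
    imp <- mean_decrease_accuracy(f, co$z, seed = s)
    g <- co$truth$informative_genes
    imp[g] > 0 && all(imp[g] > imp[names(imp) != g])
  }, logical(1))
  expect_true(all(wins))

  # a pure-noise gene averages ~0 over 20 seeds
  noise_imp <- vapply(1:20, function(s) {
    co <- make_cohort(n_genes = 20, n_case = 15, n_control = 15,
                      n_informative = 1, effect_size = 3, seed = 100 + s)
    f <- fit_forest(co$z, n_trees = 100, seed = s)
    imp <- mean_decrease_accuracy(f, co$z, seed = s)
    mean(imp[setdiff(names(imp), co$truth$informative_genes)])
  }, numeric(1))
  expect_lt(abs(mean(noise_imp)), 0.02)

  # a constant gene is never split on -> importance exactly 0
  withr::local_seed(4)
  vals <- rbind(matrix(rnorm(5 * 30), 5), konst = rep(0, 30))
  m <- make_expr(vals, rep(c("case", "control"), each = 15),
                 genes = c(paste0("g", 1:5), "konst"))
  f <- fit_forest(m, n_trees = 100, seed = 2)
  imp <- mean_decrease_accuracy(f, m, seed = 3)
  expect_identical(unname(imp["konst"]), 0)
})

test_that("importance agrees with randomForest's raw MeanDecreaseAccuracy", {
  co <- make_cohort(n_genes = 40, n_case = 30, n_control = 30,
                    n_informative = 8, effect_size = 1.5, seed = 8)
  f <- fit_forest(co$z, n_trees = 300, seed = 8)
  mine <- mean_decrease_accuracy(f, co$z, seed = 8)
  ref <- withr::with_seed(8, randomForest::randomForest(
    t(co$z$values), co$z$labels, ntree = 300, importance = TRUE))
  theirs <- ref$importance[, "MeanDecreaseAccuracy"]
  expect_gt(cor(mine, theirs[names(mine)]), 0.9)
})

test_that("elimination terminates at a nonnegative fixed point within the shrinkage bound", {
  co <- make_cohort(n_genes = 80, n_case = 25, n_control = 25,
                    n_informative = 10, effect_size = 2, seed = 10)
  tr <- eliminate_until_nonnegative(co$z, n_trees = 200, seed = 3)
  expect_true(all(tr$terminal_importance >= 0))
  expect_lte(length(tr$iterations), 81)
  sizes <- lengths(lapply(tr$iterations, `[[`, "genes"))
  expect_true(all(diff(sizes) < 0))
  expect_setequal(names(tr$terminal_importance), tr$terminal_genes)
  # trace genes shrink strictly except at the fixed point
  expect_identical(tr$iterations[[length(tr$iterations)]]$genes,
                   tr$terminal_genes)
})

test_that("elimination retains the planted genes under strong signal", {
  kept <- vapply(1:5, function(s) {
    sim <- generate_expression(synthetic_spec(
      n_genes = 100, n_case = 40, n_control = 40, n_informative = 10,
      effect_size = 2, noise_sd = 1, seed = s))
    z <- zscore(sim$matrix)
    tr <- eliminate_until_nonnegative(z, n_trees = 200, seed = s)
    sum(sim$truth$informative_genes %in% tr$terminal_genes)
  }, numeric(1))
  expect_gte(mean(kept), 8)
})

test_that("consensus vote applies the appearance threshold and is deterministic", {
  co <- make_cohort(n_genes = 40, n_case = 30, n_control = 30,
                    n_informative = 6, effect_size = 2, seed = 14)
  sel1 <- consensus_select(co$z, n_cycles = 4, min_appearances = 2,
                           n_trees = 100, base_seed = 50)
  sel2 <- consensus_select(co$z, n_cycles = 4, min_appearances = 2,
                           n_trees = 100, base_seed = 50)
  expect_identical(sel1, sel2)
  expect_setequal(sel1$final_genes,
                  names(sel1$appearance_counts)[sel1$appearance_counts >= 2])
  expect_true(all(sel1$appearance_counts <= 4))

  # min_appearances = 1: final set is the union of terminal sets
  sel_union <- consensus_select(co$z, n_cycles = 4, min_appearances = 1,
                                n_trees = 100, base_seed = 50)
  expect_setequal(sel_union$final_genes,
                  unique(unlist(sel_union$cycle_results)))

  # counts are exchangeable across cycle order
  rev_sel <- consensus_select(co$z, n_cycles = 4, min_appearances = 2,
                              n_trees = 100, cycle_seeds = c(53:50))
  expect_identical(rev_sel$appearance_counts, sel1$appearance_counts)
})

test_that("consensus recovers planted genes with high precision and recall", {
  stats <- vapply(1:2, function(s) {
    sim <- generate_expression(synthetic_spec(
      n_genes = 120, n_case = 40, n_control = 40, n_informative = 12,
      effect_size = 2, noise_sd = 1, seed = s))
    z <- zscore(sim$matrix)
    sel <- consensus_select(z, n_cycles = 10, min_appearances = 4,
                            n_trees = 200, base_seed = 20 + s)
    tp <- sum(sel$final_genes %in% sim$truth$informative_genes)
    c(tp / length(sel$final_genes), tp / 12)
  }, numeric(2))
  expect_gte(mean(stats[1, ]), 0.8)  # precision
  expect_gte(mean(stats[2, ]), 0.8)  # recall
})
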