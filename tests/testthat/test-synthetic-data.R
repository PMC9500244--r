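test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(n_genes = 10, n_case = 5, n_control = 5,
                              n_informative = 11),
               "n_informative", class = "mpsdiag_validation_error")
  expect_error(synthetic_spec(n_genes = 10, n_case = 5, n_control = 5,
                              noise_sd = 0),
               "noise_sd", class = "mpsdiag_validation_error")
  expect_error(synthetic_spec(n_genes = 0, n_case = 5, n_control = 5),
               "n_genes", class = "mpsdiag_validation_error")
})

test_that("planted structure is exactly as specified", {
  sim <- generate_expression(synthetic_spec(
    n_genes = 100, n_case = 8, n_control = 8, n_informative = 10,
    effect_size = 2, seed = 3))
  expect_equal(dim(sim$matrix$values), c(100L, 16L))
  expect_length(sim$truth$informative_genes, 10)
  expect_equal(sum(abs(sim$truth$shift) == 2), 10)
  expect_true(all(sim$truth$shift[setdiff(names(sim$truth$shift),
                                          sim$truth$informative_genes)] == 0))
  # half up, half down
  expect_equal(sum(sim$truth$shift > 0), 5)

  null_sim <- generate_expression(synthetic_spec(
    n_genes = 50, n_case = 5, n_control = 5, effect_size = 0,
    n_informative = 5, seed = 3))
  expect_true(all(null_sim$truth$shift == 0))
})

test_that("identical spec and seed reproduce the matrix; seeds differ", {
  sp <- synthetic_spec(n_genes = 40, n_case = 6, n_control = 6,
                       n_informative = 4, effect_size = 1, seed = 11)
  a <- generate_expression(sp)
  b <- generate_expression(sp)
  expect_identical(a$matrix$values, b$matrix$values)
  sp2 <- synthetic_spec(n_genes = 40, n_case = 6, n_control = 6,
                        n_informative = 4, effect_size = 1, seed = 12)
  c_ <- generate_expression(sp2)
  expect_true(any(a$matrix$values != c_$matrix$values))
})

test_that("shared structure seed with different sampling seeds gives an independent cohort with the same planted genes", {
  a <- generate_expression(synthetic_spec(n_genes = 50, n_case = 10,
    n_control = 10, n_informative = 5, effect_size = 2, seed = 5))
  b <- generate_expression(synthetic_spec(n_genes = 50, n_case = 10,
    n_control = 10, n_informative = 5, effect_size = 2, seed = 5,
    sampling_seed = 99))
  expect_identical(a$truth, b$truth)
  expect_true(all(a$matrix$values != b$matrix$values))
})

test_that("null data give uniform Welch p-values and calibrated type-I error", {
  # pooled over 3 seeds for the flagged fraction; KS on one 10,000-gene draw
  fractions <- vapply(1:3, function(s) {
    sim <- generate_expression(synthetic_spec(
      n_genes = 10000, n_case = 40, n_control = 40, n_informative = 0,
      seed = s))
    wt <- welch_t(sim$matrix$values[, case_columns(sim$matrix)],
                  sim$matrix$values[, control_columns(sim$matrix)])
    if (s == 1) {
      ks <- suppressWarnings(stats::ks.test(wt$p_value, "punif"))
      expect_gt(ks$p.value, 0.001)
    }
    mean(wt$p_value < 0.05)
  }, numeric(1))
  band <- stats::qbinom(c(0.005, 0.995), 10000, 0.05) / 10000
  expect_true(all(fractions >= band[1] & fractions <= band[2]))
})

test_that("empirical planted effect converges to effect_size", {
  sim <- generate_expression(synthetic_spec(
    n_genes = 200, n_case = 50, n_control = 40, n_informative = 20,
    effect_size = 1.5, noise_sd = 1, seed = 2))
  m <- sim$matrix
  diff <- rowMeans(m$values[, case_columns(m)]) -
    rowMeans(m$values[, control_columns(m)])
  inf <- sim$truth$informative_genes
  dev <- abs(diff[inf] - sim$truth$shift[inf])
  expect_true(all(dev < 3 * 1 / sqrt(40)))
})

test_that("probe layer expands genes and collapses back to one row per gene", {
  sim <- generate_expression(synthetic_spec(
    n_genes = 100, n_case = 5, n_control = 5, seed = 4))
  pm <- attach_probe_layer(sim$matrix, probes_per_gene = 3, seed = 8)
  expect_equal(nrow(pm$values), 300)
  expect_setequal(unique(pm$probe_map$gene_symbol), rownames(sim$matrix$values))
  expect_setequal(pm$probe_map$probe_id, rownames(pm$values))
  collapsed <- collapse_probes(pm)
  expect_equal(nrow(collapsed$values), 100)
  expect_setequal(rownames(collapsed$values), rownames(sim$matrix$values))

  # identity case: one probe per gene, values pass through
  pm1 <- attach_probe_layer(sim$matrix, probes_per_gene = 1)
  expect_equal(unname(pm1$values), unname(sim$matrix$values))
  expect_equal(nrow(pm1$probe_map), 100)
})

test_that("series-matrix dialect round-trips exactly, labels included", {
  m <- make_expr(matrix(c(1.25, -3.5, pi, exp(1)), 2, 2),
                 c("case", "control"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_series_matrix(m, path)
  back <- read_series_matrix(path)
  expect_identical(back$values, m$values)
  expect_identical(back$labels, m$labels)

  sim <- generate_expression(synthetic_spec(
    n_genes = 1000, n_case = 50, n_control = 40, n_informative = 30,
    effect_size = 1, seed = 6))
  write_series_matrix(sim$matrix, path)
  back <- read_series_matrix(path)
  expect_identical(back$values, sim$matrix$values)
  suppressWarnings(
    expect_error(write_series_matrix(m, file.path(tempdir(), "no/such/dir/x")),
                 class = "mpsdiag_io_error"))
})
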