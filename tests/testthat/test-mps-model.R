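test_that("training is seeded, monotone in loss, and separates a strong gene", {
  co <- make_cohort(n_genes = 3, n_case = 15, n_control = 15,
                    n_informative = 1, effect_size = 6, seed = 5)
  cfg <- training_config(seed = 2)
  net1 <- train_network(co$z, config = cfg)
  net2 <- train_network(co$z, config = cfg)
  expect_identical(net1$W1, net2$W1)
  expect_identical(net1$loss_history, net2$loss_history)
  expect_true(all(diff(net1$loss_history) <= 0))
  expect_lt(net1$loss_history[length(net1$loss_history)],
            net1$loss_history[1])
  out <- predict_network(net1, co$z)
  expect_equal(auc_pairwise(out, as.character(co$z$labels)), 1.0)
})

test_that("degenerate label sets are rejected", {
  co <- make_cohort(n_genes = 4, seed = 6)
  expect_error(train_network(co$z, labels = rep("case", ncol(co$z$values))),
               class = "mpsdiag_validation_error")
})

test_that("a single hidden unit cannot represent XOR", {
  withr::local_seed(3)
  n_per <- 10
  g1 <- rep(c(-1, -1, 1, 1), each = n_per) + rnorm(4 * n_per, sd = 0.05)
  g2 <- rep(c(-1, 1, -1, 1), each = n_per) + rnorm(4 * n_per, sd = 0.05)
  lab <- ifelse(rep(c(-1, -1, 1, 1), each = n_per) *
                  rep(c(-1, 1, -1, 1), each = n_per) > 0, "case", "control")
  m <- make_expr(rbind(g1, g2), lab, genes = c("gA", "gB"))
  net <- train_network(m, config = training_config(max_iterations = 500,
                                                   seed = 1))
  out <- predict_network(net, m)
  expect_lte(auc_pairwise(out, lab), 0.75)
})

test_that("back-propagated gradients match finite differences", {
  for (s in 1:5) {
    co <- make_cohort(n_genes = 5, n_case = 10, n_control = 10,
                      n_informative = 2, effect_size = 1, seed = s)
    net <- train_network(co$z, config = training_config(max_iterations = 20,
                                                        seed = s))
    expect_lt(gradient_check(net, co$z, epsilon = 1e-6), 1e-5)
  }
  # discrepancy of the one-sided quotient shrinks with epsilon
  co <- make_cohort(n_genes = 4, n_case = 8, n_control = 8, seed = 30)
  net <- train_network(co$z, config = training_config(max_iterations = 5))
  d <- vapply(c(1e-2, 1e-4, 1e-6), function(e)
    gradient_check(net, co$z, epsilon = e, method = "forward"), numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("output-bias gradient has its closed form at zero weights", {
  co <- make_cohort(n_genes = 4, n_case = 10, n_control = 10, seed = 7)
  X <- t(co$z$values)
  y <- as.numeric(co$z$labels == "case")
  params <- list(W1 = matrix(0, 4, 1), b1 = 0, W2 = matrix(0, 1, 1), b2 = 0)
  g <- mpsdiag:::net_gradient(params, X, y)
  fw <- mpsdiag:::net_forward(params, X)
  expect_equal(g$b2, mean(fw$yhat) - mean(y), tolerance = 1e-12)
  expect_equal(unname(fw$yhat), rep(0.5, 20))
})

test_that("linearization is the W1 * W2 product and inherits the network ranking", {
  co <- make_cohort(n_genes = 2, n_case = 5, n_control = 5, seed = 8)
  net <- train_network(co$z, config = training_config(max_iterations = 2))
  net$W1 <- matrix(c(0.5, -1.0), 2, 1, dimnames = list(net$genes, NULL))
  net$W2 <- matrix(2.0, 1, 1)
  w <- extract_gene_weights(net)
  expect_equal(w$weight, c(1.0, -2.0))
  net$W2 <- matrix(0, 1, 1)
  expect_equal(extract_gene_weights(net)$weight, c(0, 0))

  # with zero biases the MPS ranking equals the network-output ranking,
  # so the two ROC curves coincide
  for (s in 1:5) {
    co <- make_cohort(n_genes = 6, n_case = 12, n_control = 12,
                      n_informative = 2, effect_size = 1.5, seed = s)
    net <- train_network(co$z, config = training_config(max_iterations = 50,
                                                        seed = s))
    net$b1 <- 0; net$b2 <- 0
    mps <- compute_mps(extract_gene_weights(net), co$z)
    out <- predict_network(net, co$z)
    expect_identical(order(mps$mps), order(out))
    net_scores <- data.frame(mps = as.numeric(out), label = mps$label)
    suppressWarnings({  # an untrained net may score below chance; irrelevant here
      expect_identical(as.data.frame(roc_curve(mps))[, c("fpr", "tpr")],
                       as.data.frame(roc_curve(net_scores))[, c("fpr", "tpr")])
    })
  }
})

test_that("hidden layers wider than one node refuse to linearize", {
  co <- make_cohort(n_genes = 3, seed = 9)
  net <- train_network(co$z, config = training_config(hidden_size = 2,
                                                      max_iterations = 5))
  expect_error(extract_gene_weights(net),
               class = "mpsdiag_unsupported_architecture_error")
})

test_that("MPS is the weighted sum of Z-scores, linear in the weights", {
  z1 <- make_expr(matrix(c(1, 1, 0, 2), 2, 2,
                         dimnames = list(c("MYH6", "JAK2"), NULL)),
                  c("case", "control"), genes = c("MYH6", "JAK2"))
  w <- data.frame(gene = c("MYH6", "JAK2"), weight = c(0.3718, -0.6003))
  res <- compute_mps(w, z1)
  expect_equal(res$mps[1], 0.3718 - 0.6003, tolerance = 1e-12)
  expect_equal(res$mps[2], -2 * 0.6003, tolerance = 1e-12)
  w2 <- transform(w, weight = 2 * weight)
  expect_equal(compute_mps(w2, z1)$mps, 2 * res$mps)
  # all-zero scores give MPS 0
  z0 <- make_expr(matrix(0, 2, 2, dimnames = list(c("MYH6", "JAK2"), NULL)),
                  c("case", "control"), genes = c("MYH6", "JAK2"))
  expect_equal(compute_mps(w, z0)$mps, c(0, 0))
  # missing gene is named in the error
  expect_error(compute_mps(data.frame(gene = "ABC1", weight = 1), z1),
               "ABC1", class = "mpsdiag_validation_error")
})

test_that("network and weight tables round-trip through their text formats", {
  co <- make_cohort(n_genes = 5, n_case = 8, n_control = 8, seed = 11)
  net <- train_network(co$z, config = training_config(max_iterations = 30))
  path <- withr::local_tempfile()
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$W1, net$W1)
  expect_identical(back$W2, net$W2)
  expect_identical(back$b1, net$b1)
  expect_identical(back$b2, net$b2)
  expect_equal(predict_network(back, co$z), predict_network(net, co$z))

  wpath <- withr::local_tempfile()
  w <- extract_gene_weights(net)
  write_gene_weights(w, wpath)
  w2 <- read.delim(wpath)
  expect_equal(w2$weight, w$weight)
})

test_that("training against nnet reaches comparable discrimination", {
  co <- make_cohort(n_genes = 8, n_case = 20, n_control = 20,
                    n_informative = 3, effect_size = 2, seed = 12)
  net <- train_network(co$z, config = training_config(seed = 1))
  ours <- auc_pairwise(predict_network(net, co$z), as.character(co$z$labels))
  ref <- withr::with_seed(1, nnet::nnet(t(co$z$values),
    as.numeric(co$z$labels == "case"), size = 1, maxit = 200,
    entropy = TRUE, trace = FALSE))
  theirs <- auc_pairwise(as.numeric(predict(ref, t(co$z$values))),
                         as.character(co$z$labels))
  expect_lt(abs(ours - theirs), 0.05)
})
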