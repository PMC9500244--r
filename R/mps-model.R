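#' Configuration for training the single-hidden-node network
#'
#' @param hidden_size hidden units (the MPS linearization requires 1, the
#'   default).
#' @param max_iterations gradient-descent iterations (default 200).
#' @param learning_rate base step size for full-batch gradient descent.
#' @param l2_decay weight-decay coefficient on all parameters (default 0).
#' @param seed integer seed for the uniform `[-0.5, 0.5]` weight
#'   initialization.
#' @param convergence_tol stop early when the loss decrease falls below this.
#' @param loss `"cross_entropy"` (default) or `"squared_error"`.
#' @return A list of class `training_config`.
#' @export
training_config <- function(hidden_size = 1L, max_iterations = 200L,
                            learning_rate = 0.1, l2_decay = 0,
                            seed = 1L, convergence_tol = 1e-8,
                            loss = c("cross_entropy", "squared_error")) {
  stopifnot_count(hidden_size, "hidden_size")
  stopifnot_count(max_iterations, "max_iterations")
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    mps_abort("'learning_rate' must be > 0", "mpsdiag_validation_error",
              field = "learning_rate")
  }
  if (!is.numeric(l2_decay) || l2_decay < 0) {
    mps_abort("'l2_decay' must be >= 0", "mpsdiag_validation_error",
              field = "l2_decay")
  }
  structure(list(hidden_size = as.integer(hidden_size),
                 max_iterations = as.integer(max_iterations),
                 learning_rate = learning_rate, l2_decay = l2_decay,
                 seed = as.integer(seed), convergence_tol = convergence_tol,
                 loss = match.arg(loss)),
            class = "training_config")
}

sigmoid <- function(u) 1 / (1 + exp(-u))

# forward pass; X is n x p, params a list(W1 p x H, b1 H, W2 H x 1, b2 1)
net_forward <- function(params, X) {
  h <- sigmoid(sweep(X %*% params$W1, 2L, params$b1, "+"))
  yhat <- as.vector(sigmoid(h %*% params$W2 + params$b2))
  list(h = h, yhat = yhat)
}

net_loss <- function(params, X, y, l2_decay = 0,
                     loss = "cross_entropy") {
  yhat <- net_forward(params, X)$yhat
  eps <- 1e-12
  data_loss <- if (loss == "cross_entropy") {
    -mean(y * log(pmax(yhat, eps)) + (1 - y) * log(pmax(1 - yhat, eps)))
  } else {
    mean((yhat - y)^2)
  }
  data_loss + l2_decay * (sum(params$W1^2) + sum(params$b1^2) +
                            sum(params$W2^2) + params$b2^2)
}

# analytic gradient by back-propagation (chain rule applied layer by layer)
net_gradient <- function(params, X, y, l2_decay = 0,
                         loss = "cross_entropy") {
  fw <- net_forward(params, X)
  n <- nrow(X)
  delta2 <- if (loss == "cross_entropy") {
    (fw$yhat - y) / n                      # d loss / d output pre-activation
  } else {
    2 * (fw$yhat - y) * fw$yhat * (1 - fw$yhat) / n
  }
  gW2 <- crossprod(fw$h, delta2) + 2 * l2_decay * params$W2
  gb2 <- sum(delta2) + 2 * l2_decay * params$b2
  delta1 <- (delta2 %*% t(params$W2)) * fw$h * (1 - fw$h)
  gW1 <- crossprod(X, delta1) + 2 * l2_decay * params$W1
  gb1 <- colSums(delta1) + 2 * l2_decay * params$b1
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Train the feed-forward back-propagation network on gene Z-scores
#'
#' A single-hidden-layer network with logistic-sigmoid hidden and output
#' units, trained by full-batch gradient descent on the mean per-sample loss
#' (binary cross-entropy by default), with gradients obtained by
#' back-propagation. If a step would increase the loss, the step size is
#' halved (backtracking) until the loss decreases, so the recorded loss
#' history is non-increasing. Training stops at `max_iterations` or when the
#' loss improvement drops below `convergence_tol`. Initial weights are drawn
#' uniformly from `[-0.5, 0.5]` under the config seed, making the fit fully
#' reproducible.
#'
#' @param z a `zmatrix` restricted to the final (characteristic) genes.
#' @param labels case/control per sample; case is encoded as 1.
#' @param config a [training_config()].
#' @return An object of class `trained_net`: `W1` (gene x hidden input
#'   weights), `b1`, `W2`, `b2`, `loss_history`, `genes`, `config`.
#' @export
train_network <- function(z, labels = z$labels, config = training_config()) {
  stopifnot(inherits(z, "expr_matrix"), inherits(config, "training_config"))
  labels <- factor(as.character(labels), c("case", "control"))
  if (nlevels(droplevels(labels)) < 2L || min(table(labels)) < 2L) {
    mps_abort("need >= 2 samples in each of case and control",
              "mpsdiag_validation_error", field = "labels")
  }
  X <- t(z$values)
  y <- as.numeric(labels == "case")
  p <- ncol(X); H <- config$hidden_size
  params <- withr::with_seed(config$seed, list(
    W1 = matrix(runif(p * H, -0.5, 0.5), p, H,
                dimnames = list(colnames(X), NULL)),
    b1 = runif(H, -0.5, 0.5),
    W2 = matrix(runif(H, -0.5, 0.5), H, 1L),
    b2 = runif(1L, -0.5, 0.5)))
  loss_history <- net_loss(params, X, y, config$l2_decay, config$loss)
  for (it in seq_len(config$max_iterations)) {
    grad <- net_gradient(params, X, y, config$l2_decay, config$loss)
    step <- config$learning_rate
    current <- loss_history[length(loss_history)]
    repeat {
      cand <- list(W1 = params$W1 - step * grad$W1,
                   b1 = params$b1 - step * grad$b1,
                   W2 = params$W2 - step * grad$W2,
                   b2 = params$b2 - step * grad$b2)
      new_loss <- net_loss(cand, X, y, config$l2_decay, config$loss)
      if (!is.finite(new_loss)) {
        mps_abort("training diverged (non-finite loss); lower learning_rate",
                  "mpsdiag_divergence_error")
      }
      if (new_loss <= current || step < 1e-12) break
      step <- step / 2
    }
    if (new_loss > current) break      # no descent possible: at a minimum
    params <- cand
    loss_history <- c(loss_history, new_loss)
    if (current - new_loss < config$convergence_tol) break
  }
  structure(c(params, list(loss_history = loss_history,
                           genes = colnames(X), config = config)),
            class = "trained_net")
}

#' @export
print.trained_net <- function(x, ...) {
  cat(sprintf("<trained_net> %d genes -> %d hidden -> 1; %d iterations, final loss %.6g\n",
              nrow(x$W1), ncol(x$W1), length(x$loss_history) - 1L,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Network output (predicted case probability) for samples
#' @param net a `trained_net`.
#' @param z a `zmatrix` containing the network's genes.
#' @return Named numeric vector of predicted case probabilities.
#' @export
predict_network <- function(net, z) {
  stopifnot(inherits(net, "trained_net"))
  missing <- setdiff(net$genes, rownames(z$values))
  if (length(missing) > 0L) {
    mps_abort(paste0("z lacks network gene(s): ",
                     paste(missing, collapse = ", ")),
              "mpsdiag_validation_error")
  }
  X <- t(z$values[net$genes, , drop = FALSE])
  stats::setNames(net_forward(net, X)$yhat, rownames(X))
}

#' Compare back-propagated gradients with finite-difference estimates
#'
#' Perturbs every parameter in turn and compares the resulting
#' finite-difference slope of the cost with the analytic back-propagated
#' partial derivative, returning the maximum discrepancy over parameters
#' (relative where the gradient is large, absolute where it is near zero:
#' `|g_bp - g_fd| / max(1, |g_bp|, |g_fd|)`).
#'
#' @param net a `trained_net` (its current weights are the evaluation point).
#' @param z a `zmatrix` with the network's genes.
#' @param labels case/control per sample.
#' @param epsilon perturbation size (> 0).
#' @param method `"central"` (default, O(eps^2)) or `"forward"` (the one-sided
#'   quotient `(C(w + eps e_j) - C(w)) / eps`).
#' @return Maximum discrepancy (a single number).
#' @export
gradient_check <- function(net, z, labels = z$labels, epsilon = 1e-6,
                           method = c("central", "forward")) {
  method <- match.arg(method)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    mps_abort("'epsilon' must be > 0", "mpsdiag_validation_error")
  }
  X <- t(z$values[net$genes, , drop = FALSE])
  y <- as.numeric(factor(as.character(labels), c("case", "control")) == "case")
  cfg <- net$config
  params <- net[c("W1", "b1", "W2", "b2")]
  analytic <- net_gradient(params, X, y, cfg$l2_decay, cfg$loss)
  theta <- unlist(params)
  ga <- unlist(analytic)
  f <- function(v) {
    pp <- utils::relist(v, params)
    pp$W1 <- matrix(pp$W1, nrow(params$W1)); pp$W2 <- matrix(pp$W2, nrow(params$W2))
    net_loss(pp, X, y, cfg$l2_decay, cfg$loss)
  }
  f0 <- f(theta)
  gfd <- vapply(seq_along(theta), function(j) {
    e <- theta; e[j] <- e[j] + epsilon
    if (method == "forward") {
      (f(e) - f0) / epsilon
    } else {
      e2 <- theta; e2[j] <- e2[j] - epsilon
      (f(e) - f(e2)) / (2 * epsilon)
    }
  }, numeric(1))
  max(abs(ga - gfd) / pmax(1, abs(ga), abs(gfd)))
}

#' Collapse the trained one-hidden-node network to linear gene weights
#'
#' Drops the biases and the nonlinear activations and keeps, for each gene,
#' the product of its input-to-hidden weight and the hidden-to-output weight:
#' `Gene_Weight_g = W1[g] * W2`. Because the logistic links are monotone,
#' ranking samples by this linear score is identical to ranking by the full
#' network output whenever the biases are zero, and the linear score is the
#' interpretable "MPS" form of the model. Defined only for one hidden node.
#'
#' @param net a `trained_net` with `hidden_size = 1`.
#' @return data.frame of class `gene_weight_table` with columns `gene`,
#'   `weight`.
#' @export
extract_gene_weights <- function(net) {
  stopifnot(inherits(net, "trained_net"))
  if (ncol(net$W1) != 1L) {
    mps_abort("linearization is defined only for hidden_size = 1",
              "mpsdiag_unsupported_architecture_error")
  }
  out <- data.frame(gene = net$genes,
                    weight = as.vector(net$W1[, 1L] * net$W2[1L, 1L]),
                    row.names = NULL)
  class(out) <- c("gene_weight_table", class(out))
  out
}

#' Molecular prediction score: weighted sum of gene Z-scores
#'
#' `MPS(sample) = sum_g Gene_Weight_g * Gene_Score_{g,sample}`, where the
#' Gene_Score is the per-gene expression Z-score. Every weighted gene must be
#' present in `z` (apply [align_genes()] and refit weights, or drop absent
#' genes from the table, beforehand).
#'
#' @param weights a `gene_weight_table` (or data.frame with `gene`,
#'   `weight`).
#' @param z a `zmatrix`.
#' @return data.frame of class `mps_scores` with columns `sample`, `mps`,
#'   `label`.
#' @export
compute_mps <- function(weights, z) {
  stopifnot(inherits(z, "expr_matrix"))
  missing <- setdiff(weights$gene, rownames(z$values))
  if (length(missing) > 0L) {
    mps_abort(paste0("z lacks weighted gene(s): ",
                     paste(missing, collapse = ", ")),
              "mpsdiag_validation_error")
  }
  w <- stats::setNames(weights$weight, weights$gene)
  scores <- as.vector(t(z$values[weights$gene, , drop = FALSE]) %*% w)
  out <- data.frame(sample = colnames(z$values), mps = scores,
                    label = as.character(z$labels), row.names = NULL)
  class(out) <- c("mps_scores", class(out))
  out
}

#' Serialize a trained network as a plain-text key-value file
#'
#' Format: one `key<TAB>value` pair per line; keys `gene:<id>` hold the
#' input-to-hidden weight of that gene, `b1`, `w2`, `b2` the remaining
#' parameters (hidden size 1 only). Round-trips exactly at 17 significant
#' digits.
#'
#' @param net a `trained_net` with one hidden node.
#' @param path file path.
#' @return `read_network` returns a `trained_net` (with empty loss history).
#' @export
write_network <- function(net, path) {
  if (ncol(net$W1) != 1L) {
    mps_abort("text serialization supports hidden_size = 1 only",
              "mpsdiag_unsupported_architecture_error")
  }
  lines <- c(sprintf("gene:%s\t%.17g", net$genes, net$W1[, 1L]),
             sprintf("b1\t%.17g", net$b1),
             sprintf("w2\t%.17g", net$W2[1L, 1L]),
             sprintf("b2\t%.17g", net$b2))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  kv <- read.delim(path, header = FALSE, col.names = c("key", "value"),
                   colClasses = c("character", "numeric"))
  is_gene <- startsWith(kv$key, "gene:")
  genes <- sub("^gene:", "", kv$key[is_gene])
  val <- function(k) kv$value[kv$key == k]
  structure(list(W1 = matrix(kv$value[is_gene], ncol = 1L,
                             dimnames = list(genes, NULL)),
                 b1 = val("b1"), W2 = matrix(val("w2"), 1L, 1L), b2 = val("b2"),
                 loss_history = numeric(0), genes = genes,
                 config = training_config()),
            class = "trained_net")
}

#' @rdname compute_mps
#' @param table a `gene_weight_table` or `mps_scores`.
#' @param path file path.
#' @export
write_gene_weights <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
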