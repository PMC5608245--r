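#' Restricted Boltzmann machine parameters
#'
#' A bipartite energy-based model over binary visible and hidden units,
#' used here to initialize the weights of each sparse-autoencoder layer
#' before backpropagation.  The energy is the standard
#' `E(v, h) = -b'v - c'h - v'Wh`; the model likelihood carries a squared
#' Frobenius weight penalty with coefficient `lambda`.
#'
#' @param n_visible,n_hidden layer sizes.
#' @param lambda nonnegative weight-penalty coefficient.
#' @param init_sd standard deviation of the Gaussian weight initialization.
#' @param seed integer seed.
#' @return an `rbm_params` object with fields `W` (`n_visible x n_hidden`),
#'   `b` (visible biases), `c` (hidden biases), `lambda`.
#' @export
rbm_params <- function(n_visible, n_hidden, lambda = 0, init_sd = 0.01,
                       seed = 1L) {
  stopifnot(n_visible >= 1, n_hidden >= 1, lambda >= 0)
  withr::with_seed(derive_seed(seed, "rbm-init"), {
    W <- matrix(stats::rnorm(n_visible * n_hidden, sd = init_sd),
                n_visible, n_hidden)
  })
  structure(list(W = W, b = numeric(n_visible), c = numeric(n_hidden),
                 lambda = lambda),
            class = "rbm_params")
}

check_rbm <- function(params) {
  stopifnot(inherits(params, "rbm_params"))
  if (!all(is.finite(params$W)) || !all(is.finite(params$b)) ||
      !all(is.finite(params$c))) stop("non-finite RBM parameters")
  invisible(params)
}

#' RBM energy of a joint configuration
#'
#' `E(v, h) = -sum_i b_i v_i - sum_j c_j h_j - sum_ij w_ij v_i h_j`.
#'
#' @param v visible vector (binary or in `[0, 1]`).
#' @param h hidden vector.
#' @param params an `rbm_params`.
#' @return scalar energy.
#' @export
rbm_energy <- function(v, h, params) {
  check_rbm(params)
  if (length(v) != nrow(params$W) || length(h) != ncol(params$W))
    stop("v/h length does not match the RBM")
  -sum(params$b * v) - sum(params$c * h) -
    as.numeric(t(v) %*% params$W %*% h)
}

#' Conditional activation probabilities of an RBM
#'
#' Because the graph is bipartite, units of one layer are conditionally
#' independent given the other: `P(h_j = 1 | v) = sigmoid(W[, j]'v + c_j)`
#' and `P(v_i = 1 | h) = sigmoid(W[i, ]'h + b_i)`.
#'
#' @param v,h a vector, or a matrix with one configuration per row.
#' @param params an `rbm_params`.
#' @return probabilities with the same row structure as the input.
#' @export
rbm_prob_hidden <- function(v, params) {
  check_rbm(params)
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (ncol(V) != nrow(params$W)) stop("visible size mismatch")
  P <- sigmoid(sweep(V %*% params$W, 2, params$c, `+`))
  if (is.matrix(v)) P else as.vector(P)
}

#' @rdname rbm_prob_hidden
#' @export
rbm_prob_visible <- function(h, params) {
  check_rbm(params)
  H <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  if (ncol(H) != ncol(params$W)) stop("hidden size mismatch")
  P <- sigmoid(sweep(H %*% t(params$W), 2, params$b, `+`))
  if (is.matrix(h)) P else as.vector(P)
}

#' One contrastive-divergence (CD-1) update
#'
#' Positive statistics use the data and the exact hidden probabilities;
#' the negative phase runs one Gibbs half-cycle (sample binary hiddens,
#' reconstruct visibles mean-field, recompute hidden probabilities).  The
#' weight gradient is `<v h'>_data - <v' h''>_recon - (2 lambda / N) W`,
#' with `N` the batch size.
#'
#' @param batch matrix of visible vectors (rows), values in `[0, 1]`.
#' @param params an `rbm_params`.
#' @param learning_rate positive step size.
#' @param seed integer seed for the hidden sampling.
#' @return the updated `rbm_params`.
#' @export
rbm_cd1 <- function(batch, params, learning_rate = 0.1, seed = 1L) {
  check_rbm(params)
  if (!is.matrix(batch) || nrow(batch) == 0L) stop("empty batch")
  if (any(batch < 0 | batch > 1)) stop("batch values must lie in [0, 1]")
  assert_scalar_pos(learning_rate, "learning_rate")
  M <- nrow(batch)
  h0 <- rbm_prob_hidden(batch, params)
  withr::with_seed(derive_seed(seed, "cd1"), {
    hs <- matrix(stats::runif(length(h0)) < h0, nrow(h0), ncol(h0)) * 1
  })
  v1 <- rbm_prob_visible(hs, params)
  h1 <- rbm_prob_hidden(v1, params)
  dW <- (t(batch) %*% h0 - t(v1) %*% h1) / M - (2 * params$lambda / M) * params$W
  params$W <- params$W + learning_rate * dW
  params$b <- params$b + learning_rate * colMeans(batch - v1)
  params$c <- params$c + learning_rate * colMeans(h0 - h1)
  params
}

#' Train an RBM with repeated CD-1 epochs
#'
#' @param batch matrix of visible vectors (rows), values in `[0, 1]`.
#' @param params starting `rbm_params`.
#' @param learning_rate positive step size.
#' @param epochs number of passes.
#' @param batch_size minibatch size (`NULL` = full batch).
#' @param seed integer seed.
#' @return the trained `rbm_params`.
#' @export
rbm_train <- function(batch, params, learning_rate = 0.1, epochs = 10L,
                      batch_size = NULL, seed = 1L) {
  stopifnot(is.matrix(batch), nrow(batch) > 0L)
  M <- nrow(batch)
  bs <- batch_size %||% M
  for (e in seq_len(epochs)) {
    ord <- withr::with_seed(derive_seed(seed, paste0("rbm-shuffle-", e)),
                            sample.int(M))
    starts <- seq(1, M, by = bs)
    for (k in seq_along(starts)) {
      idx <- ord[starts[k]:min(starts[k] + bs - 1, M)]
      params <- rbm_cd1(batch[idx, , drop = FALSE], params, learning_rate,
                        seed = derive_seed(seed, paste0("cd-", e, "-", k)))
    }
  }
  params
}

# all binary configurations of n units, one per row (n <= ~20)
binary_states <- function(n) {
  if (n == 0L) return(matrix(0, 1, 0))
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))
}

#' Exact regularized log-likelihood of an RBM (enumeration oracle)
#'
#' Computes `(1/N) sum_n log P(v_n) - (lambda/N) ||W||_F^2` with the
#' partition function obtained by summing `exp(-E)` over all
#' `2^(n_visible + n_hidden)` joint states.  Only feasible for tiny RBMs;
#' intended as a training diagnostic and test oracle.
#'
#' @param params an `rbm_params` with `n_visible + n_hidden <= 20`.
#' @param data matrix of binary visible vectors (rows).
#' @return scalar objective value.
#' @export
rbm_exact_loglik <- function(params, data) {
  check_rbm(params)
  nv <- nrow(params$W); nh <- ncol(params$W)
  if (nv + nh > 20L) stop("state space too large for exact enumeration")
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  Hs <- binary_states(nh)                         # 2^nh x nh
  # unnormalized marginal of v: sum_h exp(-E(v, h))
  un_marg <- function(V) {
    A <- sweep(V %*% params$W, 2, params$c, `+`)  # n x nh pre-activations
    base <- as.vector(V %*% params$b)
    rowSums(exp(base + A %*% t(Hs)))              # exp(-E) summed over h
  }
  Vs <- binary_states(nv)
  Z <- sum(un_marg(Vs))
  N <- nrow(data)
  mean(log(un_marg(data) / Z)) - (params$lambda / N) * sum(params$W^2)
}

#' Exact joint probabilities of a tiny RBM (enumeration)
#'
#' Returns the full joint table `P(v, h)` by enumeration; used to verify
#' the conditional-probability formulas by Bayes' rule.
#'
#' @param params an `rbm_params` with `n_visible + n_hidden <= 20`.
#' @return list with `visible`, `hidden` state matrices and the joint
#'   probability matrix (`2^nv x 2^nh`).
#' @export
rbm_exact_joint <- function(params) {
  check_rbm(params)
  nv <- nrow(params$W); nh <- ncol(params$W)
  if (nv + nh > 20L) stop("state space too large for exact enumeration")
  Vs <- binary_states(nv); Hs <- binary_states(nh)
  E <- matrix(0, nrow(Vs), nrow(Hs))
  for (i in seq_len(nrow(Vs)))
    for (j in seq_len(nrow(Hs)))
      E[i, j] <- rbm_energy(Vs[i, ], Hs[j, ], params)
  P <- exp(-E)
  list(visible = Vs, hidden = Hs, joint = P / sum(P))
}
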