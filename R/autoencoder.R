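#' Sparsity and regularization configuration for autoencoders
#'
#' `alpha1` weights the Frobenius-norm penalty on the weight matrices
#' (unsquared by default, i.e. `||W_enc||_F + ||W_dec||_F`; set
#' `frobenius_squared = TRUE` for the squared variant).  `alpha2` weights
#' the Kullback-Leibler sparsity penalty driving the batch-mean hidden
#' activation of each unit toward the target `rho0`.
#'
#' @param alpha1,alpha2 nonnegative penalty weights.
#' @param rho0 target mean activation in `(0, 1)`.
#' @param frobenius_squared use `||W||_F^2` instead of `||W||_F`.
#' @return a `sparsity_config` object.
#' @export
sparsity_config <- function(alpha1 = 1e-4, alpha2 = 0.1, rho0 = 0.05,
                            frobenius_squared = FALSE) {
  if (alpha1 < 0 || alpha2 < 0) stop("alphas must be >= 0")
  if (rho0 <= 0 || rho0 >= 1) stop("rho0 must lie in (0, 1)")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, rho0 = rho0,
                 frobenius_squared = isTRUE(frobenius_squared)),
            class = "sparsity_config")
}

#' Autoencoder parameters
#'
#' Encoder `h = sigmoid(W_enc' x + b_enc)` and decoder
#' `o = sigmoid(W_dec' h + b_dec)`.  Weights are drawn uniformly in
#' `[-r, r]` with `r = sqrt(6 / (fan_in + fan_out))`.
#'
#' @param n_in,n_hidden,n_out layer sizes (`n_out` defaults to `n_in`).
#' @param seed integer seed.
#' @return an `ae_params` object with `W_enc` (`n_in x n_hidden`), `b_enc`,
#'   `W_dec` (`n_hidden x n_out`), `b_dec`.
#' @export
ae_params <- function(n_in, n_hidden, n_out = n_in, seed = 1L) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  withr::with_seed(derive_seed(seed, "ae-init"), {
    r1 <- sqrt(6 / (n_in + n_hidden))
    r2 <- sqrt(6 / (n_hidden + n_out))
    W_enc <- matrix(stats::runif(n_in * n_hidden, -r1, r1), n_in, n_hidden)
    W_dec <- matrix(stats::runif(n_hidden * n_out, -r2, r2), n_hidden, n_out)
  })
  structure(list(W_enc = W_enc, b_enc = numeric(n_hidden),
                 W_dec = W_dec, b_dec = numeric(n_out)),
            class = "ae_params")
}

as_batch <- function(x, d, what = "input") {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != d) stop(what, " width ", ncol(X), " does not match ", d)
  X
}

#' Encode / decode through an autoencoder
#'
#' @param x input vector or batch matrix (rows = samples).
#' @param h hidden vector or batch matrix.
#' @param params an `ae_params`.
#' @return activations in `(0, 1)`, matching the input's row structure.
#' @export
ae_encode <- function(x, params) {
  X <- as_batch(x, nrow(params$W_enc))
  H <- sigmoid(sweep(X %*% params$W_enc, 2, params$b_enc, `+`))
  if (is.matrix(x)) H else as.vector(H)
}

#' @rdname ae_encode
#' @export
ae_decode <- function(h, params) {
  H <- as_batch(h, nrow(params$W_dec), "hidden")
  O <- sigmoid(sweep(H %*% params$W_dec, 2, params$b_dec, `+`))
  if (is.matrix(h)) O else as.vector(O)
}

KL_EPS <- 1e-8

#' Kullback-Leibler sparsity penalty
#'
#' `sum_j [ rho_j log(rho_j / rho0) + (1 - rho_j) log((1 - rho_j) /
#' (1 - rho0)) ]` in natural log, with `rho_j` the observed mean activation
#' of hidden unit `j` (clipped to `(1e-8, 1 - 1e-8)`).
#'
#' @param rho_hat mean hidden activations.
#' @param rho0 target sparsity in `(0, 1)`.
#' @return scalar penalty, 0 iff `rho_hat == rho0` everywhere.
#' @export
kl_sparsity <- function(rho_hat, rho0) {
  if (rho0 <= 0 || rho0 >= 1) stop("rho0 must lie in (0, 1)")
  r <- pmin(pmax(rho_hat, KL_EPS), 1 - KL_EPS)
  sum(r * log(r / rho0) + (1 - r) * log((1 - r) / (1 - rho0)))
}

# derivative of kl_sparsity w.r.t. rho_hat (0 in the clipped region)
kl_sparsity_grad <- function(rho_hat, rho0) {
  r <- pmin(pmax(rho_hat, KL_EPS), 1 - KL_EPS)
  g <- log(r / rho0) - log((1 - r) / (1 - rho0))
  g[rho_hat <= KL_EPS | rho_hat >= 1 - KL_EPS] <- 0
  g
}

frob_penalty <- function(W, squared) if (squared) sum(W * W) else frob_norm(W)

frob_penalty_grad <- function(W, squared) {
  if (squared) return(2 * W)
  n <- frob_norm(W)
  if (n == 0) W * 0 else W / n
}

#' Sparse-autoencoder objective
#'
#' Mean over the batch of the squared reconstruction error `||o - x||^2`,
#' plus `alpha1` times the (un)squared Frobenius norms of both weight
#' matrices, plus `alpha2` times the KL sparsity penalty on the batch-mean
#' hidden activations.
#'
#' @param params an `ae_params`.
#' @param batch input matrix (rows = samples), nonempty.
#' @param config a `sparsity_config`.
#' @return scalar objective value.
#' @export
ae_objective <- function(params, batch, config) {
  X <- as_batch(batch, nrow(params$W_enc))
  if (nrow(X) == 0L) stop("empty batch")
  H <- ae_encode(X, params)
  O <- ae_decode(H, params)
  recon <- mean(rowSums((O - X)^2))
  pen_w <- config$alpha1 * (frob_penalty(params$W_enc, config$frobenius_squared) +
                            frob_penalty(params$W_dec, config$frobenius_squared))
  pen_kl <- if (config$alpha2 > 0)
    config$alpha2 * kl_sparsity(colMeans(H), config$rho0) else 0
  recon + pen_w + pen_kl
}

#' Exact gradients of the sparse-autoencoder objective
#'
#' Analytic backpropagation through both sigmoid layers, including the KL
#' term's dependence on the encoder via the batch-mean activation, and the
#' Frobenius term with the convention `d||W||_F/dW = W / ||W||_F` (0 at
#' `W = 0`).
#'
#' @inheritParams ae_objective
#' @return list with `W_enc`, `b_enc`, `W_dec`, `b_dec` gradients.
#' @export
ae_gradients <- function(params, batch, config) {
  X <- as_batch(batch, nrow(params$W_enc))
  if (nrow(X) == 0L) stop("empty batch")
  M <- nrow(X)
  H <- ae_encode(X, params)
  O <- ae_decode(H, params)
  dO <- (2 / M) * (O - X) * O * (1 - O)
  gW_dec <- t(H) %*% dO +
    config$alpha1 * frob_penalty_grad(params$W_dec, config$frobenius_squared)
  gb_dec <- colSums(dO)
  dH <- dO %*% t(params$W_dec)
  if (config$alpha2 > 0) {
    klg <- kl_sparsity_grad(colMeans(H), config$rho0)
    dH <- sweep(dH, 2, (config$alpha2 / M) * klg, `+`)
  }
  dH <- dH * H * (1 - H)
  gW_enc <- t(X) %*% dH +
    config$alpha1 * frob_penalty_grad(params$W_enc, config$frobenius_squared)
  gb_enc <- colSums(dH)
  list(W_enc = gW_enc, b_enc = gb_enc, W_dec = gW_dec, b_dec = gb_dec)
}

#' Train a single sparse autoencoder
#'
#' Mini-batch gradient descent on [ae_objective()], optionally starting
#' from contrastive-divergence-pretrained RBM weights (encoder takes
#' `(W, c)`, decoder takes `(W', b)` -- tied shapes, untied values from
#' then on).
#'
#' @param batch training inputs in `[0, 1]` (rows = samples).
#' @param n_hidden hidden-layer width.
#' @param config a `sparsity_config`.
#' @param learning_rate fixed step size (default 0.1).
#' @param epochs training passes (default 400).
#' @param batch_size minibatch size (`NULL` = full batch).
#' @param rbm_init initialize from a CD-1-trained RBM.
#' @param rbm_epochs,rbm_lr,rbm_lambda RBM pretraining settings.
#' @param seed integer seed.
#' @param track record the objective every `track` epochs (0 = off).
#' @return list with `params` (an `ae_params`) and `history` (data frame of
#'   tracked objective values).
#' @export
train_autoencoder <- function(batch, n_hidden, config = sparsity_config(),
                              learning_rate = 0.1, epochs = 400L,
                              batch_size = NULL, rbm_init = TRUE,
                              rbm_epochs = 5L, rbm_lr = 0.05,
                              rbm_lambda = 1e-4, seed = 1L, track = 0L) {
  stopifnot(is.matrix(batch), nrow(batch) > 0L)
  d <- ncol(batch)
  params <- ae_params(d, n_hidden, d, seed = seed)
  if (rbm_init) {
    rbm <- rbm_params(d, n_hidden, lambda = rbm_lambda, seed = seed)
    rbm <- rbm_train(pmin(pmax(batch, 0), 1), rbm, learning_rate = rbm_lr,
                     epochs = rbm_epochs, batch_size = batch_size %||% 128L,
                     seed = derive_seed(seed, "ae-rbm"))
    params$W_enc <- rbm$W
    params$b_enc <- rbm$c
    params$W_dec <- t(rbm$W)
    params$b_dec <- rbm$b
  }
  M <- nrow(batch)
  bs <- batch_size %||% M
  hist_ep <- integer(0); hist_obj <- numeric(0)
  for (e in seq_len(epochs)) {
    ord <- if (bs < M)
      withr::with_seed(derive_seed(seed, paste0("ae-shuffle-", e)),
                       sample.int(M))
    else seq_len(M)
    starts <- seq(1, M, by = bs)
    for (k in seq_along(starts)) {
      idx <- ord[starts[k]:min(starts[k] + bs - 1, M)]
      g <- ae_gradients(params, batch[idx, , drop = FALSE], config)
      params$W_enc <- params$W_enc - learning_rate * g$W_enc
      params$b_enc <- params$b_enc - learning_rate * g$b_enc
      params$W_dec <- params$W_dec - learning_rate * g$W_dec
      params$b_dec <- params$b_dec - learning_rate * g$b_dec
    }
    if (track > 0L && (e %% track == 0L || e == epochs)) {
      obj <- ae_objective(params, batch, config)
      if (!is.finite(obj)) stop("autoencoder training diverged (epoch ", e, ")")
      hist_ep <- c(hist_ep, e); hist_obj <- c(hist_obj, obj)
    }
  }
  list(params = params,
       history = data.frame(epoch = hist_ep, objective = hist_obj))
}

#' Render hidden-unit filters as patch images
#'
#' Each hidden unit's incoming weight vector, reshaped to the patch
#' geometry -- the "filters" view of what the first layer has learned.
#'
#' @param W_enc encoder weight matrix (`n_in x n_hidden`).
#' @param patch_size `(l, k)` patch dimensions; `n_in` must be a multiple
#'   of `l * k` (one block per input frame).
#' @return list (one per hidden unit) of lists of `l x k` matrices.
#' @export
ae_filters <- function(W_enc, patch_size) {
  l <- patch_size[1]; k <- patch_size[2]
  if (nrow(W_enc) %% (l * k) != 0) stop("n_in is not a multiple of l*k")
  n_blocks <- nrow(W_enc) / (l * k)
  lapply(seq_len(ncol(W_enc)), function(j) {
    w <- W_enc[, j]
    lapply(seq_len(n_blocks), function(b) {
      block <- w[((b - 1) * l * k + 1):(b * l * k)]
      matrix(block, l, k, byrow = TRUE)
    })
  })
}
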