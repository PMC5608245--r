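#' Extract adjacent-frame patch datasets
#'
#' Slides an `l x k` window over every fully-interior position of the
#' reconstruction at the given stride.  At each position the patches of the
#' `n_window` frames centred on `frame_index` (edge frames replicated at
#' the sequence boundary) are flattened row-major and concatenated --
#' earliest frame first -- into one input row.  When ground truth is given,
#' the label is the truth patch of `frame_index` at the same position.  All
#' values are mapped to `[0, 1]` by a recorded affine map (`v * scale +
#' offset`, default `offset = 0`, `scale = 1/max`).
#'
#' @param recon a `recon_series`, `dynamic_phantom`, or list of matrices.
#' @param truth optional `dynamic_phantom` (or frame list) for labels.
#' @param frame_index frame to be estimated, `1..n_frames`.
#' @param patch_size integer `(l, k)`.
#' @param stride positive step between window positions (default 1).
#' @param n_window odd number of frames fed to the model (default 3).
#' @param norm optional affine map `list(offset, scale)` to reuse (e.g. a
#'   trained model's); computed from the data when `NULL`.
#' @return a `patch_dataset`: `inputs` (`M x n_window*l*k`), `labels`
#'   (`M x l*k` or `NULL`), `positions` (top-left corners), `patch_size`,
#'   `n_window`, `frame_index`, `norm`, `grid`.
#' @export
extract_patches <- function(recon, truth = NULL, frame_index,
                            patch_size = c(7L, 7L), stride = 1L,
                            n_window = 3L, norm = NULL) {
  frames <- as_frame_list(recon)
  n_frames <- length(frames)
  l <- as.integer(patch_size[1]); k <- as.integer(patch_size[2])
  if (frame_index < 1 || frame_index > n_frames)
    stop("frame_index out of range")
  if (n_window %% 2L != 1L) stop("n_window must be odd")
  rows <- nrow(frames[[1]]); cols <- ncol(frames[[1]])
  if (l > rows || k > cols) stop("patch larger than image")
  if (stride < 1L) stop("stride must be >= 1")

  half <- (n_window - 1L) %/% 2L
  widx <- pmin(pmax(frame_index + (-half):half, 1L), n_frames)
  truth_frames <- if (!is.null(truth)) as_frame_list(truth)

  if (is.null(norm)) {
    # anchor the [0,1] map on the ground truth when available, so labels use
    # the full sigmoid output range; reconstruction noise may exceed 1
    hi <- if (!is.null(truth_frames)) max(truth_frames[[frame_index]]) else 0
    if (hi <= 0) hi <- max(vapply(frames[widx], max, 0))
    if (hi <= 0) hi <- 1
    norm <- list(offset = 0, scale = 1 / hi)
  }

  r0 <- seq(1L, rows - l + 1L, by = stride)
  c0 <- seq(1L, cols - k + 1L, by = stride)
  pos <- cbind(rep(r0, times = length(c0)), rep(c0, each = length(r0)))
  M <- nrow(pos)

  flatten <- function(img) {
    # M x (l*k), row-major pixel order within each patch
    out <- matrix(0, M, l * k)
    col <- 0L
    for (dr in 0:(l - 1L)) for (dc in 0:(k - 1L)) {
      col <- col + 1L
      out[, col] <- img[cbind(pos[, 1] + dr, pos[, 2] + dc)]
    }
    out
  }
  to01 <- function(v) (v + norm$offset) * norm$scale
  inputs <- do.call(cbind, lapply(frames[widx], function(f) to01(flatten(f))))
  labels <- if (!is.null(truth_frames))
    pmin(pmax(to01(flatten(truth_frames[[frame_index]])), 0), 1)
  structure(list(inputs = inputs, labels = labels, positions = pos,
                 patch_size = c(l, k), n_window = as.integer(n_window),
                 frame_index = as.integer(frame_index), norm = norm,
                 grid = c(rows, cols)),
            class = "patch_dataset")
}

#' Combine patch datasets from several training sets
#'
#' Recomputes a common normalization (the max of the sets' individual
#' scales' inverses) and stacks inputs and labels.
#'
#' @param datasets list of `patch_dataset`s with matching geometry.
#' @return a single `patch_dataset`.
#' @export
rbind_patches <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  d1 <- datasets[[1]]
  scales <- vapply(datasets, function(d) d$norm$scale, 0)
  scale <- min(scales)     # smallest scale <=> largest data maximum
  adj <- function(d) {
    f <- scale / d$norm$scale
    d$inputs <- d$inputs * f
    if (!is.null(d$labels)) d$labels <- d$labels * f
    d
  }
  datasets <- lapply(datasets, adj)
  structure(list(inputs = do.call(rbind, lapply(datasets, `[[`, "inputs")),
                 labels = if (!is.null(d1$labels))
                   do.call(rbind, lapply(datasets, `[[`, "labels")),
                 positions = NULL, patch_size = d1$patch_size,
                 n_window = d1$n_window, frame_index = d1$frame_index,
                 norm = list(offset = 0, scale = scale), grid = d1$grid),
            class = "patch_dataset")
}

#' Greedy layer-wise pretraining of the encoder stack
#'
#' Layer 1 is trained as a sparse autoencoder (RBM-initialized) on the raw
#' inputs; each subsequent layer on the previous layer's hidden
#' activations.  Intermediate decoders are discarded.
#'
#' @param dataset a `patch_dataset` (or bare input matrix).
#' @param hidden_sizes integer vector `(h1, ..., hs)`, nonempty.
#' @param config a `sparsity_config`.
#' @param learning_rate,epochs,batch_size,rbm_init,rbm_epochs,rbm_lr,seed
#'   forwarded to [train_autoencoder()].
#' @return list of encoder layers, each `list(W, b)`.
#' @export
greedy_pretrain <- function(dataset, hidden_sizes, config = sparsity_config(),
                            learning_rate = 0.1, epochs = 100L,
                            batch_size = 128L, rbm_init = TRUE,
                            rbm_epochs = 5L, rbm_lr = 0.05, seed = 1L) {
  X <- if (inherits(dataset, "patch_dataset")) dataset$inputs else dataset
  stopifnot(is.matrix(X), length(hidden_sizes) >= 1L)
  layers <- vector("list", length(hidden_sizes))
  for (t in seq_along(hidden_sizes)) {
    fit <- train_autoencoder(X, hidden_sizes[t], config,
                             learning_rate = learning_rate, epochs = epochs,
                             batch_size = batch_size, rbm_init = rbm_init,
                             rbm_epochs = rbm_epochs, rbm_lr = rbm_lr,
                             seed = derive_seed(seed, paste0("layer-", t)))
    layers[[t]] <- list(W = fit$params$W_enc, b = fit$params$b_enc)
    X <- sigmoid(sweep(X %*% layers[[t]]$W, 2, layers[[t]]$b, `+`))
  }
  layers
}

sae_forward <- function(model, X) {
  acts <- vector("list", length(model$layers) + 1L)
  H <- X
  for (t in seq_along(model$layers)) {
    H <- sigmoid(sweep(H %*% model$layers[[t]]$W, 2, model$layers[[t]]$b, `+`))
    acts[[t]] <- H
  }
  O <- sigmoid(sweep(H %*% model$output$W, 2, model$output$b, `+`))
  acts[[length(acts)]] <- O
  acts
}

#' Supervised fine-tuning of the stacked model
#'
#' Appends a sigmoid output layer mapping the last hidden layer to the
#' `l*k` patch of the target frame, then backpropagates the mean squared
#' error against the ground-truth patches through the whole stack (or only
#' the output layer when `output_only = TRUE`).
#'
#' @param stack encoder layers from [greedy_pretrain()].
#' @param dataset a `patch_dataset` with `labels`.
#' @param epochs,learning_rate,batch_size optimizer settings.
#' @param output_only freeze the pretrained encoders.
#' @param seed integer seed.
#' @param track record the loss every `track` epochs (0 = off).
#' @return a trained `sae_model`.
#' @export
sae_finetune <- function(stack, dataset, epochs = 100L, learning_rate = 0.1,
                         batch_size = 128L, output_only = FALSE, seed = 1L,
                         track = 10L) {
  stopifnot(inherits(dataset, "patch_dataset"), !is.null(dataset$labels))
  X <- dataset$inputs; Y <- dataset$labels
  n_out <- ncol(Y)
  if (inherits(stack, "sae_model")) {
    # continue fine-tuning an existing model
    model <- stack
  } else {
    h_s <- ncol(stack[[length(stack)]]$W)
    withr::with_seed(derive_seed(seed, "sae-output-init"), {
      r <- sqrt(6 / (h_s + n_out))
      Wo <- matrix(stats::runif(h_s * n_out, -r, r), h_s, n_out)
    })
    # start the output units at the base rate of their labels
    bo <- stats::qlogis(pmin(pmax(colMeans(Y), 1e-3), 1 - 1e-3))
    model <- structure(
      list(layers = stack, output = list(W = Wo, b = bo),
           patch_size = dataset$patch_size, n_window = dataset$n_window,
           frame_index = dataset$frame_index, norm = dataset$norm,
           history = NULL, seed = as.integer(seed)),
      class = "sae_model")
  }
  stack <- model$layers

  M <- nrow(X)
  bs <- min(batch_size %||% M, M)
  ns <- length(stack)
  hist_ep <- integer(0); hist_loss <- numeric(0)
  for (e in seq_len(epochs)) {
    ord <- if (bs < M)
      withr::with_seed(derive_seed(seed, paste0("ft-shuffle-", e)),
                       sample.int(M))
    else seq_len(M)
    starts <- seq(1, M, by = bs)
    for (kk in seq_along(starts)) {
      idx <- ord[starts[kk]:min(starts[kk] + bs - 1, M)]
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      m <- nrow(Xb)
      acts <- sae_forward(model, Xb)
      O <- acts[[ns + 1L]]
      d <- (2 / m) * (O - Yb) * O * (1 - O)
      Hs <- acts[[ns]]
      gWo <- t(Hs) %*% d; gbo <- colSums(d)
      if (!output_only) {
        dH <- d %*% t(model$output$W)
        for (t in ns:1) {
          H <- acts[[t]]
          dH <- dH * H * (1 - H)
          inp <- if (t == 1L) Xb else acts[[t - 1L]]
          gW <- t(inp) %*% dH; gb <- colSums(dH)
          if (t > 1L) dH <- dH %*% t(model$layers[[t]]$W)
          model$layers[[t]]$W <- model$layers[[t]]$W - learning_rate * gW
          model$layers[[t]]$b <- model$layers[[t]]$b - learning_rate * gb
        }
      }
      model$output$W <- model$output$W - learning_rate * gWo
      model$output$b <- model$output$b - learning_rate * gbo
    }
    if (track > 0L && (e %% track == 0L || e == epochs)) {
      loss <- sae_loss(model, X, Y)
      if (!is.finite(loss)) stop("fine-tuning diverged (epoch ", e, ")")
      hist_ep <- c(hist_ep, e); hist_loss <- c(hist_loss, loss)
    }
  }
  model$history <- data.frame(epoch = hist_ep, loss = hist_loss)
  model
}

# mean over samples of the summed squared patch error
sae_loss <- function(model, X, Y) {
  O <- sae_predict(model, X, denormalize = FALSE)
  mean(rowSums((O - Y)^2))
}

#' Predict patches with a trained SAE
#'
#' Forward pass through the encoder stack and the output layer.  With
#' `denormalize = TRUE` the stored affine map is inverted so predictions
#' are on the activity scale of the reconstruction.
#'
#' @param model an `sae_model` (or the identity oracle from
#'   [make_identity_model()]).
#' @param x one input row or a batch matrix.
#' @param denormalize invert the recorded `[0, 1]` map.
#' @return predicted patch vector(s), matching the input's row structure.
#' @export
sae_predict <- function(model, x, denormalize = FALSE) {
  UseMethod("sae_predict")
}

#' @export
sae_predict.sae_model <- function(model, x, denormalize = FALSE) {
  d_in <- nrow(model$layers[[1]]$W)
  X <- as_batch(x, d_in)
  O <- sae_forward(model, X)[[length(model$layers) + 1L]]
  if (denormalize) O <- O / model$norm$scale - model$norm$offset
  if (is.matrix(x)) O else as.vector(O)
}

#' Identity oracle model
#'
#' A pseudo-model whose prediction is exactly the middle-frame block of the
#' input row.  Used to validate the patch sweep (extraction order, kernel
#' normalization, de-normalization) independently of any training.
#'
#' @param patch_size integer `(l, k)`.
#' @param n_window odd window width.
#' @param frame_index frame the model "reconstructs".
#' @return an object usable wherever an `sae_model` is.
#' @export
make_identity_model <- function(patch_size = c(7L, 7L), n_window = 3L,
                                frame_index = 1L) {
  structure(list(patch_size = as.integer(patch_size),
                 n_window = as.integer(n_window),
                 frame_index = as.integer(frame_index),
                 norm = list(offset = 0, scale = 1)),
            class = c("sae_identity", "sae_model"))
}

#' @export
sae_predict.sae_identity <- function(model, x, denormalize = FALSE) {
  lk <- prod(model$patch_size)
  X <- as_batch(x, model$n_window * lk)
  half <- (model$n_window - 1L) %/% 2L
  O <- X[, (half * lk + 1L):((half + 1L) * lk), drop = FALSE]
  if (denormalize) O <- O / model$norm$scale - model$norm$offset
  if (is.matrix(x)) O else as.vector(O)
}

#' @export
print.sae_model <- function(x, ...) {
  if (inherits(x, "sae_identity")) {
    cat("<sae_model> identity oracle\n")
    return(invisible(x))
  }
  sizes <- c(nrow(x$layers[[1]]$W),
             vapply(x$layers, function(l) ncol(l$W), 0L),
             ncol(x$output$W))
  cat("<sae_model>", paste(sizes, collapse = " -> "),
      sprintf("(patch %dx%d, window %d)\n",
              x$patch_size[1], x$patch_size[2], x$n_window))
  invisible(x)
}

#' Save / load a trained model
#'
#' @param model an `sae_model`.
#' @param path file path.
#' @export
save_sae_model <- function(model, path) {
  stopifnot(inherits(model, "sae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sae_model
#' @export
load_sae_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sae_model"))
  model
}
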