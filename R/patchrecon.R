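#' Gaussian patch-weighting kernel
#'
#' Isotropic Gaussian weights over an odd-sided patch, normalized to sum
#' 1, used to turn a predicted patch into a single center-pixel estimate.
#' `sigma = Inf` gives uniform weights; small `sigma` concentrates all
#' weight on the center pixel.
#'
#' @param patch_size integer `(l, k)`, both odd.
#' @param sigma positive width in pixels (or `Inf`); default 0.5 px, which
#'   keeps the estimate local to the center pixel -- the network, not the
#'   kernel, is responsible for spatial smoothing.
#' @return a `gaussian_kernel` with `weights` (`l x k`, sum 1) and `sigma`.
#' @export
gaussian_kernel <- function(patch_size = c(7L, 7L), sigma = NULL) {
  l <- as.integer(patch_size[1]); k <- as.integer(patch_size[2])
  if (l %% 2L == 0L || k %% 2L == 0L)
    stop("patch sides must be odd (center pixel must be defined)")
  sigma <- sigma %||% 0.5
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar (possibly Inf)")
  r0 <- (l + 1) / 2; c0 <- (k + 1) / 2
  d2 <- outer(seq_len(l) - r0, seq_len(k) - c0, function(a, b) a^2 + b^2)
  w <- if (is.infinite(sigma)) matrix(1, l, k) else exp(-d2 / (2 * sigma^2))
  structure(list(weights = w / sum(w), sigma = sigma),
            class = "gaussian_kernel")
}

#' Reconstruct one frame by sweeping the SAE over all patch positions
#'
#' For each interior center position the adjacent-frame input row is built
#' exactly as during training, passed through the model, de-normalized,
#' and reduced to a scalar by the Gaussian kernel (a convex combination of
#' the predicted patch).  The border band of half the patch width is
#' filled from the MLEM image of the target frame; the result is clipped
#' at 0.  `aggregate = "overlap"` instead overlap-averages every predicted
#' patch into the image with kernel weights.
#'
#' @param model a trained `sae_model` (or identity oracle).
#' @param recon a `recon_series` (or frame list) of MLEM images.
#' @param frame_index frame to estimate; defaults to the model's.
#' @param kernel a `gaussian_kernel`; default `sigma = 0.5`.
#' @param aggregate `"center"` (default) or `"overlap"`.
#' @return nonnegative 2-D activity estimate.
#' @export
reconstruct_frame <- function(model, recon, frame_index = NULL, kernel = NULL,
                              aggregate = c("center", "overlap")) {
  aggregate <- match.arg(aggregate)
  frame_index <- frame_index %||% model$frame_index
  frames <- as_frame_list(recon)
  l <- model$patch_size[1]; k <- model$patch_size[2]
  kernel <- kernel %||% gaussian_kernel(model$patch_size)
  if (any(dim(kernel$weights) != c(l, k)))
    stop("kernel size does not match the model's patch size")
  ds <- extract_patches(frames, truth = NULL, frame_index = frame_index,
                        patch_size = c(l, k), stride = 1L,
                        n_window = model$n_window, norm = model$norm)
  P <- sae_predict(model, ds$inputs, denormalize = TRUE)
  rows <- ds$grid[1]; cols <- ds$grid[2]
  out <- frames[[frame_index]]          # border band = MLEM passthrough
  hr <- (l - 1L) %/% 2L; hc <- (k - 1L) %/% 2L
  # row-major kernel vector to match the patch flattening
  kv <- as.vector(t(kernel$weights))
  if (aggregate == "center") {
    est <- as.vector(P %*% kv)
    out[cbind(ds$positions[, 1] + hr, ds$positions[, 2] + hc)] <- est
  } else {
    acc <- matrix(0, rows, cols); wacc <- matrix(0, rows, cols)
    col <- 0L
    for (dr in 0:(l - 1L)) for (dc in 0:(k - 1L)) {
      col <- col + 1L
      idx <- cbind(ds$positions[, 1] + dr, ds$positions[, 2] + dc)
      acc[idx] <- acc[idx] + kv[col] * P[, col]
      wacc[idx] <- wacc[idx] + kv[col]
    }
    covered <- wacc > 0
    out[covered] <- acc[covered] / wacc[covered]
  }
  pmax(out, 0)
}
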