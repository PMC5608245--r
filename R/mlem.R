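#' Per-frame MLEM reconstruction
#'
#' Classical maximum-likelihood expectation-maximization for emission
#' tomography (Shepp-Vardi), applied independently to every time frame:
#'
#' \deqn{x \leftarrow \frac{x}{s} \odot G^T\!\left(\frac{y}{Gx}\right),
#'       \qquad s = G^T 1}
#'
#' The update is multiplicative, preserves nonnegativity, and never
#' decreases the Poisson log-likelihood.  Detector bins whose forward
#' projection is zero are excluded from the ratio; voxels with zero
#' sensitivity (outside the rays' coverage) are held at zero with a warning
#' when they fall inside the field of view.
#'
#' @param G a `system_matrix`.
#' @param sinogram a `sinogram_series`; `counts` is used when present,
#'   otherwise the noiseless `expected` data.
#' @param n_iterations number of full EM iterations (>= 1); default 50.
#' @param init optional strictly positive starting image (matrix); default
#'   is a uniform image matched to the frame's total counts.
#' @param keep_loglik record the Poisson log-likelihood per iteration.
#' @return a `recon_series`: `images` (list of nonnegative matrices, one per
#'   frame), `n_iterations`, the geometry and, optionally, a
#'   `loglik` matrix (frames x iterations).
#' @export
mlem_reconstruct <- function(G, sinogram, n_iterations = 50L, init = NULL,
                             keep_loglik = FALSE) {
  stopifnot(inherits(G, "system_matrix"), inherits(sinogram, "sinogram_series"))
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  Y <- sinogram$counts %||% sinogram$expected
  if (is.null(Y)) stop("sinogram carries neither counts nor expected data")
  if (any(Y < 0)) stop("negative counts")
  rows <- G$grid_size[1]; cols <- G$grid_size[2]
  W <- G$weights
  Wt <- Matrix::t(W)
  sens <- as.vector(Matrix::colSums(W))
  pos <- sens > 0
  if (!all(pos)) {
    # voxels never traversed by a ray: held at 0
    fov <- fov_mask(G)
    if (any(!pos & as.vector(fov)))
      warning("voxel(s) with zero sensitivity inside the field of view; ",
              "held at 0")
  }
  n_frames <- nrow(Y)
  images <- vector("list", n_frames)
  ll <- if (keep_loglik) matrix(NA_real_, n_frames, n_iterations) else NULL
  for (i in seq_len(n_frames)) {
    y <- Y[i, ]
    if (is.null(init)) {
      x <- numeric(length(sens))
      x[pos] <- sum(y) / sum(sens[pos])
    } else {
      if (length(init) != length(sens)) stop("init size mismatch")
      if (any(init[pos] <= 0)) stop("init must be > 0 on covered voxels")
      x <- as.vector(init)
      x[!pos] <- 0
    }
    for (it in seq_len(n_iterations)) {
      yhat <- as.vector(W %*% x)
      ratio <- ifelse(yhat > 0, y / yhat, 0)
      back <- as.vector(Wt %*% ratio)
      x[pos] <- x[pos] * back[pos] / sens[pos]
      if (keep_loglik)
        ll[i, it] <- poisson_log_likelihood(G, x, y)
    }
    images[[i]] <- matrix(x, rows, cols)
  }
  structure(list(images = images, n_iterations = as.integer(n_iterations),
                 geometry = list(n_angles = G$n_angles, n_radial = G$n_radial,
                                 grid_size = G$grid_size),
                 loglik = ll),
            class = "recon_series")
}

#' @export
print.recon_series <- function(x, ...) {
  cat(sprintf("<recon_series> %d frame(s), %dx%d, %d MLEM iteration(s)\n",
              length(x$images), x$geometry$grid_size[1],
              x$geometry$grid_size[2], x$n_iterations))
  invisible(x)
}

# logical mask of the inscribed-circle field of view
fov_mask <- function(G) {
  rows <- G$grid_size[1]; cols <- G$grid_size[2]
  xs <- matrix(rep(seq_len(cols) - 0.5, each = rows), rows, cols)
  ys <- matrix(rep(seq_len(rows) - 0.5, cols), rows, cols)
  (xs - cols / 2)^2 + (ys - rows / 2)^2 <= (min(rows, cols) / 2)^2
}

#' Poisson log-likelihood of an emission image
#'
#' The objective MLEM ascends: `sum_q [ y_q log(yhat_q) - yhat_q ]` with
#' `yhat = G x`, dropping the data-only `log(y!)` term.  Bins with
#' `yhat = 0, y = 0` contribute 0; `yhat = 0, y > 0` makes the likelihood
#' `-Inf` (flagged with a warning).
#'
#' @param G a `system_matrix`.
#' @param image nonnegative activity map (matrix or vector).
#' @param counts one sinogram frame (vector of length `n_bins`).
#' @return scalar log-likelihood.
#' @export
poisson_log_likelihood <- function(G, image, counts) {
  stopifnot(inherits(G, "system_matrix"))
  x <- as.vector(image)
  if (any(x < 0)) stop("image must be nonnegative")
  if (length(counts) != nrow(G$weights)) stop("counts length mismatch")
  yhat <- as.vector(G$weights %*% x)
  bad <- yhat == 0 & counts > 0
  if (any(bad)) {
    warning("bins with zero expectation but positive counts: likelihood -Inf")
    return(-Inf)
  }
  ok <- yhat > 0
  sum(counts[ok] * log(yhat[ok]) - yhat[ok]) - sum(yhat[!ok])
}

#' Write / read a reconstruction series as NIfTI
#'
#' @param recon a `recon_series`.
#' @param path output `.nii` path.
#' @export
write_recon <- function(recon, path) {
  stopifnot(inherits(recon, "recon_series"))
  gs <- recon$geometry$grid_size
  vol <- array(unlist(recon$images), dim = c(gs, length(recon$images)))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}
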