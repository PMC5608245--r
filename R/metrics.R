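#' Image-quality metrics: SNR, bias, variance
#'
#' The three indexes used to score a reconstruction `u` against ground
#' truth `u_hat` over a region of `n` pixels:
#' \deqn{SNR = 20 \log_{10}\!\frac{peak}{RMSE}, \quad
#'       Bias = \frac{1}{n}\sum_i \frac{u_i - \hat u_i}{\hat u_i}, \quad
#'       Variance = \frac{1}{n}\sum_i
#'         \left(\frac{u_i - \bar u_n}{\hat u_i}\right)^2}
#' with `RMSE = sqrt(mean((u - u_hat)^2))` and `u_bar_n` the mean of the
#' reconstruction over the region.  Bias and variance divide by the truth,
#' so zero-truth pixels are excluded (the count is attached as the
#' `"n_excluded"` attribute).  `compute_snr` evaluates the values as
#' given; [roi_report()] maps images to the 0--255 range first.
#'
#' @param u reconstructed values.
#' @param u_hat ground-truth values (same length).
#' @param peak reference peak for the SNR ratio (default 255).
#' @return scalar metric value.
#' @export
compute_snr <- function(u, u_hat, peak = 255) {
  if (length(u) != length(u_hat)) stop("length mismatch")
  if (length(u) == 0L) stop("empty region")
  rmse <- sqrt(mean((u - u_hat)^2))
  if (rmse == 0) {
    warning("exact reconstruction: SNR is +Inf")
    return(Inf)
  }
  20 * log10(peak / rmse)
}

bias_var_core <- function(u, u_hat) {
  if (length(u) != length(u_hat)) stop("length mismatch")
  keep <- u_hat > 0
  n_exc <- sum(!keep)
  u <- u[keep]; u_hat <- u_hat[keep]
  if (!length(u)) stop("all pixels have zero ground truth")
  list(u = u, u_hat = u_hat, n_excluded = n_exc)
}

#' @rdname compute_snr
#' @export
compute_bias <- function(u, u_hat) {
  z <- bias_var_core(u, u_hat)
  structure(mean((z$u - z$u_hat) / z$u_hat), n_excluded = z$n_excluded)
}

#' @rdname compute_snr
#' @export
compute_variance <- function(u, u_hat) {
  z <- bias_var_core(u, u_hat)
  ubar <- mean(z$u)
  structure(mean(((z$u - ubar) / z$u_hat)^2), n_excluded = z$n_excluded)
}

#' Per-ROI, per-frame metrics report
#'
#' Evaluates SNR, bias and variance for every (ROI, frame) pair, including
#' the `"Total"` ROI.  For the SNR both images are first mapped to the
#' 0--255 range by the common affine map that sends the ground-truth
#' maximum (over all frames) to 255.  Empty masks are skipped with a
#' warning.
#'
#' @param recon_frames list of reconstructed frames (or `recon_series`).
#' @param truth_frames list of ground-truth frames (or `dynamic_phantom`).
#' @param masks named list of logical ROI masks, e.g. from [roi_masks()].
#' @param peak SNR reference peak (default 255).
#' @return a `data.frame` with columns `roi`, `frame`, `snr_db`, `bias`,
#'   `variance`, `n_pixels`, `n_excluded`.
#' @export
roi_report <- function(recon_frames, truth_frames, masks, peak = 255) {
  rf <- as_frame_list(recon_frames)
  tf <- as_frame_list(truth_frames)
  if (length(rf) != length(tf)) stop("frame count mismatch")
  tmax <- max(vapply(tf, max, 0))
  if (tmax <= 0) stop("ground truth is identically zero")
  sc <- peak / tmax
  rows <- list()
  for (m in names(masks)) {
    mask <- masks[[m]]
    if (!any(mask)) {
      warning("empty mask '", m, "' skipped")
      next
    }
    for (i in seq_along(rf)) {
      if (any(dim(rf[[i]]) != dim(mask))) stop("mask/frame shape mismatch")
      u <- rf[[i]][mask]; uh <- tf[[i]][mask]
      b <- tryCatch(compute_bias(u, uh), error = function(e) NA_real_)
      v <- tryCatch(compute_variance(u, uh), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = m, frame = i,
        snr_db = compute_snr(u * sc, uh * sc, peak = peak),
        bias = as.numeric(b), variance = as.numeric(v),
        n_pixels = sum(mask),
        n_excluded = attr(b, "n_excluded") %||% sum(mask))
    }
  }
  do.call(rbind, rows)
}

#' Write a metrics report as CSV
#'
#' @param report data frame from [roi_report()].
#' @param path output path.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
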