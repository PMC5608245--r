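# Shared test helpers: hand-built geometries and independent oracles.

# a sinogram_series carrying only counts, shaped for system matrix G
counts_sinogram <- function(counts, G) {
  structure(list(counts = counts, expected = NULL,
                 geometry = list(n_angles = G$n_angles, n_radial = G$n_radial,
                                 grid_size = G$grid_size),
                 total_counts = NULL, seed = NULL),
            class = "sinogram_series")
}

# a system matrix whose weights are the identity: one detector per voxel
identity_system_matrix <- function(n) {
  W <- Matrix::sparseMatrix(i = seq_len(n), j = seq_len(n), x = rep(1, n),
                            dims = c(n, n))
  structure(list(weights = W, n_angles = 1L, n_radial = as.integer(n),
                 grid_size = c(as.integer(n), 1L), detector_spacing = 1),
            class = "system_matrix")
}

# The same ray parameterization the projector documents: angles uniform over
# [0, pi), offsets centred across the grid, rays through the grid center.
ray_specs <- function(n_angles, n_radial, grid_size, spacing = NULL) {
  rows <- grid_size[1]; cols <- grid_size[2]
  spacing <- if (is.null(spacing)) min(grid_size) / n_radial else spacing
  cx <- cols / 2; cy <- rows / 2
  offsets <- (seq_len(n_radial) - (n_radial + 1) / 2) * spacing
  out <- list(); q <- 0L
  for (a in seq_len(n_angles)) {
    th <- (a - 1) * pi / n_angles
    for (j in seq_len(n_radial)) {
      q <- q + 1L
      out[[q]] <- c(x0 = cx + offsets[j] * cos(th),
                    y0 = cy + offsets[j] * sin(th),
                    dx = -sin(th), dy = cos(th))
    }
  }
  out
}

# Liang-Barsky: length of the segment of an infinite line inside a box.
# Independent of the Siddon-style grid traversal used by the implementation.
clip_length <- function(x0, y0, dx, dy, xmin, xmax, ymin, ymax) {
  t0 <- -Inf; t1 <- Inf
  for (side in list(c(-dx, x0 - xmin), c(dx, xmax - x0),
                    c(-dy, y0 - ymin), c(dy, ymax - y0))) {
    p <- side[1]; q <- side[2]
    if (abs(p) < 1e-14) {
      if (q < 0) return(0)
    } else if (p < 0) {
      t0 <- max(t0, q / p)
    } else {
      t1 <- min(t1, q / p)
    }
  }
  max(0, t1 - t0)
}

# brute-force forward projection: per-ray, per-pixel analytic clipping
oracle_project <- function(image, n_angles, n_radial, spacing = NULL) {
  rows <- nrow(image); cols <- ncol(image)
  rays <- ray_specs(n_angles, n_radial, c(rows, cols), spacing)
  vapply(rays, function(r) {
    s <- 0
    for (rr in seq_len(rows)) for (cc in seq_len(cols)) {
      len <- clip_length(r["x0"], r["y0"], r["dx"], r["dy"],
                         cc - 1, cc, rr - 1, rr)
      s <- s + len * image[rr, cc]
    }
    s
  }, numeric(1))
}

# small noiseless patch dataset whose labels are the middle-frame patches
identity_patch_dataset <- function(n = 800, lk = 9L, n_window = 3L,
                                   seed = 2L) {
  X <- withr::with_seed(seed,
         matrix(stats::runif(n * n_window * lk, 0.1, 0.9), n, n_window * lk))
  half <- (n_window - 1L) %/% 2L
  structure(list(inputs = X, labels = X[, (half * lk + 1):((half + 1) * lk)],
                 positions = NULL, patch_size = c(3L, 3L),
                 n_window = n_window, frame_index = 2L,
                 norm = list(offset = 0, scale = 1), grid = c(32L, 32L)),
            class = "patch_dataset")
}
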