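#' Parallel-beam system matrix
#'
#' Builds the tomographic system matrix `G` (detector bins x voxels) for a
#' 2-D parallel-beam geometry: entry `(q, p)` is the exact intersection
#' length of ray `q` with pixel `p`, computed by a Siddon-style grid
#' traversal.  Rays are uniform in angle over `[0, pi)` and uniform in
#' radial offset across the grid.  Pixels are unit squares with the image
#' origin at the corner; the field of view is the inscribed circle.
#'
#' @param n_angles number of projection angles (>= 1).
#' @param n_radial number of radial bins per angle (>= 1).
#' @param grid_size integer `(rows, cols)` of the image.
#' @param detector_spacing radial bin spacing in pixels; defaults to
#'   `min(grid_size) / n_radial` so the detector spans the field of view.
#' @return a `system_matrix`: sparse `weights` (`n_angles * n_radial` rows,
#'   `rows * cols` columns) plus the geometry.  Voxel `p` corresponds to
#'   `as.vector(image)` (column-major); bin `q = (angle - 1) * n_radial +
#'   radial`.
#' @export
build_system_matrix <- function(n_angles, n_radial, grid_size,
                                detector_spacing = NULL) {
  stopifnot(n_angles >= 1, n_radial >= 1)
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 2L || any(grid_size < 1L))
    stop("degenerate grid")
  rows <- grid_size[1]; cols <- grid_size[2]
  spacing <- detector_spacing %||% (min(grid_size) / n_radial)
  assert_scalar_pos(spacing, "detector_spacing")
  cx <- cols / 2; cy <- rows / 2
  offsets <- (seq_len(n_radial) - (n_radial + 1) / 2) * spacing
  angles <- (seq_len(n_angles) - 1L) * pi / n_angles

  eps <- 1e-9
  qi <- vector("list", n_angles * n_radial)
  pj <- vector("list", n_angles * n_radial)
  wx <- vector("list", n_angles * n_radial)
  q <- 0L
  for (a in seq_len(n_angles)) {
    th <- angles[a]
    dx <- -sin(th); dy <- cos(th)
    for (j in seq_len(n_radial)) {
      q <- q + 1L
      x0 <- cx + offsets[j] * cos(th)
      y0 <- cy + offsets[j] * sin(th)
      # clip the ray parameter s to the image box [0,cols] x [0,rows]
      smin <- -Inf; smax <- Inf
      if (abs(dx) > eps) {
        sx <- sort(c((0 - x0) / dx, (cols - x0) / dx))
        smin <- max(smin, sx[1]); smax <- min(smax, sx[2])
      } else if (x0 < 0 || x0 > cols) next
      if (abs(dy) > eps) {
        sy <- sort(c((0 - y0) / dy, (rows - y0) / dy))
        smin <- max(smin, sy[1]); smax <- min(smax, sy[2])
      } else if (y0 < 0 || y0 > rows) next
      if (smax - smin <= eps) next
      sv <- c(smin, smax)
      if (abs(dx) > eps) sv <- c(sv, ((0:cols) - x0) / dx)
      if (abs(dy) > eps) sv <- c(sv, ((0:rows) - y0) / dy)
      sv <- sort(sv[sv >= smin - eps & sv <= smax + eps])
      sv <- sv[c(TRUE, diff(sv) > 1e-12)]
      if (length(sv) < 2L) next
      mid <- (sv[-1] + sv[-length(sv)]) / 2
      len <- diff(sv)
      px <- pmin(pmax(floor(x0 + dx * mid), 0), cols - 1)
      py <- pmin(pmax(floor(y0 + dy * mid), 0), rows - 1)
      keep <- len > 1e-12
      if (!any(keep)) next
      qi[[q]] <- rep.int(q, sum(keep))
      pj[[q]] <- as.integer(px[keep] * rows + py[keep] + 1)
      wx[[q]] <- len[keep]
    }
  }
  W <- Matrix::sparseMatrix(i = unlist(qi), j = unlist(pj), x = unlist(wx),
                            dims = c(n_angles * n_radial, rows * cols))
  structure(list(weights = W, n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial), grid_size = grid_size,
                 detector_spacing = spacing),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %d angles x %d bins over %dx%d grid (%d nnz)\n",
              x$n_angles, x$n_radial, x$grid_size[1], x$grid_size[2],
              length(x$weights@x)))
  invisible(x)
}

as_frame_list <- function(frames) {
  if (inherits(frames, "dynamic_phantom")) return(frames$frames)
  if (inherits(frames, "recon_series")) return(frames$images)
  if (is.matrix(frames)) return(list(frames))
  stopifnot(is.list(frames))
  frames
}

#' Noiseless forward projection of a dynamic series
#'
#' Computes the expected sinogram `G %*% vec(frame)` for every frame: the
#' mean photon counts of the Poisson measurement model, with no noise.
#'
#' @param G a `system_matrix`.
#' @param frames a `dynamic_phantom`, `recon_series`, matrix, or list of
#'   matrices.
#' @return a `sinogram_series` with `expected` populated (`n_frames x
#'   n_bins`) and `counts` `NULL`.
#' @export
forward_project <- function(G, frames) {
  stopifnot(inherits(G, "system_matrix"))
  fl <- as_frame_list(frames)
  nv <- prod(G$grid_size)
  for (f in fl)
    if (length(f) != nv) stop("frame size does not match system matrix grid")
  expected <- t(vapply(fl, function(f) as.vector(G$weights %*% as.vector(f)),
                       numeric(nrow(G$weights))))
  new_sinogram(counts = NULL, expected = expected, G = G)
}

new_sinogram <- function(counts, expected, G, total_counts = NULL,
                         seed = NULL) {
  structure(list(counts = counts, expected = expected,
                 geometry = list(n_angles = G$n_angles, n_radial = G$n_radial,
                                 grid_size = G$grid_size),
                 total_counts = total_counts, seed = seed),
            class = "sinogram_series")
}

#' @export
print.sinogram_series <- function(x, ...) {
  m <- x$counts %||% x$expected
  cat(sprintf("<sinogram_series> %d frame(s) x %d bins (%s)\n",
              nrow(m), ncol(m),
              if (is.null(x$counts)) "expected only" else "counts"))
  invisible(x)
}

#' Rescale an expected sinogram to a total count budget
#'
#' Multiplies the noiseless sinogram so that the sum over all frames and
#' bins equals `total_counts` exactly; this is how the counting rate (total
#' coincidence events per scan) is imposed before Poisson sampling.
#'
#' @param sinogram a `sinogram_series` with `expected` populated.
#' @param total_counts positive total count budget, e.g. `5e4`.
#' @return the rescaled `sinogram_series`.
#' @export
scale_to_counts <- function(sinogram, total_counts) {
  stopifnot(inherits(sinogram, "sinogram_series"), !is.null(sinogram$expected))
  assert_scalar_pos(total_counts, "total_counts")
  s <- sum(sinogram$expected)
  if (s <= 0) stop("cannot scale an all-zero sinogram")
  sinogram$expected <- sinogram$expected * (total_counts / s)
  sinogram$total_counts <- total_counts
  sinogram
}

#' Calibrate phantom activity to a count budget
#'
#' Rescales the phantom's activity so that the total expected photon count
#' of its noiseless projection equals `total_counts` -- the "counting
#' rate" of the acquisition.  Unlike rescaling the sinogram alone, this
#' keeps ground truth, sinogram and reconstruction in one common activity
#' unit, so reconstructions are directly comparable to the truth.
#'
#' @param G a `system_matrix`.
#' @param phantom a `dynamic_phantom`.
#' @param total_counts positive expected-count budget for the whole scan.
#' @param per_frame impose the budget on every frame instead of the scan.
#' @return the rescaled `dynamic_phantom`.
#' @export
calibrate_phantom <- function(G, phantom, total_counts, per_frame = FALSE) {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  assert_scalar_pos(total_counts, "total_counts")
  sino <- forward_project(G, phantom)
  if (per_frame) {
    for (i in seq_len(phantom$n_frames)) {
      s <- sum(sino$expected[i, ])
      if (s <= 0) stop("frame ", i, " projects to zero counts")
      phantom$frames[[i]] <- phantom$frames[[i]] * (total_counts / s)
    }
  } else {
    s <- sum(sino$expected)
    if (s <= 0) stop("phantom projects to zero counts")
    phantom$frames <- lapply(phantom$frames, `*`, total_counts / s)
  }
  phantom
}

#' Sample Poisson counts from an expected sinogram
#'
#' Each detector bin is drawn independently from `Poisson(expected)`,
#' seeded and reproducible.
#'
#' @param sinogram a `sinogram_series` with nonnegative `expected`.
#' @param seed integer seed.
#' @return the `sinogram_series` with integer `counts` populated.
#' @export
sample_poisson <- function(sinogram, seed = 1L) {
  stopifnot(inherits(sinogram, "sinogram_series"), !is.null(sinogram$expected))
  if (any(sinogram$expected < 0)) stop("expected values must be >= 0")
  mu <- sinogram$expected
  withr::with_seed(derive_seed(seed, "poisson"), {
    counts <- matrix(stats::rpois(length(mu), as.vector(mu)),
                     nrow(mu), ncol(mu))
  })
  sinogram$counts <- counts
  sinogram$seed <- as.integer(seed)
  sinogram
}
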