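#' Synthetic dynamic PET phantoms
#'
#' A `dynamic_phantom` holds the ground-truth tracer activity of a dynamic
#' PET acquisition: one nonnegative 2-D activity map per time frame, plus an
#' integer region-of-interest (ROI) label map (0 = background) and per-frame
#' durations.  Activity is piecewise constant over regions within each frame;
#' each region's value over time follows its time-activity curve (TAC), so
#' the region mean at frame i equals the TAC evaluated at the frame midpoint
#' exactly.
#'
#' @name dynamic_phantom
NULL

#' Evaluate a time-activity curve
#'
#' Supported families: `constant` (value `A`), mono-exponential decay
#' `A * exp(-lambda * t)`, and gamma-variate uptake `A * t^alpha *
#' exp(-beta * t)`.  Time is in minutes.
#'
#' @param tac list with `type` and the family's parameters.
#' @param t numeric vector of times (minutes).
#' @return numeric vector of activities (arbitrary units, >= 0).
#' @export
tac_value <- function(tac, t) {
  stopifnot(is.list(tac), !is.null(tac$type))
  v <- switch(tac$type,
    constant = rep(tac$A, length(t)),
    expdecay = tac$A * exp(-tac$lambda * t),
    gamma    = tac$A * t^tac$alpha * exp(-tac$beta * t),
    stop("unknown TAC type: ", tac$type)
  )
  if (any(v < 0)) stop("TAC produced negative activity")
  v
}

# Random but reproducible TAC parameters for n regions.  Peaks are O(1);
# decay rates are chosen so that activity changes appreciably over the scan.
default_tac_params <- function(n_regions, scan_minutes) {
  lapply(seq_len(n_regions), function(j) {
    peak <- stats::runif(1, 0.5, 2)
    if (j %% 2L == 1L) {
      list(type = "expdecay", A = peak,
           lambda = stats::runif(1, 0.5, 2.5) / scan_minutes)
    } else {
      alpha <- stats::runif(1, 1.5, 3)
      t_peak <- stats::runif(1, 0.2, 0.6) * scan_minutes
      beta <- alpha / t_peak
      # normalize so the curve's maximum equals `peak`
      A <- peak / (t_peak^alpha * exp(-alpha))
      list(type = "gamma", A = A, alpha = alpha, beta = beta)
    }
  })
}

# -- region geometry ---------------------------------------------------------

place_disks <- function(grid_size, n_regions) {
  rows <- grid_size[1]; cols <- grid_size[2]
  cx <- cols / 2; cy <- rows / 2
  fov <- 0.48 * min(grid_size)
  centers <- matrix(0, 0, 2); radii <- numeric(0)
  for (j in seq_len(n_regions)) {
    placed <- FALSE
    for (try in seq_len(600)) {
      r <- stats::runif(1, 0.07, 0.16) * min(grid_size)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, max(fov - r - 1, 0))
      x <- cx + rad * cos(ang); y <- cy + rad * sin(ang)
      ok <- TRUE
      if (length(radii))
        ok <- all(sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2) >
                    radii + r + 1)
      if (ok) {
        centers <- rbind(centers, c(x, y)); radii <- c(radii, r)
        placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n_regions, " non-overlapping regions on a ",
           rows, "x", cols, " grid")
  }
  labels <- matrix(0L, rows, cols)
  xs <- matrix(rep(seq_len(cols) - 0.5, each = rows), rows, cols)
  ys <- matrix(rep(seq_len(rows) - 0.5, cols), rows, cols)
  for (j in seq_len(n_regions)) {
    inside <- (xs - centers[j, 1])^2 + (ys - centers[j, 2])^2 <= radii[j]^2
    labels[inside] <- j
  }
  labels
}

place_brain_like <- function(grid_size, n_regions) {
  rows <- grid_size[1]; cols <- grid_size[2]
  cx <- cols / 2; cy <- rows / 2
  R <- 0.47 * min(grid_size)
  xs <- matrix(rep(seq_len(cols) - 0.5, each = rows), rows, cols)
  ys <- matrix(rep(seq_len(rows) - 0.5, cols), rows, cols)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  labels <- matrix(0L, rows, cols)
  labels[d <= R & d > 0.8 * R] <- 1L            # cortical rim
  if (n_regions >= 2) labels[d <= 0.76 * R] <- 2L  # interior
  if (n_regions >= 3) {
    for (j in 3:n_regions) {                     # interior focal blobs
      r <- stats::runif(1, 0.08, 0.14) * min(grid_size)
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0, 0.6 * R - r)
      bx <- cx + rad * cos(ang); by <- cy + rad * sin(ang)
      labels[(xs - bx)^2 + (ys - by)^2 <= r^2] <- as.integer(j)
    }
  }
  labels
}

place_torso_like <- function(grid_size, n_regions) {
  rows <- grid_size[1]; cols <- grid_size[2]
  cx <- cols / 2; cy <- rows / 2
  a <- 0.46 * cols; b <- 0.36 * rows
  xs <- matrix(rep(seq_len(cols) - 0.5, each = rows), rows, cols)
  ys <- matrix(rep(seq_len(rows) - 0.5, cols), rows, cols)
  labels <- matrix(0L, rows, cols)
  labels[((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1] <- 1L
  if (n_regions >= 2) {
    for (j in 2:n_regions) {                     # offset "organ" ellipses
      oa <- stats::runif(1, 0.10, 0.18) * cols
      ob <- stats::runif(1, 0.08, 0.15) * rows
      ox <- cx + stats::runif(1, -0.5, 0.5) * (a - oa)
      oy <- cy + stats::runif(1, -0.5, 0.5) * (b - ob)
      labels[((xs - ox) / oa)^2 + ((ys - oy) / ob)^2 <= 1] <- as.integer(j)
    }
  }
  labels
}

#' Generate a seeded synthetic dynamic phantom
#'
#' Builds a multi-region 2-D phantom whose regions are piecewise constant in
#' space and follow configurable time-activity curves across frames.  Three
#' geometry families are provided: `disks` (non-overlapping disks on a
#' circular field of view), `brain_like` (cortical annulus, interior, focal
#' blobs) and `torso_like` (body ellipse with offset organs).  The same seed
#' always yields a bit-identical phantom.
#'
#' @param kind geometry family.
#' @param grid_size integer `(rows, cols)`, each >= 16.
#' @param n_frames number of time frames, >= 3.
#' @param n_regions number of labelled regions, >= 1.
#' @param tac_params optional list (length `n_regions`) of TAC parameter
#'   lists as understood by [tac_value()]; drawn reproducibly when `NULL`.
#' @param frame_durations optional positive frame durations in seconds
#'   (default: uniform 60 s frames).
#' @param seed integer seed.
#' @return a `dynamic_phantom` object.
#' @examples
#' ph <- make_dynamic_phantom("disks", c(32, 32), n_frames = 5,
#'                            n_regions = 2, seed = 1)
#' sapply(ph$frames, max)
#' @export
make_dynamic_phantom <- function(kind = c("disks", "brain_like", "torso_like"),
                                 grid_size = c(64L, 64L), n_frames = 18L,
                                 n_regions = 3L, tac_params = NULL,
                                 frame_durations = NULL, seed = 1L) {
  kind <- match.arg(kind)
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 2L || any(grid_size < 16L))
    stop("grid_size must be (rows, cols) with both >= 16")
  if (n_frames < 3L) stop("n_frames must be >= 3")
  if (n_regions < 1L) stop("n_regions must be >= 1")
  frame_durations <- frame_durations %||% rep(60, n_frames)
  if (length(frame_durations) != n_frames || any(frame_durations <= 0))
    stop("frame_durations must be ", n_frames, " positive values")
  t_mid <- (cumsum(frame_durations) - frame_durations / 2) / 60
  scan_minutes <- sum(frame_durations) / 60

  withr::with_seed(derive_seed(seed, paste0("phantom-", kind)), {
    labels <- switch(kind,
      disks      = place_disks(grid_size, n_regions),
      brain_like = place_brain_like(grid_size, n_regions),
      torso_like = place_torso_like(grid_size, n_regions))
    if (is.null(tac_params))
      tac_params <- default_tac_params(n_regions, scan_minutes)
  })
  if (length(tac_params) != n_regions)
    stop("tac_params must have one entry per region")

  tac_tab <- sapply(tac_params, tac_value, t = t_mid)   # n_frames x n_regions
  tac_tab <- matrix(tac_tab, nrow = n_frames)
  frames <- lapply(seq_len(n_frames), function(i) {
    img <- matrix(0, grid_size[1], grid_size[2])
    for (j in seq_len(n_regions)) img[labels == j] <- tac_tab[i, j]
    img
  })
  structure(list(frames = frames, grid_size = grid_size,
                 n_frames = as.integer(n_frames), roi_labels = labels,
                 frame_durations = frame_durations, tac_params = tac_params,
                 kind = kind, seed = as.integer(seed)),
            class = "dynamic_phantom")
}

#' @export
print.dynamic_phantom <- function(x, ...) {
  cat(sprintf("<dynamic_phantom> %s, %dx%d, %d frames, %d region(s)\n",
              x$kind, x$grid_size[1], x$grid_size[2], x$n_frames,
              length(x$tac_params)))
  invisible(x)
}

#' ROI masks of a phantom
#'
#' One logical mask per nonzero label, plus a `"Total"` mask equal to the
#' union of all labelled regions.  An all-zero label map yields a single
#' `"Total"` mask covering the whole grid.
#'
#' @param phantom a `dynamic_phantom`, or a bare integer label matrix.
#' @return named list of logical matrices.
#' @export
roi_masks <- function(phantom) {
  labels <- if (inherits(phantom, "dynamic_phantom")) phantom$roi_labels
            else phantom
  stopifnot(is.matrix(labels))
  lv <- sort(unique(labels[labels > 0]))
  if (!length(lv))
    return(list(Total = matrix(TRUE, nrow(labels), ncol(labels))))
  masks <- lapply(lv, function(l) labels == l)
  names(masks) <- paste0("ROI", lv)
  masks$Total <- labels > 0
  masks
}

#' Write / read a phantom as NIfTI with a JSON sidecar
#'
#' Frames are stacked on the third axis of a NIfTI volume; ROI labels, TAC
#' parameters and frame timing go to `<prefix>.json`.
#'
#' @param phantom a `dynamic_phantom`.
#' @param prefix file path without extension.
#' @return `prefix`, invisibly (for `write_phantom`); a `dynamic_phantom`
#'   (for `read_phantom`).
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  vol <- array(unlist(phantom$frames),
               dim = c(phantom$grid_size, phantom$n_frames))
  RNifti::writeNifti(RNifti::asNifti(vol), paste0(prefix, ".nii"))
  side <- list(kind = phantom$kind, grid_size = phantom$grid_size,
               n_frames = phantom$n_frames, seed = phantom$seed,
               frame_durations = phantom$frame_durations,
               tac_params = phantom$tac_params,
               roi_labels = as.integer(phantom$roi_labels))
  jsonlite::write_json(side, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  vol <- RNifti::readNifti(paste0(prefix, ".nii"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  gs <- as.integer(side$grid_size)
  nf <- as.integer(side$n_frames)
  vol <- array(as.numeric(vol), dim = c(gs, nf))
  frames <- lapply(seq_len(nf), function(i) vol[, , i])
  tacs <- side$tac_params
  if (is.data.frame(tacs))
    tacs <- lapply(seq_len(nrow(tacs)), function(i)
      Filter(Negate(is.na), as.list(tacs[i, ])))
  structure(list(frames = frames, grid_size = gs, n_frames = nf,
                 roi_labels = matrix(as.integer(side$roi_labels), gs[1], gs[2]),
                 frame_durations = side$frame_durations,
                 tac_params = tacs, kind = side$kind,
                 seed = as.integer(side$seed)),
            class = "dynamic_phantom")
}
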