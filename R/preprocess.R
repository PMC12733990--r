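# Volume preprocessing applied ahead of segmentation: kidney-window
# intensity mapping, resampling to the reference grid, three-stage intensity
# normalization, padding to the network's downsampling multiple, and
# through-plane interpolation for thin stacks.

#' Preprocessing configuration
#'
#' @param windowWidth,windowLevel CT window in HU (defaults 400 / 40, the
#'   kidney window; the retained range is `[-160, 240]`).
#' @param targetSpacing reference voxel spacing in mm.
#' @param padMultiple pad volumes so each dimension divides this.
#' @param minDepth minimum number of through-plane slices.
#' @param patchSize side of the cubic patches used by the local
#'   standardization stage.
#' @param biasCorrect hook for scanner bias-field correction; the identity
#'   here (phantoms carry no bias field).
#' @return A list of class `nx_preprocess_config`.
#' @export
preprocessConfig <- function(windowWidth = 400, windowLevel = 40,
                             targetSpacing = c(1, 1, 2.5), padMultiple = 16L,
                             minDepth = 8L, patchSize = 16L,
                             biasCorrect = FALSE) {
  stopifnot(windowWidth > 0, all(targetSpacing > 0), padMultiple >= 1)
  structure(list(windowWidth = windowWidth, windowLevel = windowLevel,
                 targetSpacing = targetSpacing, padMultiple = as.integer(padMultiple),
                 minDepth = as.integer(minDepth), patchSize = as.integer(patchSize),
                 biasCorrect = biasCorrect),
            class = "nx_preprocess_config")
}

#' Kidney-window intensity mapping
#'
#' Clips to `[level - width/2, level + width/2]` and rescales linearly to
#' `[0, 1]`; monotone nondecreasing in the input.
#'
#' @param image numeric array of HU intensities.
#' @param cfg a [preprocessConfig()].
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
huWindow <- function(image, cfg = preprocessConfig()) {
  lo <- cfg$windowLevel - cfg$windowWidth / 2
  hi <- cfg$windowLevel + cfg$windowWidth / 2
  (clamp(image, lo, hi) - lo) / (hi - lo)
}

#' Resample a labelled volume to the reference spacing
#'
#' Trilinear interpolation for the image, nearest neighbor for the mask.
#' The output shape is `round(shape * spacing / target)` per axis.
#'
#' @param v a [LabeledVolume-class].
#' @param cfg a [preprocessConfig()].
#' @return The resampled [LabeledVolume-class] at `cfg$targetSpacing`.
#' @export
resampleVolume <- function(v, cfg = preprocessConfig()) {
  if (any(v@spacing <= 0) || any(!is.finite(v@spacing)))
    nx_stop("volume spacing metadata is invalid")
  d <- dim(v@image)
  od <- pmax(1L, as.integer(round(d * v@spacing / cfg$targetSpacing)))
  if (all(od == d) && all(abs(v@spacing - cfg$targetSpacing) < 1e-12)) return(v)
  img <- resize3d_fwd_cpp(array(v@image, c(1L, d)), od)[1, , , , drop = TRUE]
  img <- array(img, od)
  # nearest-neighbor index map per axis (same half-pixel convention)
  nn_idx <- function(n_in, n_out)
    clamp(round((seq_len(n_out) - 0.5) * n_in / n_out + 0.5), 1, n_in)
  msk <- v@mask[nn_idx(d[1], od[1]), nn_idx(d[2], od[2]), nn_idx(d[3], od[3]),
                drop = FALSE]
  LabeledVolume(img, array(as.integer(msk), od), cfg$targetSpacing,
                v@patientId, meta = v@meta)
}

#' Three-stage intensity normalization
#'
#' Stage 1 z-scores the whole volume; stage 2 recenters by the mean/sd of
#' the voxels inside the kidney mask (skipped when the mask is empty);
#' stage 3 standardizes within cubic tiles (side `patchSize`, tiled from the
#' volume origin with the final tile aligned to the far edge) and averages
#' overlapping tiles.  All divisions are epsilon-guarded, so a constant
#' volume maps to zeros.
#'
#' @param image numeric 3D array.
#' @param kidneyMask logical/integer 3D array marking kidney voxels.
#' @param patchSize tile side in voxels.
#' @param eps numerical guard.
#' @return Normalized array of the same shape.
#' @export
normalizeThreeStage <- function(image, kidneyMask, patchSize = 16L,
                                eps = 1e-6) {
  x <- (image - mean(image)) / (sd(image) + eps)
  km <- kidneyMask > 0
  if (any(km)) {
    mu <- mean(x[km])
    sg <- sd(x[km])
    if (!is.finite(sg)) sg <- 0
    x <- (x - mu) / (sg + eps)
  }
  d <- dim(x)
  starts <- function(n, p) {
    if (n <= p) return(1L)
    s <- seq(1L, n - p + 1L, by = p)
    if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
    s
  }
  acc <- array(0, d)
  cnt <- array(0, d)
  p <- min(patchSize, min(d))
  for (i in starts(d[1], p)) for (j in starts(d[2], p)) for (k in starts(d[3], p)) {
    ii <- i:(i + p - 1); jj <- j:(j + p - 1); kk <- k:(k + p - 1)
    blk <- x[ii, jj, kk]
    sg <- sd(blk)
    if (!is.finite(sg)) sg <- 0
    acc[ii, jj, kk] <- acc[ii, jj, kk] + (blk - mean(blk)) / (sg + eps)
    cnt[ii, jj, kk] <- cnt[ii, jj, kk] + 1
  }
  acc / cnt
}

#' Pad a grid so every dimension divides a multiple
#'
#' Symmetric zero-padding with the extra voxel on the high side when the
#' needed padding is odd; the returned record inverts the operation
#' exactly via [unpadVolume()].
#'
#' @param x numeric 3D array.
#' @param multiple target divisor (default 16).
#' @return `list(data =, pad =)` where `pad` is a 3 x 2 matrix of low/high
#'   pad widths.
#' @export
padToMultiple <- function(x, multiple = 16L) {
  d <- dim(x)
  target <- next_multiple(d, multiple)
  extra <- target - d
  lo <- extra %/% 2L
  hi <- extra - lo
  out <- array(0, target)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- x
  list(data = out, pad = cbind(low = lo, high = hi))
}

#' Invert [padToMultiple()]
#' @param x padded array.
#' @param pad the pad record.
#' @return The original array, bit-exactly.
#' @export
unpadVolume <- function(x, pad) {
  d <- dim(x)
  x[pad[1, 1] + seq_len(d[1] - sum(pad[1, ])),
    pad[2, 1] + seq_len(d[2] - sum(pad[2, ])),
    pad[3, 1] + seq_len(d[3] - sum(pad[3, ])), drop = FALSE]
}

#' Through-plane slice interpolation for thin stacks
#'
#' Volumes with fewer than `minDepth` slices are resampled along the
#' through-plane axis to exactly `minDepth` slices with a cubic spline
#' (image) and nearest neighbor (mask); deeper volumes pass through
#' unchanged.  The result carries `meta$interpolated`.
#'
#' @param v a [LabeledVolume-class] with depth >= 2.
#' @param minDepth required minimum depth (default 8).
#' @return A [LabeledVolume-class].
#' @export
interpolateSlices <- function(v, minDepth = 8L) {
  d <- dim(v@image)
  if (d[3] < 2) nx_stop("volume must have at least 2 slices")
  if (d[3] >= minDepth) {
    v@meta$interpolated <- FALSE
    return(v)
  }
  zin <- seq_len(d[3]) - 1
  zout <- seq(0, d[3] - 1, length.out = minDepth)
  img <- array(0, c(d[1], d[2], minDepth))
  for (j in seq_len(d[2])) {
    cols <- v@image[, j, , drop = TRUE]           # d1 x depth
    img[, j, ] <- t(apply(cols, 1, function(y)
      spline(zin, y, xout = zout, method = "natural")$y))
  }
  nn <- clamp(round(zout) + 1, 1, d[3])
  msk <- v@mask[, , nn, drop = FALSE]
  new_sp <- v@spacing
  new_sp[3] <- new_sp[3] * (d[3] - 1) / max(1, minDepth - 1)
  LabeledVolume(img, array(as.integer(msk), c(d[1], d[2], minDepth)), new_sp,
                v@patientId, meta = c(v@meta, list(interpolated = TRUE)))
}

#' Full preprocessing chain for a labelled volume
#'
#' Bias hook (identity) -> through-plane interpolation -> resampling to the
#' reference grid -> kidney windowing; normalization and padding are left
#' to the caller because training operates on crops while inference pads
#' whole volumes.
#'
#' @param v a [LabeledVolume-class].
#' @param cfg a [preprocessConfig()].
#' @return A [LabeledVolume-class] with windowed intensities in [0, 1].
#' @export
preprocessVolume <- function(v, cfg = preprocessConfig()) {
  v <- interpolateSlices(v, cfg$minDepth)
  v <- resampleVolume(v, cfg)
  LabeledVolume(huWindow(v@image, cfg), v@mask, v@spacing, v@patientId,
                meta = v@meta)
}
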