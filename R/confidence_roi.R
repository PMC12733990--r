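# Pixel confidence, region confidence S_i, and the mask -> ROI extraction
# pipeline that feeds the classifier: connected components with a minimum
# volume threshold, 15%-margin bounding boxes, standardized 96 x 96 x 32
# patches and clipped z-score normalization.

#' Pixel-confidence weights
#'
#' The three terms of the voxelwise confidence: maximum class probability,
#' normalized entropy complement, and Monte Carlo agreement.  The weights
#' must sum to one.
#'
#' @param w1,w2,w3 nonnegative weights (defaults 0.5 / 0.3 / 0.2).
#' @param nMcPasses dropout inference passes for the consistency term.
#' @return A list of class `nx_confidence_weights`.
#' @export
confidenceWeights <- function(w1 = 0.5, w2 = 0.3, w3 = 0.2, nMcPasses = 5L) {
  if (abs(w1 + w2 + w3 - 1) > 1e-9 || any(c(w1, w2, w3) < 0))
    nx_stop("confidence weights must be nonnegative and sum to 1")
  structure(list(w1 = w1, w2 = w2, w3 = w3, nMcPasses = as.integer(nMcPasses)),
            class = "nx_confidence_weights")
}

#' Voxelwise segmentation confidence
#'
#' `C = w1 * max_c p + w2 * (1 - H/ln K) + w3 * Consistency`, where `H` is
#' the voxel entropy of the mean prediction and Consistency is the
#' fraction of Monte Carlo passes whose argmax equals the modal argmax.
#' The entropy enters as its normalized complement so that confidence
#' decreases with uncertainty; all three terms, and hence `C`, lie in
#' [0, 1].
#'
#' @param probs (5, X, Y, Z) mean predicted probabilities.
#' @param mcProbs nonempty list of (5, X, Y, Z) dropout-pass probabilities.
#' @param w a [confidenceWeights()].
#' @return Numeric (X, Y, Z) confidence map in [0, 1].
#' @export
pixelConfidence <- function(probs, mcProbs, w = confidenceWeights()) {
  if (length(mcProbs) < 1) nx_stop("at least one Monte Carlo pass is required")
  d <- dim(probs)
  K <- d[1]
  m <- matrix(probs, nrow = K)
  mx <- m[1, ]
  for (c in 2:K) mx <- pmax(mx, m[c, ])
  pl <- pmax(m, 1e-12)
  H <- -colSums(pl * log(pl))
  ent_term <- 1 - H / log(K)
  am <- vapply(mcProbs, function(p) max.col(t(matrix(p, nrow = K)),
                                            ties.method = "first"), numeric(ncol(m)))
  am <- matrix(am, ncol = length(mcProbs))
  consistency <- apply(am, 1, function(v) max(tabulate(v, K)) / length(v))
  cmap <- w$w1 * mx + w$w2 * ent_term + w$w3 * consistency
  array(clamp(cmap, 0, 1), d[-1])
}

#' Connected components of one pathology class
#'
#' 26-connectivity components of `mask == classLabel`; components smaller
#' than `vMin` voxels are discarded as noise.  Components are ordered by
#' size (descending), ties broken by their lexicographically smallest
#' voxel, making the pipeline deterministic.
#'
#' @param mask integer 3D label grid.
#' @param classLabel label value (2 cyst, 3 tumor, 4 stone).
#' @param vMin minimum voxel count (default 27; components of exactly 27
#'   voxels are kept).
#' @return List of components, each `list(voxels = <n x 3, 0-based>,
#'   size = n)`.
#' @export
connectedComponents <- function(mask, classLabel, vMin = 27L) {
  m <- array(mask == classLabel, dim(mask))
  lab <- label_components_cpp(m, 26L)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  comps <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    if (length(idx) < vMin) next
    vox <- arrayInd(idx, dim(mask)) - 1L
    # order rows lexicographically by (x, y, z)
    o <- order(vox[, 1], vox[, 2], vox[, 3])
    comps[[length(comps) + 1]] <- list(voxels = vox[o, , drop = FALSE],
                                       size = length(idx))
  }
  if (!length(comps)) return(list())
  keyord <- order(-vapply(comps, `[[`, 0L, "size"),
                  vapply(comps, function(cc) cc$voxels[1, 1], 0L),
                  vapply(comps, function(cc) cc$voxels[1, 2], 0L),
                  vapply(comps, function(cc) cc$voxels[1, 3], 0L))
  comps[keyord]
}

#' Expand a component's bounding box by a contextual margin
#'
#' The tight half-open box is grown by `ceiling(margin * extent)` on each
#' side per axis (context is never rounded away) and clipped to the
#' volume.
#'
#' @param component a component from [connectedComponents()] (or a bare
#'   `n x 3` 0-based voxel matrix).
#' @param volumeShape integer triple.
#' @param margin fractional margin per side (default 0.15).
#' @return Integer vector (x0, x1, y0, y1, z0, z1), 0-based half-open.
#' @export
expandBbox <- function(component, volumeShape, margin = 0.15) {
  vox <- if (is.list(component)) component$voxels else component
  lo <- apply(vox, 2, min)
  hi <- apply(vox, 2, max) + 1L
  ext <- hi - lo
  grow <- ceiling(margin * ext)
  lo <- pmax(0L, as.integer(lo - grow))
  hi <- pmin(as.integer(volumeShape), as.integer(hi + grow))
  as.integer(c(lo[1], hi[1], lo[2], hi[2], lo[3], hi[3]))
}

#' Extract and resize a standardized ROI patch
#'
#' Crops the half-open box and resizes to `target` with trilinear
#' interpolation.  When the per-axis scale factors differ by more than a
#' factor of two (extreme lesion dimensions), the crop is instead scaled
#' uniformly to fit and zero-padded symmetrically so the lesion's aspect
#' ratio is preserved.
#'
#' @param image numeric 3D array.
#' @param bbox integer (x0, x1, y0, y1, z0, z1), 0-based half-open.
#' @param target output patch shape (default 96 x 96 x 32).
#' @return Numeric array of shape `target`.
#' @export
extractPatch <- function(image, bbox, target = c(96L, 96L, 32L)) {
  ext <- bbox[c(2, 4, 6)] - bbox[c(1, 3, 5)]
  if (any(ext <= 0)) nx_stop("degenerate bounding box (zero extent)")
  crop <- image[(bbox[1] + 1):bbox[2], (bbox[3] + 1):bbox[4],
                (bbox[5] + 1):bbox[6], drop = FALSE]
  f <- target / ext
  if (max(f) / min(f) <= 2) {
    out <- resize3d_fwd_cpp(array(crop, c(1L, dim(crop))), as.integer(target))
    return(array(out, target))
  }
  s <- min(f)
  sz <- pmin(as.integer(target), pmax(1L, as.integer(round(ext * s))))
  mid <- resize3d_fwd_cpp(array(crop, c(1L, dim(crop))), sz)
  out <- array(0, target)
  off <- (target - sz) %/% 2L
  out[off[1] + seq_len(sz[1]), off[2] + seq_len(sz[2]), off[3] + seq_len(sz[3])] <-
    array(mid, sz)
  out
}

#' Clipped z-score normalization of an ROI patch
#'
#' `clip((x - mean) / (sd + 1e-6), -3, 3)`; a constant patch maps to
#' zeros.
#'
#' @param patch numeric array.
#' @param eps numerical guard (default 1e-6).
#' @return Normalized patch in [-3, 3].
#' @export
normalizeRoi <- function(patch, eps = 1e-6) {
  mu <- mean(patch)
  sg <- sqrt(mean((patch - mu)^2))
  clamp((patch - mu) / (sg + eps), -3, 3)
}

#' Region-level segmentation confidence S
#'
#' The mean of three unit-interval terms: prediction certainty (mean pixel
#' confidence over the component), boundary sharpness (mean over the
#' component's surface voxels of the largest face-neighbor jump of the
#' class probability; 1 for a binary field), and spatial consistency (the
#' component's share of all voxels of its class predicted inside its
#' expanded box).
#'
#' @param component a component from [connectedComponents()].
#' @param probs (5, X, Y, Z) predicted probabilities.
#' @param confidenceMap (X, Y, Z) map from [pixelConfidence()].
#' @param classLabel the component's label (2..4).
#' @param margin bbox margin used for the consistency term.
#' @return Scalar in [0, 1].
#' @export
regionConfidence <- function(component, probs, confidenceMap, classLabel,
                             margin = 0.15) {
  d <- dim(confidenceMap)
  vox <- component$voxels
  lin <- vox[, 1] + 1L + d[1] * (vox[, 2] + d[2] * vox[, 3])
  certainty <- mean(confidenceMap[lin])

  pc <- array(probs[classLabel + 1L, , , ], d)
  inside <- array(FALSE, d)
  inside[lin] <- TRUE
  jump_max <- numeric(nrow(vox))
  surface <- logical(nrow(vox))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- vox
    nb[, ax] <- nb[, ax] + s
    ok <- nb[, ax] >= 0L & nb[, ax] < d[ax]
    nlin <- nb[, 1] + 1L + d[1] * (nb[, 2] + d[2] * nb[, 3])
    nlin[!ok] <- 1L  # placeholder, masked below
    ext <- ok & !inside[nlin]
    surface <- surface | ext
    jump <- abs(pc[lin] - pc[nlin])
    jump[!ext] <- 0
    jump_max <- pmax(jump_max, jump)
  }
  sharpness <- if (any(surface)) mean(jump_max[surface]) else 1

  bbox <- expandBbox(component, d, margin)
  am <- argmax_ch(probs)
  sub <- am[(bbox[1] + 1):bbox[2], (bbox[3] + 1):bbox[4], (bbox[5] + 1):bbox[6]]
  total_cl <- sum(sub == classLabel)
  consistency <- if (total_cl > 0) component$size / total_cl else 1
  clamp(mean(c(certainty, sharpness, min(consistency, 1))), 0, 1)
}

#' One-hot segmentation output from a reference mask
#'
#' Wraps a ground-truth (oracle) label mask as a [SegOutput-class] so the
#' ROI pipeline can run on reference segmentations.
#'
#' @param mask integer 3D label grid (0..4).
#' @return A [SegOutput-class] with one-hot probabilities.
#' @export
segOutputFromMask <- function(mask) {
  probs <- onehot_grid(mask, 5L)
  new("SegOutput", probs = probs, logits = log(pmax(probs, P_CLAMP)))
}

#' ROI extraction configuration
#' @param vMin minimum component volume in voxels.
#' @param margin contextual bbox margin.
#' @param target standardized patch shape.
#' @param weights a [confidenceWeights()].
#' @return A list of class `nx_roi_config`.
#' @export
roiConfig <- function(vMin = 27L, margin = 0.15, target = c(96L, 96L, 32L),
                      weights = confidenceWeights()) {
  structure(list(vMin = as.integer(vMin), margin = margin,
                 target = as.integer(target), weights = weights),
            class = "nx_roi_config")
}

#' Extract standardized classification ROIs from a segmentation
#'
#' Argmax mask -> per-class 26-connectivity components -> volume filter ->
#' 15%-margin bounding boxes -> trilinear patch standardization -> clipped
#' z-score normalization, each patch annotated with its region confidence
#' S.  A volume with no surviving pathological component yields a single
#' whole-kidney ROI labelled "normal".
#'
#' @param image numeric 3D array (intensities aligned with `seg`).
#' @param seg a [SegOutput-class].
#' @param cfg a [roiConfig()].
#' @param confidenceMap optional precomputed [pixelConfidence()] map; by
#'   default the map is computed from the mean prediction alone (single
#'   pass, full consistency).
#' @param patientId id attached to the emitted records.
#' @return List of [ROIRecord-class] objects.
#' @export
roiPipeline <- function(image, seg, cfg = roiConfig(),
                        confidenceMap = NULL, patientId = "anon") {
  probs <- seg@probs
  d <- dim(image)
  if (!identical(dim(probs)[-1], d)) nx_stop("image and segmentation misaligned")
  if (is.null(confidenceMap))
    confidenceMap <- pixelConfidence(probs, list(probs), cfg$weights)
  am <- argmax_ch(probs)
  rois <- list()
  for (cl in c(2L, 3L, 4L)) {
    comps <- connectedComponents(am, cl, cfg$vMin)
    for (comp in comps) {
      bbox <- expandBbox(comp, d, cfg$margin)
      patch <- normalizeRoi(extractPatch(image, bbox, cfg$target))
      S <- regionConfidence(comp, probs, confidenceMap, cl, cfg$margin)
      rois[[length(rois) + 1]] <- new("ROIRecord", patch = patch,
        sourceBbox = bbox, predictedClass = names(MASK_LEVELS)[cl + 1L],
        confidenceS = S, patientId = patientId,
        voxelCount = as.integer(comp$size))
    }
  }
  if (!length(rois)) {
    kid <- which(am == 1L)
    if (length(kid) >= cfg$vMin) {
      vox <- arrayInd(kid, d) - 1L
      bbox <- expandBbox(vox, d, cfg$margin)
      S <- clamp(mean(confidenceMap[kid]), 0, 1)
      nv <- length(kid)
    } else {
      bbox <- as.integer(c(0L, d[1], 0L, d[2], 0L, d[3]))
      S <- clamp(mean(confidenceMap), 0, 1)
      nv <- prod(d)
    }
    patch <- normalizeRoi(extractPatch(image, bbox, cfg$target))
    rois[[1]] <- new("ROIRecord", patch = patch, sourceBbox = bbox,
                     predictedClass = "normal", confidenceS = S,
                     patientId = patientId, voxelCount = as.integer(nv))
  }
  rois
}
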