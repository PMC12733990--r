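PATHOLOGY_CLASSES <- c("normal", "cyst", "tumor", "stone")
MASK_LEVELS <- c(background = 0L, kidney = 1L, cyst = 2L, tumor = 3L, stone = 4L)

#' Synthetic CT kidney phantom specification
#'
#' Describes the study conditions under which phantom volumes are generated:
#' grid geometry, per-tissue Hounsfield-like intensity statistics, the
#' pathology class mixture of the cohort and per-class lesion size ranges.
#'
#' @slot volumeShape integer triple (in-plane, in-plane, through-plane).
#' @slot spacing numeric voxel spacing in mm.
#' @slot classMix named proportions over (normal, cyst, tumor, stone),
#'   summing to one.
#' @slot lesionRadiusRange named list of `c(min, max)` lesion radii in mm
#'   for cyst, tumor and stone.
#' @slot huParams named list of per-tissue `c(mean, sd)` intensities.
#' @slot noiseStd global multiplier on the per-tissue intensity noise.
#' @slot nLesions lesions per pathological patient (1--3).
#' @slot seed integer base seed; every patient derives its own stream.
#' @export
setClass("PhantomSpec", representation(
  volumeShape = "integer", spacing = "numeric", classMix = "numeric",
  lesionRadiusRange = "list", huParams = "list", noiseStd = "numeric",
  nLesions = "integer", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@volumeShape) != 3 || any(object@volumeShape < 8))
    msgs <- c(msgs, "volumeShape must be 3 values, all >= 8")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive values")
  if (!identical(sort(names(object@classMix)), sort(PATHOLOGY_CLASSES)))
    msgs <- c(msgs, "classMix must be named over normal/cyst/tumor/stone")
  if (abs(sum(object@classMix) - 1) > 1e-9 || any(object@classMix < 0))
    msgs <- c(msgs, "classMix proportions must be nonnegative and sum to 1")
  for (cl in c("cyst", "tumor", "stone")) {
    r <- object@lesionRadiusRange[[cl]]
    if (is.null(r) || length(r) != 2 || any(r <= 0) || r[1] > r[2])
      msgs <- c(msgs, sprintf("lesionRadiusRange$%s must be a positive interval", cl))
  }
  if (object@nLesions < 1L || object@nLesions > 3L)
    msgs <- c(msgs, "nLesions must be in 1..3")
  if (length(msgs)) msgs else TRUE
})

#' A labelled CT-like volume
#'
#' A 3D intensity grid in Hounsfield-like units with voxel spacing, an
#' aligned 5-class label mask (0 background, 1 kidney parenchyma, 2 cyst,
#' 3 tumor, 4 stone) and the patient the volume belongs to.
#'
#' @slot image numeric 3D array.
#' @slot mask integer 3D array with values in 0..4.
#' @slot spacing numeric voxel spacing in mm.
#' @slot patientId character scalar.
#' @slot meta free-form list (e.g. analytic lesion parameters for phantoms,
#'   or processing flags such as `interpolated`).
#' @export
setClass("LabeledVolume", representation(
  image = "array", mask = "array", spacing = "numeric", patientId = "character",
  meta = "list"
))

setValidity("LabeledVolume", function(object) {
  msgs <- character()
  if (!identical(dim(object@image), dim(object@mask)))
    msgs <- c(msgs, "image and mask must have identical dimensions")
  if (length(dim(object@image)) != 3)
    msgs <- c(msgs, "image must be a 3D array")
  mv <- unique(as.integer(object@mask))
  if (!all(mv %in% 0:4))
    msgs <- c(msgs, "mask values must be in {0, 1, 2, 3, 4}")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 positive values")
  if (length(msgs)) msgs else TRUE
})

#' Patient-level dataset split
#'
#' Disjoint train/validation/test patient-id sets; no patient ever appears
#' in more than one partition.
#'
#' @slot trainIds,valIds,testIds character vectors of patient ids.
#' @export
setClass("DatasetSplit", representation(
  trainIds = "character", valIds = "character", testIds = "character"
))

setValidity("DatasetSplit", function(object) {
  all_ids <- c(object@trainIds, object@valIds, object@testIds)
  if (anyDuplicated(all_ids)) "split partitions must be pairwise disjoint" else TRUE
})

#' Voxelwise segmentation output
#'
#' Per-voxel class probabilities (5 channels, summing to one at every voxel)
#' together with the raw logits.
#'
#' @slot probs numeric array (5, X, Y, Z).
#' @slot logits numeric array (5, X, Y, Z).
#' @export
setClass("SegOutput", representation(probs = "array", logits = "array"))

setValidity("SegOutput", function(object) {
  if (dim(object@probs)[1] != 5) return("probs must have 5 channels")
  s <- colSums(matrix(object@probs, nrow = 5))
  if (max(abs(s - 1)) > 1e-5) return("per-voxel probabilities must sum to 1")
  TRUE
})

#' A standardized classification region of interest
#'
#' One lesion (or whole-kidney) patch resized to 96 x 96 x 32 voxels, with
#' its source bounding box (0-based, half-open), the segmentation-derived
#' class, the scalar segmentation confidence S and bookkeeping fields.
#'
#' @slot patch numeric array (96, 96, 32).
#' @slot sourceBbox integer vector (x0, x1, y0, y1, z0, z1), half-open.
#' @slot predictedClass one of "normal", "cyst", "tumor", "stone".
#' @slot confidenceS segmentation confidence in [0, 1].
#' @slot patientId character scalar.
#' @slot voxelCount component size in voxels.
#' @export
setClass("ROIRecord", representation(
  patch = "array", sourceBbox = "integer", predictedClass = "character",
  confidenceS = "numeric", patientId = "character", voxelCount = "integer"
))

setValidity("ROIRecord", function(object) {
  msgs <- character()
  if (!identical(dim(object@patch), c(96L, 96L, 32L)))
    msgs <- c(msgs, "patch must be exactly 96 x 96 x 32")
  if (object@confidenceS < 0 || object@confidenceS > 1)
    msgs <- c(msgs, "confidenceS must lie in [0, 1]")
  if (!object@predictedClass %in% PATHOLOGY_CLASSES)
    msgs <- c(msgs, "predictedClass must be normal/cyst/tumor/stone")
  if (length(object@sourceBbox) != 6)
    msgs <- c(msgs, "sourceBbox must have 6 coordinates")
  if (object@voxelCount < 27L)
    msgs <- c(msgs, "voxelCount must be >= 27")
  if (length(msgs)) msgs else TRUE
})

#' Evidential Dirichlet classification output
#'
#' Concentration parameters over the four pathology classes.  Expected class
#' probabilities are alpha / sum(alpha) and the vacuity-style uncertainty is
#' K / sum(alpha), so accumulating evidence for any class reduces
#' uncertainty.
#'
#' @slot alpha numeric length-4 concentrations, all >= 1.
#' @export
setClass("DirichletPrediction", representation(alpha = "numeric"))

setValidity("DirichletPrediction", function(object) {
  if (length(object@alpha) != 4) return("alpha must have length 4 (K classes)")
  if (any(object@alpha < 1 - 1e-9)) return("all concentrations must be >= 1")
  TRUE
})

# ---- generics & accessors -------------------------------------------------

#' @export
setGeneric("scanArray", function(x) standardGeneric("scanArray"))
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @export
setGeneric("probsArray", function(x) standardGeneric("probsArray"))
#' @export
setGeneric("expectedProbs", function(x) standardGeneric("expectedProbs"))
#' @export
setGeneric("uncertainty", function(x) standardGeneric("uncertainty"))
#' @export
setGeneric("evidenceStrength", function(x) standardGeneric("evidenceStrength"))

#' @describeIn LabeledVolume intensity array accessor
#' @param x object
#' @export
setMethod("scanArray", "LabeledVolume", function(x) x@image)
#' @describeIn LabeledVolume label mask accessor
#' @export
setMethod("maskArray", "LabeledVolume", function(x) x@mask)
#' @describeIn LabeledVolume voxel spacing in mm
#' @export
setMethod("voxelSpacing", "LabeledVolume", function(x) x@spacing)
#' @describeIn LabeledVolume patient identifier
#' @export
setMethod("patientId", "LabeledVolume", function(x) x@patientId)
#' @describeIn SegOutput per-voxel class probabilities
#' @export
setMethod("probsArray", "SegOutput", function(x) x@probs)
#' @describeIn DirichletPrediction expected class probabilities alpha / S
#' @export
setMethod("expectedProbs", "DirichletPrediction", function(x) {
  p <- x@alpha / sum(x@alpha)
  names(p) <- PATHOLOGY_CLASSES
  p
})
#' @describeIn DirichletPrediction vacuity uncertainty K / S in (0, 1]
#' @export
setMethod("uncertainty", "DirichletPrediction", function(x)
  length(x@alpha) / sum(x@alpha))
#' @describeIn DirichletPrediction total evidence strength S = sum(alpha)
#' @export
setMethod("evidenceStrength", "DirichletPrediction", function(x) sum(x@alpha))

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@image)
  cat(sprintf("LabeledVolume '%s': %d x %d x %d @ %.1f x %.1f x %.1f mm\n",
              object@patientId, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  tab <- table(factor(object@mask, levels = 0:4,
                      labels = names(MASK_LEVELS)))
  cat("  voxels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d val / %d test patients\n",
              length(object@trainIds), length(object@valIds),
              length(object@testIds)))
})

setMethod("show", "ROIRecord", function(object) {
  cat(sprintf("ROIRecord '%s': class %s, %d voxels, S = %.3f\n",
              object@patientId, object@predictedClass, object@voxelCount,
              object@confidenceS))
})

setMethod("show", "DirichletPrediction", function(object) {
  p <- expectedProbs(object)
  cat(sprintf("DirichletPrediction: argmax %s (p = %.3f, u = %.3f)\n",
              names(p)[which.max(p)], max(p), uncertainty(object)))
  cat("  alpha:", paste(sprintf("%.2f", object@alpha), collapse = ", "), "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %s mm, seed %d\n",
              paste(object@volumeShape, collapse = "x"),
              paste(object@spacing, collapse = "x"), object@seed))
  cat("  class mix:", paste(sprintf("%s=%.3f", names(object@classMix),
                                    object@classMix), collapse = ", "), "\n")
})

#' Construct a LabeledVolume
#' @param image numeric 3D array of HU-like intensities.
#' @param mask integer 3D array, labels 0..4.
#' @param spacing voxel spacing in mm.
#' @param patientId patient identifier.
#' @return A [LabeledVolume-class] object.
#' @export
LabeledVolume <- function(image, mask, spacing, patientId = "anon",
                          meta = list()) {
  storage.mode(mask) <- "integer"
  new("LabeledVolume", image = image, mask = mask,
      spacing = as.numeric(spacing), patientId = as.character(patientId),
      meta = meta)
}

#' Construct a DirichletPrediction from concentration parameters
#' @param alpha numeric length-4, all >= 1.
#' @return A [DirichletPrediction-class] object.
#' @export
DirichletPrediction <- function(alpha) new("DirichletPrediction", alpha = as.numeric(alpha))
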