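# Cascade inference: preprocess -> segment -> pixel confidence (Monte
# Carlo dropout) -> ROI extraction -> evidential classification.

#' Run the full two-stage cascade on a volume
#'
#' The volume is windowed (and, if needed, slice-interpolated and
#' resampled), padded to the segmenter's downsampling multiple, segmented,
#' voxel confidence is estimated from Monte Carlo dropout passes, ROIs are
#' extracted from the predicted mask, and each ROI is classified with its
#' Dirichlet uncertainty.
#'
#' @param vol a [LabeledVolume-class] (the mask, if any, is ignored).
#' @param segNet segmentation network.
#' @param clsNet classifier network.
#' @param prepCfg a [preprocessConfig()].
#' @param roiCfg a [roiConfig()].
#' @param seed seed for the Monte Carlo dropout passes.
#' @return A list with `seg` ([SegOutput-class], original grid),
#'   `mask` (argmax labels), `confidence` (voxel map), `rois`
#'   (list of [ROIRecord-class]) and `predictions` (list of
#'   [DirichletPrediction-class], aligned with `rois`).
#' @export
cascadeInfer <- function(vol, segNet, clsNet, prepCfg = preprocessConfig(),
                         roiCfg = roiConfig(), seed = 1L) {
  v <- preprocessVolume(vol, prepCfg)
  div <- 2^(length(segNet$cfg$encoderChannels) - 1)
  pd <- padToMultiple(v@image, div)
  out <- segForward(segNet, pd$data, mode = "eval")

  nmc <- roiCfg$weights$nMcPasses
  mc <- with_seed(deriveSeed(seed, paste0("mc-", v@patientId)), {
    lapply(seq_len(nmc), function(i)
      segForward(segNet, pd$data, mode = "mc")@probs)
  })

  unpad_ch <- function(p) {
    d <- dim(p)
    keep <- lapply(1:3, function(a)
      pd$pad[a, 1] + seq_len(d[a + 1] - sum(pd$pad[a, ])))
    p[, keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  }
  probs <- unpad_ch(out@probs)
  logits <- unpad_ch(out@logits)
  mc <- lapply(mc, unpad_ch)
  seg <- new("SegOutput", probs = probs, logits = logits)
  cmap <- pixelConfidence(probs, mc, roiCfg$weights)
  rois <- roiPipeline(v@image, seg, roiCfg, confidenceMap = cmap,
                      patientId = v@patientId)
  preds <- if (is.null(clsNet)) list()
  else lapply(rois, function(r) clsForward(clsNet, r))
  list(seg = seg, mask = argmax_ch(probs), confidence = cmap, rois = rois,
       predictions = preds)
}

#' Evaluate a trained cascade on a list of labelled volumes
#'
#' @param vols list of [LabeledVolume-class] with ground-truth masks.
#' @param segNet,clsNet trained networks.
#' @param prepCfg,roiCfg configuration objects.
#' @param seed Monte Carlo seed.
#' @return A list with `seg` (per-volume metric data.frame) and `cls`
#'   (a [clsMetrics()] report over patient-level lesion classes).
#' @export
evaluateCascade <- function(vols, segNet, clsNet,
                            prepCfg = preprocessConfig(),
                            roiCfg = roiConfig(), seed = 1L) {
  seg_rows <- list()
  preds <- integer(0)
  truth <- integer(0)
  scores <- NULL
  for (v in vols) {
    r <- cascadeInfer(v, segNet, clsNet, prepCfg, roiCfg, seed)
    m <- segMetrics(r$mask, v@mask, v@spacing)
    m$patient <- v@patientId
    seg_rows[[length(seg_rows) + 1]] <- m
    # patient-level class: the prediction of the largest-confidence ROI
    best <- which.max(vapply(r$rois, function(x) x@confidenceS, 0))
    p <- expectedProbs(r$predictions[[best]])
    preds <- c(preds, which.max(p))
    truth <- c(truth, match(v@meta$lesionClass %||% "normal", PATHOLOGY_CLASSES))
    scores <- rbind(scores, as.numeric(p))
  }
  list(seg = do.call(rbind, seg_rows),
       cls = clsMetrics(preds, truth, scores))
}
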