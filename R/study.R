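# Desk-scale end-to-end study: generate a phantom cohort, train the tiny
# segmenter on the training patients, train the tiny classifier on
# oracle-mask ROIs, and evaluate held-out segmentation Dice and ROI
# classification accuracy.  This is the reference experiment both the test
# suite and the acceptance script run.

# predicted label mask for one volume (windowed, padded forward, unpadded)
predict_mask <- function(net, vol, prepCfg = preprocessConfig()) {
  img <- huWindow(vol@image, prepCfg)
  div <- 2^(length(net$cfg$encoderChannels) - 1)
  pd <- padToMultiple(img, div)
  out <- segForward(net, pd$data, mode = "eval")
  unpadVolume(argmax_ch(out@probs), pd$pad)
}

# oracle-mask ROIs (one per patient) with patient-level labels
oracle_rois <- function(vols, prepCfg = preprocessConfig(),
                        roiCfg = roiConfig()) {
  rois <- list()
  labs <- character(0)
  for (v in vols) {
    rr <- roiPipeline(huWindow(v@image, prepCfg), segOutputFromMask(v@mask),
                      roiCfg, patientId = v@patientId)
    for (r in rr) {
      rois[[length(rois) + 1]] <- r
      labs <- c(labs, v@meta$lesionClass %||% "normal")
    }
  }
  list(rois = rois, labels = labs)
}

#' Run the desk-scale two-stage study end to end
#'
#' Generates `nPatients` phantoms under the spec seed, splits patients
#' 70/15/15 under the split seed, trains the tiny segmentation network for
#' `segEpochs` epochs, evaluates held-out cohort Dice, then trains the
#' tiny classifier for `clsEpochs` epochs on oracle-mask ROIs of the
#' training patients and reports held-out ROI classification accuracy.
#'
#' @param nPatients cohort size (default 120).
#' @param seed data seed: phantom spec and patient split (default 42).
#' @param modelSeed network initialization seed (default 123).
#' @param segEpochs,clsEpochs training epochs of the two stages.
#' @param segCfg,clsCfg optional network configurations (tiny defaults).
#' @return A list with `dice` (per-class held-out Dice), `meanDice`,
#'   `clsAccuracy`, `clsReport`, the two training logs and the split.
#' @export
deskScaleStudy <- function(nPatients = 120L, seed = 42L, modelSeed = 123L,
                           segEpochs = 5L, clsEpochs = 10L,
                           segCfg = tinySegConfig(), clsCfg = tinyClsConfig()) {
  spec <- phantomSpec(seed = as.integer(seed))
  vols <- generateCohort(spec, nPatients)
  ids <- vapply(vols, patientId, "")
  split <- splitPatients(ids, seed = as.integer(seed))
  vol_of <- setNames(vols, ids)
  tr <- vol_of[split@trainIds]
  va <- vol_of[split@valIds]
  te <- vol_of[split@testIds]

  segnet <- buildSegNet(segCfg, seed = as.integer(modelSeed))
  seg_res <- trainSeg(segnet, tr, va,
                      cfg = tinySegTrainConfig(epochs = as.integer(segEpochs),
                                               modelSeed = as.integer(modelSeed),
                                               splitSeed = as.integer(seed)))
  pred_masks <- lapply(te, function(v) predict_mask(seg_res$net, v))
  gt_masks <- lapply(te, maskArray)
  dice <- aggregateDice(pred_masks, gt_masks)

  tr_rois <- oracle_rois(tr)
  te_rois <- oracle_rois(te)
  clsnet <- buildClsNet(clsCfg, seed = as.integer(modelSeed))
  cls_res <- trainCls(clsnet, tr_rois$rois, tr_rois$labels,
                      cfg = tinyClsTrainConfig(epochs = as.integer(clsEpochs),
                                               modelSeed = as.integer(modelSeed),
                                               splitSeed = as.integer(seed)))
  scores <- do.call(rbind, lapply(te_rois$rois, function(r)
    as.numeric(expectedProbs(clsForward(cls_res$net, r)))))
  preds <- max.col(scores, ties.method = "first")
  report <- clsMetrics(preds, te_rois$labels, scores)

  list(dice = dice, meanDice = mean(dice), clsAccuracy = report$accuracy,
       clsReport = report, segLog = seg_res$log, clsLog = cls_res$log,
       lambdaLog = cls_res$lambdaLog, split = split)
}
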