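# Training loops: AdamW with linear warmup + cosine decay, gradient
# accumulation over mini-batches, gradient-norm clipping, per-epoch
# validation tracking with best-checkpoint retention, and (for the
# classifier) per-epoch adaptive loss-weight updates.

#' Training configuration
#'
#' Defaults follow the full-scale protocol: AdamW (beta1 0.9, beta2 0.999,
#' eps 1e-8, weight decay 0.01), gradient clipping at norm 1, linear
#' warmup from 1e-6 over the first epochs followed by cosine decay to
#' 1e-7, seeds 42 (data splitting) and 123 (model initialization).
#'
#' @param epochs,lr,batch training length, maximum learning rate, batch
#'   size.
#' @param warmupEpochs warmup duration in epochs (must be < epochs).
#' @param warmupStart,floorLr schedule endpoints.
#' @param beta1,beta2,eps,weightDecay AdamW settings.
#' @param clipNorm gradient-norm clip.
#' @param splitSeed,modelSeed reproducibility seeds.
#' @param cropSize optional training crop (segmentation only); `NULL`
#'   trains on whole volumes.
#' @param lesionCropProb probability that a crop is centered on a lesion
#'   voxel (class-balanced patch sampling).
#' @param cropsPerVolume crops drawn from each training volume per epoch.
#' @param classBalance sample training volumes inversely to their lesion
#'   class frequency (segmentation only), so rare pathologies are seen as
#'   often as common ones.
#' @param stratified class-stratified batch ordering (classifier only).
#' @return A list of class `nx_train_config`.
#' @export
trainConfig <- function(epochs, lr, batch, warmupEpochs = 5L,
                        warmupStart = 1e-6, floorLr = 1e-7, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, weightDecay = 0.01,
                        clipNorm = 1, splitSeed = 42L, modelSeed = 123L,
                        cropSize = NULL, lesionCropProb = 0.5,
                        cropsPerVolume = 1L, classBalance = FALSE,
                        stratified = FALSE) {
  stopifnot(epochs >= 1, lr > 0, batch >= 1, warmupEpochs < epochs)
  structure(list(epochs = as.integer(epochs), lr = lr, batch = as.integer(batch),
                 warmupEpochs = as.integer(warmupEpochs),
                 warmupStart = warmupStart, floorLr = floorLr, beta1 = beta1,
                 beta2 = beta2, eps = eps, weightDecay = weightDecay,
                 clipNorm = clipNorm, splitSeed = as.integer(splitSeed),
                 modelSeed = as.integer(modelSeed), cropSize = cropSize,
                 lesionCropProb = lesionCropProb,
                 cropsPerVolume = as.integer(cropsPerVolume),
                 classBalance = classBalance, stratified = stratified),
            class = "nx_train_config")
}

#' Full-scale segmentation training settings (100 epochs, lr 1e-4, batch 4)
#' @param ... overrides passed to [trainConfig()].
#' @export
segTrainConfig <- function(...) {
  args <- utils::modifyList(list(epochs = 100L, lr = 1e-4, batch = 4L), list(...))
  do.call(trainConfig, args)
}

#' Full-scale classifier training settings (50 epochs, lr 5e-5, batch 16)
#' @param ... overrides passed to [trainConfig()].
#' @export
clsTrainConfig <- function(...) {
  args <- utils::modifyList(list(epochs = 50L, lr = 5e-5, batch = 16L), list(...))
  do.call(trainConfig, args)
}

#' Desk-scale segmentation training (5 epochs, lesion-biased 32x32x16 crops)
#'
#' Short-schedule settings for CPU experiments: a higher learning rate and
#' a single warmup epoch so the tiny network can converge within a few
#' epochs, and lesion-biased crop sampling to counter the extreme
#' background imbalance.
#' @param ... overrides passed to [trainConfig()].
#' @export
tinySegTrainConfig <- function(...) {
  args <- utils::modifyList(
    list(epochs = 5L, lr = 1e-2, batch = 2L, warmupEpochs = 1L,
         cropSize = c(32L, 32L, 16L), cropsPerVolume = 2L,
         classBalance = TRUE), list(...))
  do.call(trainConfig, args)
}

#' Desk-scale classifier training (10 epochs, stratified batches)
#' @param ... overrides passed to [trainConfig()].
#' @export
tinyClsTrainConfig <- function(...) {
  args <- utils::modifyList(
    list(epochs = 10L, lr = 3e-3, batch = 4L, warmupEpochs = 1L,
         stratified = TRUE), list(...))
  do.call(trainConfig, args)
}

#' Learning-rate schedule: linear warmup then cosine decay
#'
#' Linear from `warmupStart` to `lr` over the warmup steps, then cosine
#' from `lr` down to `floorLr`, reaching the floor exactly at the final
#' step; the schedule is continuous at the joint.
#'
#' @param step 0-based global optimizer step.
#' @param cfg a [trainConfig()].
#' @param stepsPerEpoch optimizer steps per epoch.
#' @return The learning rate for `step`.
#' @export
lrSchedule <- function(step, cfg, stepsPerEpoch) {
  warm <- cfg$warmupEpochs * stepsPerEpoch
  total <- cfg$epochs * stepsPerEpoch
  if (step < warm)
    return(cfg$warmupStart + (cfg$lr - cfg$warmupStart) * step / warm)
  denom <- max(1L, total - warm - 1L)
  t <- min(1, (step - warm) / denom)
  cfg$floorLr + 0.5 * (cfg$lr - cfg$floorLr) * (1 + cos(pi * t))
}

# sample a training crop (0-based lower corner) for a volume; lesion-biased
sample_crop <- function(mask, crop) {
  d <- dim(mask)
  les <- which(mask >= 2L)
  if (length(les) && runif(1) < attr(crop, "lesion_prob") %||% 0.5) {
    v <- arrayInd(les[sample.int(length(les), 1)], d) - 1L
    lo <- pmin(pmax(v - crop %/% 2L, 0L), d - crop)
  } else {
    lo <- vapply(1:3, function(a) if (d[a] > crop[a])
      sample.int(d[a] - crop[a] + 1L, 1) - 1L else 0L, 0L)
  }
  as.integer(lo)
}

crop_arr <- function(x, lo, sz)
  x[(lo[1] + 1):(lo[1] + sz[1]), (lo[2] + 1):(lo[2] + sz[2]),
    (lo[3] + 1):(lo[3] + sz[3]), drop = FALSE]

#' Train the segmentation network
#'
#' Volumes are windowed once, then iterated in seeded shuffled order with
#' optional lesion-biased crop sampling; gradients are accumulated over
#' each mini-batch, clipped at the configured norm and applied with AdamW
#' under the warmup/cosine schedule.  Per-epoch train loss (with the
#' per-term breakdown), validation loss and validation foreground Dice
#' are logged, and the parameters of the best validation epoch are
#' restored at the end.
#'
#' @param net a network from [buildSegNet()].
#' @param trainVols,valVols lists of [LabeledVolume-class].
#' @param cfg a [trainConfig()] (see [segTrainConfig()]).
#' @param lossWeights a [segLossWeights()].
#' @param prepCfg a [preprocessConfig()] (for intensity windowing).
#' @return `list(net =, log =, bestEpoch =)`; the log is a data.frame
#'   with one row per epoch.
#' @export
trainSeg <- function(net, trainVols, valVols = list(), cfg = segTrainConfig(),
                     lossWeights = segLossWeights(),
                     prepCfg = preprocessConfig()) {
  if (!length(trainVols)) nx_stop("empty training set")
  xs <- lapply(trainVols, function(v) huWindow(v@image, prepCfg))
  ms <- lapply(trainVols, function(v) v@mask)
  vx <- lapply(valVols, function(v) huWindow(v@image, prepCfg))
  vm <- lapply(valVols, function(v) v@mask)
  n <- length(xs)
  reps <- if (is.null(cfg$cropSize)) 1L else max(1L, cfg$cropsPerVolume %||% 1L)
  n_iter <- n * reps
  steps_per_epoch <- max(1L, n_iter %/% cfg$batch)
  crop <- cfg$cropSize
  if (!is.null(crop)) {
    crop <- as.integer(crop)
    attr(crop, "lesion_prob") <- cfg$lesionCropProb
  }

  vol_cls <- vapply(trainVols, function(v)
    v@meta$lesionClass %||% names(MASK_LEVELS)[max(v@mask) + 1L], "")
  cls_n <- table(vol_cls)
  samp_w <- if (isTRUE(cfg$classBalance)) 1 / as.numeric(cls_n[vol_cls])
  else rep(1, n)

  set.seed(deriveSeed(cfg$modelSeed, "train-seg"))
  gstep <- 0L
  log <- list()
  best <- list(loss = Inf, values = NULL, epoch = NA_integer_)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- if (isTRUE(cfg$classBalance))
      sample(seq_len(n), n_iter, replace = TRUE, prob = samp_w)
    else sample(rep(seq_len(n), reps))
    ep_terms <- c(ce = 0, dice = 0, boundary = 0, focal = 0)
    ep_loss <- 0
    nb <- 0L
    i <- 1L
    while (i + cfg$batch - 1L <= n_iter || (i <= n_iter && n_iter < cfg$batch)) {
      idx <- ord[i:min(n_iter, i + cfg$batch - 1L)]
      i <- i + cfg$batch
      zero_grads(net$params)
      bloss <- 0
      for (j in idx) {
        img <- xs[[j]]
        msk <- ms[[j]]
        if (!is.null(crop)) {
          cs <- pmin(crop, dim(msk))  # crops never exceed the volume
          attr(cs, "lesion_prob") <- attr(crop, "lesion_prob")
          lo <- sample_crop(msk, cs)
          img <- crop_arr(img, lo, cs)
          msk <- crop_arr(msk, lo, cs)
        }
        y <- onehot_grid(msk, 5L)
        sdt <- sdt_per_class(y, sigma = lossWeights$sdtSigma)
        tape_start()
        out <- seg_forward_nodes(net, img, mode = "train")
        loss <- op_seg_loss(out$probs, y, lossWeights, sdt)
        sloss <- op_scalar_mul(loss, 1 / length(idx))
        tape_backward(sloss)
        tape_stop()
        if (!is.finite(loss$v))
          nx_stop("divergence: non-finite loss at epoch ", epoch)
        bloss <- bloss + loss$v / length(idx)
        ep_terms <- ep_terms + loss$terms / length(idx)
      }
      gstep <- gstep + 1L
      adamw_step(net$params, lrSchedule(gstep - 1L, cfg, steps_per_epoch),
                 cfg$beta1, cfg$beta2, cfg$eps, cfg$weightDecay, gstep,
                 cfg$clipNorm)
      ep_loss <- ep_loss + bloss
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    ep_terms <- ep_terms / nb

    val_loss <- NA_real_
    val_dice <- NA_real_
    if (length(vx)) {
      vl <- 0
      vd <- 0
      div <- 2^(length(net$cfg$encoderChannels) - 1)
      for (k in seq_along(vx)) {
        pd <- padToMultiple(vx[[k]], div)
        out <- segForward(net, pd$data, mode = "eval")
        probs <- out@probs
        pm <- unpadVolume(argmax_ch(probs), pd$pad)
        y <- onehot_grid(padToMultiple(vm[[k]] + 0, div)$data, 5L)
        r <- seg_loss_valgrad(probs, y, lossWeights,
                              sdt_per_class(y, sigma = lossWeights$sdtSigma),
                              want_grad = FALSE)
        vl <- vl + r$total
        vd <- vd + mean(dice_by_class(pm, vm[[k]]))
      }
      val_loss <- vl / length(vx)
      val_dice <- vd / length(vx)
      if (val_loss < best$loss) {
        best$loss <- val_loss
        best$values <- params_values(net$params)
        best$epoch <- epoch
      }
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss,
                               ce = ep_terms["ce"], dice = ep_terms["dice"],
                               boundary = ep_terms["boundary"],
                               focal = ep_terms["focal"], val_loss = val_loss,
                               val_dice = val_dice, row.names = NULL)
  }
  if (!is.null(best$values)) params_restore(net$params, best$values)
  list(net = net, log = do.call(rbind, log), bestEpoch = best$epoch)
}

# class-stratified ordering: interleave shuffled per-class pools
stratified_order <- function(labels) {
  pools <- lapply(sort(unique(labels)), function(cl) sample(which(labels == cl)))
  ord <- integer(0)
  while (any(lengths(pools) > 0)) {
    for (k in seq_along(pools)) {
      if (length(pools[[k]])) {
        ord <- c(ord, pools[[k]][1])
        pools[[k]] <- pools[[k]][-1]
      }
    }
  }
  ord
}

#' Train the ROI classifier
#'
#' Mini-batch AdamW training of the evidential classifier with the
#' adaptive multi-objective loss; the four loss weights are re-derived
#' from per-term learning progress after every epoch and logged together
#' with the progress statistics.
#'
#' @param net a classifier from [buildClsNet()].
#' @param rois list of [ROIRecord-class] training patches.
#' @param labels true class per ROI (indices 1..4 or names).
#' @param valRois,valLabels optional held-out ROIs for accuracy tracking.
#' @param cfg a [trainConfig()] (see [clsTrainConfig()]).
#' @return `list(net =, log =, lambdaLog =)`.
#' @export
trainCls <- function(net, rois, labels, valRois = list(), valLabels = NULL,
                     cfg = clsTrainConfig()) {
  if (!length(rois)) nx_stop("empty ROI training set")
  to_idx <- function(x) if (is.numeric(x)) as.integer(x)
    else match(as.character(x), PATHOLOGY_CLASSES)
  y <- to_idx(labels)
  n <- length(rois)
  steps_per_epoch <- max(1L, n %/% cfg$batch)
  state <- adaptiveWeightState()
  term_hist <- NULL

  set.seed(deriveSeed(cfg$modelSeed, "train-cls"))
  gstep <- 0L
  log <- list()
  lambda_log <- list()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- if (cfg$stratified) stratified_order(y) else sample.int(n)
    ep_terms <- c(ce = 0, edl = 0, kl = 0, conf = 0)
    ep_loss <- 0
    ep_correct <- 0L
    nb <- 0L
    i <- 1L
    while (i <= n) {
      idx <- ord[i:min(n, i + cfg$batch - 1L)]
      i <- i + cfg$batch
      zero_grads(net$params)
      for (j in idx) {
        tape_start()
        fw <- cls_forward_nodes(net, rois[[j]]@patch, rois[[j]]@confidenceS,
                                mode = "train")
        loss <- op_cls_loss(fw$alpha, y[j], rois[[j]]@confidenceS,
                            state$lambda)
        sloss <- op_scalar_mul(loss, 1 / length(idx))
        tape_backward(sloss)
        tape_stop()
        if (!is.finite(loss$v))
          nx_stop("divergence: non-finite loss at epoch ", epoch)
        ep_loss <- ep_loss + loss$v
        ep_terms <- ep_terms + loss$terms
        ep_correct <- ep_correct + (which.max(fw$alpha$v) == y[j])
      }
      gstep <- gstep + 1L
      adamw_step(net$params, lrSchedule(gstep - 1L, cfg, steps_per_epoch),
                 cfg$beta1, cfg$beta2, cfg$eps, cfg$weightDecay, gstep,
                 cfg$clipNorm)
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / n
    ep_terms <- ep_terms / n
    term_hist <- rbind(term_hist, ep_terms)
    state <- adaptiveWeights(term_hist, state)

    val_acc <- NA_real_
    if (length(valRois)) {
      vy <- to_idx(valLabels)
      preds <- vapply(valRois, function(r)
        which.max(clsForward(net, r)@alpha), 0L)
      val_acc <- mean(preds == vy)
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss,
                               ce = ep_terms["ce"], edl = ep_terms["edl"],
                               kl = ep_terms["kl"], conf = ep_terms["conf"],
                               train_acc = ep_correct / n, val_acc = val_acc,
                               row.names = NULL)
    lambda_log[[epoch]] <- data.frame(epoch = epoch,
                                      t(setNames(state$lambda,
                                                 paste0("lambda_", names(ep_terms)))),
                                      t(setNames(state$z,
                                                 paste0("z_", names(ep_terms)))),
                                      row.names = NULL)
  }
  list(net = net, log = do.call(rbind, log),
       lambdaLog = do.call(rbind, lambda_log))
}
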