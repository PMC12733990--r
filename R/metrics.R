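# Evaluation metrics: volumetric overlap (Dice), boundary-precision
# surface metrics (95th-percentile Hausdorff distance, boundary IoU) for
# segmentation, and standard classification metrics (accuracy, per-class
# precision/recall/F1, one-vs-rest AUC by the rank statistic).

# face-connected surface voxels of a logical region (volume border counts
# as outside)
surface_voxels <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  if (!any(m)) return(out)
  shift_out <- function(ax, s) {
    r <- array(TRUE, d)  # out-of-volume treated as background
    n <- d[ax]
    if (n < 2) return(r)  # singleton axis: every voxel touches the border
    idx_src <- lapply(d, seq_len)
    idx_dst <- lapply(d, seq_len)
    if (s == 1) { idx_src[[ax]] <- 1:(n - 1); idx_dst[[ax]] <- 2:n }
    else { idx_src[[ax]] <- 2:n; idx_dst[[ax]] <- 1:(n - 1) }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      !m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  nb_bg <- array(FALSE, d)
  for (ax in 1:3) for (s in c(1, -1)) nb_bg <- nb_bg | shift_out(ax, s)
  m & nb_bg
}

# 26-connectivity dilation by one voxel (Chebyshev ball = Euclidean <= sqrt(3))
dilate1_26 <- function(m) {
  if (!any(m)) return(m)
  dst <- edt_cpp(array(m, dim(m)), c(1, 1, 1))
  array(dst <= sqrt(3) + 1e-9, dim(m))
}

#' Segmentation metrics for one class pair
#'
#' Dice from voxel counts, HD95 as the larger of the two directed 95th
#' percentiles of surface-to-surface distances (mm, spacing-aware), and
#' boundary IoU on 1-voxel-dilated surface bands.  A class absent from
#' both masks scores Dice 1, HD95 0, boundary IoU 1; a class present in
#' only one scores Dice 0, HD95 Inf, boundary IoU 0.
#'
#' @param pred,gt logical 3D region masks.
#' @param spacing voxel spacing in mm.
#' @return Named vector `c(dice =, hd95 =, biou =)`.
#' @export
surfaceMetrics <- function(pred, gt, spacing = c(1, 1, 1)) {
  np <- sum(pred)
  ng <- sum(gt)
  if (np == 0 && ng == 0) return(c(dice = 1, hd95 = 0, biou = 1))
  if (np == 0 || ng == 0) return(c(dice = 0, hd95 = Inf, biou = 0))
  dice <- 2 * sum(pred & gt) / (np + ng)
  sp_ <- surface_voxels(array(pred, dim(pred)))
  sg_ <- surface_voxels(array(gt, dim(gt)))
  d_to_g <- edt_cpp(sg_, as.numeric(spacing))
  d_to_p <- edt_cpp(sp_, as.numeric(spacing))
  da <- d_to_g[sp_]
  db <- d_to_p[sg_]
  hd95 <- max(quantile(da, 0.95, names = FALSE),
              quantile(db, 0.95, names = FALSE))
  ba <- dilate1_26(sp_)
  bb <- dilate1_26(sg_)
  biou <- sum(ba & bb) / sum(ba | bb)
  c(dice = dice, hd95 = hd95, biou = biou)
}

#' Per-class segmentation metrics
#'
#' @param predMask,gtMask integer label grids (0..4).
#' @param spacing voxel spacing in mm.
#' @param classes label values to evaluate (default foreground 1..4).
#' @return data.frame with columns class, dice, hd95, biou.
#' @export
segMetrics <- function(predMask, gtMask, spacing = c(1, 1, 1), classes = 1:4) {
  if (!identical(dim(predMask), dim(gtMask)))
    nx_stop("masks must have identical shape")
  rows <- lapply(classes, function(cl) {
    m <- surfaceMetrics(predMask == cl, gtMask == cl, spacing)
    data.frame(class = names(MASK_LEVELS)[cl + 1L], dice = m["dice"],
               hd95 = m["hd95"], biou = m["biou"], row.names = NULL)
  })
  do.call(rbind, rows)
}

# one-vs-rest AUC by the Mann-Whitney rank statistic (midranks for ties)
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification evaluation report
#'
#' @param pred predicted class indices (1..4) or class names.
#' @param labels true class indices (1..4) or names.
#' @param scores optional n x 4 score matrix (e.g. expected probabilities)
#'   for the one-vs-rest AUC.
#' @return A list with `accuracy`, `perClass` (precision/recall/F1/AUC/
#'   support; zero-division conventions give 0), and the `confusion`
#'   matrix (rows = truth).
#' @export
clsMetrics <- function(pred, labels, scores = NULL) {
  to_idx <- function(x) if (is.numeric(x)) as.integer(x)
    else match(as.character(x), PATHOLOGY_CLASSES)
  p <- to_idx(pred)
  y <- to_idx(labels)
  if (length(p) < 1) nx_stop("need at least one prediction")
  K <- 4L
  conf <- matrix(0L, K, K, dimnames = list(truth = PATHOLOGY_CLASSES,
                                           pred = PATHOLOGY_CLASSES))
  for (i in seq_along(p)) conf[y[i], p[i]] <- conf[y[i], p[i]] + 1L
  acc <- sum(diag(conf)) / length(p)
  per <- lapply(seq_len(K), function(k) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    auc <- if (!is.null(scores)) auc_rank(scores[, k], y == k) else NA_real_
    data.frame(class = PATHOLOGY_CLASSES[k], precision = prec, recall = rec,
               f1 = f1, auc = auc, support = sum(y == k))
  })
  list(accuracy = acc, perClass = do.call(rbind, per), confusion = conf)
}

# hard per-class Dice of an argmax mask vs ground truth (counts only);
# used for cheap validation tracking during training
dice_by_class <- function(predMask, gtMask, classes = 1:4) {
  vapply(classes, function(cl) {
    np <- sum(predMask == cl)
    ng <- sum(gtMask == cl)
    if (np == 0 && ng == 0) return(1)
    2 * sum(predMask == cl & gtMask == cl) / (np + ng)
  }, 0)
}

#' Cohort-aggregated per-class Dice
#'
#' Voxel counts are pooled over all volumes before the Dice ratio is
#' formed, so small lesions are weighted by their voxels rather than by
#' patient; classes absent from the whole cohort are dropped.
#'
#' @param predMasks,gtMasks aligned lists of label grids.
#' @param classes label values to evaluate (default foreground 1..4).
#' @return Named per-class Dice vector.
#' @export
aggregateDice <- function(predMasks, gtMasks, classes = 1:4) {
  out <- vapply(classes, function(cl) {
    np <- ng <- ni <- 0
    for (i in seq_along(gtMasks)) {
      np <- np + sum(predMasks[[i]] == cl)
      ng <- ng + sum(gtMasks[[i]] == cl)
      ni <- ni + sum(predMasks[[i]] == cl & gtMasks[[i]] == cl)
    }
    if (ng == 0 && np == 0) return(NA_real_)
    2 * ni / (np + ng)
  }, 0)
  names(out) <- names(MASK_LEVELS)[classes + 1L]
  out[!is.na(out)]
}
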