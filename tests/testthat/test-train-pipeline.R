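# Training machinery (schedule, descent, determinism, adaptive weights)
# and the cascade inference contract.

test_that("the learning-rate schedule hits its anchors and is continuous", {
  cfg <- trainConfig(epochs = 20L, lr = 1e-4, batch = 4L, warmupEpochs = 5L)
  spe <- 10L
  expect_equal(lrSchedule(0, cfg, spe), 1e-6)
  expect_equal(lrSchedule(5L * spe, cfg, spe), 1e-4)
  total <- 20L * spe
  expect_lt(abs(lrSchedule(total - 1L, cfg, spe) - 1e-7), 1e-9)
  # continuity at the warmup/cosine joint
  before <- lrSchedule(5L * spe - 1L, cfg, spe)
  after <- lrSchedule(5L * spe, cfg, spe)
  expect_lt(abs(after - before), (1e-4 - 1e-6) / (5 * spe) * 1.5)
  # warmup is monotone increasing, decay monotone decreasing
  lrs <- vapply(0:(total - 1), lrSchedule, 0, cfg = cfg, stepsPerEpoch = spe)
  expect_true(all(diff(lrs[1:(5 * spe + 1)]) > 0))
  expect_true(all(diff(lrs[(5 * spe + 1):total]) <= 0))
})

test_that("segmentation training descends and is seed-reproducible", {
  spec <- tiny_spec(seed = 17L)
  vols <- lapply(1:6, function(i)
    generatePhantom(spec, sprintf("T%02d", i),
                    lesionClass = c("cyst", "normal", "tumor")[1 + i %% 3]))
  cfg <- tinySegTrainConfig(epochs = 3L, cropSize = c(16L, 16L, 12L),
                            classBalance = FALSE)
  net <- buildSegNet(tinySegConfig(), seed = 123L)
  r <- trainSeg(net, vols, vols[1:2], cfg = cfg)
  expect_equal(nrow(r$log), 3)
  expect_lt(r$log$loss[3], r$log$loss[1])
  expect_true(all(is.finite(r$log$val_loss)))
  # identical seeds reproduce the first-epoch loss bit-identically
  net2 <- buildSegNet(tinySegConfig(), seed = 123L)
  r2 <- trainSeg(net2, vols, list(), cfg = cfg)
  expect_identical(r2$log$loss[1], r$log$loss[1])
})

test_that("classifier training improves accuracy and logs unit-sum weights", {
  spec <- tiny_spec(seed = 23L)
  vols <- lapply(1:12, function(i)
    generatePhantom(spec, sprintf("C%02d", i),
                    lesionClass = c("normal", "cyst", "tumor", "stone")[1 + i %% 4]))
  rr <- nephrodx:::oracle_rois(vols, roiCfg = roiConfig(vMin = 10L))
  net <- buildClsNet(tinyClsConfig(), seed = 123L)
  r <- trainCls(net, rr$rois, rr$labels, cfg = tinyClsTrainConfig(epochs = 4L))
  lam <- as.matrix(r$lambdaLog[, paste0("lambda_", c("ce", "edl", "kl", "conf"))])
  expect_equal(unname(rowSums(lam)), rep(1, 4), tolerance = 1e-9)
  expect_gt(r$log$train_acc[4], r$log$train_acc[1] - 0.1)
  expect_lt(r$log$loss[4], r$log$loss[1])
})

test_that("stratified ordering interleaves classes near-proportionally", {
  set.seed(5)
  labels <- rep(1:4, times = c(8, 8, 4, 4))
  ord <- nephrodx:::stratified_order(labels)
  expect_setequal(ord, seq_along(labels))
  # every consecutive block of 4 contains at least 3 distinct classes early on
  first4 <- labels[ord[1:4]]
  expect_gte(length(unique(first4)), 3)
})

test_that("cascade inference is deterministic and contract-clean", {
  v <- generatePhantom(tiny_spec(seed = 41L), "P1", lesionClass = "cyst")
  segnet <- buildSegNet(tinySegConfig(), seed = 123L)
  clsnet <- buildClsNet(tinyClsConfig(), seed = 123L)
  roi_cfg <- roiConfig(weights = confidenceWeights(nMcPasses = 2L))
  r1 <- cascadeInfer(v, segnet, clsnet, roiCfg = roi_cfg, seed = 7L)
  r2 <- cascadeInfer(v, segnet, clsnet, roiCfg = roi_cfg, seed = 7L)
  expect_identical(r1$mask, r2$mask)
  expect_identical(lapply(r1$predictions, function(p) p@alpha),
                   lapply(r2$predictions, function(p) p@alpha))
  expect_identical(dim(r1$mask), dim(scanArray(v)))
  expect_gte(length(r1$rois), 1)
  for (p in r1$predictions) {
    expect_true(validObject(p))
    expect_equal(sum(expectedProbs(p)), 1, tolerance = 1e-7)
    u <- uncertainty(p)
    expect_true(u > 0 && u <= 1)
  }
  for (roi in r1$rois) expect_true(validObject(roi))
})

test_that("checkpoints round-trip parameters for both networks", {
  seg <- buildSegNet(tinySegConfig(), seed = 5L)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(seg, f)
  seg2 <- loadCheckpoint(f)
  expect_identical(nephrodx:::params_values(seg$params),
                   nephrodx:::params_values(seg2$params))
  cls <- buildClsNet(tinyClsConfig(), seed = 6L)
  saveCheckpoint(cls, f)
  cls2 <- loadCheckpoint(f)
  expect_identical(cls2$kind, "cls")
  expect_identical(nephrodx:::params_values(cls$params),
                   nephrodx:::params_values(cls2$params))
})
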