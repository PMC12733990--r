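# Pixel/region confidence and the mask -> ROI pipeline.

test_that("pixel confidence matches hand arithmetic of its three terms", {
  w <- confidenceWeights()
  dims <- c(2, 2, 1)
  # fully confident: one-hot mean + identical passes
  oh <- nephrodx:::onehot_grid(array(1L, dims), 5L)
  cm <- pixelConfidence(oh, list(oh, oh), w)
  expect_lt(max(abs(cm - 1)), 1e-6)
  # uniform prediction + maximally disagreeing passes
  unif <- array(0.2, c(5, dims))
  passes <- lapply(0:4, function(k) nephrodx:::onehot_grid(array(k, dims), 5L))
  cm2 <- pixelConfidence(unif, passes, w)
  want <- w$w1 * 0.2 + w$w2 * 0 + w$w3 * (1 / 5)
  expect_lt(max(abs(cm2 - want)), 1e-6)
  # skewed prediction, all passes agreeing
  p <- array(c(0.6, 0.1, 0.1, 0.1, 0.1), c(5, 1, 1, 1))
  am <- nephrodx:::onehot_grid(array(0L, c(1, 1, 1)), 5L)
  H <- -(0.6 * log(0.6) + 4 * 0.1 * log(0.1))
  want3 <- 0.5 * 0.6 + 0.3 * (1 - H / log(5)) + 0.2 * 1
  expect_equal(as.vector(pixelConfidence(p, list(am, am), w)), want3,
               tolerance = 1e-6)
  expect_error(pixelConfidence(p, list(), w), "Monte Carlo")
  expect_error(confidenceWeights(0.5, 0.5, 0.5), "sum to 1")
})

test_that("connected components apply the volume threshold at exactly 27", {
  d <- c(12, 12, 8)
  m <- array(0L, d)
  m[1:3, 1:3, 1:3] <- 2L          # 27 voxels -> kept
  m[7:9, 7:9, 1:3] <- 2L
  m[9, 9, 3] <- 0L                # 26 voxels -> dropped
  comps <- connectedComponents(m, 2L)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$size, 27L)
  expect_length(connectedComponents(array(0L, d), 2L), 0)
})

test_that("components agree with a flood-fill oracle on random grids", {
  set.seed(77)
  for (rep in 1:12) {
    d <- c(10, 10, 6)
    m <- array(ifelse(runif(prod(d)) < 0.25, 3L, 0L), d)
    got <- connectedComponents(m, 3L, vMin = 1L)
    want <- oracle_components(m, 3L)
    expect_equal(length(got), length(want))
    got_sets <- lapply(got, function(cc)
      sort(cc$voxels[, 1] + 1 + d[1] * (cc$voxels[, 2] + d[2] * cc$voxels[, 3])))
    # set equality irrespective of ordering convention
    expect_setequal(vapply(got_sets, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("components are ordered by size then lexicographic minimum voxel", {
  d <- c(10, 10, 4)
  m <- array(0L, d)
  m[8:9, 8:9, 1:2] <- 4L  # 8 voxels, later corner
  m[1:2, 1:2, 1:2] <- 4L  # 8 voxels, origin corner
  m[4:6, 4:6, 1:3] <- 4L  # 27 voxels
  comps <- connectedComponents(m, 4L, vMin = 1L)
  expect_equal(vapply(comps, `[[`, 0L, "size"), c(27L, 8L, 8L))
  expect_equal(comps[[2]]$voxels[1, ], c(0L, 0L, 0L))
})

test_that("bounding boxes grow by the ceiling margin and clip to the volume", {
  comp <- list(voxels = cbind(10:19, 5L, 5L), size = 10L)
  bb <- expandBbox(comp, c(100L, 100L, 100L), margin = 0.15)
  expect_equal(bb[1:2], c(8L, 22L))          # ceil(1.5) = 2 per side
  expect_equal(bb[3:4], c(4L, 7L))           # extent 1, ceil(0.15) = 1
  comp0 <- list(voxels = cbind(0:5, 0L, 0L), size = 6L)
  bb0 <- expandBbox(comp0, c(10L, 10L, 10L))
  expect_equal(bb0[1], 0L)
  # expanded always contains the tight box
  expect_true(bb[1] <= 10 && bb[2] >= 20)
})

test_that("patch extraction resizes, preserves constants and extreme aspect", {
  img <- array(rnorm(96 * 96 * 40), c(96, 96, 40))
  idp <- extractPatch(img, c(0L, 96L, 0L, 96L, 0L, 32L))
  expect_lt(max(abs(idp - img[, , 1:32])), 1e-5)
  cst <- extractPatch(array(3.5, c(20, 20, 10)), c(0L, 20L, 0L, 20L, 0L, 10L))
  expect_lt(max(abs(cst - 3.5)), 1e-10)
  # 96 x 96 x 8 crop: scale factors (1, 1, 4) -> aspect-preserving branch
  big <- array(0, c(96, 96, 8))
  big[25:72, 25:72, 3:6] <- 1   # lesion block with 12:1 in-plane:depth ratio
  pat <- extractPatch(big, c(0L, 96L, 0L, 96L, 0L, 8L))
  expect_identical(dim(pat), c(96L, 96L, 32L))
  on <- which(pat > 0.5, arr.ind = TRUE)
  ratio_in <- (72 - 25 + 1) / (6 - 3 + 1)  # 48 voxels wide, 4 deep
  ratio_out <- (diff(range(on[, 1])) + 1) / (diff(range(on[, 3])) + 1)
  expect_lt(abs(ratio_out / ratio_in - 1), 0.05)
  expect_error(extractPatch(img, c(0L, 0L, 0L, 96L, 0L, 32L)), "degenerate")
})

test_that("ROI normalization is a clipped z-score with hand-checked values", {
  expect_true(all(normalizeRoi(array(4, c(3, 3, 3))) == 0))
  set.seed(2)
  p <- normalizeRoi(array(rnorm(1000, 5, 2), c(10, 10, 10)))
  expect_true(all(p >= -3 & p <= 3))
  x <- array(100, c(4, 4, 4))
  x[1:32] <- 90; x[33:64] <- 110   # mean 100, sd 10
  x[1] <- 130                       # would map beyond +3 without the mean shift
  mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
  expect_equal(max(normalizeRoi(x)), min((130 - mu) / (sg + 1e-6), 3))
})

test_that("region confidence is 1 for a binary single component and splits mass", {
  d <- c(16, 16, 8)
  m <- array(0L, d)
  m[5:9, 5:9, 3:5] <- 2L
  seg <- segOutputFromMask(m)
  cmap <- pixelConfidence(seg@probs, list(seg@probs))
  comp <- connectedComponents(m, 2L)[[1]]
  S <- regionConfidence(comp, seg@probs, cmap, 2L)
  expect_equal(S, 1, tolerance = 1e-9)
  # an equal-size twin component inside the expanded box halves consistency
  m2 <- m
  m2[11:15, 5:9, 3:5] <- 2L
  seg2 <- segOutputFromMask(m2)
  cmap2 <- pixelConfidence(seg2@probs, list(seg2@probs))
  comp2 <- connectedComponents(m2, 2L)[[1]]
  S2 <- regionConfidence(comp2, seg2@probs, cmap2, 2L, margin = 2)
  expect_equal(S2, mean(c(1, 1, 0.5)), tolerance = 1e-9)
})

test_that("the ROI pipeline emits contracts, filters speckle and recalls lesions", {
  v <- generatePhantom(tiny_spec(seed = 31L), "P1", lesionClass = "cyst")
  img <- huWindow(scanArray(v))
  rois <- roiPipeline(img, segOutputFromMask(maskArray(v)), patientId = "P1")
  expect_length(rois, 1)
  expect_equal(rois[[1]]@predictedClass, "cyst")
  expect_true(validObject(rois[[1]]))
  # sub-threshold speckle only -> a single whole-kidney "normal" ROI
  m <- maskArray(v)
  m[m == 2L] <- 1L
  set.seed(3)
  for (k in 1:6) {  # implant 6 speckles of < 27 voxels
    at <- sample(which(m == 1L), 1)
    v3 <- arrayInd(at, dim(m))
    m[v3[1], v3[2], v3[3]] <- 4L
  }
  rois2 <- roiPipeline(img, segOutputFromMask(m), patientId = "P1")
  expect_length(rois2, 1)
  expect_equal(rois2[[1]]@predictedClass, "normal")
})
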