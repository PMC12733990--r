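# Compound segmentation objective: closed forms, counting oracles,
# brute-force distance transforms and structural identities.

test_that("cross-entropy has its closed-form anchors", {
  dims <- c(4, 4, 2)
  y <- random_onehot(5, dims)
  expect_lt(crossEntropyLoss(y, y), 1e-6)
  unif <- array(0.2, c(5, dims))
  expect_equal(crossEntropyLoss(unif, y), log(5), tolerance = 1e-4)
  expect_error(crossEntropyLoss(unif, y[, 1:2, , , drop = FALSE]), "shape")
})

test_that("focal loss reduces to cross-entropy at gamma = 0 and is bounded by it", {
  set.seed(8)
  dims <- c(5, 4, 3)
  p <- random_probs(5, dims)
  y <- random_onehot(5, dims)
  expect_lt(abs(focalLoss(p, y, focalGamma = 0) - crossEntropyLoss(p, y)), 1e-7)
  for (g in c(0.5, 1, 2, 4))
    expect_lte(focalLoss(p, y, focalGamma = g), crossEntropyLoss(p, y) + 1e-12)
  # single-voxel hand value: p_true = 0.5, gamma = 2
  p1 <- array(c(0.5, 0.5, 0, 0, 0), c(5, 1, 1, 1))
  y1 <- array(c(1, 0, 0, 0, 0), c(5, 1, 1, 1))
  expect_equal(focalLoss(p1, y1, 2), 0.25 * (-log(0.5)), tolerance = 1e-5)
  expect_lt(abs(0.25 * (-log(0.5)) - 0.17329), 1e-5)
  # perfectly classified voxel contributes nothing
  expect_equal(focalLoss(y1, y1, 2), 0)
})

test_that("Dice loss matches the integer set-overlap oracle", {
  dims <- c(2, 2, 1)
  y <- nephrodx:::onehot_grid(array(c(1L, 1L, 0L, 0L), dims), 5L)
  p <- nephrodx:::onehot_grid(array(c(1L, 0L, 1L, 0L), dims), 5L)
  expect_lt(diceLoss(y, y), 1e-4)
  # half overlap for the kidney class: |A| = |B| = 2, |A n B| = 1
  d_kidney <- 2 * 1 / (2 + 2)
  expect_equal(d_kidney, 0.5)
  # remaining three foreground classes are absent from both (Dice 1)
  expect_equal(diceLoss(p, y), 1 - mean(c(0.5, 1, 1, 1)), tolerance = 1e-4)
  # fully disjoint class
  y2 <- nephrodx:::onehot_grid(array(c(2L, 2L, 0L, 0L), dims), 5L)
  p2 <- nephrodx:::onehot_grid(array(c(0L, 0L, 2L, 2L), dims), 5L)
  expect_equal(diceLoss(p2, y2), 1 - mean(c(1, 0, 1, 1)), tolerance = 1e-3)
})

test_that("signed distance transform equals the all-pairs oracle", {
  set.seed(42)
  for (rep in 1:20) {
    d <- c(8, 8, 4)
    m <- array(runif(prod(d)) < 0.3, d)
    if (!any(m) || all(m)) next
    got <- signedDistanceTransform(m)
    want <- oracle_sdt(m)
    expect_lt(max(abs(got - want)), 1e-9)
    # sign flips exactly at membership
    expect_true(all((got < 0) == m))
    # boundary-adjacent exterior voxels are within one voxel of the region
    surf_out <- !m & nephrodx:::dilate1_26(m) &
      (nephrodx:::edt_cpp(m, c(1, 1, 1)) <= 1)
    if (any(surf_out))
      expect_true(all(got[surf_out] > 0 & got[surf_out] <= 1))
  }
})

test_that("degenerate masks yield flagged constant transforms", {
  d <- c(4, 4, 2)
  e <- signedDistanceTransform(array(FALSE, d))
  expect_true(attr(e, "degenerate"))
  expect_true(all(e > 0))
  f <- signedDistanceTransform(array(TRUE, d))
  expect_true(attr(f, "degenerate"))
  expect_true(all(f < 0))
})

test_that("boundary loss matches hand evaluation on a 1D-style toy", {
  # 5 x 1 x 1 grid, ground truth = center voxel of the kidney class
  gt <- array(0L, c(5, 1, 1))
  gt[3, 1, 1] <- 1L
  y <- nephrodx:::onehot_grid(gt, 5L)
  D <- oracle_sdt(gt > 0)
  mk_probs <- function(pos) {
    p <- array(0, c(5, 5, 1, 1))
    p[1, , , ] <- 1
    p[1, pos, 1, 1] <- 0
    p[2, pos, 1, 1] <- 1
    p
  }
  loss_center <- boundaryLoss(mk_probs(3), y, sigma = 0)
  loss_end <- boundaryLoss(mk_probs(1), y, sigma = 0)
  # hand evaluation: all mass on one voxel -> loss = D at that voxel
  expect_equal(loss_center, D[3, 1, 1], tolerance = 1e-6)
  expect_equal(loss_end, D[1, 1, 1], tolerance = 1e-6)
  expect_lt(loss_center, loss_end)
  # uniform phi over the grid equals the plain mean of D
  pu <- array(0.2, c(5, 5, 1, 1))
  expect_equal(boundaryLoss(pu, y, sigma = 0), mean(D), tolerance = 1e-6)
})

test_that("boundary loss grows monotonically as a predicted blob moves away", {
  d <- c(16, 16, 8)
  gt <- array(0L, d)
  gt[6:9, 6:9, 3:5] <- 1L
  y <- nephrodx:::onehot_grid(gt, 5L)
  losses <- vapply(0:5, function(shift) {
    pm <- array(0L, d)
    pm[6:9 + shift, 6:9, 3:5] <- 1L
    p <- nephrodx:::onehot_grid(pm, 5L)
    boundaryLoss(p, y, sigma = 0)
  }, 0)
  expect_true(all(diff(losses) > 0))
})

test_that("compound loss reduces, vanishes and recombines as stated", {
  set.seed(9)
  dims <- c(6, 6, 4)
  p <- random_probs(5, dims)
  y <- random_onehot(5, dims)
  w_ce <- segLossWeights(alpha = 1, beta = 0, gamma = 0, delta = 0)
  expect_equal(compoundSegLoss(p, y, w_ce)$total, crossEntropyLoss(p, y),
               tolerance = 1e-10)
  w_zero <- segLossWeights(alpha = 0, beta = 0, gamma = 0, delta = 0)
  expect_equal(compoundSegLoss(p, y, w_zero)$total, 0)
  w <- segLossWeights()
  r <- compoundSegLoss(p, y, w)
  recomb <- 0.4 * r$terms["ce"] + 0.3 * r$terms["dice"] +
    0.2 * r$terms["boundary"] + 0.1 * r$terms["focal"]
  expect_equal(unname(recomb), r$total, tolerance = 1e-7)
  expect_error(segLossWeights(alpha = -1), "nonnegative")
})

test_that("loss terms respect their ranges and voxel-permutation symmetry", {
  set.seed(10)
  dims <- c(4, 3, 2)
  p <- random_probs(5, dims)
  y <- random_onehot(5, dims)
  expect_gte(crossEntropyLoss(p, y), 0)
  expect_gte(focalLoss(p, y), 0)
  expect_true(diceLoss(p, y) >= 0 && diceLoss(p, y) <= 1)
  # permuting voxels jointly leaves CE and focal unchanged
  perm <- sample(prod(dims))
  pm <- array(matrix(p, 5)[, perm], c(5, dims))
  ym <- array(matrix(y, 5)[, perm], c(5, dims))
  expect_equal(crossEntropyLoss(pm, ym), crossEntropyLoss(p, y), tolerance = 1e-12)
  expect_equal(focalLoss(pm, ym), focalLoss(p, y), tolerance = 1e-12)
  expect_equal(diceLoss(pm, ym), diceLoss(p, y), tolerance = 1e-12)
})
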