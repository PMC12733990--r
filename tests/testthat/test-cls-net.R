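# Classifier building blocks: adaptive residual blocks, squeeze-excitation,
# multi-resolution streams, context-aware fusion, confidence scaling and
# the evidential head.

test_that("adaptive blocks are residual-exact at alpha = 0 and init at 0.1", {
  set.seed(21)
  blk <- makeAcbBlock(8L, seed = 4L)
  expect_equal(blk$alpha$v, 0.1)
  x <- array(rnorm(8 * 6 * 6 * 4), c(8, 6, 6, 4))
  blk$alpha$v <- 0
  expect_identical(acbForward(blk, x), x)
  blk$alpha$v <- 0.1
  y <- acbForward(blk, x)
  expect_identical(dim(y), dim(x))
  expect_false(identical(y, x))
  expect_error(makeAcbBlock(2L, seReduction = 4L), "seReduction")
  expect_error(acbForward(blk, x[1:4, , , , drop = FALSE]), "channels")
})

test_that("squeeze-excitation matches a direct hand computation", {
  se <- makeSeModule(4L, reduction = 2L, seed = 6L)
  x <- array(rnorm(4 * 3 * 3 * 2), c(4, 3, 3, 2))
  r <- seForward(se, x)
  s <- rowMeans(matrix(x, 4))
  h <- pmax(se$w1$v %*% s + se$b1$v, 0)
  g <- 1 / (1 + exp(-(se$w2$v %*% h + se$b2$v)))
  expect_equal(as.vector(r$gates), as.vector(g), tolerance = 1e-12)
  expect_equal(r$out, x * as.vector(g), tolerance = 1e-12)
  # identical channels + tied weights give identical gates
  se$w1$v[] <- 0.3; se$w2$v[] <- -0.2
  xc <- array(rep(rnorm(3 * 3 * 2), each = 4), c(4, 3, 3, 2))
  gc <- seForward(se, xc)$gates
  expect_lt(diff(range(gc)), 1e-12)
})

test_that("resolution streams have the stated shapes and preserve constants", {
  p <- array(rnorm(96 * 96 * 32), c(96, 96, 32))
  st <- hmrpStreams(p)
  expect_identical(dim(st$fine), c(96L, 96L, 32L))
  expect_identical(dim(st$medium), c(72L, 72L, 24L))
  expect_identical(dim(st$coarse), c(48L, 48L, 16L))
  expect_equal(dim(st$medium), round(0.75 * dim(st$fine)))
  cst <- hmrpStreams(array(2.25, c(96, 96, 32)))
  expect_lt(max(abs(cst$medium - 2.25)), 1e-12)
  expect_lt(max(abs(cst$coarse - 2.25)), 1e-12)
  expect_error(hmrpStreams(array(0, c(48, 48, 16))), "96")
})

test_that("pathways use scale-matched kernels and respond to input scaling", {
  cfg <- tinyClsConfig()
  expect_equal(cfg$pathways$fine$kernel, c(3L, 3L, 3L))
  expect_equal(cfg$pathways$medium$kernel, c(5L, 5L, 3L))
  expect_equal(cfg$pathways$coarse$kernel, c(7L, 7L, 5L))
  net <- buildClsNet(cfg, seed = 123L)
  st <- hmrpStreams(array(rnorm(96 * 96 * 32), c(96, 96, 32)))
  r <- pathwayForward(net, "coarse", st$coarse)
  expect_length(r$desc, cfg$pathways$coarse$channels[3])
  r2 <- pathwayForward(net, "coarse", st$coarse * 2)
  expect_false(identical(r$desc, r2$desc))
  expect_true(any(r$desc != 0))
})

test_that("fusion weights are a softmax conditioned on context and confidence", {
  cfg <- tinyClsConfig()
  net <- buildClsNet(cfg, seed = 123L)
  st <- hmrpStreams(array(rnorm(96 * 96 * 32), c(96, 96, 32)))
  nm <- c("fine", "medium", "coarse")
  fw <- lapply(nm, function(s) pathwayForward(net, s, st[[s]]))
  fz <- caffFuse(net$params$caff, lapply(fw, `[[`, "map"),
                 lapply(fw, `[[`, "desc"), S = 0.8)
  expect_equal(sum(fz$weights), 1, tolerance = 1e-6)
  expect_true(all(fz$weights > 0))
  expect_length(fz$fused, cfg$fusionWidth)

  # hand-set two-unit transform on two-element descriptors
  caff <- nephrodx:::with_seed(1, nephrodx:::new_caff(c(2L, 2L, 2L),
    nephrodx:::clsNetConfig(fusionWidth = 2L, caffHidden = 2L)))
  caff$mw1$v <- matrix(0.5, 2, 7)
  caff$mb1$v <- c(0.1, -0.1)
  caff$mw2$v <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 3, 2)
  caff$mb2$v <- c(0, 0.2, -0.2)
  descs <- list(c(1, 2), c(0.5, -1), c(0, 0.25))
  maps <- lapply(1:3, function(i) array(rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2)))
  fz2 <- caffFuse(caff, maps, descs, S = 0.4)
  ctx <- c(unlist(descs), 0.4)
  h <- pmax(caff$mw1$v %*% ctx + caff$mb1$v, 0)
  logits <- caff$mw2$v %*% h + caff$mb2$v
  want <- exp(logits - max(logits)); want <- want / sum(want)
  expect_equal(fz2$weights, as.vector(want), tolerance = 1e-6)

  # identical streams + tied per-stream parameters -> uniform weights
  caff$mw2$v <- matrix(0.7, 3, 2)
  caff$mb2$v <- rep(0.1, 3)
  for (s in 2:3) {
    caff$att[[s]]$w$v <- caff$att[[1]]$w$v
    caff$att[[s]]$b$v <- caff$att[[1]]$b$v
    caff$proj[[s]]$w$v <- caff$proj[[1]]$w$v
    caff$proj[[s]]$b$v <- caff$proj[[1]]$b$v
  }
  fz3 <- caffFuse(caff, rep(maps[1], 3), rep(descs[1], 3), S = 0.9)
  expect_equal(fz3$weights, rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("confidence scaling interpolates between the floor and identity", {
  v <- rnorm(8)
  expect_identical(cmfsScale(v, 1), v)
  expect_equal(cmfsScale(v, 0, kappa = 0.5), v / 2)
  n1 <- sqrt(sum(cmfsScale(v, 0.2)^2))
  n2 <- sqrt(sum(cmfsScale(v, 0.7)^2))
  expect_lte(n1, n2)
  expect_error(cmfsScale(v, 1.5), "S must")
})

test_that("the evidential head obeys the Dirichlet arithmetic", {
  net <- buildClsNet(tinyClsConfig(), seed = 123L)
  # zero evidence: zero out the head
  net$params$edl$w$v[] <- 0
  net$params$edl$b$v[] <- -40      # softplus(-40) ~ 0
  pred <- edlHead(net, rnorm(net$cfg$fusionWidth))
  expect_equal(pred@alpha, rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(expectedProbs(pred)), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(uncertainty(pred), 1, tolerance = 1e-9)

  p10 <- DirichletPrediction(c(10, 1, 1, 1))
  expect_equal(unname(expectedProbs(p10)), c(10, 1, 1, 1) / 13)
  expect_equal(uncertainty(p10), 4 / 13)
  expect_equal(evidenceStrength(p10), 13)
  # uncertainty strictly decreases as any evidence grows
  us <- vapply(seq(0, 5, by = 0.5), function(e)
    uncertainty(DirichletPrediction(c(1 + e, 1, 1, 1))), 0)
  expect_true(all(diff(us) < 0))
  expect_error(DirichletPrediction(c(0.5, 1, 1, 1)))
})

test_that("classification is deterministic in evaluation mode", {
  net <- buildClsNet(tinyClsConfig(), seed = 123L)
  patch <- array(rnorm(96 * 96 * 32), c(96, 96, 32))
  a <- clsForward(net, patch, S = 0.6)
  b <- clsForward(net, patch, S = 0.6)
  expect_identical(a@alpha, b@alpha)
  net2 <- buildClsNet(tinyClsConfig(), seed = 123L)
  expect_identical(nephrodx:::params_values(net$params),
                   nephrodx:::params_values(net2$params))
})
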