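# Differentiation tape: every operator's analytic gradient must agree
# with central finite differences on small random problems.

fd_check <- function(build_loss, params, eps = 1e-5, tol = 1e-5, n_probe = 6) {
  nephrodx:::zero_grads(params)
  nephrodx:::tape_start()
  loss <- build_loss()
  nephrodx:::tape_backward(loss)
  nephrodx:::tape_stop()
  for (p in nephrodx:::param_list(params)) {
    idx <- sample(length(p$v), min(n_probe, length(p$v)))
    for (i in idx) {
      v0 <- p$v[i]
      p$v[i] <- v0 + eps
      up <- build_loss()$v
      p$v[i] <- v0 - eps
      dn <- build_loss()$v
      p$v[i] <- v0
      num <- (up - dn) / (2 * eps)
      ana <- if (is.null(p$g)) 0 else p$g[i]
      expect_lt(abs(num - ana), tol * max(1, abs(num)))
    }
  }
}

test_that("convolution, normalization and activation gradients match finite differences", {
  set.seed(101)
  x <- array(rnorm(3 * 6 * 5 * 4), c(3, 6, 5, 4))
  cv1 <- nephrodx:::new_conv(3L, 4L, c(3L, 3L, 3L))          # dense
  cvd <- nephrodx:::new_conv(4L, 4L, c(3L, 3L, 1L), groups = 4L)  # depthwise
  cvs <- nephrodx:::new_conv(4L, 5L, c(2L, 2L, 2L), stride = c(2L, 2L, 2L),
                             pad = c(0L, 0L, 0L))            # strided
  gn <- nephrodx:::new_groupnorm(5L)
  params <- list(cv1, cvd, cvs, gn)
  fd_check(function() {
    h <- nephrodx:::conv_apply(nephrodx:::nd_const(x), cv1)
    h <- nephrodx:::op_gelu(h)
    h <- nephrodx:::conv_apply(h, cvd)
    h <- nephrodx:::op_silu(h)
    h <- nephrodx:::conv_apply(h, cvs)
    h <- nephrodx:::op_groupnorm(h, gn$gamma, gn$beta, 5L)
    h <- nephrodx:::op_sigmoid(h)
    nephrodx:::nd_make(sum(h$v^2), list(h), function(n)
      nephrodx:::acc_grad(h, n$g * 2 * h$v))
  }, params)
})

test_that("dilated convolution matches the direct-convolution oracle", {
  set.seed(5)
  x <- array(rnorm(2 * 8 * 7 * 6), c(2, 8, 7, 6))
  w <- array(rnorm(3 * 2 * 27), c(3, 2, 3, 3, 3))
  b <- rnorm(3)
  for (dil in list(c(1, 1, 1), c(2, 2, 1), c(3, 2, 2))) {
    got <- nephrodx:::conv3d_fwd_cpp(x, w, b, c(1L, 1L, 1L), as.integer(dil),
                                     as.integer(dil), 1L)
    want <- oracle_conv3d(x, w, b, dil = dil, pad = dil)
    expect_equal(dim(got), dim(want))
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("attention, pooling, resize and fusion gradients match finite differences", {
  set.seed(102)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  g <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  gate <- nephrodx:::with_seed(1, list(wg = nephrodx:::new_conv(4L, 3L),
                                       wx = nephrodx:::new_conv(4L, 3L),
                                       psi = nephrodx:::new_conv(3L, 1L)))
  ls <- nephrodx:::nx_param(rnorm(4) * 0.1)
  lin <- nephrodx:::with_seed(2, list(
    w = nephrodx:::nx_param(matrix(rnorm(3 * 4), 3, 4)),
    b = nephrodx:::nx_param(rnorm(3))))
  params <- list(gate, ls, lin)
  fd_check(function() {
    xn <- nephrodx:::nd_const(x)
    gn_ <- nephrodx:::nd_const(g)
    at <- nephrodx:::att_node(gn_, xn, gate)$gated
    at <- nephrodx:::op_scale_ch(at, ls)
    up <- nephrodx:::op_resize3d(at, c(6L, 6L, 3L))
    cc <- nephrodx:::op_concat_ch(list(up, up))
    d <- nephrodx:::op_gap(cc)
    sl <- nephrodx:::nd_make(d$v[1:4], list(d), function(n) {
      gfull <- numeric(8)
      gfull[1:4] <- n$g
      nephrodx:::acc_grad(d, gfull)
    })
    d2 <- nephrodx:::op_softplus(nephrodx:::op_linear(sl, lin$w, lin$b))
    sm <- nephrodx:::op_softmax_vec(d2)
    nephrodx:::nd_make(sum(sm$v * c(0.2, 0.5, 0.3)), list(sm), function(n)
      nephrodx:::acc_grad(sm, n$g * c(0.2, 0.5, 0.3)))
  }, params)
})

test_that("segmentation loss gradient matches finite differences", {
  set.seed(103)
  dims <- c(5, 5, 3)
  y <- random_onehot(5, dims)
  w <- segLossWeights()
  sdt <- nephrodx:::sdt_per_class(y, sigma = w$sdtSigma)
  logits <- nephrodx:::nx_param(array(rnorm(5 * prod(dims)), c(5, dims)))
  fd_check(function() {
    p <- nephrodx:::op_softmax_ch(logits)
    nephrodx:::op_seg_loss(p, y, w, sdt)
  }, list(logits), tol = 1e-4)
})

test_that("classification loss gradient matches finite differences", {
  set.seed(104)
  raw <- nephrodx:::nx_param(rnorm(4))
  lam <- c(0.3, 0.3, 0.2, 0.2)
  fd_check(function() {
    e <- nephrodx:::op_softplus(raw)
    a <- nephrodx:::nd_make(e$v + 1, list(e), function(n)
      nephrodx:::acc_grad(e, n$g))
    nephrodx:::op_cls_loss(a, 2L, 0.7, lam)
  }, list(raw), tol = 1e-5)
})

test_that("whole networks have exact gradients and no dead parameters", {
  set.seed(105)
  cfg <- segNetConfig(encoderChannels = c(4L, 8L), asppRates = c(1L, 2L),
                      expansion = 2L, dropoutRate = 0)
  net <- buildSegNet(cfg, seed = 9L)
  img <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  y <- random_onehot(5, c(8, 8, 8))
  w <- segLossWeights()
  sdt <- nephrodx:::sdt_per_class(y, sigma = w$sdtSigma)
  build <- function() {
    out <- nephrodx:::seg_forward_nodes(net, img, mode = "eval")
    nephrodx:::op_seg_loss(out$probs, y, w, sdt)
  }
  fd_check(build, net$params, tol = 2e-4, n_probe = 2)
  # gradient flow: every parameter tensor receives some gradient
  nephrodx:::zero_grads(net$params)
  nephrodx:::tape_start()
  nephrodx:::tape_backward(build())
  nephrodx:::tape_stop()
  norms <- vapply(nephrodx:::param_list(net$params), function(p)
    if (is.null(p$g)) 0 else sqrt(sum(p$g^2)), 0)
  expect_true(all(norms > 0))
})
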