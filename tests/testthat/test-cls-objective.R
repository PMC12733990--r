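# Evidential classification objective: digamma closed forms vs sampling
# oracles, Dirichlet KL vs quadrature, confidence alignment and the
# temperature-softmax adaptive weights.

test_that("expected cross-entropy matches digamma arithmetic and its limits", {
  expect_equal(edlLoss(DirichletPrediction(c(1, 1, 1, 1)), 1),
               digamma(4) - digamma(1), tolerance = 1e-12)
  expect_equal(digamma(4) - digamma(1), 1.8333, tolerance = 1e-3)
  # strictly decreasing in the true class's evidence
  ls <- vapply(seq(1, 50, by = 2), function(a)
    edlLoss(c(a, 1, 1, 1), 1), 0)
  expect_true(all(diff(ls) < 0))
  # vanishing in the strong-evidence limit
  expect_lt(edlLoss(c(1e7, 1, 1, 1), 1), 1e-5)
  expect_error(edlLoss(c(0.2, 1, 1, 1), 1), ">= 1")
})

test_that("expected cross-entropy matches a Monte Carlo oracle within 3 SE", {
  set.seed(11)
  for (rep in 1:10) {
    a <- 1 + rexp(4, 1 / 3)
    label <- sample.int(4, 1)
    n <- 1e5
    g <- matrix(rgamma(4 * n, shape = rep(a, each = n)), n, 4)
    p <- g / rowSums(g)
    draws <- -log(p[, label])
    mc <- mean(draws)
    se <- sd(draws) / sqrt(n)
    expect_lt(abs(edlLoss(a, label) - mc), 3 * se)
  }
})

test_that("misleading-evidence KL has its exact zeros", {
  expect_identical(klUniform(c(1, 1, 1, 1), 1), 0)
  # evidence only on the true class is removed before the KL
  expect_equal(klUniform(c(2, 1, 1, 1), 1), 0, tolerance = 1e-12)
  expect_gt(klUniform(c(1, 2, 1, 1), 1), 0)
})

test_that("Dirichlet KL matches quadrature on the two-class reduction", {
  # K = 2: Dir(a, b) is Beta(a, b); integrate the KL density directly
  kl2 <- function(a, b) {
    f <- function(x) dbeta(x, a, b) * (dbeta(x, a, b, log = TRUE) -
                                       dbeta(x, 1, 1, log = TRUE))
    integrate(f, 0, 1, rel.tol = 1e-10)$value
  }
  for (ab in list(c(2, 1), c(1.5, 3), c(4, 2.5))) {
    closed <- nephrodx:::dirichlet_kl_uniform(ab)
    expect_equal(closed, kl2(ab[1], ab[2]), tolerance = 1e-6)
  }
})

test_that("K = 4 KL matches a sampling oracle", {
  set.seed(12)
  a <- c(1, 2.5, 1.2, 3)
  n <- 2e5
  g <- matrix(rgamma(4 * n, shape = rep(a, each = n)), n, 4)
  p <- g / rowSums(g)
  ldir <- function(p, al) lgamma(sum(al)) - sum(lgamma(al)) +
    colSums((al - 1) * log(t(p)))
  draws <- ldir(p, a) - ldir(p, rep(1, 4))
  expect_lt(abs(nephrodx:::dirichlet_kl_uniform(a) - mean(draws)),
            3 * sd(draws) / sqrt(n) + 1e-4)
})

test_that("confidence alignment is the squared mismatch of u and 1 - S", {
  pr <- DirichletPrediction(c(2, 2, 2, 2))   # u = 0.5
  expect_equal(confidenceLoss(pr, 0.5), 0)
  expect_equal(confidenceLoss(DirichletPrediction(c(1, 1, 1, 1)), 1), 1)
  set.seed(3)
  for (i in 1:20) {
    a <- 1 + rexp(4)
    S <- runif(1)
    v <- confidenceLoss(a, S)
    expect_true(v >= 0 && v <= 1)
  }
  expect_error(confidenceLoss(pr, 1.2), "S must")
})

test_that("adaptive weights follow the temperature softmax of progress", {
  st <- adaptiveWeightState()
  expect_equal(st$lambda, rep(0.25, 4))
  st2 <- adaptiveWeightState(z = c(2, 0, 0, 0), tau = 2)
  expect_equal(st2$lambda[1], exp(1) / (exp(1) + 3), tolerance = 1e-10)
  expect_equal(st2$lambda[1], 0.4754, tolerance = 1e-4)
  expect_equal(sum(st2$lambda), 1, tolerance = 1e-12)
  expect_true(all(st2$lambda > 0))
  # invariance to adding a constant to all z
  st3 <- adaptiveWeightState(z = c(2, 0, 0, 0) + 7, tau = 2)
  expect_equal(st3$lambda, st2$lambda, tolerance = 1e-12)
  expect_error(adaptiveWeightState(tau = 0), "tau")
})

test_that("adaptive updates are EMAs of relative one-epoch improvements", {
  st <- adaptiveWeightState()
  hist <- rbind(c(1, 1, 1, 1))
  st <- adaptiveWeights(hist, st)
  expect_equal(st$z, rep(0, 4))         # single epoch: unchanged
  hist <- rbind(hist, c(0.5, 1, 1.5, 1))
  st <- adaptiveWeights(hist, st)
  want <- 0.9 * 0 + 0.1 * c(0.5, 0, -0.5, 0) / (1 + 1e-8)
  expect_equal(st$z, want, tolerance = 1e-6)
})

test_that("the compound loss reduces, recombines and stays nonnegative", {
  a <- c(3, 1.5, 1, 2)
  st <- adaptiveWeightState(z = c(100, 0, 0, 0), tau = 0.1)  # ~ pure CE
  r <- compoundClsLoss(a, 2, 0.8, st)
  expect_equal(r$total, -log(a[2] / sum(a)), tolerance = 1e-6)
  st2 <- adaptiveWeightState()
  r2 <- compoundClsLoss(a, 2, 0.8, st2)
  expect_equal(unname(sum(st2$lambda * r2$terms)), r2$total, tolerance = 1e-7)
  expect_gte(r2$total, 0)
})
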