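# Multi-objective classification loss over evidential Dirichlet outputs:
# cross-entropy on the expected probabilities, the digamma expected
# cross-entropy under the Dirichlet, a KL regularizer that shrinks
# misleading evidence toward the uniform prior, and a confidence-alignment
# term coupling evidential uncertainty to segmentation quality.  The four
# terms are combined with temperature-softmax adaptive weights driven by
# per-term learning progress.

#' Expected cross-entropy under a Dirichlet prediction
#'
#' `E_Dir(alpha)[-log p_y] = digamma(sum(alpha)) - digamma(alpha_y)`.
#'
#' @param pred a [DirichletPrediction-class] (or bare alpha vector).
#' @param label class index in 1..4 (normal, cyst, tumor, stone).
#' @return Scalar loss.
#' @export
edlLoss <- function(pred, label) {
  a <- if (is(pred, "DirichletPrediction")) pred@alpha else pred
  if (any(a < 1 - 1e-9)) nx_stop("concentrations must be >= 1")
  digamma(sum(a)) - digamma(a[label])
}

# closed-form KL( Dir(a) || Dir(1,...,1) )
dirichlet_kl_uniform <- function(a) {
  K <- length(a)
  S <- sum(a)
  lgamma(S) - sum(lgamma(a)) - lgamma(K) +
    sum((a - 1) * (digamma(a) - digamma(S)))
}

#' KL divergence of the misleading evidence from the uniform Dirichlet
#'
#' The true class's concentration is reset to 1 (`alpha_tilde = y +
#' (1 - y) * alpha`), and `KL(Dir(alpha_tilde) || Dir(1))` penalizes
#' evidence placed on the wrong classes.
#'
#' @inheritParams edlLoss
#' @return Scalar >= 0.
#' @export
klUniform <- function(pred, label) {
  a <- if (is(pred, "DirichletPrediction")) pred@alpha else pred
  at <- a
  at[label] <- 1
  dirichlet_kl_uniform(at)
}

#' Confidence-alignment loss
#'
#' `(u - (1 - S))^2`: evidential uncertainty should be high exactly when
#' segmentation confidence is low.
#'
#' @inheritParams edlLoss
#' @param S segmentation confidence in [0, 1].
#' @return Scalar in [0, 1].
#' @export
confidenceLoss <- function(pred, S) {
  if (!is.finite(S) || S < 0 || S > 1) nx_stop("S must lie in [0, 1]")
  a <- if (is(pred, "DirichletPrediction")) pred@alpha else pred
  u <- length(a) / sum(a)
  (u - (1 - S))^2
}

#' Adaptive loss-weight state
#'
#' @param z initial per-term progress statistics (length 4).
#' @param tau softmax temperature (default 2).
#' @param momentum EMA momentum of the progress statistic (default 0.9).
#' @return A list of class `nx_adaptive_weights` with fields `z`,
#'   `lambda`, `tau`, `momentum`.
#' @export
adaptiveWeightState <- function(z = rep(0, 4), tau = 2.0, momentum = 0.9) {
  if (tau <= 0) nx_stop("tau must be positive")
  lam <- exp(z / tau - max(z / tau))
  structure(list(z = z, lambda = lam / sum(lam), tau = tau,
                 momentum = momentum),
            class = "nx_adaptive_weights")
}

#' Update adaptive weights from per-term loss history
#'
#' Each term's progress statistic is an exponential moving average
#' (momentum 0.9) of its relative one-epoch improvement
#' `(L_prev - L_cur) / (|L_prev| + 1e-8)`; the weights are
#' `softmax(z / tau)`.  With a single recorded epoch the statistics are
#' unchanged and the weights stay uniform.
#'
#' @param lossHistory numeric matrix (epochs x 4) of per-term losses, or a
#'   vector for a single epoch.
#' @param state an [adaptiveWeightState()].
#' @return The updated state.
#' @export
adaptiveWeights <- function(lossHistory, state = adaptiveWeightState()) {
  h <- rbind(lossHistory)
  if (nrow(h) >= 2) {
    prev <- h[nrow(h) - 1, ]
    cur <- h[nrow(h), ]
    delta <- (prev - cur) / (abs(prev) + 1e-8)
    state$z <- state$momentum * state$z + (1 - state$momentum) * delta
  }
  zs <- state$z / state$tau
  lam <- exp(zs - max(zs))
  state$lambda <- lam / sum(lam)
  state
}

# value + gradient (w.r.t. alpha) of the compound classification loss
cls_loss_valgrad <- function(a, label, S, lambda, want_grad = TRUE) {
  K <- length(a)
  Sa <- sum(a)
  y <- as.numeric(seq_len(K) == label)

  p <- a / Sa
  ce <- -log(max(p[label], P_CLAMP))
  edl <- digamma(Sa) - digamma(a[label])
  at <- a
  at[label] <- 1
  kl <- dirichlet_kl_uniform(at)
  u <- K / Sa
  conf <- (u - (1 - S))^2

  terms <- c(ce = ce, edl = edl, kl = kl, conf = conf)
  total <- sum(lambda * terms)
  if (!want_grad) return(list(total = total, terms = terms))

  g_ce <- rep(1 / Sa, K) - y / a[label]
  g_edl <- rep(trigamma(Sa), K) - y * trigamma(a[label])
  St <- sum(at)
  g_kl <- ((at - 1) * trigamma(at) - (St - K) * trigamma(St)) * (1 - y)
  g_conf <- rep(2 * (u - (1 - S)) * (-K / Sa^2), K)
  grad <- lambda[1] * g_ce + lambda[2] * g_edl + lambda[3] * g_kl +
    lambda[4] * g_conf
  list(total = total, terms = terms, grad = grad)
}

#' Compound classification loss
#'
#' `L = lambda_1 CE + lambda_2 EDL + lambda_3 KL + lambda_4 Conf`, with
#' CE computed on the expected probabilities `alpha / sum(alpha)`.
#'
#' @inheritParams edlLoss
#' @param S segmentation confidence in [0, 1].
#' @param weights an [adaptiveWeightState()] (its `lambda` is used).
#' @return `list(total =, terms =)` with the unweighted per-term values.
#' @export
compoundClsLoss <- function(pred, label, S, weights = adaptiveWeightState()) {
  a <- if (is(pred, "DirichletPrediction")) pred@alpha else pred
  cls_loss_valgrad(a, label, S, weights$lambda, want_grad = FALSE)
}

# tape node version operating on an alpha node
op_cls_loss <- function(anode, label, S, lambda) {
  r <- cls_loss_valgrad(anode$v, label, S, lambda, want_grad = TRUE)
  node <- nd_make(r$total, list(anode), function(node)
    acc_grad(anode, node$g * r$grad))
  node$terms <- r$terms
  node
}
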