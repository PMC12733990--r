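# Minimal reverse-mode differentiation tape.
#
# A node is an environment with fields `v` (value: array, vector or scalar),
# `g` (accumulated gradient, NULL until backward touches it), and — when
# recorded on the active tape — `parents` and `bw`, a closure that propagates
# the node's gradient into its parents.  Parameters are persistent leaf nodes
# that also carry AdamW state.  Recording is switched on only inside
# training steps; inference runs the same ops without building a graph.

tape_start <- function() {
  .nx$recording <- TRUE
  .nx$tape <- new.env(parent = emptyenv())
  .nx$tape$nodes <- vector("list", 256L)
  .nx$tape$n <- 0L
  invisible(NULL)
}

tape_stop <- function() {
  .nx$recording <- FALSE
  .nx$tape <- NULL
  invisible(NULL)
}

tape_record <- function(node) {
  tp <- .nx$tape
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- node
  tp$n <- n
  invisible(node)
}

# Create a node.  `bw` is function(node) reading node$g and accumulating
# into parents via acc_grad().
nd_make <- function(v, parents = NULL, bw = NULL) {
  node <- new.env(parent = emptyenv())
  node$v <- v
  node$g <- NULL
  if (isTRUE(.nx$recording) && !is.null(bw)) {
    node$parents <- parents
    node$bw <- bw
    tape_record(node)
  }
  node
}

nd_const <- function(v) nd_make(v)

acc_grad <- function(node, g) {
  if (is.null(node$g)) node$g <- g else node$g <- node$g + g
  invisible(NULL)
}

# Run backward from a scalar loss node over the active tape.
tape_backward <- function(loss) {
  loss$g <- 1
  tp <- .nx$tape
  if (tp$n > 0L) for (i in tp$n:1L) {
    node <- tp$nodes[[i]]
    if (!is.null(node$bw) && !is.null(node$g)) node$bw(node)
  }
  invisible(NULL)
}

# ---- parameters -----------------------------------------------------------

nx_param <- function(v) {
  p <- new.env(parent = emptyenv())
  p$v <- v
  p$g <- NULL
  p$m1 <- NULL
  p$m2 <- NULL
  p
}

param_list <- function(x, out = list()) {
  if (is.environment(x)) return(c(out, list(x)))
  if (is.list(x)) for (el in x) out <- param_list(el, out)
  out
}

zero_grads <- function(params) {
  for (p in param_list(params)) p$g <- NULL
  invisible(NULL)
}

n_params <- function(params) sum(vapply(param_list(params), function(p) length(p$v), 0))

# ---- elementwise ops ------------------------------------------------------

op_add <- function(a, b) {
  nd_make(a$v + b$v, list(a, b), function(node) {
    acc_grad(a, node$g)
    acc_grad(b, node$g)
  })
}

op_mul <- function(a, b) {
  nd_make(a$v * b$v, list(a, b), function(node) {
    acc_grad(a, node$g * b$v)
    acc_grad(b, node$g * a$v)
  })
}

op_scalar_mul <- function(a, s) {
  nd_make(a$v * s, list(a), function(node) acc_grad(a, node$g * s))
}

op_relu <- function(a) {
  m <- a$v > 0
  nd_make(a$v * m, list(a), function(node) acc_grad(a, node$g * m))
}

op_gelu <- function(a) {
  r <- act_cpp(a$v, 0L)
  nd_make(r$y, list(a), function(node) acc_grad(a, node$g * r$d))
}

op_silu <- function(a) {
  r <- act_cpp(a$v, 1L)
  nd_make(r$y, list(a), function(node) acc_grad(a, node$g * r$d))
}

op_sigmoid <- function(a) {
  r <- act_cpp(a$v, 2L)
  nd_make(r$y, list(a), function(node) acc_grad(a, node$g * r$d))
}

op_softplus <- function(a) {
  # numerically stable log(1 + exp(x))
  v <- a$v
  small <- v <= 30
  v[small] <- log1p(exp(v[small]))
  s <- 1 / (1 + exp(-a$v))
  nd_make(v, list(a), function(node) acc_grad(a, node$g * s))
}

op_dropout <- function(a, rate, active) {
  if (!active || rate <= 0) return(a)
  keep <- (runif(length(a$v)) >= rate) / (1 - rate)
  if (!is.null(dim(a$v))) keep <- array(keep, dim(a$v))
  nd_make(a$v * keep, list(a), function(node) acc_grad(a, node$g * keep))
}

# ---- feature-map ops (arrays with dim (C, X, Y, Z)) -----------------------

op_conv3d <- function(x, w, b, stride = c(1L, 1L, 1L), dil = c(1L, 1L, 1L),
                      pad = c(0L, 0L, 0L), groups = 1L) {
  v <- conv3d_fwd_cpp(x$v, w$v, b$v, as.integer(stride), as.integer(dil),
                      as.integer(pad), as.integer(groups))
  nd_make(v, list(x, w, b), function(node) {
    r <- conv3d_bwd_cpp(x$v, w$v, node$g, as.integer(stride), as.integer(dil),
                        as.integer(pad), as.integer(groups))
    acc_grad(x, r$gx)
    acc_grad(w, r$gw)
    acc_grad(b, r$gb)
  })
}

# per-channel scaling of a (C, ...) map by a length-C vector (LayerScale)
op_scale_ch <- function(x, gamma) {
  C <- dim(x$v)[1]
  v <- x$v * as.vector(gamma$v)  # recycles along the fastest (channel) axis
  nd_make(v, list(x, gamma), function(node) {
    acc_grad(x, node$g * as.vector(gamma$v))
    acc_grad(gamma, rowSums(matrix(node$g * x$v, nrow = C)))
  })
}

# multiply a (C, X, Y, Z) map by a single-channel (1, X, Y, Z) gate
op_gate <- function(x, gate) {
  d <- dim(x$v)
  C <- d[1]
  gfull <- array(rep(gate$v, each = C), d)
  nd_make(x$v * gfull, list(x, gate), function(node) {
    acc_grad(x, node$g * gfull)
    gg <- colSums(matrix(node$g * x$v, nrow = C))
    acc_grad(gate, array(gg, dim(gate$v)))
  })
}

op_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  r <- gn_fwd_cpp(x$v, gamma$v, beta$v, as.integer(groups), eps)
  nd_make(r$y, list(x, gamma, beta), function(node) {
    b <- gn_bwd_cpp(node$g, r$xhat, gamma$v, r$sg, as.integer(groups))
    acc_grad(x, b$gx)
    acc_grad(gamma, b$ggamma)
    acc_grad(beta, b$gbeta)
  })
}

op_softmax_ch <- function(x) {
  d <- dim(x$v)
  C <- d[1]
  m <- matrix(x$v, nrow = C)
  mx <- m[1, ]
  if (C > 1) for (c in 2:C) mx <- pmax(mx, m[c, ])
  e <- exp(m - rep(mx, each = C))
  p <- e / rep(colSums(e), each = C)
  v <- array(p, d)
  nd_make(v, list(x), function(node) {
    gm <- matrix(node$g, nrow = C)
    dot <- colSums(gm * p)
    acc_grad(x, array(p * (gm - rep(dot, each = C)), d))
  })
}

# global average pooling (C, X, Y, Z) -> length-C vector
op_gap <- function(x) {
  d <- dim(x$v)
  C <- d[1]
  N <- prod(d[-1])
  v <- rowMeans(matrix(x$v, nrow = C))
  nd_make(v, list(x), function(node)
    acc_grad(x, array(rep(node$g / N, N), d)))
}

# broadcast a length-C vector over a spatial grid -> (C, dims)
op_broadcast <- function(x, sdim) {
  C <- length(x$v)
  N <- prod(sdim)
  v <- array(rep(x$v, N), c(C, sdim))
  nd_make(v, list(x), function(node)
    acc_grad(x, rowSums(matrix(node$g, nrow = C))))
}

op_concat_ch <- function(nodes) {
  Cs <- vapply(nodes, function(n) dim(n$v)[1], 0L)
  d1 <- dim(nodes[[1]]$v)
  v <- array(0, c(sum(Cs), d1[-1]))
  at <- 0L
  for (i in seq_along(nodes)) {
    v[at + seq_len(Cs[i]), , , ] <- nodes[[i]]$v
    at <- at + Cs[i]
  }
  nd_make(v, nodes, function(node) {
    at <- 0L
    for (i in seq_along(nodes)) {
      acc_grad(nodes[[i]], node$g[at + seq_len(Cs[i]), , , , drop = FALSE])
      at <- at + Cs[i]
    }
  })
}

op_resize3d <- function(x, odim) {
  idim <- dim(x$v)[-1]
  if (all(idim == odim)) return(x)
  v <- resize3d_fwd_cpp(x$v, as.integer(odim))
  nd_make(v, list(x), function(node)
    acc_grad(x, resize3d_bwd_cpp(node$g, as.integer(idim))))
}

# ---- vector ops -----------------------------------------------------------

op_linear <- function(x, W, b) {
  v <- as.vector(W$v %*% x$v) + b$v
  nd_make(v, list(x, W, b), function(node) {
    acc_grad(x, as.vector(crossprod(W$v, node$g)))
    acc_grad(W, node$g %*% t(x$v))
    acc_grad(b, node$g)
  })
}

op_concat_vec <- function(nodes) {
  ls <- vapply(nodes, function(n) length(n$v), 0L)
  v <- unlist(lapply(nodes, function(n) n$v), use.names = FALSE)
  nd_make(v, nodes, function(node) {
    at <- 0L
    for (i in seq_along(nodes)) {
      acc_grad(nodes[[i]], node$g[at + seq_len(ls[i])])
      at <- at + ls[i]
    }
  })
}

op_softmax_vec <- function(x) {
  e <- exp(x$v - max(x$v))
  p <- e / sum(e)
  nd_make(p, list(x), function(node)
    acc_grad(x, p * (node$g - sum(node$g * p))))
}

# fused = sum_i w[i] * vec_i  with both the weights and the vectors nodes
op_weighted_sum <- function(vecs, w) {
  v <- 0
  for (i in seq_along(vecs)) v <- v + w$v[i] * vecs[[i]]$v
  nd_make(v, c(vecs, list(w)), function(node) {
    gw <- numeric(length(vecs))
    for (i in seq_along(vecs)) {
      acc_grad(vecs[[i]], node$g * w$v[i])
      gw[i] <- sum(node$g * vecs[[i]]$v)
    }
    acc_grad(w, gw)
  })
}

# mean of scalar loss nodes (batch averaging)
op_mean_scalar <- function(nodes) {
  n <- length(nodes)
  v <- mean(vapply(nodes, function(x) x$v, 0))
  nd_make(v, nodes, function(node)
    for (p in nodes) acc_grad(p, node$g / n))
}

# ---- optimizer ------------------------------------------------------------

# AdamW step over a parameter tree; `lr` per call, decoupled weight decay.
adamw_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01, step, clip_norm = 1) {
  ps <- param_list(params)
  if (!is.null(clip_norm) && clip_norm > 0) {
    tot <- 0
    for (p in ps) if (!is.null(p$g)) tot <- tot + sum(p$g^2)
    gn <- sqrt(tot)
    if (is.finite(gn) && gn > clip_norm) {
      sc <- clip_norm / gn
      for (p in ps) if (!is.null(p$g)) p$g <- p$g * sc
    }
  }
  b1c <- 1 - beta1^step
  b2c <- 1 - beta2^step
  for (p in ps) {
    if (is.null(p$g)) next
    if (is.null(p$m1)) {
      p$m1 <- p$g * 0
      p$m2 <- p$g * 0
    }
    p$m1 <- beta1 * p$m1 + (1 - beta1) * p$g
    p$m2 <- beta2 * p$m2 + (1 - beta2) * p$g^2
    upd <- (p$m1 / b1c) / (sqrt(p$m2 / b2c) + eps)
    p$v <- p$v - lr * upd - lr * weight_decay * p$v
  }
  invisible(NULL)
}

grad_global_norm <- function(params) {
  tot <- 0
  for (p in param_list(params)) if (!is.null(p$g)) tot <- tot + sum(p$g^2)
  sqrt(tot)
}
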