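# Stage-one segmentation network: a 3D U-Net-style encoder-decoder whose
# levels are large-kernel depthwise-separable residual blocks (inverted
# bottleneck, GELU, LayerScale residual), with an atrous spatial pyramid
# pooling bottleneck and additive spatial attention gates on the skip
# connections.  Output is a 5-class voxel softmax.

#' Segmentation network configuration
#'
#' @param encoderChannels widths per encoder level (the last entry is the
#'   bottleneck width); the default is the full desk-scale setting, use
#'   [tinySegConfig()] for CPU training experiments.
#' @param nClasses number of output classes (background, kidney, cyst,
#'   tumor, stone).
#' @param asppRates dilation rates of the pyramid branches.
#' @param dropoutRate decoder dropout used for Monte Carlo confidence
#'   sampling.
#' @param dwKernel depthwise kernel (in-plane, in-plane, through-plane);
#'   the anisotropic 7 x 7 x 3 default matches thick-slice CT geometry.
#' @param expansion inverted-bottleneck expansion ratio.
#' @param layerscaleInit initial residual scale (near zero for stable deep
#'   training).
#' @return A list of class `nx_seg_config`.
#' @export
segNetConfig <- function(encoderChannels = c(32L, 64L, 128L, 256L),
                         nClasses = 5L, asppRates = c(1L, 3L, 6L),
                         dropoutRate = 0.1, dwKernel = c(7L, 7L, 3L),
                         expansion = 4L, layerscaleInit = 1e-6) {
  stopifnot(length(encoderChannels) >= 2, nClasses == 5L, expansion >= 1)
  structure(list(encoderChannels = as.integer(encoderChannels),
                 nClasses = as.integer(nClasses),
                 asppRates = as.integer(asppRates), dropoutRate = dropoutRate,
                 dwKernel = as.integer(dwKernel), expansion = as.integer(expansion),
                 layerscaleInit = layerscaleInit),
            class = "nx_seg_config")
}

#' Desk-scale segmentation configuration (CPU-trainable, < 0.5 M parameters)
#' @param ... overrides passed to [segNetConfig()].
#' @export
tinySegConfig <- function(...) {
  args <- list(encoderChannels = c(8L, 16L, 32L), asppRates = c(1L, 2L, 3L),
               expansion = 4L)
  do.call(segNetConfig, utils::modifyList(args, list(...)))
}

# ---- parameter constructors (must be called inside with_seed) -------------

he_normal <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

xavier_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

# A convolution layer: depthwise kernels get He normal initialization
# (variance-preserving under GELU-family activations), pointwise 1x1x1
# mixing convolutions Xavier uniform, dense spatial convolutions He normal.
new_conv <- function(cin, cout, k = c(1L, 1L, 1L), stride = c(1L, 1L, 1L),
                     dil = c(1L, 1L, 1L), pad = (k - 1) %/% 2 * dil,
                     groups = 1L) {
  cg <- cin %/% groups
  dims <- c(cout, cg, k)
  fan_in <- cg * prod(k)
  fan_out <- (cout %/% groups) * prod(k)
  w <- if (groups > 1) he_normal(dims, fan_in)
  else if (all(k == 1L)) xavier_uniform(dims, fan_in, fan_out)
  else he_normal(dims, fan_in)
  list(w = nx_param(w), b = nx_param(numeric(cout)),
       stride = as.integer(stride), dil = as.integer(dil),
       pad = as.integer(pad), groups = as.integer(groups))
}

conv_apply <- function(x, cv, dil = NULL, pad = NULL)
  op_conv3d(x, cv$w, cv$b, cv$stride, dil %||% cv$dil, pad %||% cv$pad, cv$groups)

new_groupnorm <- function(channels) {
  g <- min(8L, channels)
  while (channels %% g != 0) g <- g - 1L  # groups must tile the channels
  list(gamma = nx_param(rep(1, channels)), beta = nx_param(numeric(channels)),
       groups = g)
}

gn_apply <- function(x, gn) op_groupnorm(x, gn$gamma, gn$beta, gn$groups)

#' Create an enhanced residual convolution block
#'
#' Depthwise large-kernel convolution, group normalization, pointwise
#' expansion, GELU, pointwise projection, and a LayerScale-weighted
#' residual: `ECB(x) = x + gamma * PW(GELU(PW(GN(DW(x)))))`.
#'
#' @param channels feature width.
#' @param dwKernel depthwise kernel size (odd per axis).
#' @param expansion inverted-bottleneck ratio.
#' @param layerscaleInit initial per-channel residual scale.
#' @param seed optional seed; when given the block is built reproducibly.
#' @return Parameter list for [ecbForward()].
#' @export
makeEcbBlock <- function(channels, dwKernel = c(7L, 7L, 3L), expansion = 4L,
                         layerscaleInit = 1e-6, seed = NULL) {
  build <- function() new_ecb(channels, dwKernel, expansion, layerscaleInit)
  if (is.null(seed)) build() else with_seed(seed, build())
}

new_ecb <- function(channels, dwKernel, expansion, layerscaleInit) {
  mid <- channels * expansion
  list(dw = new_conv(channels, channels, dwKernel, groups = channels),
       gn = new_groupnorm(channels),
       pw1 = new_conv(channels, mid),
       pw2 = new_conv(mid, channels),
       ls = nx_param(rep(layerscaleInit, channels)),
       channels = channels)
}

ecb_node <- function(x, blk) {
  if (dim(x$v)[1] != blk$channels)
    nx_stop("block expects ", blk$channels, " channels, got ", dim(x$v)[1])
  h <- conv_apply(x, blk$dw)
  h <- gn_apply(h, blk$gn)
  h <- conv_apply(h, blk$pw1)
  h <- op_gelu(h)
  h <- conv_apply(h, blk$pw2)
  op_add(x, op_scale_ch(h, blk$ls))
}

#' Apply an enhanced convolution block to a feature array
#' @param blk block from [makeEcbBlock()].
#' @param x numeric array (C, X, Y, Z).
#' @return Array of the same shape.
#' @export
ecbForward <- function(blk, x) ecb_node(nd_const(x), blk)$v

# ---- attention gate -------------------------------------------------------

#' Create an additive spatial attention gate
#'
#' `alpha = sigmoid(psi^T ReLU(Wg g + Wx x + b))`, applied multiplicatively
#' to the skip features.
#'
#' @param channels width of both the gating signal and the skip features.
#' @param inter intermediate width (default `max(4, channels / 2)`).
#' @param seed optional reproducibility seed.
#' @return Parameter list for [attentionGate()].
#' @export
makeAttentionGate <- function(channels, inter = NULL, seed = NULL) {
  inter <- as.integer(inter %||% max(4L, channels %/% 2L))
  build <- function() list(
    wg = new_conv(channels, inter),
    wx = new_conv(channels, inter),
    psi = new_conv(inter, 1L))
  if (is.null(seed)) build() else with_seed(seed, build())
}

att_node <- function(g, x, gate) {
  if (!identical(dim(g$v)[-1], dim(x$v)[-1]))
    nx_stop("attention gate: gating and skip grids are not aligned")
  a <- op_add(conv_apply(g, gate$wg), conv_apply(x, gate$wx))
  a <- op_relu(a)
  a <- op_sigmoid(conv_apply(a, gate$psi))
  list(gated = op_gate(x, a), alpha = a)
}

#' Apply an attention gate to arrays
#' @param gate parameters from [makeAttentionGate()].
#' @param g decoder gating feature array (C, X, Y, Z).
#' @param x encoder skip feature array, spatially aligned with `g`.
#' @return `list(gated =, alpha =)` arrays; `alpha` is in (0, 1).
#' @export
attentionGate <- function(gate, g, x) {
  r <- att_node(nd_const(g), nd_const(x), gate)
  list(gated = r$gated$v, alpha = r$alpha$v)
}

# ---- ASPP -----------------------------------------------------------------

new_aspp <- function(channels, rates) {
  brs <- lapply(rates, function(r) new_conv(channels, channels, c(3L, 3L, 3L)))
  list(branches = brs, rates = as.integer(rates),
       fuse = new_conv(channels * (length(rates) + 1L), channels),
       channels = channels)
}

aspp_node <- function(x, aspp) {
  sdim <- dim(x$v)[-1]
  if (any(sdim < 3))
    nx_stop("ASPP needs every spatial dimension >= 3 at the bottleneck")
  outs <- list(op_broadcast(op_gap(x), sdim))
  for (i in seq_along(aspp$branches)) {
    r <- aspp$rates[i]
    # cap the dilation per axis so the kernel span fits the grid
    de <- pmin(r, pmax(1L, as.integer((sdim - 1) %/% 2)))
    outs[[i + 1]] <- conv_apply(x, aspp$branches[[i]], dil = de, pad = de)
  }
  conv_apply(op_concat_ch(outs), aspp$fuse)
}

#' Multi-scale pyramid pooling over a feature array
#' @param aspp parameters from the network builder.
#' @param x numeric array (C, X, Y, Z).
#' @return Fused array of the same shape (no resolution loss).
#' @export
asppForward <- function(aspp, x) aspp_node(nd_const(x), aspp)$v

# ---- full network ---------------------------------------------------------

#' Build the segmentation network
#'
#' All parameters are drawn inside a single seeded stream, so two builds
#' with the same configuration and seed are identical.
#'
#' @param cfg a [segNetConfig()].
#' @param seed model initialization seed (default 123).
#' @return A list with `cfg` and the parameter tree `params`.
#' @export
buildSegNet <- function(cfg = segNetConfig(), seed = 123L) {
  ch <- cfg$encoderChannels
  L <- length(ch)
  with_seed(seed, {
    params <- list(stem = new_conv(1L, ch[1], c(3L, 3L, 3L)))
    params$enc <- lapply(seq_len(L), function(l)
      new_ecb(ch[l], cfg$dwKernel, cfg$expansion, cfg$layerscaleInit))
    params$down <- lapply(seq_len(L - 1), function(l)
      new_conv(ch[l], ch[l + 1], c(2L, 2L, 2L), stride = c(2L, 2L, 2L),
               pad = c(0L, 0L, 0L)))
    params$aspp <- new_aspp(ch[L], cfg$asppRates)
    params$up <- lapply(seq_len(L - 1), function(l) new_conv(ch[l + 1], ch[l]))
    params$att <- lapply(seq_len(L - 1), function(l)
      list(wg = new_conv(ch[l], max(4L, ch[l] %/% 2L)),
           wx = new_conv(ch[l], max(4L, ch[l] %/% 2L)),
           psi = new_conv(max(4L, ch[l] %/% 2L), 1L)))
    params$fuse <- lapply(seq_len(L - 1), function(l)
      new_conv(2L * ch[l], ch[l]))
    params$dec <- lapply(seq_len(L - 1), function(l)
      new_ecb(ch[l], cfg$dwKernel, cfg$expansion, cfg$layerscaleInit))
    params$head <- new_conv(ch[1], cfg$nClasses)
    list(cfg = cfg, params = params)
  })
}

# forward pass returning tape nodes; `mode` is "eval", "train" or "mc"
seg_forward_nodes <- function(net, image, mode = "eval") {
  cfg <- net$cfg
  p <- net$params
  L <- length(cfg$encoderChannels)
  d <- dim(image)
  if (length(d) == 3) image <- array(image, c(1L, d))
  sdim <- dim(image)[-1]
  div <- 2^(L - 1)
  if (any(sdim %% div != 0))
    nx_stop("spatial dimensions must divide ", div,
            "; apply padToMultiple() first")
  drop_on <- mode %in% c("train", "mc")

  x <- conv_apply(nd_const(image), p$stem)
  skips <- vector("list", L - 1)
  for (l in seq_len(L)) {
    x <- ecb_node(x, p$enc[[l]])
    if (l < L) {
      skips[[l]] <- x
      x <- conv_apply(x, p$down[[l]])
    }
  }
  x <- aspp_node(x, p$aspp)
  for (l in rev(seq_len(L - 1))) {
    up <- op_resize3d(x, dim(skips[[l]]$v)[-1])
    up <- conv_apply(up, p$up[[l]])
    gated <- att_node(up, skips[[l]], p$att[[l]])$gated
    x <- conv_apply(op_concat_ch(list(up, gated)), p$fuse[[l]])
    x <- ecb_node(x, p$dec[[l]])
    x <- op_dropout(x, cfg$dropoutRate, drop_on)
  }
  logits <- conv_apply(x, p$head)
  list(logits = logits, probs = op_softmax_ch(logits))
}

#' Run the segmentation network on a preprocessed volume
#'
#' @param net a network from [buildSegNet()].
#' @param image numeric array (X, Y, Z) (windowed intensities) with spatial
#'   dimensions divisible by `2^(levels - 1)`.
#' @param mode "eval" (deterministic), or "mc" to activate decoder dropout
#'   for Monte Carlo confidence sampling.
#' @return A [SegOutput-class].
#' @export
segForward <- function(net, image, mode = "eval") {
  r <- seg_forward_nodes(net, image, mode)
  new("SegOutput", probs = r$probs$v, logits = r$logits$v)
}

#' Number of trainable parameters of a network
#' @param net a built network (segmentation or classification).
#' @return Integer parameter count.
#' @export
countParams <- function(net) n_params(net$params)

# serialize / restore parameter values (structure-preserving)
params_values <- function(x) {
  if (is.environment(x)) return(x$v)
  if (is.list(x)) return(lapply(x, params_values))
  x
}

params_restore <- function(x, vals) {
  if (is.environment(x)) { x$v <- vals; return(invisible(NULL)) }
  if (is.list(x)) for (i in seq_along(x)) params_restore(x[[i]], vals[[i]])
  invisible(NULL)
}

#' Save network parameters and configuration to a file
#' @param net a built network.
#' @param path destination file.
#' @export
saveCheckpoint <- function(net, path) {
  saveRDS(list(cfg = net$cfg, values = params_values(net$params),
               kind = net$kind %||% "seg"), path)
}

#' Load a checkpoint saved by [saveCheckpoint()]
#' @param path checkpoint file.
#' @return The rebuilt network with restored parameters.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  net <- if (identical(ck$kind, "cls")) buildClsNet(ck$cfg) else buildSegNet(ck$cfg)
  params_restore(net$params, ck$values)
  net
}
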