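# Stage-two classifier: three parallel pathways process each standardized
# ROI at full, 0.75x and 0.5x resolution with scale-matched kernels,
# adaptive residual blocks (GroupNorm -> depthwise conv -> SiLU -> pointwise
# -> dropout -> pointwise -> squeeze-excitation gating -> scaled residual),
# context-aware attention fusion conditioned on the segmentation confidence,
# confidence-modulated feature scaling, and an evidential Dirichlet head
# over the four pathology classes.

#' Classifier configuration
#'
#' @param fineChannels,mediumChannels,coarseChannels stage widths of the
#'   three pathways (fine pathway: small kernels, high widths; coarse:
#'   large kernels, low widths).
#' @param expansion inverted-bottleneck expansion of the adaptive blocks.
#' @param dropout dropout rate inside the blocks (0.15 by default).
#' @param blockScaleInit initial value of the learnable residual scale.
#' @param seReduction squeeze-excitation bottleneck ratio.
#' @param fusionWidth common width the three streams are projected to.
#' @param caffHidden hidden width of the fusion-weight transform.
#' @param kappa confidence floor of the feature scaling (`kappa +
#'   (1 - kappa) * S`), so zero-confidence ROIs still classify.
#' @return A list of class `nx_cls_config`.
#' @export
clsNetConfig <- function(fineChannels = c(256L, 512L, 1024L),
                         mediumChannels = c(128L, 256L, 512L),
                         coarseChannels = c(64L, 128L, 256L),
                         expansion = 4L, dropout = 0.15,
                         blockScaleInit = 0.1, seReduction = 4L,
                         fusionWidth = 512L, caffHidden = 64L, kappa = 0.5) {
  pathways <- list(
    fine = list(kernel = c(3L, 3L, 3L), channels = as.integer(fineChannels),
                shape = c(96L, 96L, 32L), stemStride = c(4L, 4L, 4L)),
    medium = list(kernel = c(5L, 5L, 3L), channels = as.integer(mediumChannels),
                  shape = c(72L, 72L, 24L), stemStride = c(4L, 4L, 4L)),
    coarse = list(kernel = c(7L, 7L, 5L), channels = as.integer(coarseChannels),
                  shape = c(48L, 48L, 16L), stemStride = c(2L, 2L, 2L)))
  structure(list(pathways = pathways, expansion = as.integer(expansion),
                 dropout = dropout, blockScaleInit = blockScaleInit,
                 seReduction = as.integer(seReduction),
                 fusionWidth = as.integer(fusionWidth),
                 caffHidden = as.integer(caffHidden), kappa = kappa,
                 nClasses = 4L),
            class = "nx_cls_config")
}

#' Desk-scale classifier configuration (CPU-trainable)
#' @param ... overrides passed to [clsNetConfig()].
#' @export
tinyClsConfig <- function(...) {
  args <- list(fineChannels = c(16L, 32L, 64L), mediumChannels = c(8L, 16L, 32L),
               coarseChannels = c(4L, 8L, 16L), expansion = 2L,
               fusionWidth = 32L, caffHidden = 16L)
  do.call(clsNetConfig, utils::modifyList(args, list(...)))
}

# ---- squeeze-excitation ---------------------------------------------------

#' Create a 3D squeeze-and-excitation module
#' @param channels feature width.
#' @param reduction bottleneck ratio.
#' @param seed optional reproducibility seed.
#' @return Parameter list for [seForward()].
#' @export
makeSeModule <- function(channels, reduction = 4L, seed = NULL) {
  mid <- max(1L, channels %/% reduction)
  build <- function() list(
    w1 = nx_param(xavier_uniform(c(mid, channels), channels, mid)),
    b1 = nx_param(numeric(mid)),
    w2 = nx_param(xavier_uniform(c(channels, mid), mid, channels)),
    b2 = nx_param(numeric(channels)))
  if (is.null(seed)) build() else with_seed(seed, build())
}

se_node <- function(x, se) {
  s <- op_gap(x)
  s <- op_relu(op_linear(s, se$w1, se$b1))
  g <- op_sigmoid(op_linear(s, se$w2, se$b2))
  list(out = op_scale_ch(x, g), gates = g)
}

#' Apply squeeze-excitation gating to a feature array
#' @param se parameters from [makeSeModule()].
#' @param x numeric array (C, X, Y, Z).
#' @return `list(out =, gates =)`: the gated map and per-channel gates.
#' @export
seForward <- function(se, x) {
  r <- se_node(nd_const(x), se)
  list(out = r$out$v, gates = r$gates$v)
}

# ---- adaptive convolution block -------------------------------------------

#' Create an adaptive residual convolution block
#'
#' `ACB(x) = x + alpha * LayerScale(SE(PW(Drop(PW(SiLU(DW(GN(x))))))))`
#' with the block scale `alpha` initialized to 0.1.
#'
#' @param channels feature width (must be >= `seReduction`).
#' @param dwKernel depthwise kernel (default 5 x 5 x 3).
#' @param expansion pointwise expansion ratio.
#' @param dropout dropout rate (identity in evaluation mode).
#' @param blockScaleInit initial residual scale alpha.
#' @param seReduction squeeze-excitation ratio.
#' @param seed optional reproducibility seed.
#' @return Parameter list for [acbForward()].
#' @export
makeAcbBlock <- function(channels, dwKernel = c(5L, 5L, 3L), expansion = 4L,
                         dropout = 0.15, blockScaleInit = 0.1,
                         seReduction = 4L, seed = NULL) {
  if (channels < seReduction)
    nx_stop("channels must be >= seReduction")
  build <- function() new_acb(channels, dwKernel, expansion, dropout,
                              blockScaleInit, seReduction)
  if (is.null(seed)) build() else with_seed(seed, build())
}

new_acb <- function(channels, dwKernel, expansion, dropout, blockScaleInit,
                    seReduction) {
  mid <- channels * expansion
  list(gn = new_groupnorm(channels),
       dw = new_conv(channels, channels, dwKernel, groups = channels),
       pw1 = new_conv(channels, mid),
       pw2 = new_conv(mid, channels),
       se = makeSeModule(channels, seReduction),
       ls = nx_param(rep(1, channels)),
       alpha = nx_param(blockScaleInit),
       dropout = dropout, channels = channels)
}

acb_node <- function(x, blk, mode = "eval") {
  if (dim(x$v)[1] != blk$channels)
    nx_stop("block expects ", blk$channels, " channels, got ", dim(x$v)[1])
  h <- gn_apply(x, blk$gn)
  h <- conv_apply(h, blk$dw)
  h <- op_silu(h)
  h <- conv_apply(h, blk$pw1)
  h <- op_dropout(h, blk$dropout, identical(mode, "train"))
  h <- conv_apply(h, blk$pw2)
  h <- se_node(h, blk$se)$out
  h <- op_scale_ch(h, blk$ls)
  op_add(x, op_mul(h, op_broadcast_like(blk$alpha, h)))
}

# broadcast a scalar parameter over an array node's shape
op_broadcast_like <- function(par, x) {
  d <- dim(x$v)
  nd_make(array(par$v, d), list(par), function(node)
    acc_grad(par, sum(node$g)))
}

#' Apply an adaptive convolution block to a feature array
#' @param blk block from [makeAcbBlock()].
#' @param x numeric array (C, X, Y, Z).
#' @param mode "eval" (dropout off) or "train".
#' @return Array of the same shape.
#' @export
acbForward <- function(blk, x, mode = "eval") acb_node(nd_const(x), blk, mode)$v

# ---- multi-resolution streams ---------------------------------------------

#' Generate the three resolution streams of an ROI patch
#'
#' Fine = the 96 x 96 x 32 patch itself, medium = trilinear resize to
#' 72 x 72 x 24 (0.75x), coarse = 48 x 48 x 16 (0.5x).
#'
#' @param patch numeric array of shape exactly (96, 96, 32).
#' @return `list(fine =, medium =, coarse =)` arrays.
#' @export
hmrpStreams <- function(patch) {
  if (!identical(dim(patch), c(96L, 96L, 32L)))
    nx_stop("ROI patch must be exactly 96 x 96 x 32")
  x <- array(patch, c(1L, 96L, 96L, 32L))
  list(fine = patch,
       medium = array(resize3d_fwd_cpp(x, c(72L, 72L, 24L)), c(72, 72, 24)),
       coarse = array(resize3d_fwd_cpp(x, c(48L, 48L, 16L)), c(48, 48, 16)))
}

new_pathway <- function(pw, cfg) {
  ch <- pw$channels
  n <- length(ch)
  stages <- vector("list", n)
  for (i in seq_len(n)) {
    stages[[i]] <- list(
      acb = new_acb(ch[i], pw$kernel, cfg$expansion, cfg$dropout,
                    cfg$blockScaleInit, cfg$seReduction),
      trans = if (i < n) new_conv(ch[i], ch[i + 1], c(2L, 2L, 2L),
                                  stride = c(2L, 2L, 2L), pad = c(0L, 0L, 0L)))
  }
  list(stem = new_conv(1L, ch[1], pw$kernel, stride = pw$stemStride),
       stages = stages, top = ch[n])
}

pathway_node <- function(x, path, mode = "eval") {
  x <- conv_apply(x, path$stem)
  for (st in path$stages) {
    x <- acb_node(x, st$acb, mode)
    if (!is.null(st$trans)) x <- conv_apply(x, st$trans)
  }
  list(map = x, desc = op_gap(x))
}

#' Run one classification pathway over a stream
#' @param net a classifier from [buildClsNet()].
#' @param stream which pathway ("fine", "medium", "coarse").
#' @param x the stream array from [hmrpStreams()].
#' @return `list(map =, desc =)`: final feature map and pooled descriptor.
#' @export
pathwayForward <- function(net, stream, x) {
  r <- pathway_node(nd_const(array(x, c(1L, dim(x)))),
                    net$params$pathways[[stream]])
  list(map = r$map$v, desc = r$desc$v)
}

# ---- context-aware fusion --------------------------------------------------

new_caff <- function(tops, cfg) {
  wsum <- sum(tops) + 1L
  list(att = lapply(tops, function(ct) new_conv(ct, 1L)),
       proj = lapply(tops, function(ct) list(
         w = nx_param(xavier_uniform(c(cfg$fusionWidth, ct), ct, cfg$fusionWidth)),
         b = nx_param(numeric(cfg$fusionWidth)))),
       mw1 = nx_param(xavier_uniform(c(cfg$caffHidden, wsum), wsum, cfg$caffHidden)),
       mb1 = nx_param(numeric(cfg$caffHidden)),
       mw2 = nx_param(xavier_uniform(c(3L, cfg$caffHidden), cfg$caffHidden, 3L)),
       mb2 = nx_param(numeric(3L)))
}

caff_node <- function(caff, maps, descs, S) {
  if (length(maps) != 3 || length(descs) != 3)
    nx_stop("fusion expects exactly 3 streams")
  pooled <- vector("list", 3)
  for (s in 1:3) {
    psi <- op_sigmoid(conv_apply(maps[[s]], caff$att[[s]]))
    attended <- op_gate(maps[[s]], psi)
    phi <- op_gap(attended)
    pooled[[s]] <- op_linear(phi, caff$proj[[s]]$w, caff$proj[[s]]$b)
  }
  ctx <- op_concat_vec(c(descs, list(nd_const(S))))
  h <- op_relu(op_linear(ctx, caff$mw1, caff$mb1))
  w <- op_softmax_vec(op_linear(h, caff$mw2, caff$mb2))
  list(fused = op_weighted_sum(pooled, w), weights = w)
}

#' Context-aware fusion of the three stream representations
#'
#' Each stream's final map is spatially attended (sigmoid gate), globally
#' pooled and projected to the fusion width; the streams are then combined
#' with softmax attention weights computed from the pooled descriptors and
#' the segmentation confidence, so the weights always sum to one.
#'
#' @param caff fusion parameters (from a built classifier:
#'   `net$params$caff`).
#' @param maps list of 3 final feature maps (arrays).
#' @param descs list of 3 pooled descriptors (vectors).
#' @param S segmentation confidence scalar in [0, 1].
#' @return `list(fused =, weights =)`.
#' @export
caffFuse <- function(caff, maps, descs, S) {
  r <- caff_node(caff, lapply(maps, nd_const), lapply(descs, nd_const), S)
  list(fused = r$fused$v, weights = r$weights$v)
}

#' Confidence-modulated feature scaling
#'
#' Scales the fused representation by `kappa + (1 - kappa) * S`: poorly
#' segmented regions contribute proportionally less, but never vanish.
#'
#' @param fused numeric vector.
#' @param S segmentation confidence in [0, 1].
#' @param kappa floor in [0, 1] (default 0.5).
#' @return Scaled vector.
#' @export
cmfsScale <- function(fused, S, kappa = 0.5) {
  if (!is.finite(S) || S < 0 || S > 1) nx_stop("S must lie in [0, 1]")
  fused * (kappa + (1 - kappa) * S)
}

#' Evidential head: evidence and Dirichlet concentrations
#'
#' `e = softplus(W x + b) >= 0`, `alpha = e + 1`; uncertainty is
#' `K / sum(alpha)`, decreasing as any evidence grows.
#'
#' @param net a built classifier.
#' @param fused fused feature vector.
#' @return A [DirichletPrediction-class].
#' @export
edlHead <- function(net, fused) {
  e <- op_softplus(op_linear(nd_const(fused), net$params$edl$w, net$params$edl$b))
  DirichletPrediction(e$v + 1)
}

# ---- full classifier -------------------------------------------------------

#' Build the ROI classifier
#' @param cfg a [clsNetConfig()].
#' @param seed model initialization seed (default 123).
#' @return A list with `cfg`, parameter tree `params` and `kind = "cls"`.
#' @export
buildClsNet <- function(cfg = clsNetConfig(), seed = 123L) {
  with_seed(seed, {
    pathways <- lapply(cfg$pathways, new_pathway, cfg = cfg)
    tops <- vapply(pathways, `[[`, 0L, "top")
    params <- list(
      pathways = pathways,
      caff = new_caff(tops, cfg),
      edl = list(w = nx_param(xavier_uniform(c(cfg$nClasses, cfg$fusionWidth),
                                             cfg$fusionWidth, cfg$nClasses)),
                 b = nx_param(numeric(cfg$nClasses))))
    list(cfg = cfg, params = params, kind = "cls")
  })
}

cls_forward_nodes <- function(net, patch, S, mode = "eval") {
  streams <- hmrpStreams(patch)
  maps <- descs <- vector("list", 3)
  nm <- c("fine", "medium", "coarse")
  for (s in 1:3) {
    x <- nd_const(array(streams[[nm[s]]], c(1L, dim(streams[[nm[s]]]))))
    r <- pathway_node(x, net$params$pathways[[nm[s]]], mode)
    maps[[s]] <- r$map
    descs[[s]] <- r$desc
  }
  fz <- caff_node(net$params$caff, maps, descs, S)
  scaled <- op_scalar_mul(fz$fused, net$cfg$kappa + (1 - net$cfg$kappa) * S)
  e <- op_softplus(op_linear(scaled, net$params$edl$w, net$params$edl$b))
  alpha <- nd_make(e$v + 1, list(e), function(node) acc_grad(e, node$g))
  list(alpha = alpha, evidence = e, weights = fz$weights, fused = scaled)
}

#' Classify a standardized ROI
#'
#' @param net a classifier from [buildClsNet()].
#' @param roi a [ROIRecord-class], or a bare 96 x 96 x 32 patch array.
#' @param S segmentation confidence (taken from the record if omitted).
#' @return A [DirichletPrediction-class].
#' @export
clsForward <- function(net, roi, S = NULL) {
  if (is(roi, "ROIRecord")) {
    S <- S %||% roi@confidenceS
    patch <- roi@patch
  } else {
    patch <- roi
    S <- S %||% 1
  }
  if (!is.finite(S) || S < 0 || S > 1) nx_stop("S must lie in [0, 1]")
  r <- cls_forward_nodes(net, patch, S, mode = "eval")
  DirichletPrediction(r$alpha$v)
}
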