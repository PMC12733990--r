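# Brute-force oracles, intentionally naive and independent of the package
# kernels: all-pairs distances, BFS flood fill, direct convolution.

# signed distance transform by exhaustive nearest-site search
oracle_sdt <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  idx <- arrayInd(seq_len(prod(d)), d)
  mm <- sweep(idx - 1, 2, spacing, `*`)
  inside <- as.vector(mask > 0)
  out <- numeric(prod(d))
  din <- mm[inside, , drop = FALSE]
  dout <- mm[!inside, , drop = FALSE]
  mind <- function(p, set) {
    if (!nrow(set)) return(Inf)
    sqrt(min(colSums((t(set) - p)^2)))
  }
  for (i in seq_len(prod(d)))
    out[i] <- if (inside[i]) -mind(mm[i, ], dout) else mind(mm[i, ], din)
  array(out, d)
}

# connected components by BFS flood fill
oracle_components <- function(mask, label, connectivity = 26) {
  d <- dim(mask)
  tgt <- mask == label
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  comps <- list()
  for (start in which(tgt & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      members <- c(members, cur)
      v <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- v + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (tgt[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps
}

# surface voxels: region voxels with a face neighbor outside (or on the
# volume border)
oracle_surface <- function(m) {
  d <- dim(m)
  keep <- array(FALSE, d)
  for (i in which(m)) {
    v <- arrayInd(i, d)
    edge <- FALSE
    for (ax in 1:3) for (s in c(-1, 1)) {
      nb <- v
      nb[ax] <- nb[ax] + s
      if (any(nb < 1) || any(nb > d)) { edge <- TRUE; next }
      if (!m[nb[1], nb[2], nb[3]]) edge <- TRUE
    }
    keep[i] <- edge
  }
  keep
}

# HD95 by all-pairs surface distances
oracle_hd95 <- function(pred, gt, spacing = c(1, 1, 1)) {
  sp <- oracle_surface(pred)
  sg <- oracle_surface(gt)
  d <- dim(pred)
  co <- function(m) sweep(arrayInd(which(m), d) - 1, 2, spacing, `*`)
  a <- co(sp)
  b <- co(sg)
  dm <- sqrt(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b))
  dm[dm < 0 | is.nan(dm)] <- 0
  max(quantile(apply(dm, 1, min), 0.95, names = FALSE),
      quantile(apply(dm, 2, min), 0.95, names = FALSE))
}

# direct (dense) dilated 3D convolution, channels-first arrays
oracle_conv3d <- function(x, w, b, stride = c(1, 1, 1), dil = c(1, 1, 1),
                          pad = c(0, 0, 0)) {
  xd <- dim(x)
  wd <- dim(w)
  osz <- function(X, k, s, d, p) (X + 2 * p - d * (k - 1) - 1) %/% s + 1
  od <- c(osz(xd[2], wd[3], stride[1], dil[1], pad[1]),
          osz(xd[3], wd[4], stride[2], dil[2], pad[2]),
          osz(xd[4], wd[5], stride[3], dil[3], pad[3]))
  y <- array(0, c(wd[1], od))
  for (oz in 1:od[3]) for (oy in 1:od[2]) for (ox in 1:od[1]) {
    acc <- b
    for (kk in 1:wd[5]) for (jj in 1:wd[4]) for (ii in 1:wd[3]) {
      ix <- (ox - 1) * stride[1] + (ii - 1) * dil[1] - pad[1] + 1
      iy <- (oy - 1) * stride[2] + (jj - 1) * dil[2] - pad[2] + 1
      iz <- (oz - 1) * stride[3] + (kk - 1) * dil[3] - pad[3] + 1
      if (ix >= 1 && ix <= xd[2] && iy >= 1 && iy <= xd[3] &&
          iz >= 1 && iz <= xd[4])
        acc <- acc + matrix(w[, , ii, jj, kk], wd[1], wd[2]) %*% x[, ix, iy, iz]
    }
    y[, ox, oy, oz] <- acc
  }
  y
}

# random voxel probability grid normalized over channels
random_probs <- function(K, dims) {
  p <- array(exp(rnorm(K * prod(dims))), c(K, dims))
  s <- colSums(matrix(p, nrow = K))
  array(p / rep(s, each = K), c(K, dims))
}

# random one-hot grid
random_onehot <- function(K, dims) {
  lab <- array(sample.int(K, prod(dims), replace = TRUE) - 1L, dims)
  nephrodx:::onehot_grid(lab, K)
}

# small deterministic phantom for unit tests
tiny_spec <- function(seed = 7L)
  phantomSpec(volumeShape = c(32L, 32L, 12L), seed = seed,
              lesionRadiusRange = list(cyst = c(3, 5), tumor = c(3.5, 5),
                                       stone = c(3, 4)))
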