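#' @useDynLib nephrodx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd median spline setNames
#' @importFrom utils read.csv write.csv head tail
#' @import methods
NULL

.nx <- new.env(parent = emptyenv())
.nx$recording <- FALSE
.nx$tape <- NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

nx_stop <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible sub-seed from a base seed and a tag
#'
#' Mixes an integer seed with a character tag (e.g. a patient id) so that
#' every generated object has its own deterministic random stream.  The
#' result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Integer base seed.
#' @param tag Character scalar.
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- 7
  for (k in utf8ToInt(as.character(tag))) h <- (h * 131 + k) %% m
  s <- (abs(as.numeric(seed)) %% m) * 48271 %% m
  as.integer((s + h) %% (m - 1) + 1)
}

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the
# caller's RNG state afterwards so generators are pure functions of seeds.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# next multiple of m at or above x
next_multiple <- function(x, m) as.integer(ceiling(x / m) * m)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# one-hot encode an integer label grid (values 0..K-1) as (K, dims)
onehot_grid <- function(mask, K) {
  d <- dim(mask)
  out <- array(0, c(K, d))
  flat <- as.integer(mask)
  idx <- (flat) + K * (seq_along(flat) - 1L) + 1L
  out[idx] <- 1
  out
}

# argmax over channel (first) dimension of a (K, dims) array -> labels 0..K-1
argmax_ch <- function(p) {
  d <- dim(p)
  m <- matrix(p, nrow = d[1])
  lab <- max.col(t(m), ties.method = "first") - 1L
  array(as.integer(lab), d[-1])
}
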