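# Differentiable layer primitives for the 3D U-Net engine.
#
# Feature maps are column-major arrays [nx, ny, nz, C]. Every layer has a
# *_fwd() returning list(y, cache) and a *_bwd(cache, dy) returning
# list(dx, grads). Convolution, instance norm and leaky ReLU run through
# cache-blocked C++ kernels (src/kernels.cpp); an im2col + GEMM convolution
# path is kept alongside as an independent cross-check of the direct
# kernels.

LRELU_SLOPE <- 0.01
IN_EPS <- 1e-5

sigmoid <- function(x) 1 / (1 + exp(-x))

spatial_dims <- function(x) dim(x)[1:3]
n_channels <- function(x) if (length(dim(x)) == 4L) dim(x)[4] else 1L

#' @noRd
conv3d_init <- function(cin, cout, k) {
  fan_in <- cin * k^3
  # Kaiming init for leaky-ReLU networks
  sd <- sqrt(2 / ((1 + LRELU_SLOPE^2) * fan_in))
  list(W = matrix(stats::rnorm(fan_in * cout, sd = sd), fan_in, cout),
       b = numeric(cout), k = k)
}

as_dbl <- function(x) if (is.double(x)) x else as.numeric(x)

conv3d_fwd <- function(x, p) {
  d <- spatial_dims(x)
  cin <- n_channels(x)
  x <- as_dbl(x)
  y <- conv3d_direct_fwd(x, p$W, p$b, as.integer(d), cin, p$k)
  dim(y) <- c(d, ncol(p$W))
  list(y = y, cache = list(x = x, d = d, cin = cin))
}

conv3d_bwd <- function(p, cache, dy) {
  d <- cache$d
  dy <- as_dbl(dy)
  dx <- conv3d_direct_bwd_dx(dy, p$W, as.integer(d), cache$cin, p$k)
  dim(dx) <- c(d, cache$cin)
  gw <- conv3d_direct_bwd_dw(cache$x, dy, as.integer(d), cache$cin,
                             ncol(p$W), p$k)
  list(dx = dx, grads = list(W = gw$dW, b = gw$db))
}

#' @noRd
instnorm_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))

instnorm_fwd <- function(x, p) {
  d <- dim(x)
  r <- instnorm3d_fwd(as_dbl(x), prod(d[1:3]), d[4], p$gamma, p$beta, IN_EPS)
  y <- r$y
  dim(y) <- d
  list(y = y, cache = list(xhat = r$xhat, istd = r$istd, d = d))
}

instnorm_bwd <- function(p, cache, dy) {
  d <- cache$d
  r <- instnorm3d_bwd(as_dbl(dy), cache$xhat, cache$istd, p$gamma,
                      prod(d[1:3]), d[4])
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

lrelu_fwd <- function(x) {
  r <- lrelu3d_fwd(as_dbl(x), LRELU_SLOPE)
  y <- r$y
  dim(y) <- dim(x)
  list(y = y, cache = r$neg)
}

lrelu_bwd <- function(cache, dy) {
  dx <- lrelu3d_bwd(as_dbl(dy), cache, LRELU_SLOPE)
  dim(dx) <- dim(dy)
  dx
}

# Inverted dropout; draws from the session RNG so set.seed() governs it.
dropout_fwd <- function(x, rate, active) {
  if (!active || rate <= 0) return(list(y = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

maxpool_fwd <- function(x) {
  d <- dim(x)
  r <- maxpool3d_fwd(as.numeric(x), d[1], d[2], d[3], d[4])
  y <- r$y
  dim(y) <- c(d[1:3] %/% 2L, d[4])
  list(y = y, cache = list(idx = r$idx, n_in = prod(d), d = d))
}

maxpool_bwd <- function(cache, dy) {
  dx <- maxpool3d_bwd(as.numeric(dy), cache$idx, cache$n_in)
  dim(dx) <- cache$d
  dx
}

upsample_fwd <- function(x, out_dims) {
  d <- dim(x)
  y <- upsample3d_fwd(as.numeric(x), as.integer(d[1:3]), as.integer(out_dims), d[4])
  dim(y) <- c(out_dims, d[4])
  list(y = y, cache = list(ind = d[1:3], outd = out_dims, C = d[4]))
}

upsample_bwd <- function(cache, dy) {
  dx <- upsample3d_bwd(as.numeric(dy), as.integer(cache$ind),
                       as.integer(cache$outd), cache$C)
  dim(dx) <- c(cache$ind, cache$C)
  dx
}

softmax_channels <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, prod(d[1:3]), d[4])
  mx <- m[, 1L]
  if (d[4] > 1L) for (j in 2:d[4]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

# dL/dlogits given dL/dprobs, via the softmax Jacobian
softmax_bwd <- function(probs, dprobs) {
  d <- dim(probs)
  pm <- matrix(probs, prod(d[1:3]), d[4])
  gm <- matrix(dprobs, prod(d[1:3]), d[4])
  dl <- pm * (gm - rowSums(gm * pm))
  dim(dl) <- d
  dl
}
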