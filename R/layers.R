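# Low-level layers used by the residual backbone. Activations are stored as
# H x W x C x N arrays (column-major), kernels as kh x kw x Cin x Cout.

conv_forward <- function(x, w, stride = 1L, pad = 1L) {
  .conv2d_fwd(x, w, as.integer(stride), as.integer(pad))
}

conv_backward <- function(x, w, dy, stride = 1L, pad = 1L) {
  .conv2d_bwd(x, w, dy, as.integer(stride), as.integer(pad))
}

make_conv <- function(kh, kw, c_in, c_out) {
  # He initialization; the caller controls the RNG stream.
  array(rnorm(kh * kw * c_in * c_out, sd = sqrt(2 / (kh * kw * c_in))),
        dim = c(kh, kw, c_in, c_out))
}

make_bn <- function(c_out) {
  list(gamma = rep(1, c_out), beta = rep(0, c_out),
       rmean = rep(0, c_out), rvar = rep(1, c_out))
}

# Broadcast a per-channel vector over an H x W x C x N array. A vector of
# length H*W*C recycles correctly over the image dimension.
ch_expand <- function(v, hw) rep(v, each = hw)

# Per-channel sums over H, W and N.
ch_sum <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- x
  dim(m) <- c(hw, d[3] * d[4])
  cs <- colSums(m)
  dim(cs) <- c(d[3], d[4])
  rowSums(cs)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Batch normalization. In training mode uses batch statistics and updates
# running statistics; in eval mode applies the frozen running statistics so
# that gain changes propagate instead of being renormalized away.
bn_forward <- function(x, bn, train = FALSE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  n_red <- hw * d[4]
  if (train) {
    mu <- ch_sum(x) / n_red
    xc <- x - ch_expand(mu, hw)
    v <- ch_sum(xc * xc) / n_red
    bn$rmean <- (1 - BN_MOMENTUM) * bn$rmean + BN_MOMENTUM * mu
    bn$rvar <- (1 - BN_MOMENTUM) * bn$rvar + BN_MOMENTUM * v * n_red / max(1, n_red - 1)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * ch_expand(invstd, hw)
    y <- xhat * ch_expand(bn$gamma, hw) + ch_expand(bn$beta, hw)
    list(y = y, bn = bn, cache = list(xhat = xhat, invstd = invstd, hw = hw,
                                      n_red = n_red, gamma = bn$gamma))
  } else {
    invstd <- 1 / sqrt(bn$rvar + BN_EPS)
    y <- (x - ch_expand(bn$rmean, hw)) * ch_expand(bn$gamma * invstd, hw) +
      ch_expand(bn$beta, hw)
    list(y = y, bn = bn, cache = NULL)
  }
}

bn_backward <- function(dy, cache) {
  hw <- cache$hw
  n_red <- cache$n_red
  xhat <- cache$xhat
  dgamma <- ch_sum(dy * xhat)
  dbeta <- ch_sum(dy)
  dxhat <- dy * ch_expand(cache$gamma, hw)
  s1 <- ch_sum(dxhat)
  s2 <- ch_sum(dxhat * xhat)
  dx <- (dxhat - ch_expand(s1 / n_red, hw) - xhat * ch_expand(s2 / n_red, hw)) *
    ch_expand(cache$invstd, hw)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Global average pooling: H x W x C x N -> C x N.
gap_forward <- function(x) {
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1] * d[2], d[3] * d[4])
  f <- colMeans(m)
  dim(f) <- c(d[3], d[4])
  f
}

gap_backward <- function(df, d_in) {
  hw <- d_in[1] * d_in[2]
  dx <- rep(as.numeric(df) / hw, each = hw)
  dim(dx) <- d_in
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean (over samples) multi-label sigmoid cross-entropy and its gradient in
# the logits. `targets` is a 0/1 matrix shaped like `scores` (K x N).
sigmoid_bce <- function(scores, targets) {
  p <- sigmoid(scores)
  eps <- 1e-12
  n <- ncol(scores)
  loss <- -sum(targets * log(p + eps) + (1 - targets) * log(1 - p + eps)) / n
  list(loss = loss, dscores = (p - targets) / n)
}
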