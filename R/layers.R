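# Layer primitives for the CPU networks. Feature maps are arrays of dim
# c(h, w, channels); convolution weights are (kh*kw*c_in) x c_out matrices
# fed to the compiled im2col/GEMM kernels. Every forward returns the values
# it caches for the matching backward.

conv_fwd <- function(x, W, b, k, stride, pad) {
  cpp_conv2d_fwd(x, W, b, k, k, stride, pad)
}
conv_bwd <- function(x, W, gout, k, stride, pad) {
  cpp_conv2d_bwd(x, W, gout, k, k, stride, pad)
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}
relu_bwd <- function(g, y) g * (y > 0)

lrelu_fwd <- function(x, slope = 0.2) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}
lrelu_bwd <- function(g, y, slope = 0.2) {
  g[y < 0] <- slope * g[y < 0]
  g
}

# Channel normalization shared by instance norm (shift 0 / scale 1) and
# AdaIN: per channel c over spatial positions,
#   y_c = scale_c * (x_c - mean(x_c)) / (sd(x_c) + eps) + shift_c
# with the population standard deviation. eps keeps constant channels finite.
chan_norm_fwd <- function(x, shift, scale, eps) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  z <- sweep(m, 2, mu)
  sd <- sqrt(colMeans(z * z))
  xhat <- sweep(z, 2, sd + eps, "/")
  y <- sweep(sweep(xhat, 2, scale, "*"), 2, shift, "+")
  dim(y) <- d
  list(y = y, xhat = xhat, sd = sd, eps = eps, scale = scale, d = d)
}

chan_norm_bwd <- function(cache, gy) {
  d <- cache$d
  g <- matrix(gy, d[1] * d[2], d[3])
  g <- sweep(g, 2, cache$scale, "*")
  gscale <- colSums(matrix(gy, d[1] * d[2], d[3]) * cache$xhat)
  gshift <- colSums(matrix(gy, d[1] * d[2], d[3]))
  denom <- cache$sd + cache$eps
  sd_safe <- pmax(cache$sd, 1e-12)
  gm <- colMeans(g)
  gxh <- colMeans(g * cache$xhat) * (denom / sd_safe)
  gx <- sweep(g, 2, gm) - sweep(cache$xhat, 2, gxh, "*")
  gx <- sweep(gx, 2, denom, "/")
  dim(gx) <- d
  list(gx = gx, gshift = gshift, gscale = gscale)
}

fc_fwd <- function(x, W, b) as.vector(crossprod(W, x)) + b
fc_bwd <- function(x, W, gy) {
  list(gx = as.vector(W %*% gy), gW = outer(x, gy), gb = gy)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# elementwise sum of two structurally identical named gradient lists
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}
scale_grads <- function(a, s) lapply(a, function(g) g * s)
zero_like <- function(params) lapply(params, function(p) p * 0)
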