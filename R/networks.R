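# The switchable CycleGAN networks: one shared residual generator whose
# AdaIN-modulated residual blocks are steered by per-direction codes from a
# small fully connected code generator (ACG), plus two patch-level
# discriminators. Forward and backward passes are explicit; see layers.R for
# the primitives.

GEN_DOWN_FACTOR <- 4L  # two stride-2 encoder blocks

#' Initialize a switchable CycleGAN model bundle
#'
#' Creates the shared generator, the AdaIN code generator (ACG), and the two
#' patch-level discriminators with seeded Gaussian(0, 0.02) weights. The
#' generator is an encoder (one stride-1 and two stride-2 convolution blocks
#' with instance normalization), `n_res_blocks` residual blocks whose two
#' normalizations are AdaIN-modulated, and a nearest-neighbour upsampling
#' decoder; its output is a tanh-bounded residual added to the input image.
#' The ACG maps a one-hot direction tag (forward: X to Y; backward: Y to X)
#' to one (shift, scale) vector pair per modulated layer, with scales made
#' strictly positive by an exponential activation.
#'
#' @param base_channels Channel width of the first encoder block.
#' @param n_res_blocks Number of AdaIN-modulated residual blocks.
#' @param disc_channels Width of the first discriminator block.
#' @param acg_hidden Hidden width of the ACG.
#' @param epsilon Stabilizer added to the feature standard deviation inside
#'   every (Ada)IN normalization.
#' @param global_skip Use the residual output head (recommended).
#' @param seed Integer seed for weight initialization.
#' @return An object of class `usgan_model`.
#' @export
model_bundle <- function(base_channels = 16, n_res_blocks = 4,
                         disc_channels = base_channels, acg_hidden = 64,
                         epsilon = 1e-5, global_skip = TRUE, seed = 1) {
  hp <- list(base_channels = base_channels, n_res_blocks = n_res_blocks,
             disc_channels = disc_channels, acg_hidden = acg_hidden,
             epsilon = epsilon, global_skip = global_skip,
             n_adain_layers = 2L * n_res_blocks,
             res_channels = 4L * base_channels,
             down_factor = GEN_DOWN_FACTOR)
  with_seed(seed, {
    structure(list(gen = init_gen(hp), acg = init_acg(hp),
                   dA = init_disc(hp), dB = init_disc(hp),
                   hp = hp, format = "usgan-model-1"),
              class = "usgan_model")
  })
}

winit <- function(k_in, c_out) matrix(rnorm(k_in * c_out, 0, 0.02),
                                      k_in, c_out)

init_gen <- function(hp) {
  C <- hp$base_channels
  p <- list(
    enc0.W = winit(9 * 1, C), enc0.b = numeric(C),
    enc1.W = winit(9 * C, 2 * C), enc1.b = numeric(2 * C),
    enc2.W = winit(9 * 2 * C, 4 * C), enc2.b = numeric(4 * C))
  for (k in seq_len(hp$n_res_blocks)) {
    p[[sprintf("res%d.c1.W", k)]] <- winit(9 * 4 * C, 4 * C)
    p[[sprintf("res%d.c1.b", k)]] <- numeric(4 * C)
    p[[sprintf("res%d.c2.W", k)]] <- winit(9 * 4 * C, 4 * C)
    p[[sprintf("res%d.c2.b", k)]] <- numeric(4 * C)
  }
  p$dec1.W <- winit(9 * 4 * C, 2 * C); p$dec1.b <- numeric(2 * C)
  p$dec2.W <- winit(9 * 2 * C, C); p$dec2.b <- numeric(C)
  p$out.W <- winit(9 * C, 1L); p$out.b <- numeric(1)
  p
}

init_acg <- function(hp) {
  nout <- hp$n_adain_layers * 2L * hp$res_channels
  list(fc1.W = winit(2, hp$acg_hidden), fc1.b = numeric(hp$acg_hidden),
       fc2.W = matrix(rnorm(hp$acg_hidden * nout, 0, 0.01),
                      hp$acg_hidden, nout),
       fc2.b = numeric(nout))
}

init_disc <- function(hp) {
  C <- hp$disc_channels
  list(c1.W = winit(16 * 1, C), c1.b = numeric(C),
       c2.W = winit(16 * C, 2 * C), c2.b = numeric(2 * C),
       c3.W = winit(16 * 2 * C, 4 * C), c3.b = numeric(4 * C),
       c4.W = winit(16 * 4 * C, 8 * C), c4.b = numeric(8 * C),
       out.W = winit(9 * 8 * C, 1L), out.b = numeric(1))
}

# ---- ACG --------------------------------------------------------------------

acg_fwd <- function(p, hp, direction) {
  tag <- switch(direction, forward = c(1, 0), backward = c(0, 1),
                stop("unknown direction tag: ", direction, call. = FALSE))
  h_pre <- fc_fwd(tag, p$fc1.W, p$fc1.b)
  h <- pmax(h_pre, 0)
  raw <- fc_fwd(h, p$fc2.W, p$fc2.b)
  cpl <- hp$res_channels
  code <- vector("list", hp$n_adain_layers)
  for (l in seq_len(hp$n_adain_layers)) {
    off <- (l - 1L) * 2L * cpl
    shift <- raw[off + seq_len(cpl)]
    scale <- exp(raw[off + cpl + seq_len(cpl)])
    code[[l]] <- list(shift = shift, scale = scale)
  }
  attr(code, "direction") <- direction
  list(code = code, cache = list(tag = tag, h = h, raw = raw, cpl = cpl))
}

acg_bwd <- function(p, hp, cache, gcode) {
  cpl <- cache$cpl
  graw <- numeric(length(cache$raw))
  for (l in seq_len(hp$n_adain_layers)) {
    off <- (l - 1L) * 2L * cpl
    graw[off + seq_len(cpl)] <- gcode[[l]]$gshift
    graw[off + cpl + seq_len(cpl)] <-
      gcode[[l]]$gscale * exp(cache$raw[off + cpl + seq_len(cpl)])
  }
  b2 <- fc_bwd(cache$h, p$fc2.W, graw)
  gh <- b2$gx * (cache$h > 0)
  b1 <- fc_bwd(cache$tag, p$fc1.W, gh)
  list(grads = list(fc1.W = b1$gW, fc1.b = b1$gb,
                    fc2.W = b2$gW, fc2.b = b2$gb))
}

#' Generate the AdaIN code for a translation direction
#'
#' Deterministically maps the direction switch to per-layer channel-wise
#' (shift, scale) modulation vectors; scales are strictly positive.
#'
#' @param bundle A `usgan_model`.
#' @param direction `"forward"` (X to Y) or `"backward"` (Y to X).
#' @return A list with one `(shift, scale)` pair per AdaIN-modulated layer,
#'   with attribute `direction`.
#' @export
acg_forward <- function(bundle, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  acg_fwd(bundle$acg, bundle$hp, direction)$code
}

#' Adaptive instance normalization
#'
#' Re-normalizes each channel of a feature map to a target mean and standard
#' deviation: `scale * (f - mean(f)) / (sd(f) + eps) + shift`, with the
#' population standard deviation taken over spatial positions.
#'
#' @param f Feature map: an `h x w` matrix or an `h x w x c` array.
#' @param shift,scale Numeric vectors of length `c`.
#' @param eps Stabilizer (default `1e-5`).
#' @return Array (or matrix) of the same shape as `f`.
#' @export
adain <- function(f, shift, scale, eps = 1e-5) {
  was_mat <- is.matrix(f)
  if (was_mat) dim(f) <- c(dim(f), 1L)
  if (length(shift) != dim(f)[3] || length(scale) != dim(f)[3])
    stop("shift/scale length (", length(shift), ", ", length(scale),
         ") does not match channel count ", dim(f)[3], call. = FALSE)
  y <- chan_norm_fwd(f, shift, scale, eps)$y
  if (was_mat) dim(y) <- dim(y)[1:2]
  y
}

# ---- generator --------------------------------------------------------------

gen_fwd <- function(p, hp, x01, code) {
  h <- nrow(x01); w <- ncol(x01)
  if (h %% hp$down_factor != 0 || w %% hp$down_factor != 0)
    stop("generator input dimensions must be multiples of ",
         hp$down_factor, " (got ", h, "x", w, ")", call. = FALSE)
  eps <- hp$epsilon
  x <- array(2 * x01 - 1, c(h, w, 1L))
  cache <- list(x01 = x01, x = x)

  a <- conv_fwd(x, p$enc0.W, p$enc0.b, 3L, 1L, 1L)
  cache$e0_pre <- a
  n0 <- chan_norm_fwd(a, 0, 1, eps); cache$e0_n <- n0
  a0 <- relu_fwd(n0$y); cache$e0 <- a0

  a <- conv_fwd(a0, p$enc1.W, p$enc1.b, 3L, 2L, 1L)
  cache$e1_pre <- a
  n1 <- chan_norm_fwd(a, 0, 1, eps); cache$e1_n <- n1
  a1 <- relu_fwd(n1$y); cache$e1 <- a1

  a <- conv_fwd(a1, p$enc2.W, p$enc2.b, 3L, 2L, 1L)
  cache$e2_pre <- a
  n2 <- chan_norm_fwd(a, 0, 1, eps); cache$e2_n <- n2
  r <- relu_fwd(n2$y); cache$e2 <- r

  cache$res <- vector("list", hp$n_res_blocks)
  for (k in seq_len(hp$n_res_blocks)) {
    rc <- list(r_in = r)
    t1 <- conv_fwd(r, p[[sprintf("res%d.c1.W", k)]],
                   p[[sprintf("res%d.c1.b", k)]], 3L, 1L, 1L)
    rc$t1_in <- r
    c1 <- code[[2 * k - 1]]
    rc$n1 <- chan_norm_fwd(t1, c1$shift, c1$scale, eps)
    rc$a1 <- relu_fwd(rc$n1$y)
    t2 <- conv_fwd(rc$a1, p[[sprintf("res%d.c2.W", k)]],
                   p[[sprintf("res%d.c2.b", k)]], 3L, 1L, 1L)
    c2 <- code[[2 * k]]
    rc$n2 <- chan_norm_fwd(t2, c2$shift, c2$scale, eps)
    r <- r + rc$n2$y
    cache$res[[k]] <- rc
  }
  cache$res_out <- r

  u1 <- cpp_upsample2(r); cache$u1 <- u1
  a <- conv_fwd(u1, p$dec1.W, p$dec1.b, 3L, 1L, 1L)
  nd1 <- chan_norm_fwd(a, 0, 1, eps); cache$d1_n <- nd1
  d1 <- relu_fwd(nd1$y); cache$d1 <- d1

  u2 <- cpp_upsample2(d1); cache$u2 <- u2
  a <- conv_fwd(u2, p$dec2.W, p$dec2.b, 3L, 1L, 1L)
  nd2 <- chan_norm_fwd(a, 0, 1, eps); cache$d2_n <- nd2
  d2 <- relu_fwd(nd2$y); cache$d2 <- d2

  raw <- conv_fwd(d2, p$out.W, p$out.b, 3L, 1L, 1L)[, , 1]
  cache$raw <- raw
  th <- tanh(raw); cache$th <- th
  if (hp$global_skip) {
    z <- x01 + th
    cache$clip_open <- z > 0 & z < 1
    y <- clamp01(z)
  } else {
    y <- (th + 1) / 2
    cache$clip_open <- NULL
  }
  list(y = y, cache = cache)
}

gen_bwd <- function(p, hp, cache, gy) {
  grads <- list()
  n_res <- hp$n_res_blocks
  gcode <- rep(list(list(gshift = 0, gscale = 0)), 2L * n_res)

  if (hp$global_skip) {
    gz <- gy * cache$clip_open
    gx01_direct <- gz
    graw <- gz * (1 - cache$th^2)
  } else {
    gx01_direct <- 0
    graw <- gy * (1 - cache$th^2) / 2
  }
  graw <- array(graw, c(dim(cache$raw), 1L))
  bo <- conv_bwd(cache$d2, p$out.W, graw, 3L, 1L, 1L)
  grads$out.W <- bo$gW; grads$out.b <- bo$gb

  g <- relu_bwd(bo$gx, cache$d2)
  g <- chan_norm_bwd(cache$d2_n, g)$gx
  b2 <- conv_bwd(cache$u2, p$dec2.W, g, 3L, 1L, 1L)
  grads$dec2.W <- b2$gW; grads$dec2.b <- b2$gb
  g <- cpp_upsample2_bwd(b2$gx)

  g <- relu_bwd(g, cache$d1)
  g <- chan_norm_bwd(cache$d1_n, g)$gx
  b1 <- conv_bwd(cache$u1, p$dec1.W, g, 3L, 1L, 1L)
  grads$dec1.W <- b1$gW; grads$dec1.b <- b1$gb
  g <- cpp_upsample2_bwd(b1$gx)

  for (k in rev(seq_len(n_res))) {
    rc <- cache$res[[k]]
    gn2 <- chan_norm_bwd(rc$n2, g)
    gcode[[2 * k]] <- list(gshift = gn2$gshift, gscale = gn2$gscale)
    bc2 <- conv_bwd(rc$a1, p[[sprintf("res%d.c2.W", k)]], gn2$gx, 3L, 1L, 1L)
    grads[[sprintf("res%d.c2.W", k)]] <- bc2$gW
    grads[[sprintf("res%d.c2.b", k)]] <- bc2$gb
    ga1 <- relu_bwd(bc2$gx, rc$a1)
    gn1 <- chan_norm_bwd(rc$n1, ga1)
    gcode[[2 * k - 1]] <- list(gshift = gn1$gshift, gscale = gn1$gscale)
    bc1 <- conv_bwd(rc$t1_in, p[[sprintf("res%d.c1.W", k)]], gn1$gx,
                    3L, 1L, 1L)
    grads[[sprintf("res%d.c1.W", k)]] <- bc1$gW
    grads[[sprintf("res%d.c1.b", k)]] <- bc1$gb
    g <- g + bc1$gx  # residual skip
  }

  g <- relu_bwd(g, cache$e2)
  g <- chan_norm_bwd(cache$e2_n, g)$gx
  be2 <- conv_bwd(cache$e1, p$enc2.W, g, 3L, 2L, 1L)
  grads$enc2.W <- be2$gW; grads$enc2.b <- be2$gb

  g <- relu_bwd(be2$gx, cache$e1)
  g <- chan_norm_bwd(cache$e1_n, g)$gx
  be1 <- conv_bwd(cache$e0, p$enc1.W, g, 3L, 2L, 1L)
  grads$enc1.W <- be1$gW; grads$enc1.b <- be1$gb

  g <- relu_bwd(be1$gx, cache$e0)
  g <- chan_norm_bwd(cache$e0_n, g)$gx
  be0 <- conv_bwd(cache$x, p$enc0.W, g, 3L, 1L, 1L)
  grads$enc0.W <- be0$gW; grads$enc0.b <- be0$gb

  gx01 <- gx01_direct + 2 * be0$gx[, , 1]
  list(gx = gx01, grads = grads, gcode = gcode)
}

#' Translate an image with the shared generator
#'
#' A single feed-forward pass: the image is mapped through the generator with
#' the AdaIN code of the requested direction (or an explicit `code`). Input
#' dimensions must be multiples of the generator's downsampling factor (4);
#' the output has the same spatial size and lies in \[0,1\].
#'
#' @param img Grey image matrix in \[0,1\].
#' @param bundle A `usgan_model`.
#' @param direction `"forward"` (low to high quality) or `"backward"`.
#' @param code Optional explicit AdaIN code, as from [acg_forward()].
#' @return Translated grey image matrix.
#' @export
generate <- function(img, bundle, direction = c("forward", "backward"),
                     code = NULL) {
  assert_grey(img)
  stopifnot(inherits(bundle, "usgan_model"))
  if (is.null(code)) {
    direction <- match.arg(direction)
    code <- acg_forward(bundle, direction)
  }
  gen_fwd(bundle$gen, bundle$hp, img, code)$y
}

# ---- discriminator ----------------------------------------------------------

disc_fwd <- function(p, hp, x01) {
  x <- array(2 * x01 - 1, c(nrow(x01), ncol(x01), 1L))
  cache <- list(x = x)
  a <- conv_fwd(x, p$c1.W, p$c1.b, 4L, 2L, 1L)
  h1 <- lrelu_fwd(a); cache$h1 <- h1
  a <- conv_fwd(h1, p$c2.W, p$c2.b, 4L, 2L, 1L)
  n2 <- chan_norm_fwd(a, 0, 1, hp$epsilon); cache$n2 <- n2
  h2 <- lrelu_fwd(n2$y); cache$h2 <- h2
  a <- conv_fwd(h2, p$c3.W, p$c3.b, 4L, 2L, 1L)
  n3 <- chan_norm_fwd(a, 0, 1, hp$epsilon); cache$n3 <- n3
  h3 <- lrelu_fwd(n3$y); cache$h3 <- h3
  a <- conv_fwd(h3, p$c4.W, p$c4.b, 4L, 2L, 1L)
  n4 <- chan_norm_fwd(a, 0, 1, hp$epsilon); cache$n4 <- n4
  h4 <- lrelu_fwd(n4$y); cache$h4 <- h4
  s <- conv_fwd(h4, p$out.W, p$out.b, 3L, 1L, 1L)
  list(scores = matrix(s, dim(s)[1], dim(s)[2]), cache = cache)
}

disc_bwd <- function(p, hp, cache, gscores) {
  grads <- list()
  g <- array(gscores, c(dim(gscores), 1L))
  bo <- conv_bwd(cache$h4, p$out.W, g, 3L, 1L, 1L)
  grads$out.W <- bo$gW; grads$out.b <- bo$gb
  g <- lrelu_bwd(bo$gx, cache$h4)
  g <- chan_norm_bwd(cache$n4, g)$gx
  b4 <- conv_bwd(cache$h3, p$c4.W, g, 4L, 2L, 1L)
  grads$c4.W <- b4$gW; grads$c4.b <- b4$gb
  g <- lrelu_bwd(b4$gx, cache$h3)
  g <- chan_norm_bwd(cache$n3, g)$gx
  b3 <- conv_bwd(cache$h2, p$c3.W, g, 4L, 2L, 1L)
  grads$c3.W <- b3$gW; grads$c3.b <- b3$gb
  g <- lrelu_bwd(b3$gx, cache$h2)
  g <- chan_norm_bwd(cache$n2, g)$gx
  b2 <- conv_bwd(cache$h1, p$c2.W, g, 4L, 2L, 1L)
  grads$c2.W <- b2$gW; grads$c2.b <- b2$gb
  g <- lrelu_bwd(b2$gx, cache$h1)
  b1 <- conv_bwd(cache$x, p$c1.W, g, 4L, 2L, 1L)
  grads$c1.W <- b1$gW; grads$c1.b <- b1$gb
  list(gx = 2 * b1$gx[, , 1], grads = grads)
}

#' Score an image with one of the two discriminators
#'
#' Returns the patch-level realness score grid (one score per receptive
#' field) from discriminator A (low-quality domain X) or B (high-quality
#' domain Y). With four stride-2 blocks a 256x256 input yields a 16x16 grid.
#'
#' @param img Grey image matrix in \[0,1\].
#' @param bundle A `usgan_model`.
#' @param which `"A"` or `"B"`.
#' @return Matrix of realness scores.
#' @export
discriminate <- function(img, bundle, which = c("A", "B")) {
  assert_grey(img)
  which <- match.arg(which)
  p <- if (which == "A") bundle$dA else bundle$dB
  disc_fwd(p, bundle$hp, img)$scores
}

# ---- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all four weight sets, the
#' architecture hyperparameters (including the AdaIN stabilizer), an optional
#' training history, and a format version string. A save/load round trip
#' reproduces bit-identical [generate()] outputs.
#'
#' @param bundle A `usgan_model`.
#' @param path Checkpoint file path.
#' @param history Optional loss-history data frame to store alongside.
#' @return `path` invisibly (save); the restored `usgan_model` with attribute
#'   `history` (load).
#' @export
save_checkpoint <- function(bundle, path, history = NULL) {
  stopifnot(inherits(bundle, "usgan_model"))
  saveRDS(list(format = "usgan-ckpt-1", bundle = bundle, history = history),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "usgan-ckpt-1"))
    stop("not a usgan checkpoint: ", path, call. = FALSE)
  bundle <- obj$bundle
  attr(bundle, "history") <- obj$history
  bundle
}

#' @export
print.usgan_model <- function(x, ...) {
  np <- function(p) sum(vapply(p, length, integer(1)))
  cat("Switchable CycleGAN model bundle\n")
  cat(sprintf("  generator: %s channels base, %d AdaIN-modulated layers, %d parameters\n",
              x$hp$base_channels, x$hp$n_adain_layers, np(x$gen)))
  cat(sprintf("  ACG: %d parameters; discriminators A/B: %d each\n",
              np(x$acg), np(x$dA)))
  cat(sprintf("  epsilon %.1e, global skip %s\n", x$hp$epsilon,
              x$hp$global_skip))
  invisible(x)
}
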