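# Shared fixtures and independent brute-force oracles used by the unit and
# acceptance tests. Oracles are written directly from the metric definitions
# (pair enumeration, closed forms) and never call the package's
# implementation paths.

rand_img <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

tiny_bundle <- function(seed = 3) {
  model_bundle(base_channels = 4, n_res_blocks = 2, acg_hidden = 8,
               seed = seed)
}

# CR/CNR by direct mask-indexed arithmetic
oracle_cr <- function(img, fg, bg) 255 * abs(mean(img[fg]) - mean(img[bg]))
oracle_cnr <- function(img, fg, bg) {
  f <- img[fg]; b <- img[bg]
  pv <- function(v) sum((v - mean(v))^2) / length(v)
  abs(mean(f) - mean(b)) / sqrt(pv(f) + pv(b))
}

# GLCM by exhaustive pair enumeration over all pixel pairs
oracle_glcm <- function(img, levels, offset, symmetric) {
  q <- pmin(floor(img * levels), levels - 1)
  h <- nrow(img); w <- ncol(img)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    r2 <- r + offset[1]; c2 <- cc + offset[2]
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      i <- q[r, cc] + 1; j <- q[r2, c2] + 1
      counts[i, j] <- counts[i, j] + 1
      if (symmetric) counts[j, i] <- counts[j, i] + 1
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(G) {
  L <- nrow(G)
  con <- en <- hom <- num <- 0
  mi <- mj <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- G[i + 1, j + 1]
    con <- con + p * (i - j)^2
    en <- en + p^2
    hom <- hom + p / (1 + (i - j)^2)
    mi <- mi + i * p; mj <- mj + j * p
  }
  si2 <- sj2 <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- G[i + 1, j + 1]
    si2 <- si2 + (i - mi)^2 * p
    sj2 <- sj2 + (j - mj)^2 * p
    num <- num + p * (i - mi) * (j - mj)
  }
  corr <- if (si2 == 0 || sj2 == 0) 1 else num / sqrt(si2 * sj2)
  list(contrast = con, correlation = corr, energy = en, homogeneity = hom)
}

# global single-window SSIM written straight from the definition
oracle_ssim <- function(a, b) {
  c1 <- 0.01^2; c2 <- 0.03^2
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  cab <- mean((a - ma) * (b - mb))
  (2 * ma * mb + c1) * (2 * cab + c2) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

# Shannon entropy in bits over 256 fixed-width bins
oracle_entropy <- function(img) {
  bins <- pmin(floor(as.vector(img) * 256), 255)
  p <- table(bins) / length(bins)
  -sum(p * log2(p))
}

oracle_skewness <- function(img) {
  v <- as.vector(img)
  m <- mean(v); s <- sqrt(mean((v - m)^2))
  mean((v - m)^3) / s^3
}

# window-truncated Gaussian blur with mirror boundaries (bilateral limit)
oracle_gauss_window <- function(img, sigma, window) {
  r <- (window - 1) %/% 2
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  k2 <- outer(k1, k1); k2 <- k2 / sum(k2)
  h <- nrow(img); w <- ncol(img)
  rows <- c(rev(seq_len(r) + 1), seq_len(h), h - seq_len(r))
  cols <- c(rev(seq_len(r) + 1), seq_len(w), w - seq_len(r))
  p <- img[rows, cols]
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- sum(k2 * p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

# small paired synthetic evaluation set with ground-truth ROIs
synthetic_eval_set <- function(n, seed, size = 64) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  generate_dataset(n, dir, seed = seed, size = c(size, size), n_lesions = 2,
                   n_vessels = 1)
  xs <- lapply(sprintf("x_%03d.png", seq_len(n)), function(f)
    load_image(file.path(dir, "X", f)))
  ys <- lapply(sprintf("y_%03d.png", seq_len(n)), function(f)
    load_image(file.path(dir, "Y", f)))
  fg <- lapply(sprintf("x_%03d_fg.png", seq_len(n)), function(f)
    usgan:::load_mask(file.path(dir, "masks", f)))
  bg <- lapply(sprintf("x_%03d_bg.png", seq_len(n)), function(f)
    usgan:::load_mask(file.path(dir, "masks", f)))
  fg_y <- lapply(sprintf("y_%03d_fg.png", seq_len(n)), function(f)
    usgan:::load_mask(file.path(dir, "masks", f)))
  bg_y <- lapply(sprintf("y_%03d_bg.png", seq_len(n)), function(f)
    usgan:::load_mask(file.path(dir, "masks", f)))
  list(dir = dir, x = xs, y = ys, fg_x = fg, bg_x = bg, fg_y = fg_y,
       bg_y = bg_y)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
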