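# Quantitative evaluation suite: contrast ratio (CR) and contrast-to-noise
# ratio (CNR) over foreground/background regions of interest, patch-wise
# SSIM, first-order intensity statistics, grey-level co-occurrence matrix
# (GLCM) texture features, and a Frechet distance on pluggable image
# features. CR is reported on the 0-255 intensity scale, first-order
# statistics on the [0,1] scale, entropy in bits.

check_roi <- function(img, fg, bg) {
  if (!identical(dim(fg), dim(img)) || !identical(dim(bg), dim(img)))
    stop("ROI masks must match the image shape", call. = FALSE)
  if (!any(fg) || !any(bg)) stop("empty ROI mask", call. = FALSE)
  if (any(fg & bg)) stop("foreground and background masks overlap",
                         call. = FALSE)
}

#' Contrast ratio
#'
#' Absolute difference between the mean foreground and mean background
#' intensity, on the 0-255 scale. Higher is better for the enhancement task.
#'
#' @param img Grey image matrix in \[0,1\].
#' @param fg_mask,bg_mask Disjoint non-empty logical masks.
#' @return Non-negative scalar.
#' @export
contrast_ratio <- function(img, fg_mask, bg_mask) {
  assert_grey(img)
  check_roi(img, fg_mask, bg_mask)
  255 * abs(mean(img[fg_mask]) - mean(img[bg_mask]))
}

#' Contrast-to-noise ratio
#'
#' `|mean(fg) - mean(bg)| / sqrt(var(fg) + var(bg))` with population
#' variances; dimensionless and invariant to rescaling the whole image.
#'
#' @inheritParams contrast_ratio
#' @return Non-negative scalar; error when both regional variances are zero.
#' @export
contrast_to_noise <- function(img, fg_mask, bg_mask) {
  assert_grey(img)
  check_roi(img, fg_mask, bg_mask)
  if (sum(fg_mask) < 2 || sum(bg_mask) < 2)
    stop("CNR needs at least 2 pixels per region", call. = FALSE)
  f <- img[fg_mask]; b <- img[bg_mask]
  pvar <- function(v) mean((v - mean(v))^2)
  denom <- sqrt(pvar(f) + pvar(b))
  if (denom == 0) stop("CNR undefined: both regional variances are zero",
                       call. = FALSE)
  abs(mean(f) - mean(b)) / denom
}

# single-window SSIM on the unit data range
ssim_window <- function(a, b, c1 = 0.01^2, c2 = 0.03^2) {
  ma <- mean(a); mb <- mean(b)
  va <- mean((a - ma)^2); vb <- mean((b - mb)^2)
  cab <- mean((a - ma) * (b - mb))
  ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

#' Patch-wise structural similarity
#'
#' Standard SSIM (luminance, contrast and structure with the conventional
#' stabilizers on the unit data range) computed on square patches over a
#' stride grid and averaged. With `patch` equal to the whole image this is
#' global single-window SSIM.
#'
#' @param a,b Grey image matrices of identical shape.
#' @param patch Patch side in pixels (<= both image dimensions).
#' @param stride Grid stride in pixels.
#' @return Mean SSIM in \[-1, 1\].
#' @export
patchwise_ssim <- function(a, b, patch = 16, stride = 8) {
  if (!identical(dim(a), dim(b)))
    stop("patchwise_ssim: shape mismatch", call. = FALSE)
  h <- nrow(a); w <- ncol(a)
  if (patch > min(h, w)) stop("patch exceeds image size", call. = FALSE)
  rs <- unique(c(seq(1, h - patch + 1, by = stride), h - patch + 1))
  cs <- unique(c(seq(1, w - patch + 1, by = stride), w - patch + 1))
  vals <- numeric(0)
  for (r in rs) for (cc in cs) {
    ia <- a[r:(r + patch - 1), cc:(cc + patch - 1)]
    ib <- b[r:(r + patch - 1), cc:(cc + patch - 1)]
    vals <- c(vals, ssim_window(ia, ib))
  }
  mean(vals)
}

#' First-order intensity statistics
#'
#' Mean and population standard deviation on the \[0,1\] scale, skewness
#' `E[(v - mu)^3] / sd^3` (0 by convention for constant images), and Shannon
#' entropy in bits over a 256-bin histogram (empty bins skipped).
#'
#' @param img Grey image matrix in \[0,1\].
#' @return Named list `mean`, `std`, `skewness`, `entropy`.
#' @export
first_order_stats <- function(img) {
  assert_grey(img)
  v <- as.vector(img)
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  skew <- if (s == 0) 0 else mean((v - mu)^3) / s^3
  counts <- tabulate(pmin(floor(v * 256), 255) + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(v)
  list(mean = mu, std = s, skewness = skew, entropy = -sum(p * log2(p)))
}

#' Grey-level co-occurrence matrix
#'
#' Quantizes the image into `levels` equal-width bins on \[0,1\], counts
#' co-occurring level pairs at the given `(row, col)` offset, optionally
#' symmetrizes, and normalizes to sum 1.
#'
#' @param img Grey image matrix in \[0,1\].
#' @param levels Number of grey levels (>= 2).
#' @param offset Integer `(row step, col step)` displacement.
#' @param symmetric Count each pair in both directions.
#' @return A `levels x levels` matrix summing to 1, with attributes `levels`,
#'   `offset` and `symmetric`.
#' @export
glcm <- function(img, levels = 64, offset = c(0, 1), symmetric = TRUE) {
  assert_grey(img)
  stopifnot(levels >= 2, length(offset) == 2)
  h <- nrow(img); w <- ncol(img)
  dr <- offset[1]; dc <- offset[2]
  if (abs(dr) >= h || abs(dc) >= w)
    stop("offset larger than image", call. = FALSE)
  q <- matrix(pmin(floor(img * levels), levels - 1L), h, w)
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  from <- q[r1, c1, drop = FALSE]
  to <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(0, levels, levels)
  tab <- table(factor(from, levels = 0:(levels - 1)),
               factor(to, levels = 0:(levels - 1)))
  counts <- counts + unclass(tab)
  if (symmetric) counts <- counts + t(counts)
  G <- counts / sum(counts)
  attr(G, "levels") <- levels
  attr(G, "offset") <- offset
  attr(G, "symmetric") <- symmetric
  G
}

#' GLCM texture features
#'
#' Contrast `sum P(i,j) (i-j)^2`, correlation
#' `sum P(i,j)(i - mu_i)(j - mu_j) / (sd_i sd_j)` (1 by convention when a
#' marginal is degenerate, i.e. a constant image), energy `sum P^2`, and
#' homogeneity `sum P / (1 + (i-j)^2)`, with 0-based level indices.
#'
#' @param G A normalized GLCM from [glcm()].
#' @return Named list `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_features <- function(G) {
  L <- nrow(G)
  i <- matrix(0:(L - 1), L, L)
  j <- t(i)
  pi_ <- rowSums(G); pj_ <- colSums(G)
  mi <- sum((0:(L - 1)) * pi_); mj <- sum((0:(L - 1)) * pj_)
  si <- sqrt(sum((0:(L - 1) - mi)^2 * pi_))
  sj <- sqrt(sum((0:(L - 1) - mj)^2 * pj_))
  corr <- if (si == 0 || sj == 0) 1 else
    sum(G * (i - mi) * (j - mj)) / (si * sj)
  list(contrast = sum(G * (i - j)^2),
       correlation = corr,
       energy = sum(G^2),
       homogeneity = sum(G / (1 + (i - j)^2)))
}

#' Frechet distance between two feature sets
#'
#' `||mu_A - mu_B||^2 + tr(S_A + S_B - 2 (S_A S_B)^(1/2))` with sample
#' covariances and a symmetrized matrix square root; tiny negative
#' eigenvalues from finite precision are clamped to zero, and a small jitter
#' is added to near-singular covariances.
#'
#' @param features_A,features_B Numeric matrices, one feature vector per row
#'   (>= 2 rows each, equal column count).
#' @return Non-negative scalar (0 for identical sets up to 1e-6).
#' @export
frechet_distance <- function(features_A, features_B) {
  A <- as.matrix(features_A); B <- as.matrix(features_B)
  if (ncol(A) != ncol(B))
    stop("feature dimension mismatch", call. = FALSE)
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("need at least 2 feature vectors per set", call. = FALSE)
  muA <- colMeans(A); muB <- colMeans(B)
  SA <- stats::cov(A); SB <- stats::cov(B)
  d <- ncol(A)
  sqrtm_sym <- function(M) {
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  rootA <- sqrtm_sym(SA)
  M <- rootA %*% SB %*% rootA
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) { # near-singular interaction: jitter and retry
    jit <- diag(1e-10, d)
    rootA <- sqrtm_sym(SA + jit)
    M <- rootA %*% (SB + jit) %*% rootA
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  max(0, sum((muA - muB)^2) + sum(diag(SA)) + sum(diag(SB)) - 2 * tr_sqrt)
}

#' Seeded random-convolution feature extractor
#'
#' Returns a deterministic extractor mapping a grey image to a fixed-length
#' feature vector: the image is resized to `input_size`, convolved with
#' `n_filters` seeded random kernels, rectified, and summarized by the mean
#' and standard deviation of each response map. It is the default pluggable
#' extractor for [fid_score()]; a pretrained natural-image network can be
#' plugged in instead to approximate the usual Inception-based protocol.
#'
#' @param n_filters Number of random kernels.
#' @param kernel Kernel side in pixels.
#' @param input_size Square working resolution.
#' @param seed Integer seed fixing the kernels.
#' @return A function `image matrix -> numeric vector` of length
#'   `2 * n_filters`.
#' @export
random_conv_extractor <- function(n_filters = 16, kernel = 5,
                                  input_size = 32, seed = 7) {
  W <- with_seed(seed, matrix(rnorm(kernel * kernel * n_filters, 0,
                                    1 / kernel),
                              kernel * kernel, n_filters))
  force(input_size); force(kernel)
  function(img) {
    assert_grey(img)
    x <- cpp_resize_bilinear(img, input_size, input_size)
    maps <- cpp_conv2d_fwd(array(x, c(input_size, input_size, 1L)), W,
                           numeric(n_filters), kernel, kernel, 1L, 0L)
    maps <- pmax(maps, 0)
    m <- matrix(maps, ncol = n_filters)
    c(colMeans(m), sqrt(pmax(colMeans(m^2) - colMeans(m)^2, 0)))
  }
}

#' Frechet distance between two image sets
#'
#' Applies a feature extractor to both sets and returns the
#' [frechet_distance()] of the resulting feature matrices. Lower means the
#' sets are closer in distribution; identical sets score 0.
#'
#' @param images_A,images_B Lists of grey image matrices (non-empty).
#' @param extractor A function mapping an image to a fixed-length numeric
#'   vector; defaults to [random_conv_extractor()].
#' @return Non-negative scalar.
#' @export
fid_score <- function(images_A, images_B,
                      extractor = random_conv_extractor()) {
  if (!length(images_A) || !length(images_B))
    stop("empty image set", call. = FALSE)
  fa <- t(vapply(images_A, extractor, numeric(length(extractor(
    images_A[[1]])))))
  fb <- t(vapply(images_B, extractor, numeric(ncol(fa))))
  frechet_distance(fa, fb)
}
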