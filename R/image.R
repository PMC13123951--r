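#' @useDynLib usgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- grey-image conventions -------------------------------------------------
# A grey image is a plain numeric matrix (rows = height) with values in [0,1].
# Coordinates are (row, col), origin top-left, 0-based offsets, half-open
# crop windows. Files are 8-bit grey PNG unless stated otherwise.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

assert_grey <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop(sprintf("'%s' must lie in [0,1]", arg), call. = FALSE)
  invisible(img)
}

#' Load a grey-scale image
#'
#' Reads an 8- or 16-bit grey-scale PNG, or a single-frame grey-scale DICOM
#' file, and returns a numeric matrix with values scaled to \[0,1\] using the
#' origin bit depth. RGB PNGs whose channels are identical are collapsed to a
#' single channel; true-colour images are rejected. For DICOM input the stored
#' rescale slope/intercept are applied before scaling, and MONOCHROME1 images
#' are inverted so that bright always means echogenic.
#'
#' @param path Path to a `.png` or DICOM file.
#' @return A numeric matrix in \[0,1\] with attribute `source_path`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- if (is_dicom_file(path)) read_dicom(path) else read_grey_png(path)
  attr(img, "source_path") <- path
  img
}

read_grey_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    nc <- dim(a)[3]
    rgb <- a[, , seq_len(min(nc, 3)), drop = FALSE]
    if (dim(rgb)[3] == 3) {
      if (max(abs(rgb[, , 1] - rgb[, , 2])) > 1e-9 ||
          max(abs(rgb[, , 1] - rgb[, , 3])) > 1e-9)
        stop("true-colour PNG: channels differ, not a grey image",
             call. = FALSE)
    }
    a <- rgb[, , 1]
  }
  clamp01(a)
}

#' Save a grey-scale image as 8-bit PNG
#'
#' Values are quantized as `round(v * 255)`, so a save/load round trip has a
#' maximum absolute error of 1/510.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  assert_grey(img)
  png::writePNG(round(clamp01(img) * 255) / 255, target = path)
  invisible(path)
}

#' Resize and crop a grey image
#'
#' Bilinear-resizes the image so that its short side equals `resize_to`
#' (preserving aspect ratio), then optionally crops a `crop` x `crop` window:
#' a seeded uniform-random window when `seed` is given (training
#' augmentation), the centre window otherwise. A no-op when the dimensions
#' already match.
#'
#' @param img Numeric matrix in \[0,1\].
#' @param resize_to Target short-side length in pixels.
#' @param crop Optional square crop size in pixels; must not exceed
#'   `resize_to`.
#' @param seed Optional integer seed selecting the random crop origin.
#' @return The preprocessed image matrix, clamped to \[0,1\].
#' @export
preprocess <- function(img, resize_to, crop = NULL, seed = NULL) {
  assert_grey(img)
  if (!is.null(crop) && crop > resize_to)
    stop("crop (", crop, ") exceeds resize_to (", resize_to, ")",
         call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  if (min(h, w) != resize_to) {
    s <- resize_to / min(h, w)
    img <- cpp_resize_bilinear(img, max(resize_to, round(h * s)),
                               max(resize_to, round(w * s)))
  }
  if (!is.null(crop)) {
    h <- nrow(img); w <- ncol(img)
    if (crop > min(h, w))
      stop("crop exceeds resized dimension", call. = FALSE)
    if (is.null(seed)) {
      r0 <- (h - crop) %/% 2
      c0 <- (w - crop) %/% 2
    } else {
      old <- get_rng_state()
      on.exit(set_rng_state(old), add = TRUE)
      set.seed(seed)
      r0 <- sample.int(h - crop + 1L, 1L) - 1L
      c0 <- sample.int(w - crop + 1L, 1L) - 1L
    }
    img <- img[(r0 + 1):(r0 + crop), (c0 + 1):(c0 + crop), drop = FALSE]
  }
  clamp01(img)
}

# RNG bookkeeping so seeded helpers never disturb the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  expr
}

# ---- small spatial filters used across modules ------------------------------

pad_reflect <- function(img, k) {
  if (k == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  if (k >= h || k >= w) stop("reflection pad larger than image", call. = FALSE)
  rows <- c(rev(seq_len(k) + 1L), seq_len(h), h - seq_len(k))
  cols <- c(rev(seq_len(k) + 1L), seq_len(w), w - seq_len(k))
  img[rows, cols, drop = FALSE]
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with mirror-reflected boundaries (mean preserving).
blur_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  p <- pad_reflect(img, r)
  p <- conv2_valid(p, matrix(k, ncol = 1))   # vertical
  conv2_valid(p, matrix(k, nrow = 1))        # horizontal
}

# Valid-mode cross-correlation of a single-channel image with a small kernel.
conv2_valid <- function(img, kernel) {
  x <- array(img, c(nrow(img), ncol(img), 1L))
  W <- matrix(as.vector(kernel), ncol = 1L)
  out <- cpp_conv2d_fwd(x, W, 0, nrow(kernel), ncol(kernel), 1L, 0L)
  out[, , 1]
}
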