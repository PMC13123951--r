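# Classical enhancement baselines: an Osher-Rudin style shock filter
# (deblurring/edge sharpening) and a bilateral filter (edge-preserving
# denoising). Both use mirror-reflected boundaries and map [0,1] into [0,1].

#' Shock filter
#'
#' Iterative sharpening `v <- v - dt * sign(Laplacian(smoothed v)) * |grad v|`
#' where the Laplacian is taken on a Gaussian-smoothed copy whose kernel
#' spans the `mask_size` window (sigma = (mask_size - 1) / 6), and the
#' gradient magnitude uses central differences. Constant images are fixed
#' points; `iterations = 0` is the identity.
#'
#' @param img Grey image matrix in \[0,1\].
#' @param mask_size Odd smoothing window side (>= 3).
#' @param iterations Number of update sweeps (>= 0).
#' @param dt Time step of each sweep.
#' @return Filtered grey image matrix in \[0,1\].
#' @export
shock_filter <- function(img, mask_size = 9, iterations = 5, dt = 0.1) {
  assert_grey(img)
  if (mask_size %% 2 == 0 || mask_size < 3)
    stop("mask_size must be odd and >= 3", call. = FALSE)
  if (iterations < 0) stop("iterations must be >= 0", call. = FALSE)
  if (iterations == 0) return(img)
  sigma <- (mask_size - 1) / 6
  lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  v <- img
  for (it in seq_len(iterations)) {
    sm <- blur_gaussian(v, sigma)
    lap <- conv2_valid(pad_reflect(sm, 1L), lap_k)
    p <- pad_reflect(v, 1L)
    h <- nrow(v); w <- ncol(v)
    gr <- (p[3:(h + 2), 2:(w + 1)] - p[1:h, 2:(w + 1)]) / 2
    gc <- (p[2:(h + 1), 3:(w + 2)] - p[2:(h + 1), 1:w]) / 2
    mag <- sqrt(gr^2 + gc^2)
    v <- clamp01(v - dt * sign(lap) * mag)
  }
  v
}

#' Bilateral filter
#'
#' Each output pixel is the normalized weighted mean of its `window` x
#' `window` neighbourhood, with weights the product of a spatial Gaussian
#' (`sigma_spatial`, pixels) and a range Gaussian on the intensity
#' difference (`sigma_range`, intensity units). Weights sum to one per
#' pixel, so outputs stay within the local intensity range; as
#' `sigma_range -> Inf` the filter converges to a plain (window-truncated)
#' Gaussian blur.
#'
#' @param img Grey image matrix in \[0,1\].
#' @param sigma_spatial Spatial standard deviation in pixels (> 0).
#' @param sigma_range Range standard deviation in intensity units (> 0,
#'   `Inf` allowed).
#' @param window Odd window side in pixels.
#' @return Filtered grey image matrix in \[0,1\].
#' @export
bilateral_filter <- function(img, sigma_spatial = 3, sigma_range = 0.1,
                             window = 9) {
  assert_grey(img)
  if (window %% 2 == 0 || window < 3)
    stop("window must be odd and >= 3", call. = FALSE)
  if (sigma_spatial <= 0 || sigma_range <= 0)
    stop("sigmas must be positive", call. = FALSE)
  r <- (window - 1L) %/% 2L
  p <- pad_reflect(img, r)
  h <- nrow(img); w <- ncol(img)
  acc <- matrix(0, h, w)
  norm <- matrix(0, h, w)
  for (dr in -r:r) for (dc in -r:r) {
    shifted <- p[(1 + r + dr):(h + r + dr), (1 + r + dc):(w + r + dc)]
    wgt <- exp(-(dr^2 + dc^2) / (2 * sigma_spatial^2))
    if (is.finite(sigma_range))
      wgt <- wgt * exp(-(shifted - img)^2 / (2 * sigma_range^2))
    acc <- acc + wgt * shifted
    norm <- norm + wgt
  }
  clamp01(acc / norm)
}
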