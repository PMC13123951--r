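# Synthetic B-mode phantom generator: seeded scenes (parenchyma + hypoechoic
# lesions + dark vessels), multiplicative gamma speckle rendering, and a
# parametric degradation that emulates an aged scanner (contrast compression,
# darkening, heavier speckle, blur, near-field reverberation bands). The two
# quality domains used for training are unpaired by construction.

#' Create a synthetic phantom scene
#'
#' Builds the geometric ground truth from which B-mode-like images are
#' rendered: a homogeneous parenchyma, `n_lesions` hypoechoic discs,
#' `n_vessels` dark tubular segments, and disjoint foreground/background
#' masks used by the evaluation metrics. All geometry is drawn from the given
#' seed, so identical arguments give bit-identical scenes. Lesions, vessels
#' and both masks are kept below the top quarter of the image, which is
#' reserved for near-field reverberation artifacts.
#'
#' @param height,width Image size in pixels, at least 64.
#' @param n_lesions,n_vessels Numbers of lesions and vessels (>= 0).
#' @param seed Integer seed.
#' @return An object of class `phantom_scene`.
#' @export
make_scene <- function(height, width, n_lesions = 3, n_vessels = 1, seed = 1) {
  if (height < 64 || width < 64)
    stop("scene must be at least 64x64 pixels", call. = FALSE)
  stopifnot(n_lesions >= 0, n_vessels >= 0)
  with_seed(seed, {
    par_echo <- runif(1, 0.55, 0.65)
    rmax <- min(height, width) / 8
    top <- floor(height / 4)  # reverberation zone: keep structures below it
    lesions <- if (n_lesions > 0) {
      radius <- runif(n_lesions, 5, rmax)
      data.frame(
        row = runif(n_lesions, top + radius + 2, height - radius - 2),
        col = runif(n_lesions, radius + 2, width - radius - 2),
        radius = radius,
        echo = runif(n_lesions, 0.10, 0.30))
    } else {
      data.frame(row = numeric(), col = numeric(), radius = numeric(),
                 echo = numeric())
    }
    vessels <- if (n_vessels > 0) {
      data.frame(
        r0 = runif(n_vessels, top + 4, height - 4),
        c0 = runif(n_vessels, 4, width / 3),
        r1 = runif(n_vessels, top + 4, height - 4),
        c1 = runif(n_vessels, 2 * width / 3, width - 4),
        width = runif(n_vessels, 2, 4))
    } else {
      data.frame(r0 = numeric(), c0 = numeric(), r1 = numeric(),
                 c1 = numeric(), width = numeric())
    }
    scene <- structure(
      list(height = height, width = width,
           parenchyma_echogenicity = par_echo,
           lesions = lesions, vessels = vessels, seed = seed),
      class = "phantom_scene")
    masks <- scene_masks(scene)
    scene$fg_mask <- masks$fg
    scene$bg_mask <- masks$bg
    scene
  })
}

# squared distance from every pixel to a segment (vectorized over the grid)
seg_dist <- function(rows, cols, r0, c0, r1, c1) {
  dr <- r1 - r0; dc <- c1 - c0
  len2 <- dr^2 + dc^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((rows - r0) * dr +
                                              (cols - c0) * dc) / len2))
  sqrt((rows - (r0 + t * dr))^2 + (cols - (c0 + t * dc))^2)
}

scene_masks <- function(scene) {
  h <- scene$height; w <- scene$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  top <- floor(h / 4)
  fg <- matrix(FALSE, h, w)
  clear <- matrix(TRUE, h, w)  # candidate background: away from structures
  for (i in seq_len(nrow(scene$lesions))) {
    L <- scene$lesions[i, ]
    d <- sqrt((rows - L$row)^2 + (cols - L$col)^2)
    fg <- fg | (d <= L$radius)
    clear <- clear & (d > L$radius + 6)
  }
  if (nrow(scene$lesions) == 0) {
    d <- sqrt((rows - 0.62 * h)^2 + (cols - 0.5 * w)^2)
    fg <- d <= min(h, w) / 6
    clear <- clear & (d > min(h, w) / 6 + 6)
  }
  for (i in seq_len(nrow(scene$vessels))) {
    V <- scene$vessels[i, ]
    d <- seg_dist(rows, cols, V$r0, V$c0, V$r1, V$c1)
    fg[d <= V$width / 2] <- FALSE
    clear <- clear & (d > V$width / 2 + 6)
  }
  below <- rows > top & rows <= h - 3 & cols > 3 & cols <= w - 3
  fg <- fg & below
  bg <- clear & below
  if (!any(fg) || !any(bg))
    stop("degenerate scene: empty foreground or background mask",
         call. = FALSE)
  list(fg = fg, bg = bg)
}

# Noise-free echogenicity map implied by the scene geometry.
scene_echo_map <- function(scene) {
  h <- scene$height; w <- scene$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  e <- matrix(scene$parenchyma_echogenicity, h, w)
  for (i in seq_len(nrow(scene$lesions))) {
    L <- scene$lesions[i, ]
    e[(rows - L$row)^2 + (cols - L$col)^2 <= L$radius^2] <- L$echo
  }
  for (i in seq_len(nrow(scene$vessels))) {
    V <- scene$vessels[i, ]
    e[seg_dist(rows, cols, V$r0, V$c0, V$r1, V$c1) <= V$width / 2] <- 0.10
  }
  e
}

#' Render a B-mode-like image from a scene
#'
#' Multiplies the scene's echogenicity map by mean-one multiplicative gamma
#' speckle (shape = `speckle_looks`; fewer looks = grainier), convolves with
#' a Gaussian point-spread function, and clips to \[0,1\]. The speckle is
#' mean preserving: the expected pixel value equals the echogenicity.
#' `speckle_looks = Inf` renders the noise-free map.
#'
#' @param scene A `phantom_scene`.
#' @param speckle_looks Positive number of looks (>= 1), or `Inf`.
#' @param psf_sigma_px Gaussian point-spread sigma in pixels (0 disables).
#' @param seed Integer seed for the speckle draw.
#' @return Grey image matrix in \[0,1\].
#' @export
render_bmode <- function(scene, speckle_looks = 24, psf_sigma_px = 1,
                         seed = 1) {
  stopifnot(inherits(scene, "phantom_scene"), speckle_looks >= 1)
  e <- scene_echo_map(scene)
  img <- if (is.finite(speckle_looks)) {
    noise <- with_seed(seed, matrix(
      rgamma(length(e), shape = speckle_looks, rate = speckle_looks),
      nrow(e), ncol(e)))
    e * noise
  } else e
  if (psf_sigma_px > 0) img <- blur_gaussian(img, psf_sigma_px)
  clamp01(img)
}

#' Degradation parameters for the low-quality domain
#'
#' The identity degradation is `contrast_gain = 1`, `brightness_offset = 0`,
#' `speckle_looks = Inf`, `blur_sigma_px = 0`, `reverb_band_count = 0`.
#' Defaults emulate the clinically described gap: compressed contrast, darker
#' image, heavy speckle, mild blur, and bright near-field reverberation bands.
#'
#' @param contrast_gain Multiplier in (0,1\] on the deviation from mid-grey.
#' @param brightness_offset Additive offset in \[-0.5, 0\].
#' @param speckle_looks Positive looks of extra multiplicative speckle
#'   (`Inf` = none).
#' @param blur_sigma_px Gaussian blur sigma in pixels (>= 0).
#' @param reverb_band_count Number of horizontal bright bands in the top
#'   quarter (>= 0).
#' @param reverb_amplitude Band amplitude in \[0,1\].
#' @param seed Integer seed for the speckle draw.
#' @return An object of class `degrade_params`.
#' @export
degrade_params <- function(contrast_gain = 0.6, brightness_offset = -0.08,
                           speckle_looks = 6, blur_sigma_px = 0.8,
                           reverb_band_count = 3, reverb_amplitude = 0.2,
                           seed = 1) {
  stopifnot(contrast_gain > 0, contrast_gain <= 1,
            brightness_offset >= -0.5, brightness_offset <= 0,
            speckle_looks >= 1, blur_sigma_px >= 0,
            reverb_band_count >= 0,
            reverb_amplitude >= 0, reverb_amplitude <= 1)
  structure(list(contrast_gain = contrast_gain,
                 brightness_offset = brightness_offset,
                 speckle_looks = speckle_looks,
                 blur_sigma_px = blur_sigma_px,
                 reverb_band_count = reverb_band_count,
                 reverb_amplitude = reverb_amplitude,
                 seed = seed),
            class = "degrade_params")
}

#' Degrade a rendered image to the low-quality domain
#'
#' Applies, in order: contrast compression about mid-grey
#' (`0.5 + gain * (v - 0.5)`), a brightness offset, extra multiplicative
#' gamma speckle, Gaussian blur, additive horizontal reverberation bands in
#' the top quarter, and a final clip to \[0,1\]. Identity parameters return
#' the input exactly.
#'
#' @param img Grey image matrix in \[0,1\].
#' @param params A [degrade_params()] object.
#' @return Degraded grey image matrix.
#' @export
degrade <- function(img, params = degrade_params()) {
  assert_grey(img)
  stopifnot(inherits(params, "degrade_params"))
  v <- img
  if (params$contrast_gain != 1)
    v <- 0.5 + params$contrast_gain * (v - 0.5)
  if (params$brightness_offset != 0)
    v <- v + params$brightness_offset
  if (is.finite(params$speckle_looks)) {
    noise <- with_seed(params$seed, matrix(
      rgamma(length(v), shape = params$speckle_looks,
             rate = params$speckle_looks), nrow(v), ncol(v)))
    v <- v * noise
  }
  if (params$blur_sigma_px > 0)
    v <- blur_gaussian(v, params$blur_sigma_px)
  if (params$reverb_band_count > 0) {
    h <- nrow(v)
    top <- h / 4
    centers <- top * seq_len(params$reverb_band_count) /
      (params$reverb_band_count + 1)
    profile <- rep(0, h)
    for (ct in centers)
      profile <- profile + params$reverb_amplitude *
        exp(-(seq_len(h) - ct)^2 / (2 * 1.5^2))
    profile[seq_len(h) > floor(top)] <- 0  # bands live in the near field only
    v <- v + profile  # recycled down columns
  }
  if (identical(v, img)) img else clamp01(v)
}

#' Generate an unpaired two-domain synthetic dataset
#'
#' Writes `n_per_domain` high-quality renders to `Y/` and `n_per_domain`
#' independently seeded, different-scene degraded renders to `X/` (unpaired
#' by construction), plus per-image foreground/background mask PNGs under
#' `masks/` and a YAML manifest. With `paired = TRUE` both domains are
#' rendered from the same scenes — a debugging mode for oracle tests only.
#'
#' @param n_per_domain Number of images per domain (>= 1).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed; every file is derived from it.
#' @param size `c(height, width)` of the images.
#' @param n_lesions,n_vessels Structures per scene.
#' @param degrade_with [degrade_params()] for the low-quality domain.
#' @param hq_looks,hq_psf Speckle looks and point-spread sigma of the
#'   high-quality renders.
#' @param paired Render both domains from identical scenes.
#' @return The manifest, invisibly (also written as `manifest.yaml`).
#' @export
generate_dataset <- function(n_per_domain, out_dir, seed = 1,
                             size = c(128, 128), n_lesions = 3,
                             n_vessels = 1,
                             degrade_with = degrade_params(),
                             hq_looks = 24, hq_psf = 1, paired = FALSE) {
  stopifnot(n_per_domain >= 1)
  dir.create(file.path(out_dir, "X"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "Y"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                    4L * n_per_domain))
  records <- list()
  for (i in seq_len(n_per_domain)) {
    sy <- sub[4 * i - 3]; sx <- if (paired) sy else sub[4 * i - 2]
    ny <- sub[4 * i - 1]; nx <- sub[4 * i]
    scene_y <- make_scene(size[1], size[2], n_lesions, n_vessels, seed = sy)
    img_y <- render_bmode(scene_y, hq_looks, hq_psf, seed = ny)
    fy <- sprintf("y_%03d.png", i)
    save_image(img_y, file.path(out_dir, "Y", fy))
    save_mask(scene_y$fg_mask, file.path(out_dir, "masks",
                                         sprintf("y_%03d_fg.png", i)))
    save_mask(scene_y$bg_mask, file.path(out_dir, "masks",
                                         sprintf("y_%03d_bg.png", i)))
    scene_x <- make_scene(size[1], size[2], n_lesions, n_vessels, seed = sx)
    dp <- degrade_with
    dp$seed <- nx
    img_x <- degrade(render_bmode(scene_x, hq_looks, hq_psf, seed = nx), dp)
    fx <- sprintf("x_%03d.png", i)
    save_image(img_x, file.path(out_dir, "X", fx))
    save_mask(scene_x$fg_mask, file.path(out_dir, "masks",
                                         sprintf("x_%03d_fg.png", i)))
    save_mask(scene_x$bg_mask, file.path(out_dir, "masks",
                                         sprintf("x_%03d_bg.png", i)))
    records[[2 * i - 1]] <- list(file = file.path("Y", fy), domain = "Y",
                                 scene_seed = sy, noise_seed = ny)
    records[[2 * i]] <- list(file = file.path("X", fx), domain = "X",
                             scene_seed = sx, noise_seed = nx)
  }
  manifest <- list(
    package = "usgan", format = 1L, seed = seed,
    n_per_domain = n_per_domain, paired = paired,
    size = as.integer(size),
    degrade = unclass(degrade_with)[setdiff(names(degrade_with), "seed")],
    hq = list(looks = hq_looks, psf = hq_psf),
    images = records)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

save_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                target = path)
  invisible(path)
}

load_mask <- function(path) {
  m <- read_grey_png(path)
  m > 0.5
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom_scene %dx%d: %d lesion(s), %d vessel(s), seed %d\n",
              x$height, x$width, nrow(x$lesions), nrow(x$vessels), x$seed))
  cat(sprintf("  parenchyma echogenicity %.3f; fg %d px, bg %d px\n",
              x$parenchyma_echogenicity, sum(x$fg_mask), sum(x$bg_mask)))
  invisible(x)
}
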