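# Set-level evaluation: one metric-report row per image (CR, CNR, patch-wise
# SSIM against an optional reference set, first-order statistics, GLCM
# features) plus a mean row, written as CSV; optional set-level Frechet
# distance against a second directory.

#' Evaluate a set of images
#'
#' Computes the full metric report for every image in `img_dir`. ROI masks
#' are looked up as `<stem>_fg.png` / `<stem>_bg.png` (0/255 PNGs) in
#' `mask_dir`; when a mask pair is missing, `auto_roi = TRUE` falls back to
#' intensity quartiles (foreground = darkest quartile, background =
#' brightest quartile — the phantom's lesions are hypoechoic), otherwise an
#' ROI error is raised. When `ref_dir` is given, patch-wise SSIM is computed
#' against the same-named reference (pre-enhancement) image.
#'
#' @param img_dir Directory of PNG images (or a named list of matrices).
#' @param ref_dir Optional reference directory (or named list) for SSIM.
#' @param mask_dir Optional directory holding the mask PNGs.
#' @param auto_roi Allow the quartile fallback when masks are missing.
#' @param glcm_levels,glcm_offset Quantization levels and offset of the GLCM.
#' @param patch,stride Patch-wise SSIM grid.
#' @param fid_against Optional directory (or list) of images; adds the
#'   set-level Frechet distance (default extractor) to the mean row.
#' @param out_csv Optional path; the report is written as CSV.
#' @return Data frame with one row per image plus a `"mean"` row.
#' @export
evaluate_set <- function(img_dir, ref_dir = NULL, mask_dir = NULL,
                         auto_roi = is.null(mask_dir), glcm_levels = 64,
                         glcm_offset = c(0, 1), patch = 16, stride = 8,
                         fid_against = NULL, out_csv = NULL) {
  imgs <- load_named(img_dir)
  refs <- if (!is.null(ref_dir)) load_named(ref_dir)
  rows <- list()
  for (nm in names(imgs)) {
    img <- imgs[[nm]]
    roi <- find_roi(nm, img, mask_dir, auto_roi)
    fos <- first_order_stats(img)
    gf <- glcm_features(glcm(img, glcm_levels, glcm_offset))
    ssim <- if (!is.null(refs)) {
      if (is.null(refs[[nm]]))
        stop("no reference image for ", nm, call. = FALSE)
      patchwise_ssim(refs[[nm]], img, patch, stride)
    } else NA_real_
    rows[[nm]] <- data.frame(
      file = nm,
      CR = contrast_ratio(img, roi$fg, roi$bg),
      CNR = contrast_to_noise(img, roi$fg, roi$bg),
      patch_ssim = ssim,
      mean_intensity = fos$mean, std = fos$std, skewness = fos$skewness,
      entropy = fos$entropy,
      glcm_contrast = gf$contrast, glcm_correlation = gf$correlation,
      glcm_energy = gf$energy, glcm_homogeneity = gf$homogeneity)
  }
  report <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  mean_row <- report[1, ]
  mean_row$file <- "mean"
  for (cn in setdiff(names(report), "file"))
    mean_row[[cn]] <- mean(report[[cn]])
  report <- rbind(report, mean_row)
  if (!is.null(fid_against)) {
    report$fid <- NA_real_
    report$fid[nrow(report)] <- fid_score(unname(imgs),
                                          unname(load_named(fid_against)))
  }
  if (!is.null(out_csv))
    utils::write.csv(report, out_csv, row.names = FALSE)
  report
}

load_named <- function(x) {
  if (is.list(x)) {
    if (is.null(names(x))) names(x) <- sprintf("img_%03d", seq_along(x))
    return(lapply(x, assert_grey))
  }
  files <- sort(list.files(x, pattern = "\\.png$", ignore.case = TRUE))
  if (!length(files)) stop("no PNG images in ", x, call. = FALSE)
  imgs <- lapply(files, function(f) load_image(file.path(x, f)))
  names(imgs) <- files
  imgs
}

find_roi <- function(name, img, mask_dir, auto_roi) {
  stem <- sub("\\.png$", "", name, ignore.case = TRUE)
  if (!is.null(mask_dir)) {
    fg_path <- file.path(mask_dir, paste0(stem, "_fg.png"))
    bg_path <- file.path(mask_dir, paste0(stem, "_bg.png"))
    if (file.exists(fg_path) && file.exists(bg_path))
      return(list(fg = load_mask(fg_path), bg = load_mask(bg_path)))
  }
  if (!auto_roi)
    stop("no ROI masks for ", name, " and automatic fallback disabled",
         call. = FALSE)
  q <- stats::quantile(img, c(0.25, 0.75))
  list(fg = img <= q[1], bg = img >= q[2])
}
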