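# Minimal DICOM reader for single-frame uncompressed grey-scale images.
# Scope: little-endian implicit or explicit VR transfer syntaxes, MONOCHROME1
# and MONOCHROME2, 8- or 16-bit unsigned pixels, no sequences of undefined
# length. Anything else is rejected with an explicit error rather than
# guessed. This deliberately covers the archived B-mode export case only.

is_dicom_file <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) return(FALSE)
  if (grepl("\\.dcm$", path, ignore.case = TRUE)) return(TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

dcm_u16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1L])
dcm_u32 <- function(b, i) {
  as.numeric(b[i]) + 256 * as.numeric(b[i + 1L]) +
    65536 * as.numeric(b[i + 2L]) + 16777216 * as.numeric(b[i + 3L])
}

# Parse a run of data elements; returns a named list keyed "gggg,eeee" (hex)
# holding raw values, plus the offset one past the last element read.
dcm_parse <- function(bytes, offset, explicit, stop_group = NULL) {
  out <- list()
  n <- length(bytes)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  i <- offset
  while (i + 7L <= n) {
    grp <- dcm_u16(bytes, i); ele <- dcm_u16(bytes, i + 2L)
    if (!is.null(stop_group) && grp != stop_group) break
    if (explicit || grp == 2L) {
      vr <- rawToChar(bytes[(i + 4L):(i + 5L)])
      if (vr %in% long_vrs) {
        len <- dcm_u32(bytes, i + 8L); hdr <- 12L
      } else {
        len <- dcm_u16(bytes, i + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(bytes, i + 4L); hdr <- 8L
    }
    if (len == 4294967295) # undefined length (sequences, encapsulation)
      stop("unsupported DICOM: undefined-length element", call. = FALSE)
    key <- sprintf("%04x,%04x", grp, ele)
    val_start <- i + hdr
    if (len > 0 && val_start + len - 1L > n)
      stop("corrupt DICOM: element overruns file", call. = FALSE)
    out[[key]] <- if (len > 0)
      bytes[val_start:(val_start + len - 1L)] else raw(0)
    i <- val_start + len
    if (key == "7fe0,0010") break
  }
  list(elements = out, offset = i)
}

dcm_str <- function(el, key, default = NULL) {
  v <- el[[key]]
  if (is.null(v)) return(default)
  trimws(gsub("\\x00", "", rawToChar(v), useBytes = TRUE))
}
dcm_us <- function(el, key, default = NULL) {
  v <- el[[key]]
  if (is.null(v)) return(default)
  dcm_u16(v, 1L)
}

#' Read a single-frame grey-scale DICOM image
#'
#' Supports uncompressed little-endian (implicit or explicit VR) files with
#' one monochrome frame. Rescale slope/intercept are applied, intensities are
#' scaled to \[0,1\] by the stored bit depth, and MONOCHROME1 images are
#' inverted to the bright-is-echogenic convention.
#'
#' @param path Path to a DICOM file.
#' @return Numeric matrix in \[0,1\].
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  offset <- 0L
  explicit <- TRUE
  if (length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM") {
    meta <- dcm_parse(bytes, 133L, explicit = TRUE, stop_group = 2L)
    ts <- dcm_str(meta$elements, "0002,0010", "1.2.840.10008.1.2.1")
    offset <- meta$offset
    if (ts == "1.2.840.10008.1.2") explicit <- FALSE
    else if (ts != "1.2.840.10008.1.2.1")
      stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
  } else {
    offset <- 1L
    explicit <- FALSE
  }
  el <- dcm_parse(bytes, offset, explicit = explicit)$elements

  nframes <- dcm_str(el, "0028,0008", "1")
  if (as.integer(nframes) != 1L)
    stop("unsupported DICOM: multi-frame image (", nframes, " frames)",
         call. = FALSE)
  spp <- dcm_us(el, "0028,0002", 1L)
  if (spp != 1L)
    stop("unsupported DICOM: ", spp, " samples per pixel", call. = FALSE)
  photometric <- dcm_str(el, "0028,0004", "MONOCHROME2")
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stop("unsupported DICOM photometric interpretation: ", photometric,
         call. = FALSE)
  rows <- dcm_us(el, "0028,0010"); cols <- dcm_us(el, "0028,0011")
  bits_alloc <- dcm_us(el, "0028,0100", 8L)
  bits_stored <- dcm_us(el, "0028,0101", bits_alloc)
  pixrep <- dcm_us(el, "0028,0103", 0L)
  if (pixrep != 0L)
    stop("unsupported DICOM: signed pixel data", call. = FALSE)
  if (!bits_alloc %in% c(8L, 16L))
    stop("unsupported DICOM bit depth: ", bits_alloc, call. = FALSE)
  px <- el[["7fe0,0010"]]
  if (is.null(px)) stop("DICOM has no pixel data", call. = FALSE)

  if (bits_alloc == 8L) {
    vals <- as.integer(px[seq_len(rows * cols)])
  } else {
    idx <- seq_len(rows * cols)
    vals <- as.integer(px[2L * idx - 1L]) + 256L * as.integer(px[2L * idx])
  }
  slope <- as.numeric(dcm_str(el, "0028,1053", "1"))
  intercept <- as.numeric(dcm_str(el, "0028,1052", "0"))
  v <- (slope * vals + intercept) / (2^bits_stored - 1)
  img <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  if (photometric == "MONOCHROME1") {
    message("MONOCHROME1 DICOM: inverting to bright-is-echogenic")
    img <- 1 - img
  }
  clamp01(img)
}
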