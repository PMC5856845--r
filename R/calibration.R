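#' Image calibration for a CCM field of view
#'
#' Maps pixel coordinates to physical units. The Heidelberg Retina Tomograph
#' III with the Rostock Corneal Module images a 400 x 400 micrometre field on
#' a 384 x 384 pixel grid, which is the default; other devices or export
#' settings can be described by changing the pitch and field dimensions.
#'
#' @param pixel_pitch_um Edge length of one pixel in micrometres (> 0).
#' @param field_width_px,field_height_px Field dimensions in pixels.
#' @return A `ccm_calibration` object with the supplied fields plus the
#'   derived `field_area_mm2`, the area of the imaged field in square
#'   millimetres used to normalize all per-image endpoints.
#' @examples
#' cal <- calibration()          # HRT III convention
#' cal$field_area_mm2           # 0.16 mm^2
#' @export
calibration <- function(pixel_pitch_um = 400 / 384,
                        field_width_px = 384L,
                        field_height_px = 384L) {
  stopifnot(is.numeric(pixel_pitch_um), length(pixel_pitch_um) == 1L,
            pixel_pitch_um > 0,
            field_width_px >= 1, field_height_px >= 1)
  out <- list(
    pixel_pitch_um = as.numeric(pixel_pitch_um),
    field_width_px = as.integer(field_width_px),
    field_height_px = as.integer(field_height_px)
  )
  out$field_area_mm2 <- (out$field_width_px * out$pixel_pitch_um) *
    (out$field_height_px * out$pixel_pitch_um) / 1e6
  class(out) <- "ccm_calibration"
  out
}

#' @export
print.ccm_calibration <- function(x, ...) {
  cat(sprintf("CCM calibration: %d x %d px, %.4f um/px (%.4f mm^2 field)\n",
              x$field_width_px, x$field_height_px, x$pixel_pitch_um,
              x$field_area_mm2))
  invisible(x)
}

#' Calibrated CCM image
#'
#' Wraps an 8-bit grayscale intensity grid together with its calibration and
#' subject metadata. Intensities are stored as a numeric matrix in 0..255,
#' row-major with the origin at the top-left corner (row 1 = top image row).
#'
#' @param intensities Numeric or integer matrix with values in \[0, 255\].
#' @param calibration A [calibration()] object; its field dimensions must
#'   match `dim(intensities)` (rows = height, columns = width).
#' @param subject_id,eye,visit Optional metadata carried through analysis.
#' @return A `ccm_image` object.
#' @export
ccm_image <- function(intensities, calibration = NULL,
                      subject_id = NA_character_, eye = NA_character_,
                      visit = NA_character_) {
  stopifnot(is.matrix(intensities))
  if (is.null(calibration)) {
    calibration <- calibration(field_width_px = ncol(intensities),
                               field_height_px = nrow(intensities))
  }
  stopifnot(inherits(calibration, "ccm_calibration"))
  if (nrow(intensities) != calibration$field_height_px ||
      ncol(intensities) != calibration$field_width_px) {
    stop("calibration mismatch: image is ", nrow(intensities), "x",
         ncol(intensities), " px but calibration declares ",
         calibration$field_height_px, "x", calibration$field_width_px,
         call. = FALSE)
  }
  if (anyNA(intensities) || min(intensities) < 0 || max(intensities) > 255) {
    stop("intensities must be finite and within [0, 255]", call. = FALSE)
  }
  structure(list(intensities = intensities,
                 calibration = calibration,
                 meta = list(subject_id = subject_id, eye = eye,
                             visit = visit)),
            class = "ccm_image")
}

#' @export
print.ccm_image <- function(x, ...) {
  cat(sprintf("CCM image %dx%d px (subject %s, eye %s, visit %s)\n",
              nrow(x$intensities), ncol(x$intensities),
              x$meta$subject_id, x$meta$eye, x$meta$visit))
  print(x$calibration)
  invisible(x)
}

# Minimal reader for uncompressed BMP rasters (8-bit paletted or 24-bit);
# no R package on the system reads BMP. Returns a matrix in 0..255,
# top-left origin.
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(rawToChar(magic), "BM")) stop("not a BMP file: ", path)
  readBin(con, "raw", 8L)                                   # size + reserved
  offset <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size < 40L) stop("unsupported BMP header")
  width <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  height <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # planes
  bpp <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  compression <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (compression != 0L) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L)) stop("only 8-bit or 24-bit BMP supported")
  flipped <- height > 0
  height <- abs(height)
  seek(con, offset)
  row_bytes <- ((width * bpp / 8 + 3) %/% 4) * 4
  raw_data <- readBin(con, "raw", row_bytes * height)
  img <- matrix(0, nrow = height, ncol = width)
  for (r in seq_len(height)) {
    row <- as.integer(raw_data[((r - 1) * row_bytes + 1):((r - 1) * row_bytes + width * bpp / 8)])
    if (bpp == 24L) {
      row <- matrix(row, nrow = 3)          # BGR triplets
      row <- colMeans(row)
    }
    target <- if (flipped) height - r + 1L else r
    img[target, ] <- row
  }
  img
}

#' Load a grayscale CCM image from disk
#'
#' Reads a TIFF, PNG or uncompressed BMP raster, converts it to an 8-bit
#' 0..255 intensity matrix (multi-channel images are averaged to gray), and
#' attaches the supplied calibration. The raster dimensions must match the
#' calibration's field dimensions.
#'
#' @param path File path; format chosen by extension (`.tif`/`.tiff`,
#'   `.png`, `.bmp`).
#' @param calibration A [calibration()]; defaults to one matching the raster.
#' @inheritParams ccm_image
#' @return A [ccm_image()].
#' @export
load_image <- function(path, calibration = NULL, subject_id = NA_character_,
                       eye = NA_character_, visit = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    bmp = read_bmp(path) / 255,
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img <- round(img * 255)
  ccm_image(img, calibration, subject_id = subject_id, eye = eye,
            visit = visit)
}

#' Write a binary nerve mask as a PNG (0/255)
#'
#' @param mask A [segment_nerves()] result or a 0/1 matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "nerve_mask")) mask$mask else mask
  png::writePNG(m * 1.0, path)
  invisible(path)
}

#' Write a calibrated image as an 8-bit TIFF
#'
#' @param image A [ccm_image()].
#' @param path Output path.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image$intensities / 255, path, bits.per.sample = 8L)
  invisible(path)
}
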