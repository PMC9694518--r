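#' RGB cross-section image
#'
#' An `rgb_image` is an integer array of dimension height x width x 3 with
#' channel intensities in `[0, 255]`, carrying the physical pixel size in
#' micrometers as metadata. Slide scans of FASGA-stained internode sections
#' are typically acquired at 5.17 um per pixel.
#'
#' @param pixels numeric or integer array, height x width x 3, values in
#'   `[0, 255]`.
#' @param pixel_size_um physical edge length of one pixel in micrometers.
#' @return An `rgb_image` object.
#' @export
rgb_image <- function(pixels, pixel_size_um = 5.17) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one pixel", call. = FALSE)
  px <- array(as.integer(round(pixels)), dim = dim(pixels))
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("channel intensities must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar", call. = FALSE)
  structure(px, pixel_size_um = as.numeric(pixel_size_um),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, %.4g um/px\n",
              d[1], d[2], attr(x, "pixel_size_um")))
  invisible(x)
}

pixel_size <- function(image) {
  ps <- attr(image, "pixel_size_um")
  if (is.null(ps)) 5.17 else ps
}

#' Read an RGB image from disk
#'
#' Reads a TIFF, PNG or JPEG raster into an [rgb_image()]. 16-bit inputs are
#' rescaled to `[0, 255]` (integer division by 257) and any alpha channel is
#' dropped. JPEG inputs are accepted with a warning: lossy chroma subsampling
#' degrades the saturation thresholds the segmentation relies on.
#'
#' @param path path to a TIFF/PNG/JPEG file.
#' @param pixel_size_um physical pixel size recorded on the image.
#' @return An [rgb_image()].
#' @export
read_image <- function(path, pixel_size_um = 5.17) {
  if (!file.exists(path))
    stop("input image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
      png = png::readPNG(path),
      jpg = , jpeg = {
        warning("JPEG input '", basename(path),
                "': lossy compression can distort H/S/V thresholds",
                call. = FALSE)
        jpeg::readJPEG(path)
      },
      stop("unsupported image format: ", path, call. = FALSE)
    ),
    error = function(e) stop("cannot read image '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.matrix(raw))
    stop("single-channel image not supported (RGB required): ", path,
         call. = FALSE)
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] < 3L)
    stop("single-channel image not supported (RGB required): ", path,
         call. = FALSE)
  mx <- max(raw)
  px <- if (is.integer(raw) || mx > 1) {
    # integer sample values straight from the file
    if (mx > 255) raw %/% 257L else raw
  } else {
    # [0,1] floats: map to the 0..255 grid; 8-bit data (k/255 = 257k/65535)
    # comes back exactly as k, 16-bit data as floor(v/257)
    round(raw * 65535) %/% 257
  }
  rgb_image(px, pixel_size_um = pixel_size_um)
}

#' Write a label map as a single-channel 16-bit TIFF
#'
#' Background is 0; tissue/group identifiers are stored verbatim so that
#' write-then-read round-trips bit-exactly.
#'
#' @param labels integer matrix of label values in `[0, 65535]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels))
  v <- as.integer(labels)
  if (min(v) < 0L || max(v) > 65535L)
    stop("label values must lie in [0, 65535]", call. = FALSE)
  m <- matrix(v / 65535, nrow(labels), ncol(labels))
  ok <- tryCatch(tiff::writeTIFF(m, path, bits.per.sample = 16),
                 error = function(e) stop("cannot write '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a label map written by [write_label_tiff()]
#'
#' @param path path to a single-channel 16-bit TIFF.
#' @return integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (!is.matrix(m)) stop("not a single-channel label map: ", path,
                          call. = FALSE)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write an RGB image to PNG
#' @param image an [rgb_image()] or height x width x 3 array in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  arr <- unclass(image) / 255
  png::writePNG(arr, path)
  invisible(path)
}
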