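# Contrast enhancement and RGB -> HSV decomposition.
#
# Scanner output of FASGA-stained sections is dark and low in contrast;
# the workflow first doubles all RGB intensities (clipped at 255) and then
# smooths each channel with three passes of a radius-2 circular mean filter
# to suppress acquisition noise before any thresholding.

# 5x5 circular neighborhood of radius 2: the 21 offsets with dx^2+dy^2 <= 5,
# i.e. the radius-2 disc used by standard rank/mean filters.
mean_disc_kernel <- function(radius = 2) {
  r <- seq(-radius, radius)
  k <- outer(r, r, function(i, j) as.numeric(i^2 + j^2 <= radius^2 + 1))
  k / sum(k)
}

filter_channel <- function(m, kernel, passes = 1L) {
  x <- EBImage::Image(m)
  for (i in seq_len(passes)) x <- EBImage::filter2(x, kernel,
                                                   boundary = "replicate")
  EBImage::imageData(x)
}

gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  d <- seq(-r, r)
  g <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Contrast enhancement and smoothing
#'
#' Doubles every channel intensity (clipping at 255), then smooths each
#' channel with `passes` applications of a circular mean filter of the given
#' radius (replicate padding at the borders). Three passes of a radius-2 mean
#' closely approximate a Gaussian blur; `smoothing = "gaussian"` applies a
#' single Gaussian of equivalent variance instead.
#'
#' @param image an [rgb_image()].
#' @param gain intensity multiplier applied before clipping (default 2).
#' @param radius mean-filter radius in pixels.
#' @param passes number of successive mean-filter applications.
#' @param smoothing `"mean"` (iterated circular mean, the default) or
#'   `"gaussian"` (single Gaussian of matched variance).
#' @return An [rgb_image()] with the same dimensions and pixel size.
#' @export
enhance <- function(image, gain = 2, radius = 2, passes = 3L,
                    smoothing = c("mean", "gaussian")) {
  stopifnot(inherits(image, "rgb_image"))
  smoothing <- match.arg(smoothing)
  px <- pmin(unclass(image) * gain, 255)
  out <- array(0, dim = dim(px))
  if (smoothing == "mean") {
    k <- mean_disc_kernel(radius)
    for (ch in 1:3) out[, , ch] <- filter_channel(px[, , ch], k, passes)
  } else {
    k1 <- mean_disc_kernel(radius)
    r <- seq(-radius, radius)
    per_pass_var <- sum(k1 * outer(r^2, rep(1, length(r))))
    k <- gaussian_kernel(sqrt(passes * per_pass_var))
    for (ch in 1:3) out[, , ch] <- filter_channel(px[, , ch], k, 1L)
  }
  rgb_image(pmax(pmin(round(out), 255), 0), pixel_size_um = pixel_size(image))
}

#' HSV decomposition
#'
#' An `hsv_image` holds three planes `h`, `s`, `v` aligned to the source RGB
#' grid, each in `[0, 1]`. Hue is expressed as a fraction of the color circle
#' (degrees / 360); achromatic pixels (s = 0) have h = 0 by convention.
#'
#' @param image an [rgb_image()].
#' @return An `hsv_image`: a list with matrices `h`, `s`, `v` and the pixel
#'   size as attribute.
#' @export
to_hsv <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image)
  px <- unclass(image)
  m <- grDevices::rgb2hsv(
    r = as.vector(px[, , 1]), g = as.vector(px[, , 2]),
    b = as.vector(px[, , 3]), maxColorValue = 255
  )
  out <- list(h = matrix(m[1, ], d[1], d[2]),
              s = matrix(m[2, ], d[1], d[2]),
              v = matrix(m[3, ], d[1], d[2]))
  structure(out, pixel_size_um = pixel_size(image), class = "hsv_image")
}

#' @export
print.hsv_image <- function(x, ...) {
  cat(sprintf("<hsv_image> %d x %d px\n", nrow(x$h), ncol(x$h)))
  invisible(x)
}
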