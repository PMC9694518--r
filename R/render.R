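# Color renderings of label maps.

#' Palette of a catalogue or grouped map
#'
#' @param catalogue a [tissue_catalogue()].
#' @return Named character vector of hex colors keyed by tissue id
#'   (`"0"` = background, white).
#' @export
tissue_palette <- function(catalogue = tissue_catalogue()) {
  stopifnot(inherits(catalogue, "tissue_catalogue"))
  stats::setNames(c("#FFFFFF", catalogue$color_hex),
                  c("0", catalogue$tissue_id))
}

group_palette <- function(scheme) {
  if (scheme == "regions5")
    c("0" = "#FFFFFF", "1" = "#5C4033", "2" = "#8B4513", "3" = "#DAA520",
      "4" = "#1B7A1B", "5" = "#C00000")
  else
    c("0" = "#FFFFFF", "1" = "#8B4513", "2" = "#1B7A1B", "3" = "#C00000",
      "4" = "#2040C0")
}

#' Color-coded rendering of a label map
#'
#' Pure per-label color lookup. With distinct palette entries the rendering
#' is invertible back to the label map.
#'
#' @param map a `tissue_label_map` or `grouped_map`.
#' @param palette named hex color vector keyed by label id; defaults to the
#'   map's catalogue colors (or the built-in group palette).
#' @param pixel_size_um pixel size recorded on the output image.
#' @return An [rgb_image()].
#' @export
colorize <- function(map, palette = NULL, pixel_size_um = 5.17) {
  if (is.null(palette)) {
    palette <- if (inherits(map, "grouped_map"))
      group_palette(attr(map, "scheme"))
    else tissue_palette(attr(map, "catalogue"))
  }
  ids <- sort(unique(as.vector(unclass(map))))
  missing <- setdiff(as.character(ids), names(palette))
  if (length(missing))
    stop("no palette entry for label id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  rgbm <- grDevices::col2rgb(palette)
  key <- match(as.character(as.vector(unclass(map))), names(palette))
  d <- dim(map)
  px <- array(0L, c(d[1], d[2], 3))
  for (ch in 1:3) px[, , ch] <- matrix(rgbm[ch, key], d[1], d[2])
  rgb_image(px, pixel_size_um = pixel_size_um)
}

#' Invert a color rendering back to labels
#'
#' @param image an [rgb_image()] produced by [colorize()].
#' @param palette the palette used for rendering.
#' @return Integer label matrix.
#' @export
uncolorize <- function(image, palette) {
  rgbm <- grDevices::col2rgb(palette)
  keys <- rgbm[1, ] * 65536L + rgbm[2, ] * 256L + rgbm[3, ]
  px <- unclass(image)
  enc <- px[, , 1] * 65536L + px[, , 2] * 256L + px[, , 3]
  idx <- match(as.vector(enc), keys)
  if (anyNA(idx)) stop("image contains colors absent from the palette",
                       call. = FALSE)
  matrix(as.integer(names(palette))[idx], nrow(enc), ncol(enc))
}
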