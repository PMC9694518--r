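# The 15-class pixel typology.
#
# Each pixel falls in one of 3 S ranges (or none) and one of 3 V ranges (or
# none), giving 16 mutually exclusive classes:
#   0        background: S in no range AND V in no range
#   1..3     S-range i only (V in a gap)
#   4..6     V-range j only (S in a gap)
#   7..15    combination classes, id = 6 + 3*(i-1) + j
# Hue plays no role at this stage.

#' Classify pixels by saturation/value ranges
#'
#' Assigns every pixel one of 16 class identifiers (15 pixel types plus
#' background) from its S and V coordinates and a [range_set()]. The class is
#' a pure function of (s, v): 3 classes for pixels whose S lies in a range
#' while V lies in a gap, 3 for the converse, 9 for pixels inside both an S
#' and a V range, and 0 when both coordinates fall in gaps.
#'
#' @param hsv an `hsv_image` from [to_hsv()].
#' @param ranges a [range_set()].
#' @return A `pixel_class_map`: integer matrix with values in `0:15`.
#' @export
classify_pixels <- function(hsv, ranges = range_set()) {
  stopifnot(inherits(hsv, "hsv_image"), inherits(ranges, "range_set"))
  sb <- locate_bin(as.vector(hsv$s), ranges$s_ranges)
  vb <- locate_bin(as.vector(hsv$v), ranges$v_ranges)
  id <- integer(length(sb))
  both <- sb > 0L & vb > 0L
  id[both] <- 6L + 3L * (sb[both] - 1L) + vb[both]
  s_only <- sb > 0L & vb == 0L
  id[s_only] <- sb[s_only]
  v_only <- sb == 0L & vb > 0L
  id[v_only] <- 3L + vb[v_only]
  out <- matrix(id, nrow(hsv$s), ncol(hsv$s))
  structure(out, ranges = ranges, class = c("pixel_class_map", "matrix",
                                            "array"))
}

#' @export
print.pixel_class_map <- function(x, ...) {
  cat(sprintf("<pixel_class_map> %d x %d px, %d non-background classes\n",
              nrow(x), ncol(x), length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}

#' Binary mask of selected pixel classes
#'
#' @param map a `pixel_class_map` from [classify_pixels()].
#' @param ids integer vector of class identifiers in `0:15`.
#' @return Logical matrix, `TRUE` where the pixel class is in `ids`.
#' @export
class_mask <- function(map, ids) {
  stopifnot(inherits(map, "pixel_class_map"))
  ids <- as.integer(ids)
  if (length(ids) && (anyNA(ids) || any(ids < 0L) || any(ids > 15L)))
    stop("class ids must lie in 0:15", call. = FALSE)
  matrix(as.vector(map) %in% ids, nrow(map), ncol(map))
}

# All class ids whose S bin is `i` (the S-only class plus its 3 combos).
s_family <- function(i) c(i, 6L + 3L * (i - 1L) + 1:3)

# All class ids whose V bin is `j`.
v_family <- function(j) c(3L + j, 6L + 3L * (0:2) + j)
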