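# The fixed S/V/H threshold scheme.
#
# Three saturation ranges and three value ranges, identical for every image,
# drive the whole pixel typology; two hue intervals later refine the
# medullary parenchyma. All thresholds live on the [0,1] HSV scale.
#
# Interval convention: within each dimension the ranges are taken half-open,
# [low, high), except the last one which is closed, [low, high]. Printed
# range boundaries that abut (0.26 ends one S range and starts the next)
# therefore send the boundary value to the upper range, while the printed
# gaps in V (0.65-0.66 and 0.93-0.95) are real gaps: pixels falling there
# belong to no V range.

#' Threshold ranges for pixel classification
#'
#' Builds the set of saturation, value and hue intervals used throughout the
#' segmentation. Defaults are the published, image-independent thresholds:
#' S ranges `[0.05,0.26) [0.26,0.78) [0.78,1]`, V ranges
#' `[0.42,0.65) [0.66,0.93) [0.95,1]`, the "red" hue interval
#' `[0.005,0.09)` and the "blue" hue interval `[0.51,0.91)`.
#'
#' @param s_ranges 3x2 matrix of saturation intervals (rows ordered,
#'   non-overlapping, within `[0,1]`).
#' @param v_ranges 3x2 matrix of value intervals, same constraints.
#' @param h_red length-2 red hue interval used to split MT1/MT4.
#' @param h_blue length-2 blue hue interval used to split MT2/MT5.
#' @return A `range_set` object.
#' @export
range_set <- function(s_ranges = rbind(c(0.05, 0.26),
                                       c(0.26, 0.78),
                                       c(0.78, 1.00)),
                      v_ranges = rbind(c(0.42, 0.65),
                                       c(0.66, 0.93),
                                       c(0.95, 1.00)),
                      h_red  = c(0.005, 0.09),
                      h_blue = c(0.51, 0.91)) {
  s_ranges <- as.matrix(s_ranges)
  v_ranges <- as.matrix(v_ranges)
  check_ranges <- function(m, what) {
    if (nrow(m) != 3L || ncol(m) != 2L)
      stop(what, " must be a 3x2 matrix of intervals", call. = FALSE)
    if (any(m < 0) || any(m > 1))
      stop(what, " must lie within [0, 1]", call. = FALSE)
    if (any(m[, 1] >= m[, 2]))
      stop(what, " intervals must satisfy low < high", call. = FALSE)
    if (any(diff(as.vector(t(m))) < 0))
      stop(what, " intervals must be ordered and non-overlapping",
           call. = FALSE)
  }
  check_ranges(s_ranges, "s_ranges")
  check_ranges(v_ranges, "v_ranges")
  check_iv <- function(x, what) {
    if (length(x) != 2L || x[1] >= x[2] || any(x < 0) || any(x > 1))
      stop(what, " must be an increasing interval within [0, 1]",
           call. = FALSE)
  }
  check_iv(h_red, "h_red")
  check_iv(h_blue, "h_blue")
  structure(list(s_ranges = unname(s_ranges), v_ranges = unname(v_ranges),
                 h_red = unname(h_red), h_blue = unname(h_blue)),
            class = "range_set")
}

# Locate values in the 3 ordered intervals of one dimension.
# Returns 0 (no interval) or the 1-based interval index. Intervals are
# [low, high) except the last, which is [low, high].
locate_bin <- function(x, ranges) {
  bin <- integer(length(x))
  n <- nrow(ranges)
  for (k in seq_len(n)) {
    hit <- x >= ranges[k, 1] &
      (x < ranges[k, 2] | (k == n & x <= ranges[k, 2]))
    bin[hit] <- k
  }
  bin
}

# Half-open membership test for the hue split intervals.
in_interval <- function(x, iv) x >= iv[1] & x < iv[2]
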