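# Validation utilities for comparing segmentations against ground truth.

label_boundary <- function(lab) {
  d <- dim(lab)
  (lab != rbind(lab[-1, , drop = FALSE], lab[d[1], , drop = FALSE])) |
    (lab != cbind(lab[, -1, drop = FALSE], lab[, d[2], drop = FALSE]))
}

#' Pixel agreement outside boundary bands
#'
#' Fraction of pixels where two label maps agree, evaluated away from the
#' reference map's label boundaries: a band of `exclude_boundary` pixels
#' around every boundary is left out, since smoothing mixes colors there and
#' no segmentation of a discrete grid can be held to sub-band accuracy.
#'
#' @param truth reference label map (integer or logical matrix).
#' @param pred predicted label map, same shape.
#' @param exclude_boundary half-width (px) of the excluded boundary band.
#' @param mask optional logical matrix restricting the evaluation (default:
#'   non-zero pixels of `truth`).
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(truth, pred, exclude_boundary = 3, mask = NULL) {
  truth <- unclass(truth)
  pred <- unclass(pred)
  stopifnot(all(dim(truth) == dim(pred)))
  if (is.null(mask)) mask <- truth != 0
  sel <- mask
  if (exclude_boundary > 0) {
    bnd <- label_boundary(truth)
    near <- mask_dilate(bnd, exclude_boundary)
    sel <- sel & !near
  }
  if (!any(sel)) return(NA_real_)
  mean(pred[sel] == truth[sel])
}
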