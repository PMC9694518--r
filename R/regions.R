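# Automatic derivation of the spatial region masks.
#
# The whole spatialization rests on one observation: pixels with S in the
# lowest range (0.05-0.26) are dense inside the dark rind and inside the
# vascular bundles, and sparse elsewhere. A local density map of that
# selection, thresholded at 0.5, yields connected structures; the ones
# touching the outer border of the section form the dark rind, interior
# blobs of plausible size are bundles, and the remainder splits into light
# rind (a band hugging the dark rind from inside) and medullary pith.

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

cc_label <- function(mask) {
  EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
}

# Fill background components fully enclosed by `mask` whose area does not
# exceed `max_area`; larger enclosed holes (e.g. the hollow center of a
# miscanthus stem, or the pith inside the rind ring) are preserved.
fill_small_holes <- function(mask, max_area) {
  comp <- cc_label(!mask)
  if (max(comp) == 0) return(mask)
  border_ids <- unique(c(comp[1, ], comp[nrow(comp), ],
                         comp[, 1], comp[, ncol(comp)]))
  sizes <- tabulate(comp[comp > 0], nbins = max(comp))
  fill <- setdiff(which(sizes > 0 & sizes <= max_area), border_ids)
  if (length(fill)) mask[comp %in% fill] <- TRUE
  mask
}

mask_closing <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::imageData(EBImage::closing(EBImage::Image(mask * 1),
                                      disc_brush(radius))) > 0.5
}

mask_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1),
                                    disc_brush(radius))) > 0.5
}

mask_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1),
                                     disc_brush(radius))) > 0.5
}

largest_component <- function(mask) {
  comp <- cc_label(mask)
  if (max(comp) == 0) return(mask & FALSE)
  sizes <- tabulate(comp[comp > 0], nbins = max(comp))
  comp == which.max(sizes)
}

#' Morphology parameters for region derivation
#'
#' All constants of the region-mask procedure, named and configurable but
#' with image-independent defaults (no per-image tuning). Pixel units assume
#' the nominal 5.17 um/px resolution.
#'
#' @param density_radius radius (px) of the circular mean filter measuring
#'   local low-saturation pixel density.
#' @param density_threshold density fraction above which a pixel belongs to a
#'   dense (rind or bundle) structure.
#' @param min_bundle_area,max_bundle_area connected-component area bounds
#'   (px) for a dense interior blob to count as a vascular bundle.
#' @param rind_band_width width (px) of the border band used both to decide
#'   which dense structures touch the section outline and to carve the light
#'   rind band off the pith.
#' @param closing_radius radius (px) of the morphological closing applied to
#'   the section mask.
#' @param rind_closing_radius radius (px) of the closing applied to the
#'   dark-rind mask; large enough to seal the low-density corridors around
#'   rind-embedded bundles so that they are absorbed into the rind.
#' @param bundle_dilation blur compensation (px) applied to accepted bundle
#'   blobs: the smoothing stage mixes colors over a ~3 px half-width, which
#'   erodes the low-S support of a bundle by about that margin; the accepted
#'   blob is dilated back by the same amount (then hole-filled), so that the
#'   sclerenchyma caps at the bundle poles stay inside the mask.
#' @param section_hole_min_area enclosed background components larger than
#'   this (px) are treated as true biological holes and stay out of the
#'   section mask; smaller ones are filled.
#' @return A `region_params` list.
#' @export
region_params <- function(density_radius = 15,
                          density_threshold = 0.5,
                          min_bundle_area = 50,
                          max_bundle_area = 20000,
                          rind_band_width = 10,
                          closing_radius = 2,
                          rind_closing_radius = 5,
                          bundle_dilation = 3,
                          section_hole_min_area = 500) {
  stopifnot(density_radius >= 1, density_threshold > 0,
            density_threshold <= 1,
            min_bundle_area >= 0, max_bundle_area > min_bundle_area,
            rind_band_width >= 1)
  structure(list(density_radius = density_radius,
                 density_threshold = density_threshold,
                 min_bundle_area = min_bundle_area,
                 max_bundle_area = max_bundle_area,
                 rind_band_width = rind_band_width,
                 closing_radius = closing_radius,
                 rind_closing_radius = rind_closing_radius,
                 bundle_dilation = bundle_dilation,
                 section_hole_min_area = section_hole_min_area),
            class = "region_params")
}

#' Whole-section mask
#'
#' Foreground pixels are all classified pixels except background (class 0)
#' and the bright unsaturated class (V in the top range with S in no range),
#' which corresponds to the white slide background and glare. The foreground
#' is closed, the largest connected component is kept, and enclosed holes are
#' filled unless they exceed `section_hole_min_area` (true biological holes,
#' e.g. hollow internodes, stay open).
#'
#' @param class_map a `pixel_class_map`.
#' @param params a [region_params()].
#' @param image_name used in error messages.
#' @return Logical matrix: the section mask.
#' @export
build_section_mask <- function(class_map, params = region_params(),
                               image_name = "image") {
  stopifnot(inherits(class_map, "pixel_class_map"))
  fg <- !(class_map == 0L | class_map == 6L)
  if (!any(fg))
    stop("no section detected in ", image_name, call. = FALSE)
  fg <- mask_closing(fg, params$closing_radius)
  fg <- largest_component(fg)
  fill_small_holes(fg, params$section_hole_min_area)
}

#' Region masks: dark rind, bundles, light rind, pith
#'
#' Derives the four mutually exclusive regions that partition the section:
#' \enumerate{
#'   \item low-S mask: pixels whose saturation lies in the lowest S range,
#'     restricted to the section;
#'   \item local density of that mask by a circular mean filter of radius
#'     `density_radius`; dense = density at or above `density_threshold`;
#'   \item dark rind: dense connected components touching the outer border
#'     band of the section (width `rind_band_width`), closed and with
#'     enclosed holes up to `max_bundle_area` filled (rind-embedded bundles
#'     belong to the dark rind);
#'   \item bundles: remaining dense components with area within
#'     `[min_bundle_area, max_bundle_area]`, each hole-filled; dense
#'     components adjacent to the dark rind are absorbed into it;
#'   \item the remainder splits into pith (largest connected component after
#'     removing a band of width `rind_band_width` inward from the dark rind)
#'     and light rind (everything else).
#' }
#'
#' @param class_map a `pixel_class_map`.
#' @param section logical section mask from [build_section_mask()].
#' @param params a [region_params()].
#' @return A `region_mask_set`: list of logical matrices `section`,
#'   `dark_rind`, `bundles`, `light_rind`, `pith`, plus the parameters used.
#' @export
build_region_masks <- function(class_map, section, params = region_params()) {
  stopifnot(inherits(class_map, "pixel_class_map"), is.matrix(section))
  if (!any(section)) stop("empty section mask", call. = FALSE)

  low_s <- class_mask(class_map, s_family(1L)) & section
  dens <- filter_channel(low_s * 1, mean_disc_kernel(params$density_radius))
  dense <- (dens >= params$density_threshold) & section

  outer_band <- section & !mask_erode(section, params$rind_band_width)
  dcomp <- cc_label(dense)
  ncomp <- max(dcomp)
  dark_rind <- section & FALSE
  bundles <- section & FALSE
  if (ncomp > 0) {
    # The density threshold erodes structures whose boundary is convex (the
    # local mean falls below 0.5 before the true outline), so dense
    # components serve as markers only: each is grown back to its connected
    # component in the closed low-S support, which follows the true
    # structure outline. High-S inclusions (rind-embedded bundle
    # sclerenchyma, cap poles inside bundles) become enclosed holes of the
    # support and are filled.
    support <- mask_closing(low_s, params$closing_radius) & section
    scomp <- cc_label(support | dense)
    touching <- sort(unique(dcomp[outer_band & dcomp > 0]))
    if (length(touching)) {
      rind_marker <- matrix(dcomp %in% touching, nrow(dcomp), ncol(dcomp))
      rind_sids <- sort(unique(scomp[rind_marker & scomp > 0]))
      dark_rind <- matrix(scomp %in% rind_sids, nrow(scomp), ncol(scomp))
      dark_rind <- mask_closing(dark_rind, params$rind_closing_radius) &
        section
      dark_rind <- fill_small_holes(dark_rind, params$max_bundle_area)
    }
    rest_ids <- setdiff(seq_len(ncomp), if (length(touching)) touching
                        else integer())
    if (length(rest_ids)) {
      near_rind <- mask_dilate(dark_rind, 1)
      marker <- matrix(dcomp %in% rest_ids, nrow(dcomp), ncol(dcomp)) &
        !dark_rind
      sel_ids <- sort(unique(scomp[marker & scomp > 0]))
      for (id in sel_ids) {
        blob <- scomp == id & !dark_rind
        if (!any(blob)) next
        blob <- fill_small_holes(blob, params$max_bundle_area)
        if (any(blob & near_rind)) {
          dark_rind <- dark_rind | blob   # rind-adjacent blob: absorb
        } else {
          sz <- sum(blob)
          if (sz >= params$min_bundle_area && sz <= params$max_bundle_area) {
            blob <- mask_dilate(blob, params$bundle_dilation) & section &
              !dark_rind
            bundles <- bundles |
              fill_small_holes(blob, params$max_bundle_area)
          }
        }
      }
      bundles <- bundles & section & !dark_rind
    }
  }

  remainder <- section & !dark_rind & !bundles
  if (!any(dark_rind)) {
    warning("no dark rind detected; whole remainder treated as pith",
            call. = FALSE)
    pith <- remainder
    light_rind <- remainder & FALSE
  } else {
    inner <- remainder & !mask_dilate(dark_rind, params$rind_band_width)
    if (any(inner)) {
      pith <- largest_component(inner) & remainder
      light_rind <- remainder & !pith
    } else {
      pith <- remainder
      light_rind <- remainder & FALSE
    }
  }

  structure(list(section = section, dark_rind = dark_rind, bundles = bundles,
                 light_rind = light_rind, pith = pith, params = params),
            class = "region_mask_set")
}

#' @export
print.region_mask_set <- function(x, ...) {
  cat("<region_mask_set>\n")
  for (nm in c("section", "dark_rind", "bundles", "light_rind", "pith"))
    cat(sprintf("  %-10s %d px\n", nm, sum(x[[nm]])))
  invisible(x)
}
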