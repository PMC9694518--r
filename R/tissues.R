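# Combining pixel class and spatial region into named tissues.

# Lookup table: for one region, a vector mapping class id 0..15 to the
# pre-split representative tissue_id (the 'a' variant for hue-split pairs).
region_class_lookup <- function(catalogue, region) {
  idx <- which(catalogue$region == region)
  ps <- presplit_name(catalogue$name[idx], catalogue$hue_rule[idx])
  lut <- rep(NA_integer_, 16L)
  for (nm in unique(ps)) {
    members <- idx[ps == nm]
    rep_id <- catalogue$tissue_id[members[1]]   # 'a' variant listed first
    for (cl in catalogue$class_ids[[members[1]]])
      lut[cl + 1L] <- rep_id
  }
  if (anyNA(lut[2:16]))
    stop("catalogue does not cover all pixel classes in region ", region,
         call. = FALSE)
  if (is.na(lut[1])) lut[1] <- lut[which(!is.na(lut))[1]]
  lut
}

#' Assign tissues from pixel class and region membership
#'
#' Maps every section pixel to a tissue: the pixel's spatial region (dark
#' rind, bundles, light rind or pith) selects the tissue family, and its
#' pixel class selects the named tissue within the family. The result is the
#' pre-split map: the hue-split medullary pairs (MT1, MT2, MT4, MT5) are
#' still represented by a single provisional label each (36 distinct
#' assignable names); apply [split_medullary_by_hue()] to obtain the final
#' 40-type map.
#'
#' @param class_map a `pixel_class_map`.
#' @param regions a `region_mask_set` from [build_region_masks()].
#' @param catalogue a [tissue_catalogue()].
#' @return A `tissue_label_map`: integer matrix, 0 on background and the
#'   tissue id elsewhere, with the catalogue attached and `hue_split = FALSE`.
#' @export
assign_tissues <- function(class_map, regions, catalogue = tissue_catalogue()) {
  stopifnot(inherits(class_map, "pixel_class_map"),
            inherits(regions, "region_mask_set"),
            inherits(catalogue, "tissue_catalogue"))
  labels <- matrix(0L, nrow(class_map), ncol(class_map))
  for (reg in c("dark_rind", "bundles", "light_rind", "pith")) {
    lut <- region_class_lookup(catalogue, reg)
    sel <- regions[[reg]]
    labels[sel] <- lut[class_map[sel] + 1L]
  }
  structure(labels, catalogue = catalogue, hue_split = FALSE,
            ranges = attr(class_map, "ranges"),
            class = c("tissue_label_map", "matrix", "array"))
}

#' Hue split of the medullary parenchyma
#'
#' Refines the lignified medullary tissues MT1 and MT4: pixels with hue in
#' the red interval (default `[0.005, 0.09)`) become the `a` variants, all
#' others the `b` variants. Symmetrically, the poorly lignified MT2 and MT5
#' split on the blue interval (default `[0.51, 0.91)`). MT3 and MT6-MT10 are
#' untouched. This raises the number of assignable names from 36 to 40.
#'
#' @param map a pre-split `tissue_label_map` from [assign_tissues()].
#' @param h hue plane of the source image (matrix in `[0, 1]`).
#' @param ranges a [range_set()] supplying `h_red` and `h_blue`.
#' @return The final `tissue_label_map` with `hue_split = TRUE`.
#' @export
split_medullary_by_hue <- function(map, h, ranges = range_set()) {
  stopifnot(inherits(map, "tissue_label_map"), is.matrix(h))
  if (isTRUE(attr(map, "hue_split")))
    stop("map is already hue-split", call. = FALSE)
  catalogue <- attr(map, "catalogue")
  labels <- unclass(map)
  for (rule in c("red_in", "blue_in")) {
    iv <- if (rule == "red_in") ranges$h_red else ranges$h_blue
    a_rows <- which(catalogue$hue_rule == rule)
    for (ai in a_rows) {
      a_id <- catalogue$tissue_id[ai]
      b_name <- sub("a$", "b", catalogue$name[ai])
      b_id <- catalogue$tissue_id[catalogue$name == b_name]
      sel <- labels == a_id & !in_interval(h, iv)
      labels[sel] <- b_id
    }
  }
  structure(labels, catalogue = catalogue, hue_split = TRUE,
            ranges = attr(map, "ranges"),
            class = c("tissue_label_map", "matrix", "array"))
}

#' @export
print.tissue_label_map <- function(x, ...) {
  cat(sprintf("<tissue_label_map> %d x %d px, %s, %d tissues present\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "hue_split"))) "hue-split (40 types)"
              else "pre-split (36 types)",
              length(setdiff(unique(as.vector(x)), 0L))))
  invisible(x)
}
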