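# Per-tissue area quantification and region groupings.

# Percentage base of each tissue family: rind percentages (%RT) pool the
# epidermal, dark-rind and light-rind families; bundle (%BT) and medullary
# (%MT) percentages stay within their own family.
pct_region_of_family <- c(ET = "rind", DRT = "rind", LRT = "rind",
                          BT = "bundles", MT = "medullary")

#' Per-tissue area table
#'
#' Counts pixels of each of the 40 tissues, converts to physical area and
#' expresses each tissue as a percentage of its reference region: medullary
#' tissues as %MT, bundle tissues as %BT, and epidermal/dark-rind/light-rind
#' tissues jointly as %RT. Every catalogue tissue gets a row (zero counts
#' included), in catalogue order.
#'
#' @param map a hue-split `tissue_label_map`.
#' @param pixel_size_um physical pixel edge length in micrometers.
#' @return A `tissue_area_table` tibble with columns `tissue_id`, `name`,
#'   `family`, `region`, `pct_region`, `pixel_count`, `area_um2`,
#'   `pct_of_region`.
#' @export
tissue_areas <- function(map, pixel_size_um = 5.17) {
  stopifnot(inherits(map, "tissue_label_map"))
  if (!isTRUE(attr(map, "hue_split")))
    stop("apply split_medullary_by_hue() before quantification",
         call. = FALSE)
  catalogue <- attr(map, "catalogue")
  counts <- tabulate(unclass(map)[unclass(map) > 0L], nbins = 40L)
  pctreg <- pct_region_of_family[catalogue$family]
  totals <- tapply(counts, pctreg, sum)[pctreg]
  pct <- ifelse(totals > 0, 100 * counts / totals, 0)
  if (any(totals == 0))
    warning("region(s) with zero pixels: ",
            paste(unique(pctreg[totals == 0]), collapse = ", "),
            "; their tissues get pct_of_region = 0", call. = FALSE)
  out <- tibble::tibble(
    tissue_id = catalogue$tissue_id,
    name = catalogue$name,
    family = catalogue$family,
    region = catalogue$region,
    pct_region = unname(pctreg),
    pixel_count = counts[catalogue$tissue_id],
    area_um2 = counts[catalogue$tissue_id] * pixel_size_um^2,
    pct_of_region = as.numeric(pct[catalogue$tissue_id])
  )
  class(out) <- c("tissue_area_table", class(out))
  out
}

group_schemes <- c("regions5", "legland4")

#' Grouped region maps
#'
#' Collapses the 40-type map into one of two coarser views:
#' \describe{
#'   \item{`regions5`}{the five tissue families: epidermis (ET), dark rind
#'     (DRT), light rind (LRT), bundles (BT), medullary (MT).}
#'   \item{`legland4`}{rind = ET+DRT+LRT; bundles = BT; lignified medullary =
#'     MT1a/b + MT4a/b; low-lignified medullary = MT2a/b + MT5a/b. The
#'     remaining medullary tissues (MT3, MT6-MT10) are not named by the
#'     grouping's definition and go to `mt_rest` (default
#'     `"low_lignified_medullary"`).}
#' }
#'
#' @param map a hue-split `tissue_label_map`.
#' @param scheme `"regions5"` or `"legland4"`.
#' @param mt_rest destination of MT3/MT6-MT10 under `legland4`.
#' @return A `grouped_map`: integer matrix with a `legend` attribute mapping
#'   group ids to names (background = 0).
#' @export
group_tissues <- function(map, scheme = c("regions5", "legland4"),
                          mt_rest = c("low_lignified_medullary",
                                      "lignified_medullary")) {
  stopifnot(inherits(map, "tissue_label_map"))
  scheme <- match.arg(scheme)
  mt_rest <- match.arg(mt_rest)
  if (!isTRUE(attr(map, "hue_split")))
    stop("apply split_medullary_by_hue() before grouping", call. = FALSE)
  catalogue <- attr(map, "catalogue")
  if (scheme == "regions5") {
    legend <- c(epidermis = 1L, dark_rind = 2L, light_rind = 3L,
                bundles = 4L, medullary = 5L)
    fam_group <- c(ET = "epidermis", DRT = "dark_rind", LRT = "light_rind",
                   BT = "bundles", MT = "medullary")
    gid <- legend[fam_group[catalogue$family]]
  } else {
    legend <- c(rind = 1L, bundles = 2L, lignified_medullary = 3L,
                low_lignified_medullary = 4L)
    base <- presplit_name(catalogue$name, catalogue$hue_rule)
    grp <- ifelse(catalogue$family %in% c("ET", "DRT", "LRT"), "rind",
           ifelse(catalogue$family == "BT", "bundles",
           ifelse(base %in% c("MT1", "MT4"), "lignified_medullary",
           ifelse(base %in% c("MT2", "MT5"), "low_lignified_medullary",
                  mt_rest))))
    gid <- legend[grp]
  }
  lut <- c(0L, as.integer(gid[order(catalogue$tissue_id)]))
  labels <- matrix(lut[unclass(map) + 1L], nrow(map), ncol(map))
  structure(labels, scheme = scheme, legend = legend,
            class = c("grouped_map", "matrix", "array"))
}

#' @export
print.grouped_map <- function(x, ...) {
  cat(sprintf("<grouped_map> %s, %d x %d px\n", attr(x, "scheme"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Areas of a grouped map
#'
#' @param map a `grouped_map`.
#' @param pixel_size_um physical pixel edge length in micrometers.
#' @return A tibble with `group`, `pixel_count`, `area_um2`, `pct_of_section`.
#' @export
grouped_areas <- function(map, pixel_size_um = 5.17) {
  stopifnot(inherits(map, "grouped_map"))
  legend <- attr(map, "legend")
  counts <- tabulate(unclass(map)[unclass(map) > 0L],
                     nbins = max(legend))[legend]
  counts[is.na(counts)] <- 0L
  total <- sum(counts)
  tibble::tibble(
    group = names(legend),
    pixel_count = as.integer(counts),
    area_um2 = counts * pixel_size_um^2,
    pct_of_section = if (total > 0) 100 * counts / total else rep(0,
                                                                  length(counts))
  )
}
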