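# The 40-tissue taxonomy.
#
# Tissue names combine a region family with a pixel-class set:
#   ET1-ET2    epidermal tissues        (dark rind mask)
#   DRT1-DRT9  dark rind tissues        (dark rind mask)
#   LRT1-LRT10 light rind tissues       (light rind mask)
#   BT1-BT5    bundle tissues           (bundles mask)
#   MT1-MT10   medullary tissues        (pith mask), of which MT1, MT2, MT4
#              and MT5 are split by hue into a/b variants: 14 pith names,
#              40 names in total (36 before the hue split).
#
# The per-tissue pixel-class assignments order names by staining signal:
# within each family, low numbers take the strongly red-stained (high S)
# classes that mark lignified walls, with MT1/MT4 lignified and MT2/MT5
# poorly lignified, DRT8/DRT9 the sclerenchyma of rind-embedded bundles,
# BT1/BT4 the sclerenchyma poles, BT2 bundle parenchyma and BT5 phloem. The
# mapping is fully overridable through a catalogue CSV (see
# [read_tissue_catalogue()]), so users holding a reference assignment table
# can reproduce it exactly. Class id 0 (both S and V in threshold gaps)
# occurs inside the section only as rare noise/boundary pixels and is folded
# into the darkest tissue of each region.

# Pixel-class sets shared by the light-rind and medullary families; the two
# families use identical S/V definitions and differ only by spatial mask.
mt_like_classes <- list(
  `1`  = c(13L),
  `2`  = c(9L),
  `3`  = c(1L),
  `4`  = c(14L),
  `5`  = c(8L),
  `6`  = c(2L),
  `7`  = c(3L),
  `8`  = c(0L, 4L, 7L),
  `9`  = c(5L, 10L, 11L),
  `10` = c(6L, 12L, 15L)
)

default_catalogue_rows <- function() {
  row <- function(name, family, region, classes, hue_rule, color) {
    list(name = name, family = family, region = region,
         class_ids = list(classes), hue_rule = hue_rule, color_hex = color)
  }
  dr <- "dark_rind"
  rows <- list(
    row("ET1", "ET", dr, c(13L), NA, "#3B2F2F"),
    row("ET2", "ET", dr, c(7L),  NA, "#5C4033"),
    row("DRT1", "DRT", dr, c(0L, 1L), NA, "#7B3F00"),
    row("DRT2", "DRT", dr, c(2L),     NA, "#8B4513"),
    row("DRT3", "DRT", dr, c(3L),     NA, "#A0522D"),
    row("DRT4", "DRT", dr, c(4L),     NA, "#B87333"),
    row("DRT5", "DRT", dr, c(5L, 6L), NA, "#C08040"),
    row("DRT6", "DRT", dr, c(8L, 9L), NA, "#96613D"),
    row("DRT7", "DRT", dr, c(10L),    NA, "#6E3A07"),
    row("DRT8", "DRT", dr, c(11L, 12L), NA, "#D2691E"),
    row("DRT9", "DRT", dr, c(14L, 15L), NA, "#803000")
  )
  lrt_cols <- c("#FFD700", "#F0E68C", "#EEDC82", "#DAA520", "#BDB76B",
                "#E6C200", "#C9B037", "#B8A038", "#9F8F36", "#8C7B26")
  for (i in 1:10)
    rows <- c(rows, list(row(paste0("LRT", i), "LRT", "light_rind",
                             mt_like_classes[[as.character(i)]], NA,
                             lrt_cols[i])))
  rows <- c(rows, list(
    row("BT1", "BT", "bundles", c(13L, 14L),        NA, "#004D00"),
    row("BT2", "BT", "bundles", c(1L, 2L, 5L, 11L), NA, "#1B7A1B"),
    row("BT3", "BT", "bundles", c(0L, 4L, 7L, 10L), NA, "#2EB82E"),
    row("BT4", "BT", "bundles", c(3L, 15L),         NA, "#66CC66"),
    row("BT5", "BT", "bundles", c(6L, 8L, 9L, 12L), NA, "#A3E0A3")
  ))
  mt_cols <- c(MT1a = "#8B0000", MT1b = "#C00000",
               MT2a = "#00008B", MT2b = "#2040C0",
               MT3 = "#B06080",
               MT4a = "#E03030", MT4b = "#FF6347",
               MT5a = "#4169E1", MT5b = "#87A9FF",
               MT6 = "#D8BFD8", MT7 = "#9932CC", MT8 = "#505050",
               MT9 = "#808080", MT10 = "#C0C0C0")
  hue_rules <- c(MT1a = "red_in", MT1b = "red_out",
                 MT2a = "blue_in", MT2b = "blue_out",
                 MT4a = "red_in", MT4b = "red_out",
                 MT5a = "blue_in", MT5b = "blue_out")
  base_of <- function(nm) sub("[ab]$", "", nm)
  for (nm in names(mt_cols)) {
    base <- sub("^MT", "", base_of(nm))
    rows <- c(rows, list(row(nm, "MT", "pith",
                             mt_like_classes[[base]],
                             if (nm %in% names(hue_rules)) hue_rules[[nm]]
                             else NA,
                             mt_cols[[nm]])))
  }
  rows
}

#' The tissue catalogue
#'
#' Returns the catalogue of the 40 tissue types as a tibble with one row per
#' final tissue name: `tissue_id` (stable integer used in label maps),
#' `name`, `family` (ET/DRT/LRT/BT/MT), `region` (the spatial mask the tissue
#' lives in), `class_ids` (list column of source pixel classes), `hue_rule`
#' (`NA`, or `red_in`/`red_out`/`blue_in`/`blue_out` for the hue-split
#' medullary variants) and `color_hex` (display color).
#'
#' @param rows internal; pre-built row list (used by the CSV loader).
#' @return A `tissue_catalogue` tibble with 40 rows.
#' @export
tissue_catalogue <- function(rows = default_catalogue_rows()) {
  cat_df <- tibble::tibble(
    tissue_id = seq_along(rows),
    name = vapply(rows, function(r) r$name, character(1)),
    family = vapply(rows, function(r) r$family, character(1)),
    region = vapply(rows, function(r) r$region, character(1)),
    class_ids = lapply(rows, function(r) sort(unique(as.integer(
      r$class_ids[[1]])))),
    hue_rule = vapply(rows, function(r)
      if (is.na(r$hue_rule[1])) NA_character_ else r$hue_rule, character(1)),
    color_hex = vapply(rows, function(r) toupper(r$color_hex), character(1))
  )
  validate_catalogue(cat_df)
  class(cat_df) <- c("tissue_catalogue", class(cat_df))
  cat_df
}

# Pre-split name: MT1a/MT1b -> MT1 etc.; all other names unchanged.
presplit_name <- function(name, hue_rule) {
  ifelse(is.na(hue_rule), name, sub("[ab]$", "", name))
}

validate_catalogue <- function(cat_df) {
  if (nrow(cat_df) != 40L)
    stop("catalogue must have exactly 40 tissues, got ", nrow(cat_df),
         call. = FALSE)
  census <- table(cat_df$family)
  want <- c(ET = 2L, DRT = 9L, LRT = 10L, BT = 5L, MT = 14L)
  for (f in names(want))
    if (is.na(census[f]) || census[f] != want[f])
      stop("catalogue census violated: need ", want[f], " ", f,
           " tissues", call. = FALSE)
  if (anyDuplicated(cat_df$name))
    stop("duplicate tissue names in catalogue", call. = FALSE)
  if (anyDuplicated(cat_df$color_hex))
    stop("display colors must be distinct", call. = FALSE)
  bad_rule <- !is.na(cat_df$hue_rule) &
    !cat_df$hue_rule %in% c("red_in", "red_out", "blue_in", "blue_out")
  if (any(bad_rule)) stop("invalid hue_rule entries", call. = FALSE)
  reg_of_fam <- c(ET = "dark_rind", DRT = "dark_rind", LRT = "light_rind",
                  BT = "bundles", MT = "pith")
  if (any(cat_df$region != reg_of_fam[cat_df$family]))
    stop("tissue region must match its family's spatial mask", call. = FALSE)
  # pre-split names: class sets disjoint and jointly covering classes 1..15
  # within every region
  ps <- presplit_name(cat_df$name, cat_df$hue_rule)
  for (reg in unique(cat_df$region)) {
    idx <- which(cat_df$region == reg)
    per_ps <- split(idx, ps[idx])
    sets <- lapply(per_ps, function(i) {
      u <- unique(unlist(cat_df$class_ids[i]))
      # hue-split variants must share one class set
      for (j in i)
        if (!setequal(cat_df$class_ids[[j]], u))
          stop("hue-split variants of ", ps[i[1]],
               " must share one pixel-class set", call. = FALSE)
      u
    })
    all_ids <- unlist(sets)
    if (anyDuplicated(all_ids))
      stop("pixel classes assigned to multiple tissues in region ", reg,
           call. = FALSE)
    if (!all(1:15 %in% all_ids))
      stop("pixel classes not fully covered in region ", reg, call. = FALSE)
    if (!all(all_ids %in% 0:15))
      stop("invalid pixel-class ids in region ", reg, call. = FALSE)
  }
  n_presplit <- length(unique(ps))
  if (n_presplit != 36L)
    stop("catalogue must define 36 pre-split tissue names, got ",
         n_presplit, call. = FALSE)
  invisible(cat_df)
}

#' Read a tissue catalogue from CSV
#'
#' The CSV must have columns `tissue_name`, `region`
#' (dark_rind/light_rind/bundles/pith), `class_ids` ("+"-separated pixel
#' class ids) and `color_hex`. Family and hue rules are inferred from the
#' names (ET/DRT/LRT/BT/MT prefix; trailing a/b on MT1/MT2/MT4/MT5 variants).
#' The census invariants (2 ET, 9 DRT, 10 LRT, 5 BT, 14 MT; 36 pre-split
#' names; per-region class coverage) are enforced on load.
#'
#' @param path CSV file path.
#' @return A `tissue_catalogue` tibble.
#' @export
read_tissue_catalogue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tissue_name", "region", "class_ids", "color_hex")
  if (!all(need %in% names(df)))
    stop("catalogue CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  fam <- sub("^(ET|DRT|LRT|BT|MT).*$", "\\1", df$tissue_name)
  rule <- rep(NA_character_, nrow(df))
  split_base <- c("MT1", "MT2", "MT4", "MT5")
  is_a <- df$tissue_name %in% paste0(split_base, "a")
  is_b <- df$tissue_name %in% paste0(split_base, "b")
  red <- df$tissue_name %in% c("MT1a", "MT1b", "MT4a", "MT4b")
  rule[is_a] <- ifelse(red[is_a], "red_in", "blue_in")
  rule[is_b] <- ifelse(red[is_b], "red_out", "blue_out")
  rows <- lapply(seq_len(nrow(df)), function(i) {
    list(name = df$tissue_name[i], family = fam[i], region = df$region[i],
         class_ids = list(as.integer(strsplit(df$class_ids[i],
                                              "+", fixed = TRUE)[[1]])),
         hue_rule = rule[i], color_hex = df$color_hex[i])
  })
  tissue_catalogue(rows)
}

#' Write a tissue catalogue to CSV
#'
#' Inverse of [read_tissue_catalogue()].
#'
#' @param catalogue a `tissue_catalogue`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tissue_catalogue <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "tissue_catalogue"))
  out <- data.frame(
    tissue_name = catalogue$name,
    region = catalogue$region,
    class_ids = vapply(catalogue$class_ids, paste, character(1),
                       collapse = "+"),
    color_hex = catalogue$color_hex,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
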