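test_that("the default catalogue satisfies the published census", {
  cat40 <- tissue_catalogue()
  expect_equal(nrow(cat40), 40)
  fam <- table(cat40$family)
  expect_equal(as.integer(fam[c("ET", "DRT", "LRT", "BT", "MT")]),
               c(2, 9, 10, 5, 14))
  # 19 rind tissues (DRT + LRT), 14 pith, 5 bundle, 2 epidermis
  expect_equal(sum(cat40$family %in% c("DRT", "LRT")), 19)
  ps <- unique(fasgaseg:::presplit_name(cat40$name, cat40$hue_rule))
  expect_length(ps, 36)
  expect_true(all(cat40$tissue_id == seq_len(40)))
})

test_that("every pixel class resolves to exactly one tissue in every region", {
  cat40 <- tissue_catalogue()
  for (reg in c("dark_rind", "bundles", "light_rind", "pith")) {
    lut <- fasgaseg:::region_class_lookup(cat40, reg)
    expect_length(lut, 16)
    expect_false(anyNA(lut))
    # each class maps into the region's own family
    fams <- cat40$family[match(lut, cat40$tissue_id)]
    ok <- switch(reg, dark_rind = c("ET", "DRT"), bundles = "BT",
                 light_rind = "LRT", pith = "MT")
    expect_true(all(fams %in% ok))
  }
})

test_that("assign_tissues respects region membership and pixel class", {
  cat40 <- tissue_catalogue()
  # class map running over all 16 classes, one region active at a time
  cm <- structure(matrix(rep(0:15, 4), 8, 8), ranges = range_set(),
                  class = c("pixel_class_map", "matrix", "array"))
  on_mask <- matrix(TRUE, 8, 8)
  off <- matrix(FALSE, 8, 8)
  for (reg in c("dark_rind", "bundles", "light_rind", "pith")) {
    masks <- list(section = on_mask, dark_rind = off, bundles = off,
                  light_rind = off, pith = off)
    masks[[reg]] <- on_mask
    regions <- structure(c(masks, list(params = NULL)),
                         class = "region_mask_set")
    labs <- assign_tissues(cm, regions, cat40)
    expect_true(all(labs > 0L))
    expect_true(all(cat40$region[match(as.vector(labs),
                                       cat40$tissue_id)] == reg))
  }
})

test_that("the hue split follows its interval oracle over a full sweep", {
  cat40 <- tissue_catalogue()
  h <- matrix(seq(0, 1, by = 0.001), nrow = 1)
  id_of <- function(nm) cat40$tissue_id[cat40$name == nm]
  for (base in c("MT1", "MT2", "MT4", "MT5")) {
    pre <- make_tissue_map(matrix(id_of(paste0(base, "a")), 1, ncol(h)),
                           hue_split = FALSE)
    post <- split_medullary_by_hue(pre, h)
    iv <- if (base %in% c("MT1", "MT4")) c(0.005, 0.09) else c(0.51, 0.91)
    in_iv <- h >= iv[1] & h < iv[2]
    expect_identical(as.integer(post) == id_of(paste0(base, "a")),
                     as.vector(in_iv))
    expect_true(all(as.integer(post)[!in_iv] == id_of(paste0(base, "b"))))
  }
})

test_that("documented hue-split examples hold", {
  cat40 <- tissue_catalogue()
  id_of <- function(nm) cat40$tissue_id[cat40$name == nm]
  pre <- make_tissue_map(matrix(c(id_of("MT1a"), id_of("MT2a"),
                                  id_of("MT1a")), 1, 3),
                         hue_split = FALSE)
  post <- split_medullary_by_hue(pre, matrix(c(0.05, 0.7, 0.5), 1, 3))
  expect_identical(as.integer(post),
                   c(id_of("MT1a"), id_of("MT2a"), id_of("MT1b")))
  expect_error(split_medullary_by_hue(post, matrix(0.5, 1, 3)),
               "already hue-split")
})

test_that("hue-split variants partition their parent tissue on a phantom", {
  seg <- small_segmentation()
  cat40 <- tissue_catalogue()
  pre <- assign_tissues(seg$class_map, seg$regions, cat40)
  post <- split_medullary_by_hue(pre, seg$hsv$h)
  id_of <- function(nm) cat40$tissue_id[cat40$name == nm]
  for (base in c("MT1", "MT2", "MT4", "MT5")) {
    parent <- as.vector(pre) == id_of(paste0(base, "a"))
    child <- as.vector(post) %in% c(id_of(paste0(base, "a")),
                                    id_of(paste0(base, "b")))
    expect_identical(child, parent)
  }
  # non-split tissues unchanged
  untouched <- !as.vector(pre) %in% cat40$tissue_id[!is.na(cat40$hue_rule)]
  expect_identical(as.vector(post)[untouched], as.vector(pre)[untouched])
})

test_that("final labels stay within their region's family", {
  seg <- small_segmentation()
  cat40 <- tissue_catalogue()
  fam_of <- function(ids) cat40$family[match(ids, cat40$tissue_id)]
  tm <- unclass(seg$tissue_map)
  expect_true(all(fam_of(tm[seg$regions$dark_rind]) %in% c("ET", "DRT")))
  expect_true(all(fam_of(tm[seg$regions$bundles]) == "BT"))
  expect_true(all(fam_of(tm[seg$regions$light_rind]) == "LRT"))
  expect_true(all(fam_of(tm[seg$regions$pith]) == "MT"))
  expect_true(all(tm[!seg$regions$section] == 0L))
  expect_true(all(tm[seg$regions$section] > 0L))
})

test_that("catalogue CSV round-trips and invalid catalogues are rejected", {
  cat40 <- tissue_catalogue()
  f <- tempfile(fileext = ".csv")
  write_tissue_catalogue(cat40, f)
  back <- read_tissue_catalogue(f)
  expect_equal(back$name, cat40$name)
  expect_equal(back$region, cat40$region)
  expect_equal(back$class_ids, cat40$class_ids)
  expect_equal(back$hue_rule, cat40$hue_rule)

  df <- read.csv(f)
  drop <- df[-1, ]                       # 39 tissues
  f2 <- tempfile(fileext = ".csv")
  write.csv(drop, f2, row.names = FALSE)
  expect_error(read_tissue_catalogue(f2), "40")

  dup <- df
  dup$class_ids[dup$tissue_name == "ET2"] <- "7+13"  # 13 already ET1's
  f3 <- tempfile(fileext = ".csv")
  write.csv(dup, f3, row.names = FALSE)
  expect_error(read_tissue_catalogue(f3), "multiple")

  gap <- df
  gap$class_ids[gap$tissue_name == "ET1"] <- "12"    # 13 now uncovered
  f4 <- tempfile(fileext = ".csv")
  write.csv(gap, f4, row.names = FALSE)
  expect_error(read_tissue_catalogue(f4), "covered|multiple")
})
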