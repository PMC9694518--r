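test_that("section mask recovers the phantom disk, keeping true holes open", {
  ph <- small_phantom()
  seg <- small_segmentation()
  # agreement with the ground-truth disk outside a 2 px boundary band
  agree <- label_agreement(ph$region_truth$section * 1L,
                           seg$regions$section * 1L,
                           exclude_boundary = 2,
                           mask = matrix(TRUE, 320, 320))
  expect_gte(agree, 0.999)

  hole <- generate_phantom(small_spec(seed = 5, n_pith_bundles = 0,
                                      hole_radius = 57))
  hseg <- suppressWarnings(segment_image(hole$image))
  expect_gte(sum(!hole$region_truth$section & unclass(hole$tissue_truth) == 0L),
             pi * 54^2)  # the hole really is in the truth
  cx <- (320 + 1) / 2
  d <- as.matrix(expand.grid(r = 1:320, c = 1:320))
  inside_hole <- matrix(sqrt((d[, 1] - cx)^2 + (d[, 2] - cx)^2) <= 53,
                        320, 320)
  expect_lt(mean(hseg$regions$section[inside_hole]), 0.01)
})

test_that("an all-white image yields a 'no section detected' error", {
  white <- rgb_image(array(255L, c(64, 64, 3)))
  expect_error(segment_image(white, image_name = "blank.png"),
               "no section detected in blank.png")
})

test_that("region masks partition the section exhaustively and exclusively", {
  for (seed in c(7, 11)) {
    rg <- small_segmentation(seed)$regions
    combined <- rg$dark_rind + rg$bundles + rg$light_rind + rg$pith
    expect_true(all(combined[rg$section] == 1L))
    expect_true(all(combined[!rg$section] == 0L))
  }
})

test_that("region masks agree with phantom ground truth away from boundaries", {
  for (seed in c(7, 11)) {
    ph <- small_phantom(seed)
    rg <- small_segmentation(seed)$regions
    for (nm in c("dark_rind", "bundles", "light_rind", "pith")) {
      recall <- label_agreement(ph$region_truth[[nm]] * 1L, rg[[nm]] * 1L,
                                exclude_boundary = 3,
                                mask = ph$region_truth[[nm]])
      expect_gte(recall, 0.9)
    }
  }
})

test_that("planted bundles are recovered individually", {
  ph <- small_phantom()
  rg <- small_segmentation()$regions
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(
    rg$bundles * 1)))
  expect_equal(max(comp), ph$spec$n_pith_bundles)
  tcomp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(
    ph$region_truth$bundles * 1)))
  for (k in seq_len(max(tcomp))) {
    ctr <- round(colMeans(which(tcomp == k, arr.ind = TRUE)))
    expect_true(rg$bundles[ctr[1], ctr[2]])
  }
})

test_that("a section without interior low-S blobs yields empty bundles", {
  ph <- generate_phantom(small_spec(seed = 9, n_pith_bundles = 0,
                                    n_rind_bundles = 0))
  seg <- suppressWarnings(segment_image(ph$image))
  expect_false(any(seg$regions$bundles))
  expect_equal(nrow(seg$areas), 40)  # quantification still runs
})

test_that("raising the density threshold never grows the dark rind", {
  seg <- small_segmentation()
  cm <- seg$class_map
  section <- seg$regions$section
  lo <- build_region_masks(cm, section, region_params(density_threshold = 0.5))
  hi <- build_region_masks(cm, section, region_params(density_threshold = 0.7))
  expect_true(all(lo$dark_rind[hi$dark_rind]))
})

test_that("pith bundle placement does not affect the dark rind", {
  a <- generate_phantom(small_spec(seed = 13, n_pith_bundles = 3))
  b <- generate_phantom(small_spec(seed = 13, n_pith_bundles = 2))
  sa <- segment_image(a$image)
  sb <- segment_image(b$image)
  expect_identical(sa$regions$dark_rind, sb$regions$dark_rind)
})

test_that("a section with no dense border structure falls back to pith", {
  # uniform mid-range tissue: no low-S pixels at all -> no dark rind
  px <- array(0L, c(120, 120, 3))
  cx <- 60.5
  disk <- outer(1:120, 1:120, function(i, j) (i - cx)^2 + (j - cx)^2 <= 45^2)
  target <- grDevices::col2rgb(grDevices::hsv(0.1, 0.52, 0.795))
  for (ch in 1:3) {
    plane <- matrix(255L, 120, 120)
    plane[disk] <- as.integer(round(target[ch] / 2))
    px[, , ch] <- plane
  }
  img <- rgb_image(px)
  w <- capture_warnings(seg <- segment_image(img))
  expect_match(w, "no dark rind", all = FALSE)
  expect_false(any(seg$regions$dark_rind))
  expect_false(any(seg$regions$light_rind))
  expect_true(any(seg$regions$pith))
})
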