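test_that("a single-tissue region takes 100% of its region area", {
  cat40 <- tissue_catalogue()
  id <- cat40$tissue_id[cat40$name == "MT3"]
  m <- make_tissue_map(matrix(c(rep(0L, 10), rep(id, 54)), 8, 8))
  tab <- suppressWarnings(tissue_areas(m, pixel_size_um = 2))
  expect_equal(tab$pct_of_region[tab$name == "MT3"], 100)
  expect_equal(tab$pixel_count[tab$name == "MT3"], 54L)
  expect_equal(tab$area_um2[tab$name == "MT3"], 54 * 4)
  expect_true(all(tab$pixel_count[tab$name != "MT3"] == 0L))
})

test_that("tissue areas conserve section pixels and percentages sum to 100", {
  seg <- small_segmentation()
  tab <- seg$areas
  expect_equal(sum(tab$pixel_count), sum(seg$regions$section))
  expect_equal(tab$area_um2, tab$pixel_count * 5.17^2)
  for (reg in c("rind", "bundles", "medullary")) {
    expect_equal(sum(tab$pct_of_region[tab$pct_region == reg]), 100,
                 tolerance = 1e-9)
  }
})

test_that("an empty map quantifies to all zeros with a warning", {
  m <- make_tissue_map(matrix(0L, 6, 6))
  expect_warning(tab <- tissue_areas(m), "zero pixels")
  expect_true(all(tab$pixel_count == 0L))
  expect_true(all(tab$pct_of_region == 0))
  expect_equal(nrow(tab), 40)
})

test_that("a planted 30/70 medullary split is recovered within 2 points", {
  ph <- split_phantom()
  seg <- split_segmentation()
  truth <- unclass(ph$tissue_truth)
  tab <- seg$areas
  # planted lignified core (MT1a) vs poorly lignified band (MT2a), as the
  # split between the two planted tissues (hue variants pooled)
  planted_split <- 100 * sum(truth == 27L) / sum(truth %in% c(27L, 29L))
  got_mt1 <- sum(tab$pct_of_region[tab$name %in% c("MT1a", "MT1b")])
  got_mt2 <- sum(tab$pct_of_region[tab$name %in% c("MT2a", "MT2b")])
  got_split <- 100 * got_mt1 / (got_mt1 + got_mt2)
  expect_lt(abs(got_split - planted_split), 2)
  expect_lt(abs(got_split - 30), 2)  # the nominal planted geometry
})

test_that("grouping schemes collapse families as documented", {
  seg <- small_segmentation()
  tm <- seg$tissue_map
  g5 <- group_tissues(tm, "regions5")
  expect_identical(sort(names(attr(g5, "legend"))),
                   sort(c("epidermis", "dark_rind", "light_rind", "bundles",
                          "medullary")))
  g4 <- group_tissues(tm, "legland4")
  expect_identical(sort(names(attr(g4, "legend"))),
                   sort(c("rind", "bundles", "lignified_medullary",
                          "low_lignified_medullary")))
  expect_error(group_tissues(tm, "regions7"))

  # pure MT1a map -> all medullary pixels lignified under legland4
  id <- tissue_catalogue()$tissue_id[tissue_catalogue()$name == "MT1a"]
  pure <- make_tissue_map(matrix(id, 5, 5))
  gp <- group_tissues(pure, "legland4")
  expect_true(all(gp == attr(gp, "legend")[["lignified_medullary"]]))

  # MT3 placement switch
  id3 <- tissue_catalogue()$tissue_id[tissue_catalogue()$name == "MT3"]
  m3 <- make_tissue_map(matrix(id3, 3, 3))
  low <- group_tissues(m3, "legland4")
  expect_true(all(low == attr(low, "legend")[["low_lignified_medullary"]]))
  lig <- group_tissues(m3, "legland4", mt_rest = "lignified_medullary")
  expect_true(all(lig == attr(lig, "legend")[["lignified_medullary"]]))
})

test_that("grouping commutes with counting", {
  seg <- small_segmentation()
  cat40 <- tissue_catalogue()
  tab <- seg$areas
  for (scheme in c("regions5", "legland4")) {
    g <- group_tissues(seg$tissue_map, scheme)
    ga <- grouped_areas(g)
    for (k in seq_len(nrow(ga))) {
      gname <- ga$group[k]
      if (scheme == "regions5") {
        fam <- c(epidermis = "ET", dark_rind = "DRT", light_rind = "LRT",
                 bundles = "BT", medullary = "MT")[[gname]]
        members <- cat40$name[cat40$family == fam]
      } else {
        base <- fasgaseg:::presplit_name(cat40$name, cat40$hue_rule)
        members <- switch(gname,
          rind = cat40$name[cat40$family %in% c("ET", "DRT", "LRT")],
          bundles = cat40$name[cat40$family == "BT"],
          lignified_medullary = cat40$name[base %in% c("MT1", "MT4")],
          low_lignified_medullary = cat40$name[
            cat40$family == "MT" & !base %in% c("MT1", "MT4")])
      }
      expect_identical(ga$pixel_count[k],
                       sum(tab$pixel_count[tab$name %in% members]))
    }
  }
})

test_that("lignified vs low-lignified areas match the planted annuli", {
  ph <- split_phantom()
  seg <- split_segmentation()
  truth <- unclass(ph$tissue_truth)
  g4 <- group_tissues(seg$tissue_map, "legland4")
  ga <- grouped_areas(g4)
  # planted: core = MT1a (lignified), blue band = MT2a (low-lignified);
  # areas compared as shares of the medullary region (the workflow's %MT)
  planted_lig <- sum(truth == 27L)
  planted_low <- sum(truth == 29L)
  planted_share <- 100 * planted_lig / (planted_lig + planted_low)
  got_lig <- ga$pixel_count[ga$group == "lignified_medullary"]
  got_low <- ga$pixel_count[ga$group == "low_lignified_medullary"]
  got_share <- 100 * got_lig / (got_lig + got_low)
  expect_lt(abs(got_share - planted_share), 3)
})
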