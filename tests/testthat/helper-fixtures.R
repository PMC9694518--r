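# Shared fixtures: small phantoms sized for fast tests, cached per run.

.fixtures <- new.env(parent = emptyenv())

small_spec <- function(seed = 7, noise_sd = 0, n_pith_bundles = 3,
                       n_rind_bundles = 3, hole_radius = 0, ...) {
  phantom_spec(image_size = 320, section_radius = 148,
               epidermis_width = 5, dark_rind_width = 26,
               light_rind_width = 10, n_rind_bundles = n_rind_bundles,
               n_pith_bundles = n_pith_bundles,
               bundle_radius_range = c(16, 20),
               pith_blue_band_width = 40, hole_radius = hole_radius,
               noise_sd = noise_sd, seed = seed, ...)
}

small_phantom <- function(seed = 7, noise_sd = 0, ...) {
  key <- paste0("ph_", seed, "_", noise_sd, "_",
                paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_phantom(small_spec(seed, noise_sd, ...))
  .fixtures[[key]]
}

small_segmentation <- function(seed = 7, noise_sd = 0, ...) {
  key <- paste0("seg_", seed, "_", noise_sd, "_",
                paste(c(...), collapse = "_"))
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- segment_image(small_phantom(seed, noise_sd, ...)$image,
                                      image_name = paste0("phantom", seed))
  .fixtures[[key]]
}

# full-scale phantom (the workflow's target resolution), cached; shared by
# the quantification and acceptance tests
default_phantom <- function() {
  if (is.null(.fixtures$default_ph))
    .fixtures$default_ph <- generate_phantom(phantom_spec(noise_sd = 0,
                                                          seed = 1))
  .fixtures$default_ph
}

default_segmentation <- function() {
  if (is.null(.fixtures$default_seg))
    .fixtures$default_seg <- segment_image(default_phantom()$image,
                                           image_name = "phantom_default")
  .fixtures$default_seg
}

# full-scale phantom with a 30/70 lignified/low-lignified medullary split
# (core radius 232 vs pith radius 422: 30.2% lignified core by area)
split_phantom <- function() {
  if (is.null(.fixtures$split_ph))
    .fixtures$split_ph <- generate_phantom(phantom_spec(
      pith_blue_band_width = 190, noise_sd = 0, seed = 2))
  .fixtures$split_ph
}

split_segmentation <- function() {
  if (is.null(.fixtures$split_seg))
    .fixtures$split_seg <- segment_image(split_phantom()$image,
                                         image_name = "phantom_split")
  .fixtures$split_seg
}

# hsv_image built directly from planes (for threshold-level tests)
make_hsv <- function(h, s, v) {
  structure(list(h = h, s = s, v = v), pixel_size_um = 5.17,
            class = "hsv_image")
}

# label map wrapper for hand-built matrices
make_tissue_map <- function(labels, hue_split = TRUE,
                            catalogue = tissue_catalogue()) {
  structure(labels, catalogue = catalogue, hue_split = hue_split,
            class = c("tissue_label_map", "matrix", "array"))
}

# write a small batch input directory of phantom PNGs; returns the dir
write_phantom_dir <- function(seeds = c(7, 11, 23), dir = tempfile()) {
  dir.create(dir)
  for (s in seeds)
    write_png(small_phantom(s)$image,
              file.path(dir, sprintf("phantom%02d.png", s)))
  dir
}
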