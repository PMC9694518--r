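# End-to-end segmentation and the directory-in / directory-out batch driver.

#' Run configuration
#'
#' Selects which outputs a run produces and carries the (image-independent)
#' thresholds, region parameters and catalogue used for every image.
#'
#' @param input_dir directory of input images (TIFF/PNG/JPEG).
#' @param output_dir directory for outputs; created if missing.
#' @param emit_tissue_map write the 40-type label map (16-bit TIFF).
#' @param emit_region_map_5 write the 5-family grouped map.
#' @param emit_legland_map_4 write the 4-group (rind/bundles/lignified/
#'   low-lignified medullary) map.
#' @param emit_color_render write the color-coded PNG rendering.
#' @param emit_area_table write the per-tissue area CSV.
#' @param pixel_size_um physical pixel size of the inputs.
#' @param ranges a [range_set()] (threshold overrides).
#' @param params a [region_params()].
#' @param catalogue a [tissue_catalogue()], or a path to a catalogue CSV.
#' @param mt_rest placement of MT3/MT6-MT10 in the 4-group map; see
#'   [group_tissues()].
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir = ".", output_dir = ".",
                       emit_tissue_map = TRUE,
                       emit_region_map_5 = FALSE,
                       emit_legland_map_4 = FALSE,
                       emit_color_render = FALSE,
                       emit_area_table = TRUE,
                       pixel_size_um = 5.17,
                       ranges = range_set(),
                       params = region_params(),
                       catalogue = tissue_catalogue(),
                       mt_rest = "low_lignified_medullary") {
  if (is.character(catalogue)) catalogue <- read_tissue_catalogue(catalogue)
  flags <- c(emit_tissue_map, emit_region_map_5, emit_legland_map_4,
             emit_color_render, emit_area_table)
  if (!any(flags))
    stop("at least one emit flag must be set", call. = FALSE)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 emit_tissue_map = emit_tissue_map,
                 emit_region_map_5 = emit_region_map_5,
                 emit_legland_map_4 = emit_legland_map_4,
                 emit_color_render = emit_color_render,
                 emit_area_table = emit_area_table,
                 pixel_size_um = pixel_size_um,
                 ranges = ranges, params = params, catalogue = catalogue,
                 mt_rest = mt_rest),
            class = "run_config")
}

#' Segment one cross-section image
#'
#' The full workflow on one image: contrast enhancement and smoothing, HSV
#' decomposition, S/V pixel classification, automatic region masks, tissue
#' assignment and the hue split of the medullary parenchyma.
#'
#' @param image an [rgb_image()] (or a path passed to [read_image()]).
#' @param ranges a [range_set()].
#' @param params a [region_params()].
#' @param catalogue a [tissue_catalogue()].
#' @param image_name identifier used in messages.
#' @return A `segmentation` list: `tissue_map` (hue-split
#'   `tissue_label_map`), `regions`, `class_map`, `hsv`, `areas`
#'   (a [tissue_areas()] tibble) and `image_name`.
#' @export
segment_image <- function(image, ranges = range_set(),
                          params = region_params(),
                          catalogue = tissue_catalogue(),
                          image_name = "image") {
  if (is.character(image)) {
    image_name <- basename(image)
    image <- read_image(image)
  }
  stopifnot(inherits(image, "rgb_image"))
  enhanced <- enhance(image)
  hsv <- to_hsv(enhanced)
  class_map <- classify_pixels(hsv, ranges)
  section <- build_section_mask(class_map, params, image_name = image_name)
  regions <- build_region_masks(class_map, section, params)
  pre <- assign_tissues(class_map, regions, catalogue)
  tissue_map <- split_medullary_by_hue(pre, hsv$h, ranges)
  areas <- tissue_areas(tissue_map, pixel_size_um = pixel_size(image))
  structure(list(tissue_map = tissue_map, regions = regions,
                 class_map = class_map, hsv = hsv, areas = areas,
                 image_name = image_name),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s: %d section px, %d tissues present\n",
              x$image_name, sum(x$regions$section),
              length(setdiff(unique(as.vector(x$tissue_map)), 0L))))
  invisible(x)
}

area_csv_columns <- c("tissue_id", "name", "region", "pct_region",
                      "pixel_count", "area_um2", "pct_of_region")

#' Write the outputs selected by a run configuration
#'
#' Label maps are written as single-channel 16-bit TIFF (background 0, the
#' catalogue's stable tissue ids), color renderings as PNG, the area table as
#' CSV (one row per catalogue tissue, fixed order, zero counts included), and
#' a JSON run log records the thresholds and parameters used.
#'
#' @param config a [run_config()].
#' @param segmentation a result of [segment_image()].
#' @param stem output filename stem; defaults to the image name.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(config, segmentation, stem = NULL) {
  stopifnot(inherits(config, "run_config"),
            inherits(segmentation, "segmentation"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$output_dir))
    stop("cannot create output directory: ", config$output_dir,
         call. = FALSE)
  if (is.null(stem))
    stem <- tools::file_path_sans_ext(segmentation$image_name)
  out <- function(suffix) file.path(config$output_dir,
                                    paste0(stem, suffix))
  written <- character()
  tm <- segmentation$tissue_map
  if (config$emit_tissue_map)
    written <- c(written, write_label_tiff(unclass(tm),
                                           out("_tissues.tif")))
  if (config$emit_region_map_5)
    written <- c(written,
                 write_label_tiff(unclass(group_tissues(tm, "regions5")),
                                  out("_regions5.tif")))
  if (config$emit_legland_map_4)
    written <- c(written,
                 write_label_tiff(unclass(group_tissues(tm, "legland4",
                                                        config$mt_rest)),
                                  out("_legland4.tif")))
  if (config$emit_color_render)
    written <- c(written, write_png(colorize(tm), out("_render.png")))
  if (config$emit_area_table) {
    path <- out("_areas.csv")
    utils::write.csv(as.data.frame(segmentation$areas)[, area_csv_columns],
                     path, row.names = FALSE, quote = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}

list_input_images <- function(dir) {
  list.files(dir, pattern = "\\.(tif|tiff|png|jpg|jpeg)$",
             ignore.case = TRUE, full.names = TRUE)
}

#' Batch segmentation of a directory of images
#'
#' Processes every readable image in `input_dir` with the same thresholds,
#' region parameters and catalogue (no per-image tuning), writes the outputs
#' selected by the configuration, a combined area CSV across images and a
#' JSON run log. Failures on single images are recorded and do not stop the
#' batch.
#'
#' @param config a [run_config()].
#' @return A tibble with one row per image (`image`, `status`, `message`),
#'   with attribute `exit_status` (0 if all images succeeded, 1 otherwise)
#'   and `combined_csv` (path).
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- list_input_images(config$input_dir)
  if (!length(files))
    stop("no input images found in ", config$input_dir, call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  results <- vector("list", length(files))
  status <- character(length(files))
  msg <- character(length(files))
  combined <- list()
  for (i in seq_along(files)) {
    f <- files[i]
    res <- tryCatch({
      seg <- segment_image(read_image(f, config$pixel_size_um),
                           ranges = config$ranges, params = config$params,
                           catalogue = config$catalogue,
                           image_name = basename(f))
      write_outputs(config, seg)
      at <- seg$areas
      at$image <- basename(f)
      combined[[length(combined) + 1L]] <- at
      list(status = "ok", message = "")
    }, error = function(e) list(status = "failed",
                                message = conditionMessage(e)))
    status[i] <- res$status
    msg[i] <- res$message
  }
  combined_csv <- file.path(config$output_dir, "combined_areas.csv")
  if (length(combined)) {
    all_areas <- do.call(rbind, lapply(combined, as.data.frame))
    utils::write.csv(all_areas[, c("image", area_csv_columns)],
                     combined_csv, row.names = FALSE, quote = FALSE)
  }
  log <- list(
    package = "fasgaseg",
    version = as.character(utils::packageVersion("fasgaseg")),
    thresholds = list(s_ranges = config$ranges$s_ranges,
                      v_ranges = config$ranges$v_ranges,
                      h_red = config$ranges$h_red,
                      h_blue = config$ranges$h_blue),
    region_params = config$params[!vapply(config$params, is.null,
                                          logical(1))],
    mt_rest = config$mt_rest,
    images = lapply(seq_along(files), function(i)
      list(file = basename(files[i]), status = status[i],
           message = msg[i]))
  )
  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- tibble::tibble(image = basename(files), status = status,
                        message = msg)
  attr(out, "exit_status") <- if (all(status == "ok")) 0L else 1L
  attr(out, "combined_csv") <- combined_csv
  out
}
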