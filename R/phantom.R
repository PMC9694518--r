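# Synthetic cross-section phantoms with ground truth.
#
# A phantom emulates the concentric architecture of a grass internode: an
# epidermis ring, a dark sclerenchyma-rich rind with embedded bundles, a
# narrow light rind band, and a medullary pith with a peripheral
# poorly-lignified (blue) band, a lignified (red) core, scattered vascular
# bundles with sclerenchyma caps at their poles, and an optional central
# hole. Each structure is painted with one tissue of the default catalogue;
# per-pixel H/S/V values are drawn around that tissue's class centroid so
# that a noise-free phantom is exactly recoverable by the pipeline, which is
# precisely what makes it a useful validation target. The rendered RGB image
# is stored at half intensity: the acquisition contrast the pipeline's
# doubling step restores.

#' Default HSV distribution of phantom structures
#'
#' One row per painted structure: the catalogue tissue it represents and the
#' H/S/V means its pixels are drawn around (targets after contrast
#' enhancement, each centered in the tissue's S/V class ranges).
#'
#' @param jitter_sd standard deviation of the per-pixel HSV jitter.
#' @return A data frame with columns `structure`, `tissue`, `h`, `s`, `v`,
#'   `jitter_sd`.
#' @export
phantom_tissue_hsv <- function(jitter_sd = 0.01) {
  data.frame(
    structure = c("background", "epidermis", "dark_rind", "rind_bundle",
                  "light_rind", "pith_core", "blue_band", "bundle_body",
                  "bundle_cap"),
    tissue = c(NA, "ET2", "DRT1", "DRT9", "LRT9", "MT1a", "MT2a", "BT3",
               "BT1"),
    h = c(0.00, 0.08, 0.05, 0.02, 0.10, 0.05, 0.60, 0.30, 0.02),
    s = c(0.01, 0.155, 0.155, 0.85, 0.52, 0.88, 0.155, 0.155, 0.88),
    v = c(0.995, 0.535, 0.22, 0.795, 0.795, 0.535, 0.972, 0.535, 0.535),
    jitter_sd = jitter_sd,
    stringsAsFactors = FALSE
  )
}

#' Phantom specification
#'
#' Geometry, color distributions and noise of a synthetic cross section.
#' Defaults describe a 1024 px scan of a full internode at 5.17 um/px:
#' section radius 480 px, 8 px epidermis, 40 px dark rind with 6 embedded
#' bundles, 10 px light rind, a 60 px poorly-lignified band at the pith
#' periphery and 8 pith bundles of 18-30 px radius.
#'
#' @param image_size square image edge in pixels.
#' @param section_radius section radius in pixels.
#' @param epidermis_width,dark_rind_width,light_rind_width ring widths (px).
#' @param n_rind_bundles bundles embedded in the dark rind.
#' @param n_pith_bundles bundles scattered in the pith core.
#' @param bundle_radius_range min/max semi-major axis of pith bundles (px).
#' @param pith_blue_band_width width (px) of the peripheral blue pith band.
#' @param hole_radius radius (px) of a central hole; 0 = none.
#' @param tissue_hsv per-structure HSV distribution, see
#'   [phantom_tissue_hsv()].
#' @param noise_sd additive Gaussian acquisition noise (intensity steps on
#'   the stored image).
#' @param seed RNG seed; the phantom is fully reproducible from it.
#' @param pixel_size_um physical pixel size.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 1024,
                         section_radius = 480,
                         epidermis_width = 8,
                         dark_rind_width = 40,
                         light_rind_width = 10,
                         n_rind_bundles = 6,
                         n_pith_bundles = 8,
                         bundle_radius_range = c(18, 30),
                         pith_blue_band_width = 60,
                         hole_radius = 0,
                         tissue_hsv = phantom_tissue_hsv(),
                         noise_sd = 1,
                         seed = 1L,
                         pixel_size_um = 5.17) {
  spec <- list(image_size = as.integer(image_size),
               section_radius = section_radius,
               epidermis_width = epidermis_width,
               dark_rind_width = dark_rind_width,
               light_rind_width = light_rind_width,
               n_rind_bundles = as.integer(n_rind_bundles),
               n_pith_bundles = as.integer(n_pith_bundles),
               bundle_radius_range = bundle_radius_range,
               pith_blue_band_width = pith_blue_band_width,
               hole_radius = hole_radius,
               tissue_hsv = tissue_hsv,
               noise_sd = noise_sd,
               seed = as.integer(seed),
               pixel_size_um = pixel_size_um)
  rim <- spec$epidermis_width + spec$dark_rind_width + spec$light_rind_width
  pith_radius <- spec$section_radius - rim
  if (spec$section_radius >= spec$image_size / 2)
    stop("section does not fit in the image", call. = FALSE)
  if (pith_radius - spec$pith_blue_band_width <= 0)
    stop("ring widths exceed the section radius", call. = FALSE)
  core_radius <- pith_radius - spec$pith_blue_band_width
  if (spec$n_pith_bundles > 0 &&
      core_radius < max(spec$bundle_radius_range) * 2 + 10)
    stop("pith core too small for the requested bundles", call. = FALSE)
  hole_margin <- if (spec$n_pith_bundles > 0)
    max(spec$bundle_radius_range) else 5
  if (spec$hole_radius > 0 && spec$hole_radius >= core_radius - hole_margin)
    stop("hole too large for the pith core", call. = FALSE)
  if (any(!is.na(spec$tissue_hsv$h) &
          (spec$tissue_hsv$h < 0 | spec$tissue_hsv$h > 1)) ||
      any(spec$tissue_hsv$s < 0 | spec$tissue_hsv$s > 1) ||
      any(spec$tissue_hsv$v < 0 | spec$tissue_hsv$v > 1))
    stop("tissue HSV means must lie in [0, 1]", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

# hsv planes (vectors) -> 0..255 RGB matrix (3 x n)
hsv_to_rgb255 <- function(h, s, v) {
  grDevices::col2rgb(grDevices::hsv(pmin(pmax(h, 0), 1),
                                    pmin(pmax(s, 0), 1),
                                    pmin(pmax(v, 0), 1)))
}

#' Generate a synthetic cross-section phantom
#'
#' Renders the phantom image together with its ground truth: the tissue
#' label map and the region masks, both recorded from the exact geometry
#' before any jitter or noise is applied.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` (an [rgb_image()]), `tissue_truth`
#'   (a hue-split `tissue_label_map`), `region_truth` (a `region_mask_set`)
#'   and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  n <- spec$image_size
  cx <- (n + 1) / 2
  dx <- matrix(rep(seq_len(n) - cx, each = n), n, n)   # column offsets
  dy <- matrix(rep(seq_len(n) - cx, times = n), n, n)  # row offsets
  r <- sqrt(dx^2 + dy^2)

  R <- spec$section_radius
  r_ep <- R - spec$epidermis_width
  r_dr <- r_ep - spec$dark_rind_width
  r_lr <- r_dr - spec$light_rind_width
  r_core <- r_lr - spec$pith_blue_band_width

  structure_map <- matrix("background", n, n)
  structure_map[r <= R] <- "epidermis"
  structure_map[r <= r_ep] <- "dark_rind"
  structure_map[r <= r_dr] <- "light_rind"
  structure_map[r <= r_lr] <- "blue_band"
  structure_map[r <= r_core] <- "pith_core"

  # bundles embedded in the dark rind (fully enclosed by the ring)
  rb_radius <- max(4, round(spec$dark_rind_width * 0.3))
  rb_center_r <- (r_ep + r_dr) / 2
  if (spec$n_rind_bundles > 0) {
    ang <- sort(runif(spec$n_rind_bundles, 0, 2 * pi))
    for (a in ang) {
      bx <- rb_center_r * cos(a)
      by <- rb_center_r * sin(a)
      structure_map[(dx - bx)^2 + (dy - by)^2 <= rb_radius^2 &
                      r <= r_ep & r > r_dr] <- "rind_bundle"
    }
  }

  # pith bundles: random ellipses with sclerenchyma caps at the poles
  bundle_mask <- matrix(FALSE, n, n)
  cap_mask <- matrix(FALSE, n, n)
  if (spec$n_pith_bundles > 0) {
    a_max <- max(spec$bundle_radius_range)
    placed <- matrix(numeric(0), ncol = 2)
    max_center_r <- r_core - a_max - 6
    min_center_r <- if (spec$hole_radius > 0)
      spec$hole_radius + a_max + 6 else 0
    tries <- 0
    while (nrow(placed) < spec$n_pith_bundles && tries < 5000) {
      tries <- tries + 1
      cand <- c(runif(1, -max_center_r, max_center_r),
                runif(1, -max_center_r, max_center_r))
      cr <- sqrt(sum(cand^2))
      if (cr > max_center_r || cr < min_center_r) next
      if (nrow(placed) &&
          min(sqrt(rowSums(sweep(placed, 2, cand)^2))) < 2 * a_max + 8) next
      placed <- rbind(placed, cand)
    }
    if (nrow(placed) < spec$n_pith_bundles)
      stop("could not place the requested pith bundles", call. = FALSE)
    for (i in seq_len(nrow(placed))) {
      a <- runif(1, spec$bundle_radius_range[1], spec$bundle_radius_range[2])
      b <- 0.8 * a
      th <- runif(1, 0, pi)
      u <- cos(th) * (dx - placed[i, 1]) + sin(th) * (dy - placed[i, 2])
      w <- -sin(th) * (dx - placed[i, 1]) + cos(th) * (dy - placed[i, 2])
      rho2 <- (u / a)^2 + (w / b)^2
      body <- rho2 <= 1
      bundle_mask <- bundle_mask | body
      # caps: compact interior patches at the two poles of the major axis
      cap <- rho2 >= 0.72^2 & rho2 <= 0.90^2 & (u / a)^2 >= 0.78 * rho2
      cap_mask <- cap_mask | cap
    }
    structure_map[bundle_mask] <- "bundle_body"
    structure_map[cap_mask] <- "bundle_cap"
  }

  if (spec$hole_radius > 0)
    structure_map[r <= spec$hole_radius] <- "background"

  # ground truth (pre-noise, from the exact geometry)
  catalogue <- tissue_catalogue()
  hsv_tab <- spec$tissue_hsv
  tid <- stats::setNames(
    catalogue$tissue_id[match(hsv_tab$tissue, catalogue$name)],
    hsv_tab$structure)
  truth <- matrix(0L, n, n)
  for (st in hsv_tab$structure[!is.na(hsv_tab$tissue)])
    truth[structure_map == st] <- tid[[st]]
  tissue_truth <- structure(truth, catalogue = catalogue, hue_split = TRUE,
                            class = c("tissue_label_map", "matrix", "array"))

  section <- structure_map != "background"
  dark_rind <- structure_map %in% c("epidermis", "dark_rind", "rind_bundle")
  dark_rind <- matrix(dark_rind, n, n)
  bundles <- matrix(structure_map %in% c("bundle_body", "bundle_cap"), n, n)
  light_rind <- matrix(structure_map == "light_rind", n, n)
  pith <- matrix(structure_map %in% c("pith_core", "blue_band"), n, n)
  region_truth <- structure(list(section = section, dark_rind = dark_rind,
                                 bundles = bundles, light_rind = light_rind,
                                 pith = pith, params = NULL),
                            class = "region_mask_set")

  # paint: per-pixel HSV draws around each structure's means. The paint
  # stage is re-seeded so that the pixel noise field is a function of the
  # seed alone: phantoms differing only in geometry counts (e.g. number of
  # bundles) share identical staining noise everywhere else.
  set.seed(spec$seed + 1000003L)
  idx <- match(as.vector(structure_map), hsv_tab$structure)
  npx <- n * n
  jit <- hsv_tab$jitter_sd[idx]
  h <- hsv_tab$h[idx] + rnorm(npx) * jit
  s <- hsv_tab$s[idx] + rnorm(npx) * jit
  v <- hsv_tab$v[idx] + rnorm(npx) * jit
  rgb_target <- hsv_to_rgb255(h, s, v)
  raw <- round(rgb_target / 2)
  if (spec$noise_sd > 0)
    raw <- raw + matrix(rnorm(3 * npx, sd = spec$noise_sd), 3, npx)
  raw <- pmin(pmax(round(raw), 0), 255)
  px <- array(0L, c(n, n, 3))
  for (ch in 1:3) px[, , ch] <- matrix(raw[ch, ], n, n)

  list(image = rgb_image(px, pixel_size_um = spec$pixel_size_um),
       tissue_truth = tissue_truth,
       region_truth = region_truth,
       spec = spec)
}
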