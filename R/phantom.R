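#' Specification of a synthetic corneal B-scan phantom
#'
#' Describes the geometry and noise model of a two-surface corneal phantom:
#' a circular anterior arc of radius `anterior_radius_mm` with its apex at
#' `apex_column`, a bright epithelium band of `epithelium_um`, a stroma of
#' `cct_um - epithelium_um` filled with Generalised Gamma speckle, and a
#' dark Rayleigh-noise background. Rows are axial (increasing into the eye),
#' columns are lateral A-scan positions; all indices are 1-based in R,
#' 0-based in files written by [write_bscan()].
#'
#' The default pixel pitch (1.5 um axial, 3 um lateral) is chosen so that a
#' 250-row stromal region of interest fits under Bowman's layer at a normal
#' central corneal thickness across the full 450-column aperture.
#'
#' @param n_ascans number of A-scans (columns), default 1024.
#' @param n_axial pixels per A-scan (rows), default 848.
#' @param axial_pixel_um,lateral_pixel_um pixel pitch in micrometres.
#' @param anterior_radius_mm radius of the anterior corneal surface (mm).
#' @param cct_um central corneal thickness (um).
#' @param epithelium_um epithelium thickness (um); must be less than
#'   `cct_um`.
#' @param apex_column lateral position of the corneal apex (1-based column).
#' @param apex_row axial position of the anterior surface at the apex.
#' @param background_level Rayleigh scale of the background noise, in the
#'   same arbitrary intensity units as the speckle.
#' @param epithelium_mean,epithelium_sd mean and SD of the bright epithelium
#'   band (gamma-distributed pixel intensities).
#' @param seed integer seed making [simulate_bscan()] deterministic.
#' @return an object of class `"cornea_phantom_spec"`.
#' @seealso [simulate_bscan()]
#' @export
phantom_spec <- function(n_ascans = 1024, n_axial = 848,
                         axial_pixel_um = 1.5, lateral_pixel_um = 3,
                         anterior_radius_mm = 7.75, cct_um = 552.75,
                         epithelium_um = 55, apex_column = 512,
                         apex_row = 200, background_level = 0.02,
                         epithelium_mean = 0.55, epithelium_sd = 0.12,
                         seed = NULL) {
  n_ascans <- check_count(n_ascans, "n_ascans")
  n_axial <- check_count(n_axial, "n_axial")
  check_positive(axial_pixel_um, "axial_pixel_um")
  check_positive(lateral_pixel_um, "lateral_pixel_um")
  check_positive(anterior_radius_mm, "anterior_radius_mm")
  check_positive(cct_um, "cct_um")
  check_positive(epithelium_um, "epithelium_um")
  check_positive(background_level, "background_level")
  if (cct_um <= epithelium_um)
    oct_error("`cct_um` must exceed `epithelium_um`",
              "octspeckle_domain_error")
  apex_column <- check_count(apex_column, "apex_column")
  apex_row <- check_count(apex_row, "apex_row")
  if (apex_column > n_ascans)
    oct_error("`apex_column` must lie within 1..n_ascans",
              "octspeckle_domain_error")
  structure(list(
    n_ascans = n_ascans, n_axial = n_axial,
    axial_pixel_um = axial_pixel_um, lateral_pixel_um = lateral_pixel_um,
    anterior_radius_mm = anterior_radius_mm, cct_um = cct_um,
    epithelium_um = epithelium_um, apex_column = apex_column,
    apex_row = apex_row, background_level = background_level,
    epithelium_mean = epithelium_mean, epithelium_sd = epithelium_sd,
    seed = seed), class = "cornea_phantom_spec")
}

#' @export
print.cornea_phantom_spec <- function(x, ...) {
  cat(sprintf(
    "Cornea phantom spec: %d x %d px (%.3g x %.3g um), R = %.3g mm,\n",
    x$n_axial, x$n_ascans, x$axial_pixel_um, x$lateral_pixel_um,
    x$anterior_radius_mm))
  cat(sprintf("  CCT = %.4g um, epithelium = %.3g um, apex at column %d\n",
              x$cct_um, x$epithelium_um, x$apex_column))
  invisible(x)
}

# per-column 1-based boundary rows for a phantom spec; stroma thickness is
# constant per column so the construction identity
#   endothelium_row - bowman_row == round((cct - epithelium)/axial_pixel)
# holds exactly.
phantom_truth <- function(spec) {
  cols <- seq_len(spec$n_ascans)
  r_um <- spec$anterior_radius_mm * 1000
  d_um <- (cols - spec$apex_column) * spec$lateral_pixel_um
  if (any(abs(d_um) >= r_um))
    oct_error("lateral aperture exceeds the anterior radius",
              "octspeckle_geometry_error")
  sag_px <- (r_um - sqrt(r_um^2 - d_um^2)) / spec$axial_pixel_um
  epi <- as.integer(round(spec$apex_row + sag_px))
  bow <- epi + as.integer(round(spec$epithelium_um / spec$axial_pixel_um))
  endo <- bow + as.integer(round(
    (spec$cct_um - spec$epithelium_um) / spec$axial_pixel_um))
  if (min(epi) < 2L || max(endo) > spec$n_axial - 1L)
    oct_error("phantom geometry does not fit inside the raster",
              "octspeckle_geometry_error")
  data.frame(column = cols, epithelium_row = epi, bowman_row = bow,
             endothelium_row = endo)
}

#' Simulate a corneal OCT B-scan phantom with GG speckle
#'
#' Renders a linear-intensity B-scan in which the stroma (between Bowman's
#' layer and the endothelium) is filled with i.i.d. Generalised Gamma
#' speckle, the epithelium is a brighter gamma-distributed band, and the
#' background is low-intensity Rayleigh noise, so that the three layer
#' boundaries carry detectable axial gradients. The exact per-column
#' boundary rows are returned as ground truth.
#'
#' Boundary-row semantics: `epithelium_row` is the first epithelium pixel,
#' `bowman_row` the first stroma pixel and `endothelium_row` the first
#' background pixel below the stroma, so stroma pixels occupy rows
#' `bowman_row .. endothelium_row - 1`.
#'
#' @param spec a [phantom_spec()].
#' @param gg named vector or list of generating GG parameters `a`, `v`, `p`
#'   (defaults are typical corneal stroma values).
#' @return an object of class `"bscan"`: list with the pixel matrix
#'   (`n_axial` rows x `n_ascans` columns), pixel geometry, the
#'   `intensity_scale` flag (always `"linear"`), the generating parameters
#'   and the ground-truth boundary table in `$truth`.
#' @examples
#' sp <- phantom_spec(n_ascans = 256, apex_column = 128, seed = 1)
#' b <- simulate_bscan(sp)
#' dim(b$pixels)
#' @export
simulate_bscan <- function(spec,
                           gg = c(a = 0.287, v = 0.437, p = 2.80)) {
  stopifnot(inherits(spec, "cornea_phantom_spec"))
  gg <- unlist(gg)
  check_gg_params(gg[["a"]], gg[["v"]], gg[["p"]])
  truth <- phantom_truth(spec)
  nr <- spec$n_axial; nc <- spec$n_ascans
  with_seed(spec$seed, {
    # Rayleigh background everywhere first, then overwrite tissue bands
    pix <- matrix(spec$background_level * sqrt(-2 * log(stats::runif(nr * nc))),
                  nrow = nr, ncol = nc)
    rowidx <- matrix(seq_len(nr), nr, nc)
    epi_m <- matrix(truth$epithelium_row, nr, nc, byrow = TRUE)
    bow_m <- matrix(truth$bowman_row, nr, nc, byrow = TRUE)
    endo_m <- matrix(truth$endothelium_row, nr, nc, byrow = TRUE)
    in_epi <- rowidx >= epi_m & rowidx < bow_m
    in_stroma <- rowidx >= bow_m & rowidx < endo_m
    shp <- (spec$epithelium_mean / spec$epithelium_sd)^2
    pix[in_epi] <- stats::rgamma(sum(in_epi), shape = shp,
                                 scale = spec$epithelium_mean / shp)
    pix[in_stroma] <- rgg(sum(in_stroma), gg[["a"]], gg[["v"]], gg[["p"]])
  })
  structure(list(pixels = pix, axial_pixel_um = spec$axial_pixel_um,
                 lateral_pixel_um = spec$lateral_pixel_um,
                 intensity_scale = "linear", gg = gg, truth = truth,
                 spec = spec), class = "bscan")
}

#' Construct a B-scan object from a raw intensity matrix
#'
#' @param pixels numeric matrix, rows = axial, columns = lateral; all values
#'   must be non-negative.
#' @param axial_pixel_um,lateral_pixel_um pixel pitch in micrometres.
#' @param intensity_scale `"linear"` (required for speckle fitting) or
#'   `"log-compressed"`.
#' @return an object of class `"bscan"`.
#' @export
bscan <- function(pixels, axial_pixel_um = 1.5, lateral_pixel_um = 3,
                  intensity_scale = c("linear", "log-compressed")) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    oct_error("`pixels` must be a numeric matrix", "octspeckle_domain_error")
  if (any(pixels < 0, na.rm = TRUE))
    oct_error("pixel intensities must be non-negative",
              "octspeckle_domain_error")
  structure(list(pixels = pixels,
                 axial_pixel_um = check_positive(axial_pixel_um,
                                                 "axial_pixel_um"),
                 lateral_pixel_um = check_positive(lateral_pixel_um,
                                                   "lateral_pixel_um"),
                 intensity_scale = match.arg(intensity_scale)),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("OCT B-scan: %d axial x %d lateral px (%.3g x %.3g um), %s\n",
              nrow(x$pixels), ncol(x$pixels), x$axial_pixel_um,
              x$lateral_pixel_um, x$intensity_scale))
  if (!is.null(x$truth)) cat("  synthetic phantom with ground truth\n")
  invisible(x)
}

#' @export
plot.bscan <- function(x, ...) {
  graphics::image(t(x$pixels)[, rev(seq_len(nrow(x$pixels)))],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  ...)
  invisible(x)
}

#' Write / read B-scan images
#'
#' `write_bscan()` writes the image as 16-bit grayscale TIFF or 8-bit
#' grayscale PNG (by file extension; use TIFF when the intensities feed the
#' speckle fit) together with a JSON sidecar (`<path>.json`) holding the pixel
#' geometry and the intensity normalisation, and, for phantoms, a
#' ground-truth CSV (`<path>_truth.csv`) with 0-based rows. `read_bscan()`
#' reads TIFF, PNG or a plain CSV intensity matrix and re-attaches the
#' sidecar metadata when present (explicit arguments override it).
#'
#' @param image a `"bscan"` object.
#' @param path output image path ending in `.tif`, `.tiff` or `.png`; for
#'   reading also `.csv`.
#' @param axial_pixel_um,lateral_pixel_um,intensity_scale metadata overrides
#'   used when no sidecar is present.
#' @return `write_bscan()` returns `path` invisibly; `read_bscan()` a
#'   `"bscan"` object.
#' @export
write_bscan <- function(image, path) {
  stopifnot(inherits(image, "bscan"))
  ext <- tolower(tools::file_ext(path))
  imax <- max(image$pixels, 1e-12)
  norm <- image$pixels / imax
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    oct_error(sprintf("unsupported image extension '%s'", ext),
              "octspeckle_io_error")
  }
  meta <- list(axial_pixel_um = image$axial_pixel_um,
               lateral_pixel_um = image$lateral_pixel_um,
               intensity_scale = image$intensity_scale,
               intensity_max = imax)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(image$truth)) {
    tr <- image$truth
    tr$epithelium_row <- tr$epithelium_row - 1L  # 0-based on disk
    tr$bowman_row <- tr$bowman_row - 1L
    tr$endothelium_row <- tr$endothelium_row - 1L
    tr$column <- tr$column - 1L
    utils::write.csv(tr, paste0(tools::file_path_sans_ext(path),
                                "_truth.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path, axial_pixel_um = NULL, lateral_pixel_um = NULL,
                       intensity_scale = NULL) {
  if (!file.exists(path))
    oct_error(sprintf("image file '%s' not found", path),
              "octspeckle_io_error")
  ext <- tolower(tools::file_ext(path))
  pix <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    oct_error(sprintf("unsupported image extension '%s'", ext),
              "octspeckle_io_error"))
  if (length(dim(pix)) == 3L) pix <- pix[, , 1L]  # collapse grayscale RGB
  storage.mode(pix) <- "double"
  dimnames(pix) <- NULL
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side)
  if (!is.null(meta$intensity_max)) pix <- pix * as.numeric(meta$intensity_max)
  bscan(pix,
        axial_pixel_um = axial_pixel_um %||% meta$axial_pixel_um %||% 1.5,
        lateral_pixel_um = lateral_pixel_um %||% meta$lateral_pixel_um %||% 3,
        intensity_scale = intensity_scale %||% meta$intensity_scale %||%
          "linear")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
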