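#' Segment the corneal layer boundaries of a B-scan
#'
#' Identifies, per A-scan column, the axial positions of the epithelium
#' (anterior surface), Bowman's layer and the endothelium (posterior
#' surface) by edge detection on the axial intensity gradient, then smooths
#' each boundary across columns with a robust low-order polynomial fit.
#'
#' Per column the pixel profile is smoothed with a Gaussian kernel
#' (`axial_sigma_px`), differentiated with a centred first difference, and
#' scanned for local maxima of the gradient magnitude exceeding
#' `grad_threshold` times the column's maximum magnitude (a relative
#' threshold, so segmentation is invariant to adding a constant to all
#' intensities). The epithelium is the first such maximum from the top, the
#' endothelium the last, and Bowman's layer the strongest gradient extremum
#' within `bowman_window_um` below the epithelium. Columns violating the
#' ordering epithelium < Bowman < endothelium are discarded; if fewer than
#' `min_valid_frac` of columns survive, a segmentation-failure error is
#' raised (a featureless image has no gradient maxima at all).
#'
#' @param image a `"bscan"` object.
#' @param axial_sigma_px SD (pixels) of the Gaussian axial smoothing kernel
#'   applied before differentiation (default 2).
#' @param grad_threshold relative gradient-magnitude threshold in (0, 1)
#'   (default 0.2).
#' @param bowman_window_um search window for Bowman's layer below the
#'   epithelium, in micrometres (default `c(40, 80)`).
#' @param min_valid_frac minimum fraction of columns with all three
#'   boundaries (default 0.5).
#' @param poly_order order of the robust polynomial fitted across columns to
#'   each raw boundary (default 2).
#' @return an object of class `"oct_segmentation"`: per-column numeric
#'   vectors `epithelium_row`, `bowman_row`, `endothelium_row` (NA outside
#'   the fitted span), the raw detections, `valid_columns`, and
#'   `apex_column` (NA when the apex cannot be located).
#' @seealso [find_apex()], [select_roi()]
#' @export
segment_layers <- function(image, axial_sigma_px = 2, grad_threshold = 0.2,
                           bowman_window_um = c(40, 80),
                           min_valid_frac = 0.5, poly_order = 2) {
  stopifnot(inherits(image, "bscan"))
  pix <- image$pixels
  nr <- nrow(pix); nc <- ncol(pix)
  sm <- smooth_columns(pix, axial_sigma_px)
  grad <- matrix(0, nr, nc)
  grad[2:(nr - 1L), ] <- (sm[3:nr, ] - sm[1:(nr - 2L), ]) / 2
  win_px <- sort(round(bowman_window_um / image$axial_pixel_um))

  epi <- bow <- endo <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    mag <- abs(grad[, j])
    mx <- max(mag)
    if (mx <= 0) next
    thr <- grad_threshold * mx
    loc <- which(mag > thr)
    loc <- loc[loc > 1L & loc < nr]
    loc <- loc[mag[loc] >= mag[loc - 1L] & mag[loc] >= mag[loc + 1L]]
    if (length(loc) < 2L) next
    e <- min(loc); d <- max(loc)
    lo <- e + win_px[1L]; hi <- min(e + win_px[2L], nr)
    if (lo >= hi) next
    b <- lo - 1L + which.max(mag[lo:hi])
    if (e < b && b < d) { epi[j] <- e; bow[j] <- b; endo[j] <- d }
  }
  valid <- which(!is.na(epi))
  if (length(valid) < min_valid_frac * nc)
    oct_error(sprintf(
      "layer segmentation failed: only %d/%d columns have all three boundaries",
      length(valid), nc), "octspeckle_segmentation_failure")

  span <- valid
  fit_curve <- function(y) {
    cf <- robust_poly_fit(valid, y[valid], poly_order)
    out <- rep(NA_real_, nc)
    out[min(valid):max(valid)] <-
      drop(stats::poly(min(valid):max(valid), poly_order, raw = TRUE,
                       simple = TRUE) %*% cf[-1L]) + cf[1L]
    out
  }
  epi_s <- fit_curve(epi); bow_s <- fit_curve(bow); endo_s <- fit_curve(endo)

  seg <- structure(list(
    epithelium_row = epi_s, bowman_row = bow_s, endothelium_row = endo_s,
    raw = list(epithelium_row = epi, bowman_row = bow,
               endothelium_row = endo),
    valid_columns = valid, n_columns = nc,
    axial_pixel_um = image$axial_pixel_um,
    apex_column = NA_integer_), class = "oct_segmentation")
  seg$apex_column <- tryCatch(find_apex(seg), error = function(e) NA_integer_)
  seg
}

smooth_columns <- function(pix, sigma) {
  if (sigma <= 0) return(pix)
  hw <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  nr <- nrow(pix)
  padded <- rbind(pix[rep(1L, hw), , drop = FALSE], pix,
                  pix[rep(nr, hw), , drop = FALSE])
  sm <- stats::filter(padded, k, sides = 2)
  matrix(as.numeric(sm[(hw + 1L):(hw + nr), , drop = FALSE]), nr)
}

# robust (Tukey-bisquare IWLS) polynomial fit; returns intercept + powers
robust_poly_fit <- function(x, y, order, iters = 20L) {
  X <- cbind(1, stats::poly(x, order, raw = TRUE, simple = TRUE))
  w <- rep.int(1, length(y))
  cf <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
  for (i in seq_len(iters)) {
    r <- y - drop(X %*% cf)
    s <- stats::median(abs(r)) / 0.6745
    if (s <= .Machine$double.eps) break
    u <- r / (4.685 * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) <= order + 1L) break
    cf_new <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    if (max(abs(cf_new - cf)) < 1e-10) { cf <- cf_new; break }
    cf <- cf_new
  }
  cf
}

#' @export
print.oct_segmentation <- function(x, ...) {
  cat(sprintf(
    "Corneal segmentation: %d/%d columns valid, apex at column %s\n",
    length(x$valid_columns), x$n_columns,
    ifelse(is.na(x$apex_column), "<not found>", x$apex_column)))
  invisible(x)
}

#' Locate the corneal apex from a segmented epithelium curve
#'
#' The apex is the column where the first difference of the smoothed
#' epithelium curve crosses zero, i.e. the minimum axial position of the
#' anterior surface (rows increase into the eye). Ties are broken toward
#' the centre of the defined span. A monotone curve has no zero crossing
#' and raises an apex-not-found error.
#'
#' @param segmentation an `"oct_segmentation"` object, or a numeric
#'   per-column epithelium curve (NA allowed outside the defined span).
#' @return the apex column index (integer).
#' @examples
#' curve <- 200 + (seq_len(1024) - 512)^2 / 2000  # symmetric arc
#' find_apex(curve)
#' @export
find_apex <- function(segmentation) {
  curve <- if (inherits(segmentation, "oct_segmentation"))
    segmentation$epithelium_row else as.numeric(segmentation)
  span <- which(!is.na(curve))
  if (length(span) < 3L)
    oct_error("epithelium curve defined over fewer than 3 columns",
              "octspeckle_apex_error")
  cols <- min(span):max(span)
  y <- curve[cols]
  d <- diff(y)
  crossing <- which(d[-length(d)] < 0 & d[-1L] >= 0)
  if (!length(crossing)) {
    # flat stretches: accept a global interior minimum if one exists
    idx <- which(y <= min(y) + 1e-9)
    if (all(idx %in% c(1L, length(y))))
      oct_error("no apex: epithelium curve is monotone over its span",
                "octspeckle_apex_error")
    centre <- (1 + length(y)) / 2
    return(cols[idx[which.min(abs(idx - centre))]])
  }
  cand <- crossing + 1L
  centre <- (1 + length(y)) / 2
  as.integer(cols[cand[which.min(abs(cand - centre))]])
}

#' Select the stromal region of interest
#'
#' Places the fixed-size speckle ROI (by default 250 rows x 450 columns)
#' horizontally centred on the corneal apex, with its top edge `offset_um`
#' below Bowman's layer at the apex. The offset keeps the window inside the
#' stroma despite the corneal curvature: the whole ROI must lie strictly
#' below Bowman's layer and above the endothelium at every ROI column,
#' otherwise an roi-out-of-tissue error is raised.
#'
#' @param image a `"bscan"` object.
#' @param segmentation its [segment_layers()] result.
#' @param offset_um axial clearance below Bowman's layer at the apex
#'   (default 60 um, exceeding the Bowman sag across the default aperture).
#' @param n_rows,n_columns ROI size (defaults 250 x 450).
#' @return an object of class `"oct_roi"`: list with `top_row`,
#'   `left_column`, `n_rows`, `n_columns` (1-based, inclusive).
#' @seealso [extract_intensities()]
#' @export
select_roi <- function(image, segmentation, offset_um = 60,
                       n_rows = 250, n_columns = 450) {
  stopifnot(inherits(image, "bscan"),
            inherits(segmentation, "oct_segmentation"))
  n_rows <- check_count(n_rows, "n_rows")
  n_columns <- check_count(n_columns, "n_columns")
  apex <- segmentation$apex_column
  if (is.na(apex))
    oct_error("apex not found; cannot place the ROI",
              "octspeckle_apex_error")
  left <- apex - floor(n_columns / 2)
  right <- left + n_columns - 1L
  nrp <- nrow(image$pixels); ncp <- ncol(image$pixels)
  if (left < 1L || right > ncp)
    oct_error("ROI extends beyond the lateral image edge",
              "octspeckle_roi_error")
  bow_apex <- segmentation$bowman_row[apex]
  if (is.na(bow_apex))
    oct_error("Bowman's layer undefined at the apex",
              "octspeckle_roi_error")
  top <- as.integer(round(bow_apex + offset_um / image$axial_pixel_um))
  bottom <- top + n_rows - 1L
  if (top < 1L || bottom > nrp)
    oct_error("ROI extends beyond the axial image edge",
              "octspeckle_roi_error")
  cols <- left:right
  bow <- segmentation$bowman_row[cols]
  endo <- segmentation$endothelium_row[cols]
  if (anyNA(bow) || anyNA(endo) || any(top <= bow) || any(bottom >= endo))
    oct_error(
      "ROI leaves the stroma: it must stay below Bowman's layer and above the endothelium at every column",
      "octspeckle_roi_error")
  structure(list(top_row = top, left_column = as.integer(left),
                 n_rows = n_rows, n_columns = n_columns),
            class = "oct_roi")
}

#' @export
print.oct_roi <- function(x, ...) {
  cat(sprintf("ROI: %d rows x %d columns, top-left at (row %d, column %d)\n",
              x$n_rows, x$n_columns, x$top_row, x$left_column))
  invisible(x)
}

#' Extract the ROI pixel intensities
#'
#' Returns the linear pixel intensities of the ROI as a vector in row-major
#' order (all columns of the first ROI row, then the second row, ...). The
#' values are returned untransformed; images flagged as log-compressed are
#' refused rather than silently de-compressed, because the speckle model
#' applies to linear intensities only.
#'
#' @param image a `"bscan"` object with `intensity_scale = "linear"`.
#' @param roi an [select_roi()] result.
#' @param saturation_percentile optional percentile in (0, 100); pixels
#'   above it are excluded, a guard against specular-reflection saturation.
#'   Off (`NULL`) by default.
#' @return numeric vector of `n_rows * n_columns` intensities (fewer when a
#'   saturation mask is applied).
#' @export
extract_intensities <- function(image, roi, saturation_percentile = NULL) {
  stopifnot(inherits(image, "bscan"), inherits(roi, "oct_roi"))
  if (identical(image$intensity_scale, "log-compressed"))
    oct_error(
      "image is log-compressed; speckle statistics require linear intensities (no silent de-compression)",
      "octspeckle_log_compressed_error")
  rows <- roi$top_row:(roi$top_row + roi$n_rows - 1L)
  cols <- roi$left_column:(roi$left_column + roi$n_columns - 1L)
  if (max(rows) > nrow(image$pixels) || max(cols) > ncol(image$pixels))
    oct_error("ROI lies outside the image", "octspeckle_roi_error")
  vals <- as.vector(t(image$pixels[rows, cols]))
  if (!is.null(saturation_percentile)) {
    cut <- stats::quantile(vals, saturation_percentile / 100, names = FALSE)
    vals <- vals[vals <= cut]
  }
  vals
}

#' Fit the speckle model to a B-scan end to end
#'
#' Convenience pipeline: [segment_layers()] then [select_roi()] then
#' [extract_intensities()] then [fit_gg()].
#'
#' @param image a `"bscan"` object.
#' @param offset_um,n_rows,n_columns ROI placement, see [select_roi()].
#' @param saturation_percentile see [extract_intensities()].
#' @param ... further arguments passed to [fit_gg()].
#' @return list with elements `fit` (a `"gg_fit"`), `roi` and
#'   `segmentation`.
#' @examples
#' \donttest{
#' b <- simulate_bscan(phantom_spec(seed = 1))
#' res <- fit_speckle(b)
#' coef(res$fit)
#' }
#' @export
fit_speckle <- function(image, offset_um = 60, n_rows = 250,
                        n_columns = 450, saturation_percentile = NULL,
                        ...) {
  seg <- segment_layers(image)
  roi <- select_roi(image, seg, offset_um = offset_um, n_rows = n_rows,
                    n_columns = n_columns)
  vals <- extract_intensities(image, roi,
                              saturation_percentile = saturation_percentile)
  list(fit = fit_gg(vals, ...), roi = roi, segmentation = seg)
}
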