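## Per-pixel spectral acquisitions: the camera stores, for each of its 16 x 16
## detector elements, a count histogram in 0.1-keV bins from 0 to 250 keV.
## Everything downstream (window images, ROIs, count rates) starts here.

N_PIX <- 16L
N_BIN <- 2500L

#' Construct a per-pixel spectral image
#'
#' The raw measurement of the pixelated CZT camera: a 16 x 16 x 2500 cube of
#' non-negative integer counts. Bin `b` (1-based) spans energies
#' `[0.1*(b-1), 0.1*b)` keV; the last bin ends at 250.0 keV.
#'
#' @param counts Integer array of dimension `c(16, 16, 2500)`, non-negative.
#' @param duration Acquisition duration in seconds (> 0).
#' @param collimator `"LEHR"` or `"MEGP"`.
#' @param radionuclide Radionuclide label (default `"Lu-177"`).
#' @param acquired_at Optional acquisition timestamp (POSIXct or string).
#'
#' @return An object of class `spectral_image`.
#' @export
#' @examples
#' counts <- array(0L, c(16, 16, 2500))
#' counts[8, 8, 1130] <- 5L   # five counts at [112.9, 113.0) keV
#' img <- spectral_image(counts, duration = 60, collimator = "MEGP")
#' sum(img$counts)
spectral_image <- function(counts, duration, collimator = c("MEGP", "LEHR"),
                           radionuclide = "Lu-177", acquired_at = NULL) {
  collimator <- match.arg(collimator)
  if (!is.array(counts) || !identical(dim(counts), c(N_PIX, N_PIX, N_BIN)))
    stop("counts must be a 16 x 16 x 2500 array, got dimension [",
         paste(dim(counts), collapse = " x "), "]", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be integral", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a single positive number of seconds", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, bin_width_kev = GRID_KEV, duration = duration,
                 collimator = collimator, radionuclide = radionuclide,
                 acquired_at = acquired_at),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf("<spectral_image> %s / %s, %g s, %d counts total\n",
              x$radionuclide, x$collimator, x$duration, sum(x$counts)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read and write spectral images (CSV dialect)
#'
#' The open on-disk dialect is a plain-text CSV with one row per detector
#' pixel (256 rows in row-major pixel order: pixel (r, c) on line
#' `(r-1)*16 + c`) and 2500 columns of bin counts, accompanied by a YAML
#' sidecar `<path>.yaml` holding `bin_width_kev`, `duration_s`, `collimator`,
#' `radionuclide` and optionally `acquired_at`.
#'
#' @param path CSV file path. The sidecar is read from / written to
#'   `<path>.yaml`.
#' @param img A `spectral_image`.
#' @param energy_shift_bins Optional integer number of 0.1-keV bins by which
#'   to shift the spectrum on read (positive shifts counts towards higher
#'   energy); a coarse global substitute for a per-acquisition energy
#'   recalibration. Counts shifted past either end of the 0–250 keV range are
#'   dropped.
#'
#' @return `read_spectral_image` returns a validated `spectral_image`;
#'   `write_spectral_image` returns `path` invisibly.
#' @export
#' @examples
#' counts <- array(0L, c(16, 16, 2500))
#' counts[1, 1, 1131] <- 1L
#' img <- spectral_image(counts, 10, "MEGP")
#' f <- tempfile(fileext = ".csv")
#' write_spectral_image(img, f)
#' img2 <- read_spectral_image(f)
#' identical(img$counts, img2$counts)
read_spectral_image <- function(path, energy_shift_bins = 0L) {
  if (!file.exists(path))
    stop("spectral image file not found: ", path, call. = FALSE)
  if (grepl("\\.h5$|\\.hdf5$", path, ignore.case = TRUE))
    stop("HDF5 containers are not supported by this reader; ",
         "convert to the CSV + YAML dialect", call. = FALSE)
  meta_path <- sidecar_path(path)
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  for (f in c("duration_s", "collimator", "radionuclide"))
    if (is.null(meta[[f]]))
      stop("sidecar is missing required field '", f, "'", call. = FALSE)
  dt <- data.table::fread(path, header = FALSE)
  if (nrow(dt) != N_PIX * N_PIX || ncol(dt) != N_BIN)
    stop("malformed spectral CSV: expected 256 rows x 2500 columns, got ",
         nrow(dt), " x ", ncol(dt), call. = FALSE)
  m <- as.matrix(dt)
  if (anyNA(m) || any(m < 0))
    stop("spectral CSV contains negative or missing counts", call. = FALSE)
  shift <- as.integer(energy_shift_bins)
  if (shift != 0L) {
    shifted <- matrix(0L, nrow(m), ncol(m))
    src <- seq_len(N_BIN)
    dst <- src + shift
    keep <- dst >= 1L & dst <= N_BIN
    shifted[, dst[keep]] <- m[, src[keep]]
    m <- shifted
  }
  counts <- array(0L, c(N_PIX, N_PIX, N_BIN))
  for (r in seq_len(N_PIX))
    counts[r, , ] <- m[(r - 1L) * N_PIX + seq_len(N_PIX), ]
  spectral_image(counts, duration = meta$duration_s,
                 collimator = meta$collimator,
                 radionuclide = meta$radionuclide,
                 acquired_at = meta$acquired_at)
}

#' @rdname read_spectral_image
#' @export
write_spectral_image <- function(img, path) {
  stopifnot(inherits(img, "spectral_image"))
  m <- matrix(0L, N_PIX * N_PIX, N_BIN)
  for (r in seq_len(N_PIX))
    m[(r - 1L) * N_PIX + seq_len(N_PIX), ] <- img$counts[r, , ]
  data.table::fwrite(data.table::as.data.table(m), path,
                     col.names = FALSE)
  meta <- list(bin_width_kev = img$bin_width_kev, duration_s = img$duration,
               collimator = img$collimator, radionuclide = img$radionuclide)
  if (!is.null(img$acquired_at)) meta$acquired_at <- as.character(img$acquired_at)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Extract an energy-window image from a spectral image
#'
#' Sums, per pixel, the counts of all 0.1-keV bins fully contained in the
#' window under the half-open convention: bin `[e, e + 0.1)` is included when
#' `e >= lo` and `e + 0.1 <= hi`. A count recorded in the bin starting exactly
#' at `hi` therefore belongs to the next abutting window, never to both.
#'
#' @param img A `spectral_image`.
#' @param w An `energy_window`.
#' @return An object of class `window_image`: fields `values` (16 x 16 counts),
#'   `var` (per-pixel variance, equal to the raw counts until a uniformity
#'   correction rescales it), `window`, `duration`.
#' @export
extract_window_image <- function(img, w) {
  stopifnot(inherits(img, "spectral_image"), inherits(w, "energy_window"))
  lo_bin <- as.integer(round(w$lo / GRID_KEV))   # 0-based bin index of lo
  hi_bin <- as.integer(round(w$hi / GRID_KEV))
  bins <- (lo_bin + 1L):hi_bin                   # 1-based R indices
  vals <- apply(img$counts[, , bins, drop = FALSE], c(1, 2), sum)
  structure(list(values = vals, var = vals, window = w,
                 duration = img$duration),
            class = "window_image")
}

#' @export
print.window_image <- function(x, ...) {
  cat(sprintf("<window_image> %s [%.1f, %.1f) keV, %g s, %g counts\n",
              x$window$name, x$window$lo, x$window$hi, x$duration,
              sum(x$values)))
  invisible(x)
}

#' Apply a uniformity correction to a window image
#'
#' Multiplies the window image element-wise with a strictly positive 16 x 16
#' correction array (specific to radionuclide, collimator and energy window;
#' such arrays are supplied by the user, never derived here). Corrected counts
#' are no longer Poisson, so the per-pixel variance is propagated as the raw
#' variance times the squared correction.
#'
#' @param wi A `window_image`.
#' @param correction 16 x 16 matrix of strictly positive reals.
#' @return The corrected `window_image` (window and duration unchanged).
#' @export
apply_uniformity <- function(wi, correction) {
  stopifnot(inherits(wi, "window_image"))
  if (!is.matrix(correction) || !identical(dim(correction), dim(wi$values)))
    stop("correction must be a matrix with the same shape as the image",
         call. = FALSE)
  if (anyNA(correction) || any(correction <= 0))
    stop("uniformity correction entries must be strictly positive",
         call. = FALSE)
  wi$values <- wi$values * correction
  wi$var <- wi$var * correction^2
  wi
}

#' Regions of interest on the 16 x 16 pixel grid
#'
#' A circular ROI is defined by a center in fractional pixel units (row, col;
#' the center of pixel `(r, c)` is at coordinate `(r, c)`) and a radius in mm;
#' the physical pixel pitch (default 2.46 mm) converts between the two.
#' Alternatively a logical 16 x 16 mask selects pixels directly.
#'
#' @param center Numeric `(row, col)` in fractional pixel units.
#' @param radius_mm Circle radius in mm (> 0).
#' @param pixel_pitch_mm Pixel pitch in mm (default 2.46).
#' @param mask Logical 16 x 16 matrix with at least one `TRUE` pixel.
#' @return An object of class `roi`.
#' @export
#' @examples
#' roi_circle(c(8, 8), radius_mm = 12)
roi_circle <- function(center, radius_mm, pixel_pitch_mm = 2.46) {
  stopifnot(is.numeric(center), length(center) == 2L)
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0)
    stop("circle radius must be a single positive number of mm", call. = FALSE)
  structure(list(kind = "circle", center = as.numeric(center),
                 radius_mm = radius_mm, pixel_pitch_mm = pixel_pitch_mm),
            class = "roi")
}

#' @rdname roi_circle
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask) ||
      !identical(dim(mask), c(N_PIX, N_PIX)))
    stop("mask must be a logical 16 x 16 matrix", call. = FALSE)
  if (!any(mask))
    stop("mask must select at least one pixel", call. = FALSE)
  structure(list(kind = "mask", mask = mask), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  if (x$kind == "circle")
    cat(sprintf("<roi> circle at (%.2f, %.2f) px, radius %.2f mm (pitch %.2f mm)\n",
                x$center[1], x$center[2], x$radius_mm, x$pixel_pitch_mm))
  else
    cat(sprintf("<roi> mask, %d pixels\n", sum(x$mask)))
  invisible(x)
}

roi_membership <- function(roi, nrow_ = N_PIX, ncol_ = N_PIX) {
  if (roi$kind == "mask") return(roi$mask)
  rr <- matrix(seq_len(nrow_), nrow_, ncol_)
  cc <- matrix(seq_len(ncol_), nrow_, ncol_, byrow = TRUE)
  dist_mm <- roi$pixel_pitch_mm *
    sqrt((rr - roi$center[1])^2 + (cc - roi$center[2])^2)
  dist_mm <= roi$radius_mm
}

#' Automatic circular ROI from a window image
#'
#' Centers a circle at the count-weighted centre of mass of the image (in
#' fractional pixel units) with radius equal to the physical source radius
#' plus half the spatial-resolution FWHM at the source–collimator distance.
#' Conventionally computed on the 113-keV-window image and reused, unchanged,
#' for all photopeak windows so that calibration and quantification share one
#' delineation rule.
#'
#' @param wi A `window_image` with at least one positive pixel.
#' @param source_radius_mm Physical source radius in mm (>= 0).
#' @param fwhm_mm Spatial-resolution FWHM in mm at the acquisition distance
#'   (>= 0).
#' @param pixel_pitch_mm Pixel pitch in mm.
#' @return A circular `roi`.
#' @export
auto_roi <- function(wi, source_radius_mm, fwhm_mm, pixel_pitch_mm = 2.46) {
  stopifnot(inherits(wi, "window_image"),
            source_radius_mm >= 0, fwhm_mm >= 0)
  tot <- sum(wi$values)
  if (tot <= 0)
    stop("cannot place an ROI on an image with no counts", call. = FALSE)
  rr <- matrix(seq_len(nrow(wi$values)), nrow(wi$values), ncol(wi$values))
  cc <- matrix(seq_len(ncol(wi$values)), nrow(wi$values), ncol(wi$values),
               byrow = TRUE)
  center <- c(sum(rr * wi$values), sum(cc * wi$values)) / tot
  radius <- source_radius_mm + fwhm_mm / 2
  if (radius <= 0)
    stop("ROI radius is zero; provide a positive source radius or FWHM",
         call. = FALSE)
  roi_circle(center, radius, pixel_pitch_mm)
}

#' ROI count rate with Poisson variance
#'
#' Sums the window-image values over the ROI (pixel-center-in-circle
#' membership for circular ROIs, no partial-area weighting) and divides by
#' the acquisition duration. The variance is the propagated per-pixel
#' variance sum divided by duration squared; for an uncorrected image this is
#' the Poisson raw-count variance.
#'
#' @param wi A `window_image`.
#' @param roi An `roi`.
#' @return A list with `rate` (counts/s) and `variance` ((counts/s)^2).
#' @export
roi_count_rate <- function(wi, roi) {
  stopifnot(inherits(wi, "window_image"), inherits(roi, "roi"))
  member <- roi_membership(roi, nrow(wi$values), ncol(wi$values))
  if (!any(member))
    stop("ROI selects no pixels on the detector grid", call. = FALSE)
  list(rate = sum(wi$values[member]) / wi$duration,
       variance = sum(wi$var[member]) / wi$duration^2)
}
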