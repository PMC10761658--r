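## Calibration of the forward model from characterization series:
## the distance-dependent system sensitivity eps(d) = c0 + c1*exp(-d*c2)
## (the NEMA NU 1-2012 planar-sensitivity form; distance-dependent for this
## camera because of septal penetration and collimator scatter) and the
## linear build-up factor B(x) = 1 + k*x from a fixed-distance PMMA series.

#' Sensitivity and build-up model objects
#'
#' `sensitivity_model` holds the fitted parameters of the distance-dependent
#' system sensitivity `eps(d) = c0 + c1 * exp(-d * c2)` (cps/MBq, d in mm);
#' `buildup_model` holds the slope `k` of the linear build-up factor
#' `B(x) = 1 + k * x` in the dimensionless depth-attenuation product
#' `x = d * mu`. Both are tagged with the photopeak window, collimator,
#' whether the calibration rates were TEW scatter-corrected, and (for the
#' sensitivity) the calibration source geometry, because septal penetration
#' makes the sensitivity depend on source size.
#'
#' @param c0,c1,c2 Sensitivity parameters: floor (cps/MBq), amplitude
#'   (cps/MBq), decay constant (mm^-1).
#' @param window Photopeak label (`"55"`, `"113"`, `"208"`).
#' @param collimator `"MEGP"` or `"LEHR"`.
#' @param scatter_corrected Logical; `TRUE` if calibrated on TEW net rates.
#' @param source_geometry Calibration source label (e.g. `"cylinder-20mm"`).
#' @param cov Optional 3 x 3 parameter covariance from the fit.
#' @param k Build-up slope (dimensionless).
#' @return Objects of class `sensitivity_model` / `buildup_model`.
#' @export
sensitivity_model <- function(c0, c1, c2, window, collimator,
                              scatter_corrected, source_geometry = "default",
                              cov = NULL) {
  stopifnot(is.numeric(c0), is.numeric(c1), is.numeric(c2))
  structure(list(c0 = c0, c1 = c1, c2 = c2, window = as.character(window),
                 collimator = collimator,
                 scatter_corrected = isTRUE(scatter_corrected),
                 source_geometry = source_geometry, cov = cov),
            class = "sensitivity_model")
}

#' @rdname sensitivity_model
#' @export
buildup_model <- function(k, window, collimator, scatter_corrected) {
  structure(list(k = k, window = as.character(window), collimator = collimator,
                 scatter_corrected = isTRUE(scatter_corrected)),
            class = "buildup_model")
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat(sprintf(paste0("<sensitivity_model> %s keV / %s%s / %s: ",
                     "eps(d) = %.4g + %.4g * exp(-d * %.4g)\n"),
              x$window, x$collimator, if (x$scatter_corrected) " (TEW)" else "",
              x$source_geometry, x$c0, x$c1, x$c2))
  invisible(x)
}

#' @export
print.buildup_model <- function(x, ...) {
  cat(sprintf("<buildup_model> %s keV / %s%s: B(x) = 1 + %.4g * x\n",
              x$window, x$collimator,
              if (x$scatter_corrected) " (TEW)" else "", x$k))
  invisible(x)
}

#' Evaluate a sensitivity or build-up model
#'
#' @param model A `sensitivity_model` or `buildup_model`.
#' @param d Source-collimator distance(s) in mm.
#' @param x Depth-attenuation product(s) `d * mu` (dimensionless).
#' @return Sensitivity in cps/MBq, or the dimensionless build-up factor.
#' @export
eval_sensitivity <- function(model, d) {
  stopifnot(inherits(model, "sensitivity_model"))
  model$c0 + model$c1 * exp(-d * model$c2)
}

#' @rdname eval_sensitivity
#' @export
eval_buildup <- function(model, x) {
  stopifnot(inherits(model, "buildup_model"))
  1 + model$k * x
}

#' Fit the distance-dependent sensitivity model
#'
#' Ordinary (unweighted) nonlinear least squares of
#' `eps(d) = c0 + c1 * exp(-d * c2)` to a characterization series of
#' sensitivities measured at several source-collimator distances, using a
#' damped least-squares scheme. Initialization: `c0` starts at the lowest
#' measured sensitivity; `c1` and `c2` start from a linear regression of
#' `log(sensitivity - c0_init)` against distance, excluding points where the
#' subtraction is non-positive.
#'
#' @param series Data frame with columns `distance_mm` and `sensitivity`
#'   (cps/MBq); at least 4 distinct distances, all sensitivities > 0.
#' @param window,collimator,scatter_corrected,source_geometry Metadata
#'   attached to the returned model (see [sensitivity_model()]).
#' @param tol Relative parameter-change convergence tolerance.
#' @param max_iter Maximum number of damped-step iterations.
#' @return A `sensitivity_model` with fields `cov` (parameter covariance),
#'   `converged`, `n_iterations`, `chi2`, and `degenerate` (`TRUE` when the
#'   fitted amplitude `c1` is negligible against `c0`, i.e. the series shows
#'   no usable distance dependence).
#' @export
fit_sensitivity <- function(series, window = "113", collimator = "MEGP",
                            scatter_corrected = FALSE,
                            source_geometry = "default",
                            tol = 1e-8, max_iter = 200L) {
  d <- series$distance_mm
  s <- series$sensitivity
  if (length(unique(d)) < 4L)
    stop("sensitivity fit needs at least 4 distinct distances", call. = FALSE)
  if (any(s <= 0))
    stop("all sensitivities must be positive", call. = FALSE)
  c0_init <- min(s)
  excess <- s - c0_init
  keep <- excess > 0
  if (sum(keep) >= 2L) {
    fit0 <- stats::lm(log(excess[keep]) ~ d[keep])
    c1_init <- exp(unname(stats::coef(fit0)[1]))
    c2_init <- max(-unname(stats::coef(fit0)[2]), 1e-6)
  } else {
    ## flat series: no exponential component resolvable
    c1_init <- max(mean(s) * 1e-3, 1e-9)
    c2_init <- 1e-3
  }
  resid_fn <- function(p) p[1] + p[2] * exp(-d * p[3]) - s
  jac_fn <- function(p) {
    e <- exp(-d * p[3])
    cbind(1, e, -d * p[2] * e)
  }
  fit <- marquardt(c(c0_init, c1_init, c2_init), resid_fn, jac_fn,
                   tol = tol, max_iter = max_iter)
  if (!fit$converged)
    warning("sensitivity fit did not converge within ", max_iter,
            " iterations (chi2 = ", signif(fit$chi2, 4), ")")
  m <- sensitivity_model(fit$par[1], fit$par[2], fit$par[3],
                         window = window, collimator = collimator,
                         scatter_corrected = scatter_corrected,
                         source_geometry = source_geometry, cov = fit$cov)
  m$converged <- fit$converged
  m$n_iterations <- fit$n_iterations
  m$chi2 <- fit$chi2
  m$degenerate <- sum(keep) < 2L ||
    abs(fit$par[2]) < 1e-6 * max(abs(fit$par[1]), 1e-12)
  if (m$degenerate)
    warning("fitted sensitivity has negligible distance dependence (c1 ~ 0)")
  m
}

#' Build-up factors from a PMMA transmission series
#'
#' Converts a fixed-distance series of count rates measured through
#' increasing PMMA thicknesses `s` into empirical build-up factors
#' `B(s * mu) = R(s) / R(0) * exp(s * mu)`, i.e. the excess of broad-beam
#' transmission over narrow-beam exponential attenuation. The series must
#' include the unattenuated `s = 0` point; rows with non-positive rates
#' (e.g. a TEW net rate clamped at zero) are dropped with a warning since
#' the ratio is undefined there.
#'
#' @param series Data frame with columns `pmma_mm` (thickness, mm) and
#'   `rate_cps` (count rate, cps).
#' @param mu_pmma Linear attenuation coefficient of PMMA at the window's
#'   photopeak energy, mm^-1.
#' @return Data frame with columns `x` (the dimensionless product `s * mu`)
#'   and `B`.
#' @export
compute_buildup <- function(series, mu_pmma) {
  s <- series$pmma_mm
  r <- series$rate_cps
  i0 <- which(s == 0)
  if (length(i0) == 0L)
    stop("the PMMA series must include a 0-mm (unattenuated) measurement",
         call. = FALSE)
  r0 <- mean(r[i0])
  if (r0 <= 0)
    stop("the 0-mm reference rate must be positive", call. = FALSE)
  bad <- r <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive rate dropped ",
            "(build-up undefined there)")
    s <- s[!bad]; r <- r[!bad]
  }
  data.frame(x = s * mu_pmma, B = r / r0 * exp(s * mu_pmma))
}

#' Fit the linear build-up slope
#'
#' Least-squares fit of `B = 1 + k * x` with the intercept fixed at exactly 1
#' (an identity of the build-up definition at zero thickness), giving the
#' closed form `k = sum(x * (B - 1)) / sum(x^2)`.
#'
#' @param points Data frame with columns `x` and `B`, e.g. from
#'   [compute_buildup()]; must contain at least one `x > 0`.
#' @param window,collimator,scatter_corrected Metadata for the returned
#'   model.
#' @return A `buildup_model`.
#' @export
fit_buildup <- function(points, window = "113", collimator = "MEGP",
                        scatter_corrected = FALSE) {
  x <- points$x
  B <- points$B
  if (length(x) < 2L || all(x == 0))
    stop("build-up fit needs at least 2 points spanning x > 0", call. = FALSE)
  k <- sum(x * (B - 1)) / sum(x^2)
  buildup_model(k, window = window, collimator = collimator,
                scatter_corrected = scatter_corrected)
}

#' Sensitivity point from a spectral acquisition of a known activity
#'
#' Reduces one in-air characterization acquisition to a distance-tagged
#' sensitivity point: ROI count rate (gross, or TEW net) divided by the
#' known activity decay-corrected to the acquisition time.
#'
#' @param img A `spectral_image`.
#' @param known_activity_mbq Activity at the reference time (MBq, > 0).
#' @param distance_mm Source-collimator distance of the acquisition (mm).
#' @param windows An [lu177_windows()] set.
#' @param roi An `roi`, or `NULL` to place one automatically on the
#'   113-keV-window image via [auto_roi()] (the same circle is reused for
#'   every window).
#' @param tew Logical; apply TEW scatter correction.
#' @param dt_s Seconds elapsed from the activity reference time to the
#'   acquisition (the activity is decayed forward by this amount).
#' @param uniformity Optional named list of 16 x 16 correction matrices
#'   keyed by window label.
#' @param source_radius_mm,fwhm_mm Passed to [auto_roi()] when `roi` is
#'   `NULL`.
#' @return Data frame with one row per photopeak window: `distance_mm`,
#'   `window`, `sensitivity` (cps/MBq), `variance`, `clamped`.
#' @export
sensitivity_from_measurement <- function(img, known_activity_mbq, distance_mm,
                                         windows = lu177_windows(), roi = NULL,
                                         tew = TRUE, dt_s = 0,
                                         uniformity = NULL,
                                         source_radius_mm = 10, fwhm_mm = 8) {
  stopifnot(inherits(img, "spectral_image"))
  if (known_activity_mbq <= 0)
    stop("known activity must be positive", call. = FALSE)
  A_acq <- decay_correct(known_activity_mbq, dt = -dt_s)
  if (is.null(roi)) {
    wi113 <- extract_window_image(img, windows[["113"]]$main)
    roi <- auto_roi(wi113, source_radius_mm, fwhm_mm)
  }
  rows <- lapply(names(windows), function(nm) {
    peak <- windows[[nm]]
    get_rate <- function(w) {
      wi <- extract_window_image(img, w)
      if (!is.null(uniformity[[nm]])) wi <- apply_uniformity(wi, uniformity[[nm]])
      roi_count_rate(wi, roi)
    }
    main <- get_rate(peak$main)
    if (tew) {
      res <- tew_net_rate(main, get_rate(peak$lower_scatter),
                          get_rate(peak$upper_scatter), peak)
      rate <- res$net_rate; variance <- res$variance; clamped <- res$clamped
    } else {
      rate <- main$rate; variance <- main$variance; clamped <- FALSE
    }
    data.frame(distance_mm = distance_mm, window = nm,
               sensitivity = rate / A_acq, variance = variance / A_acq^2,
               clamped = clamped)
  })
  do.call(rbind, rows)
}

## ---- calibration library ---------------------------------------------------

cal_key <- function(radionuclide, collimator, window, scatter_corrected,
                    source_geometry) {
  paste(radionuclide, collimator, window,
        if (isTRUE(scatter_corrected)) "tew" else "gross",
        source_geometry, sep = "|")
}

#' Calibration library
#'
#' A container of fitted `(sensitivity_model, buildup_model)` pairs keyed by
#' (radionuclide, collimator, photopeak window, scatter-correction mode,
#' source geometry). Lookups require an exact key match: a missing entry is
#' an error listing the available keys, never a silent default, and a
#' cross-geometry lookup is refused unless explicitly overridden (source
#' size changes the septal-penetration fraction, so geometry matters).
#'
#' @param lib A `calibration_library`.
#' @param sens A `sensitivity_model`.
#' @param buildup A `buildup_model` (must agree with `sens` on window,
#'   collimator and scatter-correction mode).
#' @param radionuclide Radionuclide label.
#' @param collimator,window,scatter_corrected,source_geometry Lookup key
#'   parts.
#' @param allow_geometry_mismatch Logical; when `TRUE`, a lookup that fails
#'   on the exact geometry falls back to any entry matching the remaining
#'   key parts (with a warning).
#' @return `calibration_library()` an empty library; `cal_add()` the updated
#'   library; `cal_lookup()` a list with `sensitivity` and `buildup`.
#' @export
#' @examples
#' lib <- calibration_library()
#' s <- sensitivity_model(0.5, 12, 0.02, "113", "MEGP", TRUE, "cylinder-20mm")
#' b <- buildup_model(0.2, "113", "MEGP", TRUE)
#' lib <- cal_add(lib, s, b)
calibration_library <- function() {
  structure(list(entries = list()), class = "calibration_library")
}

#' @rdname calibration_library
#' @export
cal_add <- function(lib, sens, buildup, radionuclide = "Lu-177") {
  stopifnot(inherits(lib, "calibration_library"),
            inherits(sens, "sensitivity_model"),
            inherits(buildup, "buildup_model"))
  if (sens$window != buildup$window ||
      sens$collimator != buildup$collimator ||
      sens$scatter_corrected != buildup$scatter_corrected)
    stop("sensitivity and build-up models disagree on window/collimator/",
         "scatter mode", call. = FALSE)
  key <- cal_key(radionuclide, sens$collimator, sens$window,
                 sens$scatter_corrected, sens$source_geometry)
  lib$entries[[key]] <- list(sensitivity = sens, buildup = buildup)
  lib
}

#' @rdname calibration_library
#' @export
cal_lookup <- function(lib, collimator, window, scatter_corrected,
                       source_geometry = "default", radionuclide = "Lu-177",
                       allow_geometry_mismatch = FALSE) {
  stopifnot(inherits(lib, "calibration_library"))
  key <- cal_key(radionuclide, collimator, window, scatter_corrected,
                 source_geometry)
  entry <- lib$entries[[key]]
  if (is.null(entry) && allow_geometry_mismatch) {
    prefix <- cal_key(radionuclide, collimator, window, scatter_corrected, "")
    hits <- grep(paste0("^", gsub("([|])", "\\\\\\1", prefix)),
                 names(lib$entries), value = TRUE)
    if (length(hits)) {
      warning("calibration geometry '", source_geometry,
              "' not found; falling back to '", hits[1], "'")
      entry <- lib$entries[[hits[1]]]
    }
  }
  if (is.null(entry))
    stop("no calibration entry for key '", key, "'; available keys:\n  ",
         paste(names(lib$entries), collapse = "\n  "), call. = FALSE)
  entry
}

#' @export
print.calibration_library <- function(x, ...) {
  cat("<calibration_library> with", length(x$entries), "entries\n")
  for (k in names(x$entries)) cat("  ", k, "\n")
  invisible(x)
}

#' Read and write a calibration library as YAML
#'
#' @param lib A `calibration_library`.
#' @param path YAML file path.
#' @param provenance Optional named list (input hashes, fit diagnostics)
#'   stored alongside the entries.
#' @return `read_calibration_library` returns a `calibration_library`;
#'   `write_calibration_library` returns `path` invisibly.
#' @export
write_calibration_library <- function(lib, path, provenance = NULL) {
  stopifnot(inherits(lib, "calibration_library"))
  out <- lapply(lib$entries, function(e) list(
    sensitivity = list(c0 = e$sensitivity$c0, c1 = e$sensitivity$c1,
                       c2 = e$sensitivity$c2,
                       window = e$sensitivity$window,
                       collimator = e$sensitivity$collimator,
                       scatter_corrected = e$sensitivity$scatter_corrected,
                       source_geometry = e$sensitivity$source_geometry),
    buildup = list(k = e$buildup$k)))
  yaml::write_yaml(list(entries = out, provenance = provenance), path)
  invisible(path)
}

#' @rdname write_calibration_library
#' @export
read_calibration_library <- function(path) {
  raw <- yaml::read_yaml(path)
  lib <- calibration_library()
  for (key in names(raw$entries)) {
    e <- raw$entries[[key]]
    s <- e$sensitivity
    sens <- sensitivity_model(s$c0, s$c1, s$c2, s$window, s$collimator,
                              s$scatter_corrected, s$source_geometry)
    bu <- buildup_model(e$buildup$k, s$window, s$collimator,
                        s$scatter_corrected)
    radionuclide <- strsplit(key, "|", fixed = TRUE)[[1]][1]
    lib <- cal_add(lib, sens, bu, radionuclide = radionuclide)
  }
  lib
}
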