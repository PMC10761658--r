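## Synthetic-data generator. Everything is drawn from the same forward model
## the estimator inverts — distance-dependent sensitivity, exponential
## attenuation, linear build-up — with Poisson counting noise, so the whole
## chain (spectra -> TEW -> calibration -> estimation) is testable without
## instrument data. The generator does NOT model CZT low-energy tailing or
## septal-penetration star patterns; scatter-window content is injected as an
## explicit per-window scatter fraction so the TEW correction has a
## well-defined component to remove.

#' Synthetic truth calibration constants
#'
#' A set of plausible `(c0, c1, c2, k)` values per photopeak window and
#' collimator used as ground truth by the simulator. The constants are
#' synthetic (no instrument characterization is shipped) but
#' order-of-magnitude realistic for a small CZT camera: sensitivities of a
#' few to tens of cps/MBq with a distance dependence that is strongest for
#' LEHR at 208 keV (septal penetration), and build-up slopes that are larger
#' in gross mode than after TEW correction.
#'
#' @param collimator `"MEGP"` or `"LEHR"`.
#' @param scatter_corrected Logical; truth for TEW net rates (`TRUE`) or
#'   gross rates (`FALSE`).
#' @param source_geometry Geometry label attached to the models.
#' @return Named list keyed by window (`"55"`, `"113"`, `"208"`), each a
#'   list with `sensitivity` and `buildup` models.
#' @export
#' @examples
#' truth <- synthetic_truth_calibration("MEGP", scatter_corrected = TRUE)
#' truth[["113"]]$sensitivity
synthetic_truth_calibration <- function(collimator = c("MEGP", "LEHR"),
                                        scatter_corrected = TRUE,
                                        source_geometry = "cylinder-20mm") {
  collimator <- match.arg(collimator)
  pars <- list(
    MEGP = list("55"  = c(0.3, 6,  0.025, 0.35),
                "113" = c(0.5, 12, 0.020, 0.20),
                "208" = c(0.4, 8,  0.015, 0.10)),
    LEHR = list("55"  = c(0.6, 10, 0.030, 0.40),
                "113" = c(1.0, 20, 0.025, 0.25),
                "208" = c(2.0, 15, 0.010, 0.15)))[[collimator]]
  out <- lapply(names(pars), function(nm) {
    p <- pars[[nm]]
    if (!scatter_corrected) {
      ## gross rates carry the scatter the TEW mode removes: higher
      ## sensitivity and a steeper build-up slope
      p <- c(p[1:3] * c(1.3, 1.3, 1), p[4] + 0.15)
    }
    list(sensitivity = sensitivity_model(p[1], p[2], p[3], nm, collimator,
                                         scatter_corrected, source_geometry),
         buildup = buildup_model(p[4], nm, collimator, scatter_corrected))
  })
  names(out) <- names(pars)
  out
}

#' Default per-window scatter fractions
#'
#' Fraction of the primary window rate injected as scatter by the spectral
#' simulator, largest at 55 keV where low-energy tailing and scatter
#' contaminate the spectrum most. Values are synthetic defaults.
#'
#' @return Named numeric vector keyed by window label.
#' @export
default_scatter_fractions <- function() c("55" = 0.6, "113" = 0.25, "208" = 0.1)

#' Define a simulation scenario
#'
#' @param true_A True source activity (MBq, > 0).
#' @param true_d True source depth (mm).
#' @param material A `material` for the attenuating medium.
#' @param calibration Truth calibration: named list per window with
#'   `sensitivity` and `buildup` models (default
#'   [synthetic_truth_calibration()] for the given collimator).
#' @param collimator `"MEGP"` or `"LEHR"`.
#' @param scatter_corrected Logical; whether the truth calibration describes
#'   TEW net rates.
#' @param duration_s Acquisition duration (s, > 0).
#' @param seed Integer RNG seed recorded in the scenario.
#' @param scatter_fraction Named per-window scatter fractions for the
#'   spectral simulator.
#' @param image Optional image spec: list with `center` (fractional pixel
#'   `(row, col)`), `source_radius_mm`, `fwhm_a_mm`, `fwhm_b` (the
#'   resolution model `FWHM(d) = a + b * d`), `background_fraction`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(true_A, true_d, material = material_library()$soft_tissue,
                          calibration = NULL, collimator = "MEGP",
                          scatter_corrected = TRUE, duration_s = 300,
                          seed = 1L,
                          scatter_fraction = default_scatter_fractions(),
                          image = NULL) {
  stopifnot(true_A > 0, duration_s > 0, inherits(material, "material"))
  if (is.null(calibration))
    calibration <- synthetic_truth_calibration(collimator, scatter_corrected)
  if (!is.null(image)) {
    defaults <- list(center = c(8.5, 8.5), source_radius_mm = 10,
                     fwhm_a_mm = 4, fwhm_b = 0.05, background_fraction = 0)
    defaults[names(image)] <- image
    image <- defaults
    if (image$fwhm_a_mm + image$fwhm_b * max(true_d, 0) <= 0)
      stop("image FWHM must be positive", call. = FALSE)
  }
  structure(list(true_A = true_A, true_d = true_d, material = material,
                 calibration = calibration, collimator = collimator,
                 scatter_corrected = isTRUE(scatter_corrected),
                 duration_s = duration_s, seed = as.integer(seed),
                 scatter_fraction = scatter_fraction, image = image),
            class = "scenario_spec")
}

## Poisson draw that stays exact for ordinary counts and switches to the
## (moment-matched) normal approximation for the extreme means used in
## law-of-large-numbers checks, where rpois overflows integer range.
rpois_safe <- function(n, lambda) {
  if (any(lambda > 1e18)) stop("expected counts overflow", call. = FALSE)
  big <- lambda > 1e7
  out <- numeric(length(lambda))
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big)) out[big] <- round(stats::rnorm(sum(big), lambda[big],
                                               sqrt(lambda[big])))
  pmax(out, 0)
}

scenario_rates <- function(spec) {
  mu <- linear_attenuation(spec$material, names(spec$calibration))
  sens <- lapply(spec$calibration, `[[`, "sensitivity")
  bup <- lapply(spec$calibration, `[[`, "buildup")
  forward_model(spec$true_A, spec$true_d, mu, sens, bup)
}

#' Simulate a window-rate measurement
#'
#' Draws per-window counts from `Poisson(R_i * duration)` with `R_i` the
#' forward-model rate of the scenario, and packages them as a
#' `measurement_set` with Poisson rate variances. With `noise = FALSE` the
#' exact expected rates are returned (variance from expected counts), which
#' closes noise-free recovery loops exactly.
#'
#' @param spec A `scenario_spec`.
#' @param noise Logical; draw Poisson counts (default) or return the exact
#'   expectation.
#' @return A `measurement_set`; attribute `counts` holds the drawn counts.
#' @export
simulate_measurement <- function(spec, noise = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  rates <- scenario_rates(spec)
  lambda <- rates * spec$duration_s
  if (noise) {
    set.seed(spec$seed)
    counts <- rpois_safe(length(lambda), lambda)
  } else counts <- lambda
  obs_rate <- counts / spec$duration_s
  variance <- pmax(counts, 1) / spec$duration_s^2
  ms <- measurement_set(
    data.frame(window = names(rates), rate_cps = obs_rate,
               variance = variance, clamped = FALSE),
    collimator = spec$collimator,
    scatter_corrected = spec$scatter_corrected,
    duration_s = spec$duration_s)
  attr(ms, "counts") <- stats::setNames(counts, names(rates))
  attr(ms, "expected_rates") <- rates
  ms
}

#' Simulate an in-air sensitivity characterization series
#'
#' Emulates the distance series used to calibrate the sensitivity model: at
#' each source-collimator distance the expected rate is
#' `activity * eps_i(d)` (in air — no attenuation or build-up), Poisson
#' sampled over the acquisition duration.
#'
#' @param truth Named list of truth `sensitivity_model` objects per window.
#' @param distances_mm Numeric vector of distances (mm).
#' @param activity_mbq Source activity (MBq).
#' @param duration_s Acquisition duration per distance (s).
#' @param seed Integer seed.
#' @param noise Logical; `FALSE` returns exact expected values.
#' @return Data frame with columns `window`, `distance_mm`, `rate_cps`,
#'   `rate_var`, `sensitivity` (cps/MBq), `variance`.
#' @export
simulate_sensitivity_series <- function(truth, distances_mm = seq(0, 160, 20),
                                        activity_mbq = 10, duration_s = 120,
                                        seed = 1L, noise = TRUE) {
  if (noise) set.seed(seed)
  rows <- lapply(names(truth), function(nm) {
    eps <- eval_sensitivity(truth[[nm]], distances_mm)
    lambda <- activity_mbq * eps * duration_s
    counts <- if (noise) rpois_safe(length(lambda), lambda) else lambda
    rate <- counts / duration_s
    rate_var <- pmax(counts, 1) / duration_s^2
    data.frame(window = nm, distance_mm = distances_mm, rate_cps = rate,
               rate_var = rate_var, sensitivity = rate / activity_mbq,
               variance = rate_var / activity_mbq^2)
  })
  do.call(rbind, rows)
}

#' Simulate a fixed-distance PMMA build-up series
#'
#' Emulates the PMMA-slab transmission series used to calibrate the build-up
#' factor: the expected rate at thickness `s` is
#' `R0 * exp(-s * mu) * (1 + k * s * mu)`.
#'
#' @param truth Named list per window with `buildup` models (e.g. from
#'   [synthetic_truth_calibration()]).
#' @param rate0_cps Named unattenuated (s = 0) expected rate per window.
#' @param pmma_mm PMMA thicknesses (mm); must include 0.
#' @param mu_pmma Named linear attenuation coefficients of PMMA per window
#'   (mm^-1), e.g. `linear_attenuation(material_library()$pmma)`.
#' @param duration_s Acquisition duration per thickness (s).
#' @param seed Integer seed.
#' @param noise Logical; `FALSE` returns exact expected values.
#' @return Data frame with columns `window`, `pmma_mm`, `rate_cps`,
#'   `rate_var`.
#' @export
simulate_buildup_series <- function(truth, rate0_cps, pmma_mm = seq(0, 90, 10),
                                    mu_pmma = linear_attenuation(material_library()$pmma),
                                    duration_s = 120, seed = 1L, noise = TRUE) {
  if (!any(pmma_mm == 0))
    stop("the PMMA thickness grid must include 0", call. = FALSE)
  if (noise) set.seed(seed)
  rows <- lapply(names(truth), function(nm) {
    k <- truth[[nm]]$buildup$k
    x <- pmma_mm * mu_pmma[[nm]]
    lambda <- rate0_cps[[nm]] * exp(-x) * (1 + k * x) * duration_s
    counts <- if (noise) rpois_safe(length(lambda), lambda) else lambda
    data.frame(window = nm, pmma_mm = pmma_mm,
               rate_cps = counts / duration_s,
               rate_var = pmax(counts, 1) / duration_s^2)
  })
  do.call(rbind, rows)
}

#' Simulate a per-pixel spectral image
#'
#' Generates a full 16 x 16 x 2500 spectral acquisition from a scenario:
#' each photopeak's primary rate comes from the forward model; the gross
#' main-window rate additionally carries `scatter_fraction * R_i` of
#' scatter, and the flanking scatter windows receive rates chosen so that
#' the TEW trapezoid estimate equals that injected scatter in expectation.
#' Within every window the expected counts are spread spatially as an
#' isotropic Gaussian (FWHM from the linear resolution model
#' `FWHM = a + b * d`, truncated to the detector and renormalized) on top of
#' a uniform background fraction, and uniformly across the window's 0.1-keV
#' bins; every (pixel, bin) cell is then Poisson sampled.
#'
#' @param spec A `scenario_spec` with a non-null `image` field.
#' @param windows An [lu177_windows()] set.
#' @return A `spectral_image`; attribute `expected_rates` holds the
#'   primary (scatter-free) forward-model rates per window.
#' @export
simulate_spectral_image <- function(spec, windows = lu177_windows()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(spec$image))
    stop("scenario has no image spec; pass `image = list(...)`", call. = FALSE)
  img_spec <- spec$image
  fwhm <- img_spec$fwhm_a_mm + img_spec$fwhm_b * max(spec$true_d, 0)
  if (fwhm <= 0) stop("image FWHM must be positive", call. = FALSE)
  pitch <- 2.46
  sigma_px <- fwhm / (2 * sqrt(2 * log(2))) / pitch
  rr <- matrix(seq_len(N_PIX), N_PIX, N_PIX)
  cc <- matrix(seq_len(N_PIX), N_PIX, N_PIX, byrow = TRUE)
  g <- exp(-((rr - img_spec$center[1])^2 + (cc - img_spec$center[2])^2) /
             (2 * sigma_px^2))
  g <- g / sum(g)
  bg <- img_spec$background_fraction
  spatial <- (1 - bg) * g + bg / (N_PIX * N_PIX)
  rates <- scenario_rates(spec)
  set.seed(spec$seed)
  counts <- array(0L, c(N_PIX, N_PIX, N_BIN))
  for (nm in names(windows)) {
    peak <- windows[[nm]]
    sf <- if (nm %in% names(spec$scatter_fraction))
      spec$scatter_fraction[[nm]] else 0
    R <- rates[[nm]]
    w_m <- window_width(peak$main)
    w_l <- window_width(peak$lower_scatter)
    w_u <- window_width(peak$upper_scatter)
    ## scatter-window rate making the TEW trapezoid equal sf * R in expectation
    s_rate <- 2 * sf * R / (w_m * (1 / w_l + 1 / w_u))
    win_rates <- c(main = R * (1 + sf), lower = s_rate, upper = s_rate)
    wins <- list(main = peak$main, lower = peak$lower_scatter,
                 upper = peak$upper_scatter)
    for (part in names(wins)) {
      w <- wins[[part]]
      lo_bin <- as.integer(round(w$lo / GRID_KEV))
      hi_bin <- as.integer(round(w$hi / GRID_KEV))
      bins <- (lo_bin + 1L):hi_bin
      lambda_px <- win_rates[[part]] * spec$duration_s * spatial
      lambda_cube <- array(rep(lambda_px / length(bins), length(bins)),
                           c(N_PIX, N_PIX, length(bins)))
      counts[, , bins] <- counts[, , bins] +
        array(as.integer(rpois_safe(length(lambda_cube), lambda_cube)),
              dim(lambda_cube))
    }
  }
  out <- spectral_image(counts, duration = spec$duration_s,
                        collimator = spec$collimator,
                        radionuclide = "Lu-177")
  attr(out, "expected_rates") <- rates
  out
}

#' Reduce a spectral image to TEW net rates
#'
#' Convenience wrapper running the analysis chain on a spectral image:
#' window extraction, optional uniformity correction, automatic (or given)
#' ROI, ROI rates, and TEW scatter correction — yielding a
#' `measurement_set` ready for [estimate_activity_depth()].
#'
#' @param img A `spectral_image`.
#' @param windows An [lu177_windows()] set.
#' @param roi An `roi`, or `NULL` for [auto_roi()] on the 113-keV window.
#' @param tew Logical; apply TEW.
#' @param uniformity Optional named list of correction matrices per window.
#' @param source_radius_mm,fwhm_mm [auto_roi()] parameters used when `roi`
#'   is `NULL`.
#' @return A `measurement_set` (TEW-propagated variances in the `variance`
#'   column when `tew = TRUE`).
#' @export
measure_spectral_image <- function(img, windows = lu177_windows(), roi = NULL,
                                   tew = TRUE, uniformity = NULL,
                                   source_radius_mm = 10, fwhm_mm = 8) {
  stopifnot(inherits(img, "spectral_image"))
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
      data.frame(window = nm, rate_cps = res$net_rate,
                 variance = res$variance, clamped = res$clamped)
    } else {
      data.frame(window = nm, rate_cps = main$rate,
                 variance = main$variance, clamped = FALSE)
    }
  })
  measurement_set(do.call(rbind, rows), collimator = img$collimator,
                  scatter_corrected = tew, duration_s = img$duration)
}
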