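## Photon physics helpers: attenuation coefficients for pure and mixed
## materials, radioactive decay correction, and the intra-source
## self-attenuation adjustment. Internal length unit is mm, internal linear
## attenuation unit mm^-1; mass attenuation coefficients are carried in the
## conventional cm^2/g.

#' Define a material
#'
#' @param name Material label.
#' @param density Density in g/cm^3 (> 0).
#' @param mass_attenuation Named numeric vector of mass attenuation
#'   coefficients mu/rho in cm^2/g, keyed by photopeak energy label
#'   (e.g. `c("55" = 0.20, "113" = 0.16, "208" = 0.13)`); all entries > 0.
#' @return An object of class `material`.
#' @export
#' @examples
#' material("pmma", 1.18, c("55" = 0.20, "113" = 0.16, "208" = 0.13))
material <- function(name, density, mass_attenuation) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a single positive number (g/cm^3)", call. = FALSE)
  ma <- unlist(mass_attenuation)
  if (is.null(names(ma)) || any(!nzchar(names(ma))))
    stop("mass_attenuation must be named by photopeak energy", call. = FALSE)
  if (anyNA(ma) || any(ma < 0))
    stop("mass attenuation coefficients must be non-negative", call. = FALSE)
  structure(list(name = name, density = density, mass_attenuation = ma),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s, rho = %.3g g/cm^3\n", x$name, x$density))
  for (nm in names(x$mass_attenuation))
    cat(sprintf("  mu/rho(%s keV) = %.4g cm^2/g\n", nm, x$mass_attenuation[[nm]]))
  invisible(x)
}

#' Built-in material library
#'
#' Loads the packaged material definitions (water, soft tissue, cortical
#' bone, PMMA) with mass attenuation coefficients at the three Lu-177
#' photopeak energies. Optionally merges user materials from a YAML file of
#' the same layout; user entries override built-ins of the same name.
#'
#' @param user_path Optional path to a user material YAML file.
#' @return A named list of `material` objects.
#' @export
#' @examples
#' lib <- material_library()
#' lib$pmma
material_library <- function(user_path = NULL) {
  path <- system.file("extdata", "materials.yaml", package = "luquant")
  raw <- yaml::read_yaml(path)
  if (!is.null(user_path)) {
    user <- yaml::read_yaml(user_path)
    raw[names(user)] <- user
  }
  out <- lapply(names(raw), function(nm)
    material(nm, raw[[nm]]$density, unlist(raw[[nm]]$mass_attenuation)))
  names(out) <- names(raw)
  out
}

#' Linear attenuation coefficients of a material
#'
#' Converts mass attenuation coefficients to linear attenuation coefficients,
#' `mu = density * (mu/rho)`, returned in mm^-1 (input cm^2/g and g/cm^3 give
#' cm^-1; divided by 10).
#'
#' @param m A `material`.
#' @param energies Optional character vector of photopeak labels to extract;
#'   default all entries of the material. Missing entries are an error.
#' @return A named numeric vector of `mu` in mm^-1 (class
#'   `attenuation_context`).
#' @export
#' @examples
#' mu <- linear_attenuation(material_library()$pmma)
#' mu[["55"]]   # 1.18 * 0.20 / 10 = 0.0236 mm^-1
linear_attenuation <- function(m, energies = NULL) {
  stopifnot(inherits(m, "material"))
  if (is.null(energies)) energies <- names(m$mass_attenuation)
  missing <- setdiff(energies, names(m$mass_attenuation))
  if (length(missing))
    stop("material '", m$name, "' has no mass attenuation entry for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mu <- m$density * m$mass_attenuation[energies] / 10
  structure(mu, class = c("attenuation_context", "numeric"))
}

#' Mass-fraction mixture of materials
#'
#' Combines materials by mass fraction: the mixture's mass attenuation
#' coefficient is the mass-weighted sum of the components', and its density
#' follows the mass-weighted inverse rule `1 / sum(w_j / rho_j)` (component
#' volumes add). Used e.g. for a 50% soft-tissue / 50% cortical-bone medium
#' when quantifying skeletal lesions.
#'
#' @param materials List of `material` objects.
#' @param fractions Numeric mass fractions, same length, non-negative,
#'   summing to 1 (within 1e-9).
#' @param name Label for the mixture.
#' @return A `material`.
#' @export
#' @examples
#' lib <- material_library()
#' mixture(list(lib$soft_tissue, lib$cortical_bone), c(0.5, 0.5))
mixture <- function(materials, fractions, name = "mixture") {
  stopifnot(length(materials) == length(fractions),
            all(vapply(materials, inherits, logical(1), "material")))
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("mass fractions must be non-negative and sum to 1", call. = FALSE)
  energies <- names(materials[[1]]$mass_attenuation)
  for (m in materials)
    if (!setequal(names(m$mass_attenuation), energies))
      stop("all materials must cover the same photopeak energies", call. = FALSE)
  ma <- Reduce(`+`, Map(function(m, w) w * m$mass_attenuation[energies],
                        materials, fractions))
  density <- 1 / sum(fractions / vapply(materials, `[[`, numeric(1), "density"))
  material(name, density, ma)
}

#' Radioactive decay correction
#'
#' Rescales an activity along the exponential decay law by
#' `A * 2^(dt / half_life)`. With `dt > 0` the activity is corrected *back*
#' to an earlier reference time (the factor exceeds 1); a negative `dt`
#' decays it forward.
#'
#' @param A Activity (MBq).
#' @param dt Time difference in seconds between measurement and reference
#'   (positive when the reference precedes the measurement).
#' @param half_life Half-life in seconds (> 0); defaults to
#'   [lu177_half_life()].
#' @return The corrected activity (MBq).
#' @export
#' @examples
#' decay_correct(10, dt = lu177_half_life())       # 20: one half-life back
#' decay_correct(10, dt = -2 * lu177_half_life())  # 2.5: two half-lives forward
decay_correct <- function(A, dt, half_life = lu177_half_life()) {
  if (!is.numeric(half_life) || half_life <= 0)
    stop("half_life must be positive", call. = FALSE)
  A * 2^(dt / half_life)
}

## Uniform-slab self-attenuation factor: mean transmission of photons emitted
## uniformly through a slab of thickness T viewed face-on,
## f(T) = (1 - exp(-mu*T)) / (mu*T), with f -> 1 as mu*T -> 0.
slab_self_attenuation <- function(mu, thickness_mm) {
  x <- mu * thickness_mm
  ifelse(x < 1e-12, 1 - x / 2, (1 - exp(-x)) / x)
}

#' Intra-source attenuation correction factor
#'
#' When the thickness of the measured source differs from that of the
#' phantom used for the sensitivity calibration, their intra-source
#' self-attenuation differs and the estimated activity must be rescaled.
#' Modelling each source as a uniform slab of activity viewed face-on, the
#' mean escape probability is `f(T) = (1 - exp(-mu*T)) / (mu*T)` (with
#' `f(0) = 1`), and the correction multiplies the estimated activity by
#' `f(T_calibration) / f(T_measured)`.
#'
#' @param mu Linear attenuation coefficient of the source medium in mm^-1
#'   (>= 0).
#' @param thickness_measured_mm Thickness of the measured source (mm, >= 0).
#' @param thickness_calibration_mm Thickness of the calibration source
#'   (mm, >= 0).
#' @return Dimensionless multiplicative factor for the estimated activity.
#' @export
#' @examples
#' intra_source_correction(0.016, thickness_measured_mm = 4,
#'                         thickness_calibration_mm = 8)
intra_source_correction <- function(mu, thickness_measured_mm,
                                    thickness_calibration_mm) {
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  if (thickness_measured_mm < 0 || thickness_calibration_mm < 0)
    stop("source thicknesses must be non-negative", call. = FALSE)
  slab_self_attenuation(mu, thickness_calibration_mm) /
    slab_self_attenuation(mu, thickness_measured_mm)
}
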