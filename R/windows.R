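## Energy windows. All bounds live on the detector's 0.1-keV bin grid and
## follow a half-open [lo, hi) convention so that the abutting windows of one
## photopeak (lower scatter | main | upper scatter) can never double-count.

GRID_KEV <- 0.1

on_grid <- function(x, tol = 1e-9) {
  abs(x / GRID_KEV - round(x / GRID_KEV)) < tol
}

#' Define an energy window
#'
#' @param name Label for the window.
#' @param lo,hi Window bounds in keV. Must lie on the 0.1-keV bin grid and
#'   satisfy `0 <= lo < hi <= 250`. The window is half-open: a count recorded
#'   in the bin starting exactly at `hi` is excluded (it belongs to the next
#'   abutting window).
#'
#' @return An object of class `energy_window` with fields `name`, `lo`, `hi`.
#' @export
#' @examples
#' energy_window("113 keV main", 100.5, 120.8)
energy_window <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo >= 0 && lo < hi && hi <= 250))
    stop("energy window must satisfy 0 <= lo < hi <= 250 keV, got [",
         lo, ", ", hi, ")", call. = FALSE)
  if (!on_grid(lo) || !on_grid(hi))
    stop("window bounds must be integer multiples of 0.1 keV, got [",
         lo, ", ", hi, ")", call. = FALSE)
  structure(list(name = name, lo = lo, hi = hi), class = "energy_window")
}

#' @export
print.energy_window <- function(x, ...) {
  cat(sprintf("<energy_window> %s: [%.1f, %.1f) keV\n", x$name, x$lo, x$hi))
  invisible(x)
}

window_width <- function(w) w$hi - w$lo

#' Default Lu-177 energy window set
#'
#' The nine windows used for Lu-177 imaging with this camera: for each of the
#' three photopeaks (55.8, 112.9, 208.4 keV) a main window flanked by abutting
#' lower and upper scatter windows. The lower scatter window's upper edge
#' coincides with the main window's lower edge, and likewise at the upper
#' edge, so under the half-open bin convention every 0.1-keV bin belongs to
#' exactly one window.
#'
#' @return An object of class `energy_window_set`: a named list with entries
#'   `"55"`, `"113"`, `"208"`, each a list with `photopeak_energy` (keV) and
#'   `energy_window` objects `lower_scatter`, `main`, `upper_scatter`.
#' @export
#' @examples
#' ws <- lu177_windows()
#' ws[["113"]]$main
lu177_windows <- function() {
  mk <- function(label, peak, b) {
    list(photopeak_energy = peak,
         lower_scatter = energy_window(paste0(label, " lower scatter"), b[1], b[2]),
         main          = energy_window(paste0(label, " main"),          b[2], b[3]),
         upper_scatter = energy_window(paste0(label, " upper scatter"), b[3], b[4]))
  }
  ws <- list(
    "55"  = mk("55 keV",  55.8,  c(45.8,  49.7,  59.7,  63.6)),
    "113" = mk("113 keV", 112.9, c(96.5, 100.5, 120.8, 124.8)),
    "208" = mk("208 keV", 208.4, c(186.5, 193.8, 216.7, 224.0))
  )
  structure(ws, class = "energy_window_set")
}

#' @export
print.energy_window_set <- function(x, ...) {
  cat("<energy_window_set>\n")
  for (nm in names(x)) {
    p <- x[[nm]]
    cat(sprintf("  %s keV peak (%.1f): %.1f-%.1f | %.1f-%.1f | %.1f-%.1f\n",
                nm, p$photopeak_energy,
                p$lower_scatter$lo, p$lower_scatter$hi,
                p$main$lo, p$main$hi,
                p$upper_scatter$lo, p$upper_scatter$hi))
  }
  invisible(x)
}

validate_window_set <- function(ws) {
  stopifnot(inherits(ws, "energy_window_set"))
  for (nm in names(ws)) {
    p <- ws[[nm]]
    if (abs(p$lower_scatter$hi - p$main$lo) > 1e-9 ||
        abs(p$main$hi - p$upper_scatter$lo) > 1e-9)
      stop("scatter windows of photopeak ", nm, " do not abut the main window",
           call. = FALSE)
  }
  invisible(ws)
}

#' Serialize / deserialize an energy window set to YAML
#'
#' @param ws An `energy_window_set`.
#' @param path File path.
#' @return `read_window_set` returns an `energy_window_set`;
#'   `write_window_set` returns `path` invisibly.
#' @export
write_window_set <- function(ws, path) {
  validate_window_set(ws)
  out <- lapply(ws, function(p) list(
    photopeak_energy = p$photopeak_energy,
    lower_scatter = c(p$lower_scatter$lo, p$lower_scatter$hi),
    main          = c(p$main$lo, p$main$hi),
    upper_scatter = c(p$upper_scatter$lo, p$upper_scatter$hi)))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_window_set
#' @export
read_window_set <- function(path) {
  raw <- yaml::read_yaml(path)
  ws <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    list(photopeak_energy = p$photopeak_energy,
         lower_scatter = energy_window(paste0(nm, " keV lower scatter"),
                                       p$lower_scatter[1], p$lower_scatter[2]),
         main          = energy_window(paste0(nm, " keV main"),
                                       p$main[1], p$main[2]),
         upper_scatter = energy_window(paste0(nm, " keV upper scatter"),
                                       p$upper_scatter[1], p$upper_scatter[2]))
  })
  names(ws) <- names(raw)
  validate_window_set(structure(ws, class = "energy_window_set"))
}
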