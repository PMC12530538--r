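#' Illuminant spectra
#'
#' An illuminant is an ambient irradiance spectrum on the analysis grid,
#' expressed in relative quanta (photon flux). Spectra supplied in energy
#' units are converted with [energy_to_quanta()]. Because receptor-noise
#' distances are computed on log quantum catches, their values are invariant
#' to any overall rescaling of the illuminant; the built-in illuminants are
#' normalized to unit mean purely for presentation, user values are kept
#' as given.
#'
#' @param wl wavelength grid (nm).
#' @param irradiance nonnegative irradiance values on `wl`.
#' @param name label carried into provenance.
#' @param units `"quanta"` or `"energy"`.
#' @return object of class `illuminant`.
#' @export
illuminant <- function(wl, irradiance, name = "custom",
                       units = c("quanta", "energy")) {
  units <- match.arg(units)
  if (length(wl) != length(irradiance)) stop("wl/irradiance length mismatch")
  if (any(!is.finite(irradiance)) || any(irradiance < 0)) {
    stop("negative or non-finite irradiance")
  }
  if (all(irradiance == 0)) stop("illuminant is identically zero")
  structure(list(name = name, wl = wl, irradiance = irradiance,
                 units = units),
            class = "illuminant")
}

#' @export
print.illuminant <- function(x, ...) {
  cat(sprintf("<illuminant '%s' (%s): %d points, %g-%g nm>\n",
              x$name, x$units, length(x$wl), min(x$wl), max(x$wl)))
  invisible(x)
}

#' Convert an energy-unit illuminant to relative quanta
#'
#' Photon flux is proportional to energy flux times wavelength; the result
#' is renormalized to unit mean. Converting an already-quantal illuminant is
#' an error (the units flag is tracked).
#'
#' @param ill an `illuminant`.
#' @export
energy_to_quanta <- function(ill) {
  if (ill$units == "quanta") {
    stop("illuminant '", ill$name, "' is already in quanta units")
  }
  q <- ill$irradiance * ill$wl
  illuminant(ill$wl, q / mean(q), name = ill$name, units = "quanta")
}

#' Parametric forest-shade illuminant
#'
#' Forest shade light is "yellow-green": a broad peak near 550 nm from
#' foliage-filtered daylight plus a sharp far-red rise near 680 nm where
#' chlorophyll stops absorbing. Modelled as a Gaussian plus a logistic rise,
#' normalized to unit mean. Measured forest-shade spectra can be supplied to
#' [load_illuminant()] as a file instead.
#'
#' @param peak_nm centre of the green Gaussian peak.
#' @param peak_width Gaussian width (nm).
#' @param red_rise_nm centre of the far-red logistic rise.
#' @param rise_scale logistic scale (nm).
#' @param peak_weight,rise_weight component weights (>= 0).
#' @param baseline small flat floor keeping short-wavelength irradiance
#'   positive.
#' @param wl wavelength grid.
#' @export
forest_shade_illuminant <- function(peak_nm = 550, peak_width = 80,
                                    red_rise_nm = 680, rise_scale = 8,
                                    peak_weight = 1, rise_weight = 1,
                                    baseline = 0.05, wl = 300:700) {
  if (peak_width <= 0 || rise_scale <= 0) stop("degenerate widths")
  if (peak_nm < min(wl) || peak_nm > max(wl)) stop("peak outside grid")
  g <- exp(-((wl - peak_nm) / peak_width)^2)
  r <- 1 / (1 + exp(-(wl - red_rise_nm) / rise_scale))
  y <- baseline + peak_weight * g + rise_weight * r
  illuminant(wl, y / mean(y), name = "forestshade", units = "quanta")
}

#' Load an illuminant
#'
#' Built-ins are `"d65"` (the standard tabulated CIE D65 daylight
#' distribution bundled with the package, converted from energy to quanta)
#' and `"forestshade"` ([forest_shade_illuminant()] defaults). A file path
#' selects a two-column CSV (`wl`, `irradiance`) which is linearly regridded
#' to `wl`; set `units = "energy"` to convert file data to quanta.
#'
#' @param source builtin name or CSV path.
#' @param wl target wavelength grid.
#' @param units units of file data (ignored for built-ins).
#' @export
load_illuminant <- function(source, wl = 300:700,
                            units = c("quanta", "energy")) {
  units <- match.arg(units)
  if (source == "forestshade") {
    return(forest_shade_illuminant(wl = wl))
  }
  if (source == "d65") {
    path <- system.file("extdata", "illuminants", "d65.csv",
                        package = "morphvision", mustWork = TRUE)
    tab <- utils::read.csv(path)
    units <- "energy"
    name <- "d65"
  } else {
    tab <- utils::read.csv(source)
    if (!all(c("wl", "irradiance") %in% names(tab))) {
      stop("illuminant file needs columns 'wl' and 'irradiance'")
    }
    name <- sub("\\.[^.]*$", "", basename(source))
  }
  if (min(tab$wl) > min(wl) || max(tab$wl) < max(wl)) {
    stop("illuminant file does not cover the grid")
  }
  y <- stats::approx(tab$wl, tab$irradiance, xout = wl)$y
  ill <- illuminant(wl, y, name = name, units = units)
  if (units == "energy") ill <- energy_to_quanta(ill)
  ill
}
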