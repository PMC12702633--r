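# Wavelength-grid and spectrum primitives.
#
# A spectrum is a plain list: wavelength (nm, strictly increasing, uniform
# spacing), values (one per wavelength, finite), and a unit tag. The unit tag
# documents what the numbers mean and lets downstream code refuse nonsense
# (e.g. fitting a transmittance where an absorption coefficient is expected).

#' Construct a uniform wavelength grid
#'
#' Builds the wavelength axis used by every spectrum in a pipeline. The
#' default covers 200--1000 nm at 1 nm resolution (801 points), the range and
#' step of a typical UV--VIS--NIR integrating-sphere acquisition.
#'
#' @param start First wavelength, nm.
#' @param stop Last wavelength, nm. Must satisfy `stop > start` and be
#'   reachable from `start` in whole steps.
#' @param step Grid spacing, nm.
#' @return Numeric vector of wavelengths, strictly increasing with uniform
#'   spacing `step`.
#' @examples
#' g <- wl_grid()
#' length(g) # 801
#' @export
wl_grid <- function(start = 200, stop = 1000, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            length(start) == 1, length(stop) == 1, length(step) == 1,
            step > 0, stop > start)
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-8) {
    stop("`stop` is not reachable from `start` in whole steps of `step`")
  }
  seq(start, stop, by = step)
}

#' Canonical acquisition grid (200--1000 nm at 1 nm)
#'
#' @return `wl_grid(200, 1000, 1)`.
#' @export
canonical_grid <- function() wl_grid(200, 1000, 1)

spectrum_units <- c("cm^-1", "fraction", "normalized")

#' Create a spectrum object
#'
#' @param wavelength Wavelength grid, nm (strictly increasing, uniform
#'   spacing, at least two points).
#' @param values Numeric vector, one finite value per wavelength.
#' @param unit One of `"cm^-1"` (absorption coefficient), `"fraction"`
#'   (dimensionless measurement in \[0, 1\]) or `"normalized"` (min 0, max 1
#'   after [normalize_spectrum()]).
#' @return An object of class `"spectrum"`.
#' @examples
#' s <- new_spectrum(wl_grid(400, 700, 10), rep(0.5, 31), "fraction")
#' @export
new_spectrum <- function(wavelength, values,
                         unit = c("cm^-1", "fraction", "normalized")) {
  unit <- match.arg(unit)
  wavelength <- as.numeric(wavelength)
  values <- as.numeric(values)
  if (length(wavelength) < 2) stop("a spectrum needs at least two wavelengths")
  dw <- diff(wavelength)
  if (any(dw <= 0)) stop("wavelengths must be strictly increasing")
  if (max(dw) - min(dw) > 1e-6 * mean(dw)) {
    stop("wavelength grid must have uniform spacing")
  }
  if (length(values) != length(wavelength)) {
    stop("`values` must have one entry per wavelength")
  }
  if (!all(is.finite(values))) stop("all spectrum values must be finite")
  if (unit == "fraction" && (min(values) < 0 || max(values) > 1)) {
    stop("unit=\"fraction\" requires all values in [0, 1]")
  }
  structure(list(wavelength = wavelength, values = values, unit = unit),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %g-%g nm (step %g), unit %s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$wavelength[2] - x$wavelength[1], x$unit))
  cat(sprintf("  values: min %.6g, max %.6g\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, value = x$values)
}

#' Test whether an object is a spectrum
#' @param x Object.
#' @return Logical scalar.
#' @export
is_spectrum <- function(x) inherits(x, "spectrum")

# Shared-grid check used throughout; tolerance absorbs text round-trips.
same_grid <- function(a, b, tol = 1e-8) {
  length(a$wavelength) == length(b$wavelength) &&
    max(abs(a$wavelength - b$wavelength)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "spectra") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same wavelength grid", what))
  invisible(TRUE)
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation onto `target`. Extrapolation beyond the source range
#' is refused rather than silently clamped: a resampled value should always
#' be supported by measurements on both sides.
#'
#' @param spectrum A [new_spectrum()] object.
#' @param target Numeric wavelength grid (see [wl_grid()]).
#' @return A spectrum on `target` with the same unit.
#' @examples
#' s <- new_spectrum(wl_grid(200, 1000, 2), wl_grid(200, 1000, 2) / 1000,
#'                   "normalized")
#' r <- resample(s, wl_grid(300, 900, 1))
#' @export
resample <- function(spectrum, target) {
  stopifnot(is_spectrum(spectrum))
  target <- as.numeric(target)
  if (min(target) < min(spectrum$wavelength) - 1e-9 ||
      max(target) > max(spectrum$wavelength) + 1e-9) {
    stop(sprintf(
      "target grid [%g, %g] nm extends beyond source range [%g, %g] nm; refusing to extrapolate",
      min(target), max(target), min(spectrum$wavelength), max(spectrum$wavelength)))
  }
  out <- stats::approx(spectrum$wavelength, spectrum$values, xout = target,
                       method = "linear", rule = 1)$y
  new_spectrum(target, out, spectrum$unit)
}

#' Normalize a spectrum to the \[0, 1\] range
#'
#' Shift-then-scale normalization: the whole spectrum is displaced so its
#' minimum is zero and then divided by its maximum. This is the convention
#' applied to every component spectrum of a library before fitting, so that
#' fitted weights are comparable across components.
#'
#' @param spectrum A spectrum object with `max(values) > min(values)`.
#' @return A spectrum with unit `"normalized"`, min exactly 0, max exactly 1.
#' @examples
#' normalize_spectrum(new_spectrum(c(400, 500, 600), c(2, 4, 6)))$values
#' @export
normalize_spectrum <- function(spectrum) {
  stopifnot(is_spectrum(spectrum))
  lo <- min(spectrum$values)
  hi <- max(spectrum$values)
  if (hi <= lo) stop("cannot normalize a constant spectrum (max equals min)")
  new_spectrum(spectrum$wavelength, (spectrum$values - lo) / (hi - lo),
               "normalized")
}
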