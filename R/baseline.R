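# Pigment-baseline reconstruction and removal.
#
# Aged soft tissue accumulates melanin and lipofuscin, whose broadband
# absorption decreases smoothly with wavelength and sits under the discrete
# chromophore bands. The baseline is modeled as
#   mu_a-baseline(lambda) = p_mel * mu_a-Mel(lambda) + p_lip * mu_a-Lip(lambda)
# and fitted by nonnegative least squares over band-free wavelengths only, so
# that protein/DNA/hemoglobin bands cannot inflate the pigment weights.

#' Default band-free fit window for the pigment baseline
#'
#' Returns the wavelengths used to constrain the baseline fit: everything on
#' the grid except an exclusion zone around each known chromophore band and
#' the water-dominated region above `water_cutoff`.
#'
#' @param grid Wavelength grid, nm.
#' @param exclude_centers Band centers to exclude, nm. Defaults to the
#'   protein (235), DNA (261), hemoglobin UV (275), Soret (412) and Q-band
#'   (540, 570) positions.
#' @param exclude_halfwidth Half-width of each exclusion zone, nm. The
#'   default 45 nm covers roughly three standard deviations of the widest of
#'   these bands, so that band tails do not leak into the pigment fit.
#' @param water_cutoff Wavelengths above this value are excluded (water
#'   band). Default 900 nm.
#' @return Numeric vector of wavelengths (subset of `grid`).
#' @export
default_fit_window <- function(grid = canonical_grid(),
                               exclude_centers = c(235, 261, 275, 412, 540, 570),
                               exclude_halfwidth = 45,
                               water_cutoff = 900) {
  wl <- as.numeric(grid)
  keep <- wl <= water_cutoff
  for (c0 in exclude_centers) keep <- keep & abs(wl - c0) > exclude_halfwidth
  wl[keep]
}

#' Fit the melanin + lipofuscin baseline to an absorption spectrum
#'
#' Finds nonnegative weights `(p_mel, p_lip)` minimizing the squared misfit
#' between the spectrum and `p_mel * melanin + p_lip * lipofuscin` over the
#' fit window, then evaluates the baseline on the full grid.
#'
#' @param mu_a Absorption coefficient spectrum, cm^-1.
#' @param library A [make_library()] object containing `melanin` and
#'   `lipofuscin` on the same grid as `mu_a`.
#' @param fit_window Wavelengths (nm) constraining the fit; defaults to
#'   [default_fit_window()] on the spectrum's grid. At least 2 points.
#' @return Object of class `"baseline_fit"`: `p_mel`, `p_lip`, `baseline`
#'   (spectrum on the full grid), `fit_window`, `residual_rms` (cm^-1, over
#'   the window).
#' @examples
#' lib <- make_library()
#' truth <- reconstruct(lib, c(melanin = 2.85, lipofuscin = 2.85))
#' fit <- fit_baseline(truth, lib)
#' c(fit$p_mel, fit$p_lip)
#' @export
fit_baseline <- function(mu_a, library, fit_window = NULL) {
  stopifnot(is_spectrum(mu_a), inherits(library, "component_library"))
  if (mu_a$unit != "cm^-1") stop("`mu_a` must be an absorption spectrum (cm^-1)")
  mel <- library$components$melanin
  lip <- library$components$lipofuscin
  if (is.null(mel) || is.null(lip)) {
    stop("library must contain melanin and lipofuscin components")
  }
  stop_if_grid_mismatch(mu_a, mel, "mu_a and library")
  if (is.null(fit_window)) fit_window <- default_fit_window(mu_a$wavelength)
  idx <- match_window(mu_a$wavelength, fit_window)
  if (length(idx) < 2) {
    stop("baseline fit window must contain at least 2 grid wavelengths")
  }
  A <- cbind(mel$values[idx], lip$values[idx])
  fit <- pracma::lsqnonneg(A, mu_a$values[idx])
  p <- fit$x
  base_vals <- p[1] * mel$values + p[2] * lip$values
  resid <- mu_a$values[idx] - (p[1] * mel$values[idx] + p[2] * lip$values[idx])
  structure(list(p_mel = p[1], p_lip = p[2],
                 baseline = new_spectrum(mu_a$wavelength, base_vals, "cm^-1"),
                 fit_window = mu_a$wavelength[idx],
                 residual_rms = sqrt(mean(resid^2))),
            class = "baseline_fit")
}

# indices of grid wavelengths belonging to a window given as wavelengths
match_window <- function(grid, window) {
  which(vapply(grid, function(w) any(abs(window - w) <= 1e-8), logical(1)))
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> p_mel = %.4f, p_lip = %.4f\n", x$p_mel, x$p_lip))
  cat(sprintf("  fit window: %d wavelengths, residual RMS %.4g cm^-1\n",
              length(x$fit_window), x$residual_rms))
  invisible(x)
}

#' Subtract a fitted pigment baseline from an absorption spectrum
#'
#' Pointwise difference on the common grid. Small negative residuals are
#' reported, not clipped: clipping would bias the flat floor used by the
#' corrected-spectrum fold-ratios upward.
#'
#' @param mu_a Absorption coefficient spectrum, cm^-1.
#' @param fit A [fit_baseline()] result on the same grid.
#' @return Corrected spectrum, cm^-1.
#' @export
subtract_baseline <- function(mu_a, fit) {
  stopifnot(is_spectrum(mu_a), inherits(fit, "baseline_fit"))
  stop_if_grid_mismatch(mu_a, fit$baseline, "mu_a and baseline")
  new_spectrum(mu_a$wavelength, mu_a$values - fit$baseline$values, "cm^-1")
}

#' Flat residual floor of a corrected spectrum
#'
#' Minimum of the corrected spectrum over a band-free near-infrared window,
#' used as the denominator for fold-ratios after baseline removal.
#'
#' @param corrected Baseline-removed spectrum, cm^-1.
#' @param lo,hi Window bounds, nm (defaults 800 and 850), both inside the
#'   grid.
#' @return Scalar minimum, cm^-1.
#' @export
flat_floor <- function(corrected, lo = 800, hi = 850) {
  stopifnot(is_spectrum(corrected), lo < hi)
  sel <- corrected$wavelength >= lo & corrected$wavelength <= hi
  if (!any(sel)) {
    stop(sprintf("window [%g, %g] nm contains no grid wavelengths", lo, hi))
  }
  min(corrected$values[sel])
}
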