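# Absorption fold-ratios at named chromophore bands.
#
# The fold-ratio of a chromophore is the peak absorption of its band divided
# by the local baseline, a content proxy. Before baseline removal the
# denominator is the fitted pigment-baseline curve at the peak wavelength;
# after removal it is the flat residual floor of the corrected spectrum.

#' Define a chromophore band for peak search
#'
#' @param name Band label.
#' @param nominal_center Expected band center, nm.
#' @param search_halfwidth Half-width of the peak search window, nm
#'   (default 15: band centers in tissue drift by a few nm from the pure
#'   substance, e.g. the protein band right-shifts from 230 to ~235 nm).
#' @return List of class `"band_definition"`.
#' @export
band_definition <- function(name, nominal_center, search_halfwidth = 15) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(nominal_center), length(nominal_center) == 1,
            is.numeric(search_halfwidth), search_halfwidth > 0)
  structure(list(name = name, nominal_center = nominal_center,
                 search_halfwidth = search_halfwidth),
            class = "band_definition")
}

#' Default band set for lung-type tissue
#'
#' Proteins 235 nm, DNA 261 nm, the oxy-hemoglobin Soret band 412 nm and
#' Q-bands 540/570 nm, and water 974 nm.
#'
#' @return List of [band_definition()] objects.
#' @export
lung_bands <- function() {
  list(band_definition("proteins", 235),
       band_definition("dna", 261),
       band_definition("hbo_soret", 412),
       band_definition("hbo_q540", 540),
       band_definition("hbo_q570", 570),
       band_definition("water", 974))
}

#' Locate a band peak within its search window
#'
#' Returns the wavelength of the maximum of `spectrum` within
#' `nominal_center +/- search_halfwidth`. Ties are broken toward the nominal
#' center, then toward shorter wavelength.
#'
#' @param spectrum A spectrum.
#' @param band A [band_definition()]. The search window must intersect the
#'   grid.
#' @return Peak wavelength, nm.
#' @export
locate_peak <- function(spectrum, band) {
  stopifnot(is_spectrum(spectrum), inherits(band, "band_definition"))
  wl <- spectrum$wavelength
  sel <- which(wl >= band$nominal_center - band$search_halfwidth &
               wl <= band$nominal_center + band$search_halfwidth)
  if (length(sel) == 0) {
    stop(sprintf("search window for band \"%s\" (%g +/- %g nm) lies outside the grid [%g, %g] nm",
                 band$name, band$nominal_center, band$search_halfwidth,
                 min(wl), max(wl)))
  }
  v <- spectrum$values[sel]
  cand <- sel[v >= max(v) - 0]
  if (length(cand) > 1) {
    dist <- abs(wl[cand] - band$nominal_center)
    cand <- cand[dist == min(dist)]
    if (length(cand) > 1) cand <- cand[which.min(wl[cand])]
  }
  wl[cand]
}

#' Fold-ratios of chromophore bands against a baseline
#'
#' For each band, locates the peak (see [locate_peak()]) and divides the
#' spectrum value there by the baseline value at the same wavelength. Two
#' modes: for an original (uncorrected) spectrum the baseline is the fitted
#' pigment-baseline curve; for a baseline-removed spectrum it is a scalar
#' flat floor (see [flat_floor()]).
#'
#' @param spectrum Absorption spectrum, cm^-1 (original or corrected).
#' @param baseline_source Either a [fit_baseline()] result (mode
#'   `"original"`) or a positive scalar floor (mode `"baseline_removed"`).
#' @param bands List of [band_definition()]s; default [lung_bands()].
#' @return Data frame of class `"fold_ratio_report"` with columns `band`,
#'   `peak_nm`, `peak_mua`, `baseline_value`, `fold_ratio`; attribute `mode`.
#' @examples
#' lib <- make_library()
#' mua <- reconstruct(lib, c(melanin = 2.85, lipofuscin = 2.85, hbo = 12.62))
#' fit <- fit_baseline(mua, lib)
#' fold_ratios(mua, fit, lung_bands()[3])
#' @export
fold_ratios <- function(spectrum, baseline_source, bands = lung_bands()) {
  stopifnot(is_spectrum(spectrum), is.list(bands), length(bands) >= 1)
  if (inherits(bands, "band_definition")) bands <- list(bands)
  if (inherits(baseline_source, "baseline_fit")) {
    mode <- "original"
    stop_if_grid_mismatch(spectrum, baseline_source$baseline,
                          "spectrum and baseline")
    base_at <- function(w) {
      baseline_source$baseline$values[match(w, baseline_source$baseline$wavelength)]
    }
  } else if (is.numeric(baseline_source) && length(baseline_source) == 1) {
    mode <- "baseline_removed"
    base_at <- function(w) baseline_source
  } else {
    stop("`baseline_source` must be a baseline_fit or a scalar floor")
  }
  rows <- lapply(bands, function(b) {
    stopifnot(inherits(b, "band_definition"))
    pk <- locate_peak(spectrum, b)
    peak_val <- spectrum$values[match(pk, spectrum$wavelength)]
    bval <- base_at(pk)
    if (!is.finite(bval) || bval <= 0) {
      stop(sprintf("fold-ratio undefined for band \"%s\": baseline value %.4g at %g nm is not positive",
                   b$name, bval, pk))
    }
    data.frame(band = b$name, peak_nm = pk, peak_mua = peak_val,
               baseline_value = bval, fold_ratio = peak_val / bval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  class(out) <- c("fold_ratio_report", class(out))
  out
}
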