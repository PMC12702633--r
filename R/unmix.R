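# Weighted-component reconstruction of the absorption spectrum.
#
# The tissue absorption coefficient is modeled as a weighted sum of the
# normalized component spectra, mu_a(lambda) = sum_i p_i * mu_ai(lambda).
# The reference fitting procedure is two-step: first the broadband pigment
# baseline (melanin + lipofuscin) is fitted over band-free wavelengths and
# removed, then the remaining components (water, DNA, oxy-hemoglobin,
# proteins) are fitted to the corrected spectrum over the full grid by
# nonnegative least squares. A joint six-component fit is available for
# comparison.

#' Weighted sum of component spectra
#'
#' @param library A [make_library()] object.
#' @param weights Named nonnegative weights; every name must be a library
#'   component. Components not named get weight 0.
#' @return Spectrum on the library grid, unit cm^-1.
#' @examples
#' lib <- make_library()
#' mua <- reconstruct(lib, c(hbo = 12.62, water = 0.67))
#' @export
reconstruct <- function(library, weights) {
  stopifnot(inherits(library, "component_library"),
            is.numeric(weights), !is.null(names(weights)))
  unknown <- setdiff(names(weights), names(library$components))
  if (length(unknown) > 0) {
    stop(sprintf("unknown component(s) in weights: %s",
                 paste(unknown, collapse = ", ")))
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  vals <- rep(0, length(library$grid))
  for (nm in names(weights)) {
    vals <- vals + weights[[nm]] * library$components[[nm]]$values
  }
  new_spectrum(library$grid, vals, "cm^-1")
}

# NNLS with a guard for rank-deficient designs (e.g. duplicated components):
# collapse identical columns, warn, and split the fitted weight equally among
# the duplicates (the minimal-norm nonnegative solution for exact copies).
nnls_fit <- function(A, y, colnames_) {
  dup_of <- rep(NA_integer_, ncol(A))
  keep <- integer(0)
  for (j in seq_len(ncol(A))) {
    hit <- NA_integer_
    for (k in keep) {
      if (isTRUE(all.equal(A[, j], A[, k], tolerance = 1e-12))) { hit <- k; break }
    }
    if (is.na(hit)) keep <- c(keep, j) else dup_of[j] <- hit
  }
  if (length(keep) < ncol(A)) {
    warning(sprintf(
      "collinear design: component(s) %s duplicate earlier columns; weight split equally",
      paste(colnames_[!is.na(dup_of)], collapse = ", ")))
  }
  fit <- pracma::lsqnonneg(A[, keep, drop = FALSE], y)
  w <- numeric(ncol(A))
  for (j in seq_len(ncol(A))) {
    k <- if (is.na(dup_of[j])) j else dup_of[j]
    n_copies <- 1 + sum(dup_of == k, na.rm = TRUE)
    w[j] <- fit$x[match(k, keep)] / n_copies
  }
  names(w) <- colnames_
  w
}

#' Fit non-pigment components to a baseline-removed spectrum
#'
#' Nonnegative least squares of the corrected spectrum on the requested
#' library components over the full grid.
#'
#' @param corrected Baseline-removed absorption spectrum, cm^-1.
#' @param library A [make_library()] object on the same grid.
#' @param components Components to fit; default
#'   `c("water", "dna", "hbo", "proteins")`.
#' @return Object of class `"unmix_result"` with named `weights`,
#'   `reconstructed` spectrum, `residual_rms` and `residual_max` (cm^-1, full
#'   grid) and `method = "components"`.
#' @export
fit_components <- function(corrected, library,
                           components = c("water", "dna", "hbo", "proteins")) {
  stopifnot(is_spectrum(corrected), inherits(library, "component_library"),
            length(components) >= 1)
  missing <- setdiff(components, names(library$components))
  if (length(missing) > 0) {
    stop(sprintf("component(s) not in library: %s", paste(missing, collapse = ", ")))
  }
  stop_if_grid_mismatch(corrected, library$components[[components[1]]],
                        "corrected spectrum and library")
  A <- vapply(components, function(nm) library$components[[nm]]$values,
              numeric(length(library$grid)))
  A <- matrix(A, ncol = length(components))
  w <- nnls_fit(A, corrected$values, components)
  recon <- new_spectrum(library$grid, as.vector(A %*% w), "cm^-1")
  resid <- corrected$values - recon$values
  structure(list(weights = w, reconstructed = recon,
                 residual_rms = sqrt(mean(resid^2)),
                 residual_max = max(abs(resid)),
                 method = "components"),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf("<unmix_result> method %s\n", x$method))
  for (nm in names(x$weights)) cat(sprintf("  p_%-10s %.4f\n", nm, x$weights[[nm]]))
  cat(sprintf("  residual: rms %.4g, max %.4g cm^-1\n",
              x$residual_rms, x$residual_max))
  invisible(x)
}

#' Full reconstruction of an absorption spectrum
#'
#' Reference two-step procedure: (1) fit and subtract the melanin/lipofuscin
#' pigment baseline over band-free wavelengths; (2) fit water, DNA,
#' oxy-hemoglobin and proteins to the corrected spectrum over the full grid;
#' the reconstructed spectrum is the component sum plus the baseline.
#' `method = "joint"` instead fits all six components at once over the full
#' grid (comparison path, not the reference).
#'
#' @param mu_a Absorption coefficient spectrum, cm^-1.
#' @param library A [make_library()] object on the same grid.
#' @param method `"two_step"` (default) or `"joint"`.
#' @param fit_window Baseline fit window passed to [fit_baseline()]
#'   (two-step only).
#' @return Object of class `"unmix_result"`: six named `weights` (melanin,
#'   lipofuscin, water, dna, hbo, proteins), `reconstructed` spectrum,
#'   residual diagnostics against `mu_a`, `method`, and for the two-step
#'   path the `baseline_fit` and `corrected` spectrum.
#' @examples
#' lib <- make_library()
#' truth <- c(melanin = 2.85, lipofuscin = 2.85, water = 0.67,
#'            dna = 3.53, hbo = 12.62, proteins = 2.90)
#' res <- full_reconstruction(reconstruct(lib, truth), lib)
#' res$weights
#' @export
full_reconstruction <- function(mu_a, library,
                                method = c("two_step", "joint"),
                                fit_window = NULL) {
  method <- match.arg(method)
  stopifnot(is_spectrum(mu_a), inherits(library, "component_library"))
  if (method == "joint") {
    res <- fit_components(mu_a, library, components = names(library$components))
    res$method <- "joint"
    resid <- mu_a$values - res$reconstructed$values
    res$residual_rms <- sqrt(mean(resid^2))
    res$residual_max <- max(abs(resid))
    return(res)
  }
  bfit <- fit_baseline(mu_a, library, fit_window = fit_window)
  corrected <- subtract_baseline(mu_a, bfit)
  cfit <- fit_components(corrected, library)
  weights <- c(melanin = bfit$p_mel, lipofuscin = bfit$p_lip, cfit$weights)
  recon <- new_spectrum(mu_a$wavelength,
                        cfit$reconstructed$values + bfit$baseline$values,
                        "cm^-1")
  resid <- mu_a$values - recon$values
  structure(list(weights = weights, reconstructed = recon,
                 residual_rms = sqrt(mean(resid^2)),
                 residual_max = max(abs(resid)),
                 method = "two_step",
                 baseline_fit = bfit, corrected = corrected),
            class = "unmix_result")
}
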