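# Synthetic component library and measurement generator.
#
# No spectral library ships with the package; components are generated
# parametrically. Band positions follow the standard assignments for soft
# tissue: proteins ~230 nm (aromatic amino acids), DNA ~260 nm, oxy-hemoglobin
# with the Soret band at ~412 nm and Q-bands at ~540/570 nm plus a ~275 nm UV
# band, water at ~974 nm, and the pigments melanin and lipofuscin as smooth
# broadband curves decreasing with wavelength. Shapes are Gaussian bands and
# decaying exponentials; widths are of the order seen in published absorption
# spectra of the pure substances.

component_names <- c("melanin", "lipofuscin", "water", "dna", "hbo", "proteins")

gaussian_band <- function(wl, center, sigma, amplitude = 1) {
  amplitude * exp(-(wl - center)^2 / (2 * sigma^2))
}

# Default shape parameters per component. tau values are decay constants (nm)
# of exp(-(lambda - 200)/tau); melanin decays faster than lipofuscin.
component_defaults <- function(name) {
  switch(name,
    melanin    = list(tau = 175),
    lipofuscin = list(tau = 250),
    water      = list(center = 974, sigma = 30, tail_amp = 0.04, tail_tau = 30),
    dna        = list(center = 260, sigma = 15, bg_amp = 0.15, bg_tau = 20),
    hbo        = list(centers = c(412, 275, 540, 576),
                      sigmas  = c(10, 12, 10, 9),
                      amps    = c(1, 0.45, 0.18, 0.20)),
    proteins   = list(center = 230, sigma = 13,
                      shoulder_center = 278, shoulder_sigma = 11,
                      shoulder_amp = 0.25),
    stop(sprintf("unknown component \"%s\"; known components: %s",
                 name, paste(component_names, collapse = ", ")))
  )
}

#' Generate one synthetic component absorption spectrum
#'
#' Produces a normalized (min 0, max 1) absorption spectrum for one of the six
#' tissue chromophores. Pigments (melanin, lipofuscin) are decaying
#' exponentials; the remaining components are sums of Gaussian bands, with a
#' weak decaying ultraviolet background for DNA and a weak short-wavelength
#' tail for water.
#'
#' @param name One of `"melanin"`, `"lipofuscin"`, `"water"`, `"dna"`,
#'   `"hbo"`, `"proteins"`.
#' @param grid Wavelength grid, nm (default [canonical_grid()]).
#' @param params Named list overriding the component's default shape
#'   parameters (see Details).
#' @details Default shapes: melanin `exp(-(lambda-200)/175)`; lipofuscin
#'   `exp(-(lambda-200)/250)`; water Gaussian at 974 nm (sigma 30 nm) plus a
#'   small tail below ~300 nm; DNA Gaussian at 260 nm (sigma 15 nm) on a
#'   decaying background; oxy-hemoglobin Gaussians at 412 (Soret, largest),
#'   275, 540 and 576 nm; proteins Gaussian at 230 nm with a minor 278 nm
#'   shoulder.
#' @return A normalized spectrum on `grid`.
#' @examples
#' hbo <- make_component("hbo")
#' hbo$wavelength[which.max(hbo$values)] # 412
#' @export
make_component <- function(name, grid = canonical_grid(), params = list()) {
  if (!is.character(name) || length(name) != 1 || !(name %in% component_names)) {
    stop(sprintf("unknown component \"%s\"; known components: %s",
                 paste(name, collapse = "/"), paste(component_names, collapse = ", ")))
  }
  p <- utils::modifyList(component_defaults(name), params)
  wl <- as.numeric(grid)
  raw <- switch(name,
    melanin    = exp(-(wl - 200) / p$tau),
    lipofuscin = exp(-(wl - 200) / p$tau),
    water      = gaussian_band(wl, p$center, p$sigma) +
                 p$tail_amp * exp(-(wl - 200) / p$tail_tau),
    dna        = gaussian_band(wl, p$center, p$sigma) +
                 p$bg_amp * exp(-(wl - 200) / p$bg_tau),
    hbo        = rowSums(mapply(function(c0, s, a) gaussian_band(wl, c0, s, a),
                                p$centers, p$sigmas, p$amps)),
    proteins   = gaussian_band(wl, p$center, p$sigma) +
                 gaussian_band(wl, p$shoulder_center, p$shoulder_sigma,
                               p$shoulder_amp)
  )
  normalize_spectrum(new_spectrum(wl, raw, "normalized"))
}

#' Generate the full six-component spectral library
#'
#' @param grid Wavelength grid, nm.
#' @param overrides Named list of per-component parameter lists, e.g.
#'   `list(water = list(center = 980))`.
#' @return An object of class `"component_library"`: a shared grid plus the
#'   six normalized component spectra.
#' @examples
#' lib <- make_library()
#' names(lib$components)
#' @export
make_library <- function(grid = canonical_grid(), overrides = list()) {
  comps <- lapply(stats::setNames(component_names, component_names), function(nm) {
    make_component(nm, grid, params = if (nm %in% names(overrides)) overrides[[nm]] else list())
  })
  structure(list(grid = as.numeric(grid), components = comps),
            class = "component_library")
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %d components on %g-%g nm (%d points)\n",
              length(x$components), min(x$grid), max(x$grid), length(x$grid)))
  for (nm in names(x$components)) {
    s <- x$components[[nm]]
    cat(sprintf("  %-10s peak at %g nm\n", nm,
                s$wavelength[which.max(s$values)]))
  }
  invisible(x)
}

#' Configuration for the synthetic measurement generator
#'
#' @param true_weights Named nonnegative weights (ground truth), one per
#'   library component to include; components absent from the vector get
#'   weight 0.
#' @param thickness_cm Sample thickness, cm. Default 0.05 cm (0.5 mm), a
#'   typical cryotome section for integrating-sphere work.
#' @param transmit_fraction Fraction of the non-absorbed light that leaves as
#'   total transmittance; the rest leaves as total reflectance. The direct
#'   calculation only constrains the sum, so this split is a free simulator
#'   parameter (default 0.5).
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise applied independently to transmittance and reflectance, in
#'   fraction units. Default 0.01.
#' @param n_samples Number of measurement pairs to generate. Default 10.
#' @param seed Integer seed; every stochastic step derives from it.
#' @param background_mua Flat, wavelength-independent absorption added to the
#'   constructed coefficient, cm^-1 (default 0). Emulates broadband
#'   absorption by constituents outside the six-component library, which in
#'   real tissue leaves a nonzero flat floor after baseline removal.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(true_weights, thickness_cm = 0.05,
                         transmit_fraction = 0.5, noise_sd = 0.01,
                         n_samples = 10, seed = 1, background_mua = 0) {
  stopifnot(is.numeric(true_weights), !is.null(names(true_weights)),
            all(true_weights >= 0),
            thickness_cm > 0,
            transmit_fraction > 0, transmit_fraction < 1,
            noise_sd >= 0, n_samples >= 1, background_mua >= 0)
  structure(list(true_weights = true_weights, thickness_cm = thickness_cm,
                 transmit_fraction = transmit_fraction, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 background_mua = background_mua),
            class = "synth_config")
}

#' Generate synthetic transmittance/reflectance measurement pairs
#'
#' Builds the ground-truth absorption coefficient
#' `mu_a = sum_i p_i mu_ai + background` from `config$true_weights`, then
#' inverts the direct-calculation relation: the noiseless core satisfies
#' `T_t + R_t = 1 - mu_a * d`, split between the two channels by
#' `transmit_fraction`. Per-sample Gaussian noise (sd `noise_sd`) is added
#' independently to each channel and the result clipped to \[0, 1\].
#'
#' @param library A [make_library()] object.
#' @param config A [synth_config()] object.
#' @return List of `config$n_samples` measurement pairs (see
#'   [measurement_pair()]), reproducible under a fixed seed. The constructed
#'   true coefficient is attached as attribute `"true_mua"`.
#' @examples
#' lib <- make_library()
#' cfg <- synth_config(c(hbo = 5, water = 0.5), noise_sd = 0, n_samples = 1)
#' pairs <- synth_measurements(lib, cfg)
#' @export
synth_measurements <- function(library, config) {
  stopifnot(inherits(library, "component_library"),
            inherits(config, "synth_config"))
  mua <- reconstruct(library, config$true_weights)
  mua$values <- mua$values + config$background_mua
  d <- config$thickness_cm
  if (max(mua$values) * d > 1) {
    stop(sprintf(
      "infeasible configuration: mu_a * d reaches %.3f > 1 (max mu_a %.3f cm^-1 at %g nm, d %.3g cm); the direct-calculation regime requires mu_a * d <= 1",
      max(mua$values) * d, max(mua$values),
      mua$wavelength[which.max(mua$values)], d))
  }
  core <- 1 - mua$values * d
  t_core <- config$transmit_fraction * core
  r_core <- (1 - config$transmit_fraction) * core
  n_wl <- length(mua$wavelength)
  set.seed(config$seed)
  pairs <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    tt <- t_core
    rr <- r_core
    if (config$noise_sd > 0) {
      tt <- tt + stats::rnorm(n_wl, 0, config$noise_sd)
      rr <- rr + stats::rnorm(n_wl, 0, config$noise_sd)
    }
    tt <- pmin(pmax(tt, 0), 1)
    rr <- pmin(pmax(rr, 0), 1)
    # noise can push T_t + R_t marginally above 1 at transparent wavelengths;
    # an unbounded pair tolerance keeps the ensemble unbiased (see
    # ?measurement_pair)
    pairs[[i]] <- measurement_pair(
      transmittance = new_spectrum(mua$wavelength, tt, "fraction"),
      reflectance   = new_spectrum(mua$wavelength, rr, "fraction"),
      thickness_cm  = d,
      sample_id     = sprintf("synth_%02d", i),
      tol           = if (config$noise_sd > 0) Inf else 1e-9)
  }
  attr(pairs, "true_mua") <- mua
  pairs
}
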