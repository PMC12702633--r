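# Conversion of fitted weights into volumetric concentrations, SD
# propagation, and the hematocrit-anchored blood-volume back-calculation.

#' Reference weight vector for an adult ex vivo rabbit lung
#'
#' Weights of the six chromophores that reproduce the mean broadband
#' absorption spectrum of adult ex vivo rabbit lung: water 0.67, melanin
#' 2.85, lipofuscin 2.85, DNA 3.53, proteins 2.90, oxy-hemoglobin 12.62.
#' Useful as a ground truth for synthetic ensembles and as a worked example.
#'
#' @return Named numeric vector of weights.
#' @export
rabbit_lung_weights <- function() {
  c(water = 0.67, melanin = 2.85, lipofuscin = 2.85,
    dna = 3.53, proteins = 2.90, hbo = 12.62)
}

#' Convert fitted weights to volumetric concentrations
#'
#' Fitted weights are relative contributions with no absolute scale; the
#' conversion anchors them to a known tissue water fraction (80% is a
#' standard estimate for lung). Water is fixed at `water_fraction` and the
#' non-water weights are rescaled proportionally onto the remaining
#' `100 - water_fraction` percent; water's own fitted weight does not enter
#' the rescaling.
#'
#' @param weights Named weights including `water` and at least one non-water
#'   component with positive total weight.
#' @param water_fraction Tissue water content, % (default 80).
#' @return Object of class `"concentration_table"`: data frame with columns
#'   `component`, `weight`, `concentration` (% of tissue volume); attribute
#'   `water_fraction`. Concentrations sum to 100 exactly.
#' @examples
#' weights_to_concentrations(rabbit_lung_weights())
#' @export
weights_to_concentrations <- function(weights, water_fraction = 80) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(weights >= 0),
            is.numeric(water_fraction), length(water_fraction) == 1,
            water_fraction > 0, water_fraction < 100)
  if (!("water" %in% names(weights))) stop("`weights` must include water")
  non_water <- weights[setdiff(names(weights), "water")]
  if (length(non_water) == 0) stop("`weights` must include a non-water component")
  total <- sum(non_water)
  if (total <= 0) {
    stop("degenerate input: all non-water weights are zero, nothing to rescale")
  }
  conc <- c(water = water_fraction,
            non_water / total * (100 - water_fraction))
  out <- data.frame(component = names(conc),
                    weight = as.numeric(weights[names(conc)]),
                    concentration = as.numeric(conc),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "water_fraction") <- water_fraction
  class(out) <- c("concentration_table", class(out))
  out
}

#' Propagate spectral SD to concentration SDs
#'
#' Refits the full reconstruction on `mean + sd` and converts both weight
#' sets to concentrations; the per-component SD is the absolute difference
#' between the two concentration columns. Water is the anchor and gets SD 0.
#'
#' @param mean_mu_a Mean absorption spectrum of the ensemble, cm^-1.
#' @param sd_mu_a Pointwise SD spectrum (>= 0), same grid.
#' @param library A [make_library()] object.
#' @param water_fraction Tissue water content, % (default 80).
#' @param ... Passed to [full_reconstruction()] (e.g. `fit_window`).
#' @return Named numeric vector of SDs, % of tissue volume.
#' @export
concentration_sd <- function(mean_mu_a, sd_mu_a, library,
                             water_fraction = 80, ...) {
  stopifnot(is_spectrum(mean_mu_a), is_spectrum(sd_mu_a))
  stop_if_grid_mismatch(mean_mu_a, sd_mu_a, "mean and sd spectra")
  if (min(sd_mu_a$values) < 0) stop("sd spectrum must be nonnegative")
  conc_of <- function(spec) {
    res <- full_reconstruction(spec, library, ...)
    tab <- weights_to_concentrations(res$weights, water_fraction)
    stats::setNames(tab$concentration, tab$component)
  }
  c0 <- conc_of(mean_mu_a)
  c1 <- conc_of(new_spectrum(mean_mu_a$wavelength,
                             mean_mu_a$values + sd_mu_a$values, "cm^-1"))
  abs(c1 - c0[names(c1)])
}

#' Volumetric blood composition model
#'
#' Describes whole blood by its hematocrit (cellular fraction), the share of
#' cells other than red blood cells, the hemoglobin fraction of the red-cell
#' volume, and the plasma make-up. Two presets cover the hematocrit range of
#' adult rabbits (33--50%): `"rabbit42"` (mid-range hematocrit 42%, used for
#' the blood-volume chain) and `"rabbit45"` (hematocrit 45%, used for the
#' whole-blood composition).
#'
#' @param preset `"rabbit42"` or `"rabbit45"`.
#' @param hematocrit Cellular fraction of blood volume, %. Plasma is
#'   `100 - hematocrit`.
#' @param other_cells White cells + platelets, % of blood volume (default 1).
#' @param hb_fraction_of_rbc Hemoglobin fraction of red-cell volume, %
#'   (default 95).
#' @param plasma_protein_fraction Protein fraction of plasma, % (default 7).
#' @param albumin_fraction_of_plasma_protein Albumin share of plasma protein,
#'   % (default 55).
#' @return List of class `"blood_model"`; `plasma_fraction` is derived so
#'   that `hematocrit + plasma_fraction = 100`.
#' @export
blood_model <- function(preset = c("rabbit42", "rabbit45"),
                        hematocrit = NULL, other_cells = 1,
                        hb_fraction_of_rbc = 95,
                        plasma_protein_fraction = 7,
                        albumin_fraction_of_plasma_protein = 55) {
  preset <- match.arg(preset)
  if (is.null(hematocrit)) {
    hematocrit <- switch(preset, rabbit42 = 42, rabbit45 = 45)
  }
  fields <- c(hematocrit = hematocrit, other_cells = other_cells,
              hb_fraction_of_rbc = hb_fraction_of_rbc,
              plasma_protein_fraction = plasma_protein_fraction,
              albumin_fraction_of_plasma_protein = albumin_fraction_of_plasma_protein)
  if (any(fields < 0 | fields > 100)) stop("blood model fields must be in [0, 100]")
  structure(list(preset = preset, hematocrit = hematocrit,
                 other_cells = other_cells,
                 hb_fraction_of_rbc = hb_fraction_of_rbc,
                 plasma_fraction = 100 - hematocrit,
                 plasma_protein_fraction = plasma_protein_fraction,
                 albumin_fraction_of_plasma_protein = albumin_fraction_of_plasma_protein),
            class = "blood_model")
}

# paper-style half-up rounding, avoiding round()'s round-half-to-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Hemoglobin fraction of whole blood
#'
#' Red cells occupy `hematocrit - other_cells` percent of blood, and
#' hemoglobin occupies `hb_fraction_of_rbc` percent of the red-cell volume,
#' so the hemoglobin fraction of whole blood is
#' `(hematocrit - other_cells) * hb_fraction_of_rbc / 100`.
#'
#' @param model A [blood_model()].
#' @param rounded If `TRUE`, round to the nearest integer percent (the
#'   convention commonly used when the fraction feeds a back-of-envelope
#'   chain, e.g. 38.95 -> 39).
#' @return Percentage of blood volume.
#' @examples
#' hb_fraction_of_blood(blood_model("rabbit42"))          # 38.95
#' hb_fraction_of_blood(blood_model("rabbit42"), TRUE)    # 39
#' hb_fraction_of_blood(blood_model("rabbit45"))          # 41.8
#' @export
hb_fraction_of_blood <- function(model, rounded = FALSE) {
  stopifnot(inherits(model, "blood_model"))
  if (model$hematocrit <= model$other_cells) {
    stop("hematocrit must exceed the non-RBC cellular fraction")
  }
  f <- (model$hematocrit - model$other_cells) * model$hb_fraction_of_rbc / 100
  if (rounded) round_half_up(f) else f
}

#' Blood-volume breakdown from the tissue hemoglobin concentration
#'
#' Back-calculates the whole-blood volume concentration (BVC) of a tissue
#' from its fitted hemoglobin concentration: if hemoglobin is `f_hb` percent
#' of blood, then `hb_in_tissue` percent of tissue implies
#' `non_hb = hb_in_tissue * (100 - f_hb) / f_hb` percent of non-hemoglobin
#' blood components and `BVC = hb_in_tissue + non_hb`. The non-hemoglobin
#' part splits into the cellular remainder (red-cell membranes plus other
#' cells) and plasma; subtracting the plasma from the tissue water fraction
#' gives the water residing outside blood.
#'
#' @param hb_in_tissue Fitted hemoglobin concentration, % of tissue volume.
#' @param model A [blood_model()] (default preset `"rabbit42"`).
#' @param water_fraction Tissue water content, % (default 80).
#' @param use_rounded_hb_fraction Use the integer-rounded hemoglobin fraction
#'   of blood inside the proportions (default `TRUE`, the convention of
#'   hand-computed chains); `FALSE` uses the unrounded value.
#' @return Object of class `"blood_volume_breakdown"` with full-precision
#'   fields `hb_fraction_of_blood`, `hb_in_tissue`, `non_hb_blood_in_tissue`,
#'   `bvc`, `cellular_non_hb_in_tissue`, `plasma_in_tissue`,
#'   `non_plasma_water` (all % of tissue volume except the first) and the
#'   inputs. The identities `bvc = hb + non_hb` and
#'   `plasma = non_hb - cellular` hold exactly; see [round_like_paper()] for
#'   the printed-convention view.
#' @examples
#' blood_volume_chain(10.2)
#' @export
blood_volume_chain <- function(hb_in_tissue, model = blood_model("rabbit42"),
                               water_fraction = 80,
                               use_rounded_hb_fraction = TRUE) {
  stopifnot(is.numeric(hb_in_tissue), length(hb_in_tissue) == 1,
            hb_in_tissue >= 0)
  f_hb <- hb_fraction_of_blood(model, rounded = use_rounded_hb_fraction)
  if (f_hb <= 0) stop("hemoglobin fraction of blood must be positive")
  cellular_share <- model$hematocrit - f_hb   # membranes + other cells, % of blood
  non_hb <- hb_in_tissue * (100 - f_hb) / f_hb
  cellular <- non_hb * cellular_share / (100 - f_hb)
  plasma <- non_hb - cellular
  if (plasma > water_fraction) {
    stop(sprintf("inconsistent model: plasma in tissue (%.2f%%) exceeds the water fraction (%g%%)",
                 plasma, water_fraction))
  }
  structure(list(hb_fraction_of_blood = f_hb,
                 hb_in_tissue = hb_in_tissue,
                 non_hb_blood_in_tissue = non_hb,
                 bvc = hb_in_tissue + non_hb,
                 cellular_non_hb_in_tissue = cellular,
                 plasma_in_tissue = plasma,
                 non_plasma_water = water_fraction - plasma,
                 water_fraction = water_fraction,
                 model = model,
                 use_rounded_hb_fraction = use_rounded_hb_fraction),
            class = "blood_volume_breakdown")
}

#' @export
print.blood_volume_breakdown <- function(x, ...) {
  cat("<blood_volume_breakdown> (% of tissue volume)\n")
  cat(sprintf("  hemoglobin           %.4g\n", x$hb_in_tissue))
  cat(sprintf("  non-Hb blood         %.4g\n", x$non_hb_blood_in_tissue))
  cat(sprintf("  BVC (whole blood)    %.4g\n", x$bvc))
  cat(sprintf("  cellular non-Hb      %.4g\n", x$cellular_non_hb_in_tissue))
  cat(sprintf("  plasma               %.4g\n", x$plasma_in_tissue))
  cat(sprintf("  non-plasma water     %.4g\n", x$non_plasma_water))
  invisible(x)
}

#' Printed-convention view of a computed result
#'
#' Full-precision results do not reproduce hand-computed chains digit for
#' digit: those chains round each displayed stage and feed the rounded value
#' forward. `round_like_paper()` applies that convention.
#'
#' @param x Object to present.
#' @param ... Unused.
#' @return See methods.
#' @export
round_like_paper <- function(x, ...) UseMethod("round_like_paper")

#' @rdname round_like_paper
#' @details For a [blood_volume_chain()] result: the first-stage ratio
#'   (non-hemoglobin blood in tissue) is truncated at 0.1 -- a ratio of
#'   15.95 is displayed and carried as 15.9 -- and every later stage is
#'   computed from the already-rounded predecessors with half-up rounding at
#'   0.1. With hemoglobin 10.2% and the hematocrit-42 preset this yields
#'   non-Hb 15.9, BVC 26.1, cellular 0.8, plasma 15.1 and non-plasma water
#'   64.9.
#' @export
round_like_paper.blood_volume_breakdown <- function(x, ...) {
  non_hb <- floor(x$non_hb_blood_in_tissue * 10) / 10
  cellular_share <- x$model$hematocrit - x$hb_fraction_of_blood
  cellular <- round_half_up(non_hb * cellular_share /
                              (100 - x$hb_fraction_of_blood), 1)
  plasma <- non_hb - cellular
  c(hb_in_tissue = round_half_up(x$hb_in_tissue, 1),
    non_hb_blood_in_tissue = non_hb,
    bvc = round_half_up(x$hb_in_tissue, 1) + non_hb,
    cellular_non_hb_in_tissue = cellular,
    plasma_in_tissue = plasma,
    non_plasma_water = round_half_up(x$water_fraction - plasma, 1))
}

#' Composition of whole blood under a blood model
#'
#' @param model A [blood_model()].
#' @return Named vector, % of blood volume: `hemoglobin`, `rbc_membranes`,
#'   `other_cells`, `plasma` (these four sum to 100) and `albumin`
#'   (`plasma * plasma_protein_fraction * albumin_fraction_of_plasma_protein
#'   / 10000`, a subset of plasma).
#' @examples
#' whole_blood_composition(blood_model("rabbit45"))
#' @export
whole_blood_composition <- function(model) {
  stopifnot(inherits(model, "blood_model"))
  rbc <- model$hematocrit - model$other_cells
  hb <- rbc * model$hb_fraction_of_rbc / 100
  c(hemoglobin = hb,
    rbc_membranes = rbc - hb,
    other_cells = model$other_cells,
    plasma = model$plasma_fraction,
    albumin = model$plasma_fraction * model$plasma_protein_fraction *
      model$albumin_fraction_of_plasma_protein / 10000)
}
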