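# Delimited-text spectrum I/O and the end-to-end pipeline.
#
# Spectra travel as two-column delimited text (comma or tab), header
# `wavelength_nm,<name>`, one row per wavelength, written at full precision.
# This is the lingua franca of spectrometer exports; no binary container is
# used anywhere.

#' Write a spectrum to a delimited text file
#'
#' @param spectrum A spectrum object.
#' @param path Output file path (`.csv` comma-separated, anything else
#'   tab-separated).
#' @param name Value-column name (default `"value"`).
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spectrum, path, name = "value") {
  stopifnot(is_spectrum(spectrum))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(wavelength_nm = format(spectrum$wavelength, digits = 17,
                                          trim = TRUE, scientific = FALSE),
                   value = format(spectrum$values, digits = 17, trim = TRUE))
  names(df)[2] <- name
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from a delimited text file
#'
#' Expects a header row with a `wavelength_nm` column and one or more value
#' columns; the delimiter (comma or tab) is detected from the header line.
#'
#' @param path File path.
#' @param column Value column to read; default: the first non-wavelength
#'   column.
#' @param unit Unit to stamp on the result (the file format carries none).
#' @return A spectrum object on the file's grid.
#' @export
read_spectrum_table <- function(path, column = NULL,
                                unit = c("cm^-1", "fraction", "normalized")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!("wavelength_nm" %in% names(df))) {
    stop(sprintf("%s: missing `wavelength_nm` column (found: %s)",
                 path, paste(names(df), collapse = ", ")))
  }
  if (is.null(column)) {
    others <- setdiff(names(df), "wavelength_nm")
    if (length(others) == 0) stop(sprintf("%s: no value column", path))
    column <- others[1]
  }
  if (!(column %in% names(df))) {
    stop(sprintf("%s: missing column `%s`", path, column))
  }
  wl <- suppressWarnings(as.numeric(df$wavelength_nm))
  vals <- suppressWarnings(as.numeric(df[[column]]))
  bad <- which(!is.finite(wl) | !is.finite(vals))
  if (length(bad) > 0) {
    stop(sprintf("%s: non-numeric cell at data line %d", path, bad[1]))
  }
  if (any(diff(wl) <= 0)) {
    stop(sprintf("%s: wavelengths not strictly increasing at data line %d",
                 path, which(diff(wl) <= 0)[1] + 1))
  }
  new_spectrum(wl, vals, unit)
}

#' Write a synthetic measurement ensemble to a directory
#'
#' One `sample_XX_Tt.csv` / `sample_XX_Rt.csv` pair per sample, plus a
#' `true_weights.txt` key-value sidecar when the ensemble carries ground
#' truth.
#'
#' @param pairs List of [measurement_pair()]s (e.g. from
#'   [synth_measurements()]).
#' @param dir Output directory (created if needed).
#' @param true_weights Optional named ground-truth weights for the sidecar.
#' @return `dir`, invisibly.
#' @export
write_measurements <- function(pairs, dir, true_weights = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(pairs)) {
    write_spectrum_table(pairs[[i]]$transmittance,
                         file.path(dir, sprintf("sample_%02d_Tt.csv", i)), "Tt")
    write_spectrum_table(pairs[[i]]$reflectance,
                         file.path(dir, sprintf("sample_%02d_Rt.csv", i)), "Rt")
  }
  if (!is.null(true_weights)) {
    writeLines(sprintf("%s %.17g", names(true_weights), true_weights),
               file.path(dir, "true_weights.txt"))
  }
  invisible(dir)
}

#' Read a measurement ensemble from a directory
#'
#' @param dir Directory containing `sample_XX_Tt.csv` / `sample_XX_Rt.csv`
#'   pairs.
#' @param thickness_cm Sample thickness, cm.
#' @param tol Tolerated excess of `T_t + R_t` above 1 (see
#'   [measurement_pair()]); real noisy data need roughly the measurement
#'   noise level.
#' @return List of [measurement_pair()]s.
#' @export
read_measurements <- function(dir, thickness_cm, tol = 0.05) {
  if (!dir.exists(dir)) stop(sprintf("sample directory not found: %s", dir))
  tt_files <- sort(list.files(dir, pattern = "_Tt\\.csv$", full.names = TRUE))
  if (length(tt_files) == 0) {
    stop(sprintf("no `*_Tt.csv` sample files in %s", dir))
  }
  lapply(tt_files, function(tf) {
    rf <- sub("_Tt\\.csv$", "_Rt.csv", tf)
    if (!file.exists(rf)) stop(sprintf("missing reflectance file %s", rf))
    measurement_pair(read_spectrum_table(tf, unit = "fraction"),
                     read_spectrum_table(rf, unit = "fraction"),
                     thickness_cm = thickness_cm,
                     sample_id = sub("_Tt\\.csv$", "", basename(tf)),
                     tol = tol)
  })
}

#' Pipeline configuration
#'
#' @param samples_dir Directory of per-sample `Tt`/`Rt` CSV files.
#' @param out_dir Output directory for the report bundle.
#' @param thickness_mm Sample thickness in mm (converted to cm internally;
#'   default 0.5 mm).
#' @param water_fraction Tissue water content, % (default 80).
#' @param blood_preset [blood_model()] preset for the blood-volume chain
#'   (default `"rabbit42"`).
#' @param library Component library; default [make_library()] on the grid of
#'   the first sample.
#' @param fit_window Baseline fit window; default [default_fit_window()].
#' @param bands Fold-ratio band set; default [lung_bands()].
#' @param tr_tol Tolerated excess of `T_t + R_t` above 1 when reading
#'   samples (default 0.05).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(samples_dir, out_dir, thickness_mm = 0.5,
                            water_fraction = 80, blood_preset = "rabbit42",
                            library = NULL, fit_window = NULL,
                            bands = lung_bands(), tr_tol = 0.05) {
  stopifnot(is.character(samples_dir), is.character(out_dir),
            thickness_mm > 0)
  structure(list(samples_dir = samples_dir, out_dir = out_dir,
                 thickness_mm = thickness_mm,
                 water_fraction = water_fraction,
                 blood_preset = blood_preset, library = library,
                 fit_window = fit_window, bands = bands, tr_tol = tr_tol),
            class = "pipeline_config")
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[tissuemua] ", fmt), ...))

#' Run the full analysis pipeline
#'
#' Reads the measurement ensemble, computes per-sample absorption
#' coefficients and their ensemble mean/SD, fits and removes the pigment
#' baseline, unmixes the corrected spectrum, computes fold-ratios before and
#' after baseline removal, converts weights to concentrations with
#' propagated SDs, and back-calculates the blood-volume breakdown from the
#' hemoglobin concentration. Writes `mua_mean_sd.csv`, `baseline.csv`,
#' `weights.txt`, `recon.csv`, `foldratios.csv`, `concentrations.csv` and
#' `blood.txt` into `out_dir`. Deterministic given the same inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$samples_dir)) {
    stop(sprintf("config error: sample directory not found: %s",
                 config$samples_dir))
  }
  d_cm <- config$thickness_mm / 10
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  pairs <- stage("read_samples",
                 read_measurements(config$samples_dir, d_cm, tol = config$tr_tol))
  log_stage("read %d sample pairs from %s (d = %g mm, T+R tol %g)",
            length(pairs), config$samples_dir, config$thickness_mm,
            config$tr_tol)

  mua_list <- stage("mu_a", lapply(pairs, mu_a_from_measurement))
  stats_ <- stage("ensemble", ensemble_stats(mua_list))
  log_stage("ensemble of %d absorption spectra, mean range [%.3g, %.3g] cm^-1",
            stats_$n, min(stats_$mean$values), max(stats_$mean$values))

  lib <- config$library
  if (is.null(lib)) lib <- make_library(stats_$mean$wavelength)

  res <- stage("unmix", full_reconstruction(stats_$mean, lib,
                                            fit_window = config$fit_window))
  bfit <- res$baseline_fit
  log_stage("baseline fit over %d wavelengths: p_mel = %.4f, p_lip = %.4f",
            length(bfit$fit_window), bfit$p_mel, bfit$p_lip)
  log_stage("component weights: %s",
            paste(sprintf("%s=%.4f", names(res$weights), res$weights),
                  collapse = ", "))

  floor_ <- stage("flat_floor", flat_floor(res$corrected))
  fr_orig <- stage("fold_ratios_original",
                   fold_ratios(stats_$mean, bfit, config$bands))
  if (floor_ > 0) {
    fr_corr <- stage("fold_ratios_corrected",
                     fold_ratios(res$corrected, floor_, config$bands))
  } else {
    # a tissue with no broadband absorption beyond the fitted components has
    # a residual floor at the noise level; ratios against it are undefined
    log_stage("flat floor is not positive (%.4g cm^-1); corrected-mode fold-ratios reported as NA",
              floor_)
    fr_corr <- fr_orig
    fr_corr$fold_ratio <- NA_real_
    attr(fr_corr, "mode") <- "baseline_removed"
  }
  log_stage("flat floor (800-850 nm): %.4g cm^-1", floor_)

  conc <- stage("concentrations",
                weights_to_concentrations(res$weights, config$water_fraction))
  sds <- stage("concentration_sd",
               concentration_sd(stats_$mean, stats_$sd, lib,
                                config$water_fraction,
                                fit_window = config$fit_window))
  model <- stage("blood_model", blood_model(config$blood_preset))
  hb_conc <- conc$concentration[conc$component == "hbo"]
  blood <- stage("blood_volume",
                 blood_volume_chain(hb_conc, model, config$water_fraction))
  log_stage("hemoglobin %.2f%% of tissue -> BVC %.2f%%", hb_conc, blood$bvc)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  fmt <- function(x) format(x, digits = 17, trim = TRUE)

  utils::write.csv(data.frame(wavelength_nm = stats_$mean$wavelength,
                              mean = fmt(stats_$mean$values),
                              sd = fmt(stats_$sd$values),
                              n = stats_$n),
                   out("mua_mean_sd.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(wavelength_nm = stats_$mean$wavelength,
                              baseline = fmt(bfit$baseline$values),
                              corrected = fmt(res$corrected$values)),
                   out("baseline.csv"), row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("%s %.17g", names(res$weights), res$weights),
               sprintf("residual_rms %.17g", res$residual_rms),
               sprintf("residual_max %.17g", res$residual_max),
               sprintf("flat_floor %.17g", floor_)),
             out("weights.txt"))
  utils::write.csv(data.frame(wavelength_nm = stats_$mean$wavelength,
                              observed = fmt(stats_$mean$values),
                              reconstructed = fmt(res$reconstructed$values),
                              residual = fmt(stats_$mean$values -
                                               res$reconstructed$values)),
                   out("recon.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(band = fr_orig$band,
                              peak_nm = fr_orig$peak_nm,
                              ratio_original = fmt(fr_orig$fold_ratio),
                              ratio_corrected = fmt(fr_corr$fold_ratio)),
                   out("foldratios.csv"), row.names = FALSE, quote = FALSE)
  conc_out <- data.frame(component = conc$component,
                         weight = fmt(conc$weight),
                         concentration = fmt(conc$concentration),
                         sd = fmt(as.numeric(sds[conc$component])))
  utils::write.csv(conc_out, out("concentrations.csv"),
                   row.names = FALSE, quote = FALSE)
  rl <- round_like_paper(blood)
  writeLines(c(sprintf("hb_fraction_of_blood %.17g", blood$hb_fraction_of_blood),
               sprintf("%s %.17g", names(unclass(blood))[2:7],
                       unlist(unclass(blood)[2:7])),
               "# printed convention",
               sprintf("%s_rounded %g", names(rl), rl)),
             out("blood.txt"))
  log_stage("wrote report bundle to %s", config$out_dir)

  invisible(list(pairs = pairs, stats = stats_, library = lib,
                 result = res, floor = floor_,
                 fold_ratios_original = fr_orig,
                 fold_ratios_corrected = fr_corr,
                 concentrations = conc, concentration_sd = sds,
                 blood = blood))
}
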