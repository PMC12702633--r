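test_that("noiseless pigment mixtures are recovered exactly", {
  set.seed(41)
  for (i in 1:10) {
    a <- runif(1, 0, 5)
    b <- runif(1, 0, 5)
    mua <- reconstruct(default_lib, c(melanin = a, lipofuscin = b))
    fit <- fit_baseline(mua, default_lib)
    expect_equal(fit$p_mel, a, tolerance = 1e-9)
    expect_equal(fit$p_lip, b, tolerance = 1e-9)
    expect_lt(fit$residual_rms, 1e-9)
  }
  z <- fit_baseline(reconstruct(default_lib, c(melanin = 0)), default_lib)
  expect_equal(c(z$p_mel, z$p_lip), c(0, 0))
})

test_that("the fitted baseline is the exact weighted pigment sum on the full grid", {
  mua <- reconstruct(default_lib, lung_truth)
  fit <- fit_baseline(mua, default_lib)
  manual <- fit$p_mel * default_lib$components$melanin$values +
    fit$p_lip * default_lib$components$lipofuscin$values
  expect_equal(fit$baseline$values, manual, tolerance = 1e-14)
  expect_gte(fit$p_mel, 0)
  expect_gte(fit$p_lip, 0)
  # inherits pigment monotonicity above 300 nm
  v <- fit$baseline$values[fit$baseline$wavelength >= 300]
  expect_true(all(diff(v) <= 0))
  expect_true(all(fit$baseline$values >= 0))
})

test_that("degenerate fit windows are rejected", {
  mua <- reconstruct(default_lib, c(melanin = 1))
  expect_error(fit_baseline(mua, default_lib, fit_window = 700),
               "at least 2")
})

test_that("noisy pigment fits are unbiased within 3 standard errors", {
  set.seed(43)
  truth <- c(melanin = 2.85, lipofuscin = 2.85)
  mua0 <- reconstruct(default_lib, truth)
  win <- default_fit_window(mua0$wavelength)
  reps <- 200
  est <- matrix(NA, reps, 2)
  for (r in seq_len(reps)) {
    noisy <- new_spectrum(mua0$wavelength,
                          mua0$values + rnorm(801, 0, 0.1), "cm^-1")
    f <- fit_baseline(noisy, default_lib, fit_window = win)
    est[r, ] <- c(f$p_mel, f$p_lip)
  }
  z <- (colMeans(est) - truth) / (apply(est, 2, sd) / sqrt(reps))
  expect_true(all(abs(z) < 3))
})

test_that("subtracting a self-fit leaves only numerical dust; zero baseline is identity", {
  mua <- reconstruct(default_lib, c(melanin = 3.2, lipofuscin = 1.1))
  fit <- fit_baseline(mua, default_lib)
  resid <- subtract_baseline(mua, fit)
  expect_lt(max(abs(resid$values)), 1e-9)

  full <- reconstruct(default_lib, lung_truth)
  zfit <- fit_baseline(reconstruct(default_lib, c(melanin = 0)), default_lib)
  expect_equal(subtract_baseline(full, zfit)$values, full$values)

  other <- new_spectrum(wl_grid(300, 900, 1), rep(1, 601), "cm^-1")
  expect_error(subtract_baseline(other, fit), "grid")
})

test_that("baseline removal keeps band peaks and flattens the space between them", {
  mua <- reconstruct(default_lib, lung_truth)
  fit <- fit_baseline(mua, default_lib)
  corr <- subtract_baseline(mua, fit)
  for (b in lung_bands()) {
    pk_before <- locate_peak(mua, b)
    pk_after <- locate_peak(corr, b)
    expect_lte(abs(pk_after - b$nominal_center), b$search_halfwidth)
    expect_lte(abs(pk_after - pk_before), 5)
  }
  # between-band floor is flat relative to the band peaks
  between <- corr$values[corr$wavelength >= 620 & corr$wavelength <= 900]
  expect_lt(max(abs(between)), 0.05 * max(corr$values))
})

test_that("flat_floor equals an exhaustive-scan minimum oracle", {
  const <- new_spectrum(wl_grid(700, 900, 1), rep(1.3, 201), "cm^-1")
  expect_equal(flat_floor(const), 1.3)
  set.seed(47)
  s <- new_spectrum(wl_grid(700, 900, 1), runif(201, 0.5, 2), "cm^-1")
  sel <- s$wavelength >= 800 & s$wavelength <= 850
  oracle <- Inf
  for (i in which(sel)) oracle <- min(oracle, s$values[i])
  expect_equal(flat_floor(s), oracle)
  expect_error(flat_floor(s, 950, 990), "no grid wavelengths")
})
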