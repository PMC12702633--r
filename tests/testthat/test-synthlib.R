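peak_of <- function(s) s$wavelength[which.max(s$values)]

test_that("generated components honor the band-position invariants", {
  lib <- default_lib
  expect_true(peak_of(lib$components$proteins) >= 225 &&
                peak_of(lib$components$proteins) <= 240)
  expect_true(peak_of(lib$components$dna) >= 255 &&
                peak_of(lib$components$dna) <= 265)
  expect_true(peak_of(lib$components$hbo) >= 405 &&
                peak_of(lib$components$hbo) <= 420)
  expect_true(peak_of(lib$components$water) >= 965 &&
                peak_of(lib$components$water) <= 985)
  # hemoglobin Q-bands: local maxima inside 530-550 and 560-580 nm
  hbo <- lib$components$hbo$values
  wl <- lib$grid
  for (win in list(c(530, 550), c(560, 580))) {
    sel <- wl >= win[1] & wl <= win[2]
    pk <- wl[sel][which.max(hbo[sel])]
    i <- match(pk, wl)
    expect_gt(hbo[i], hbo[i - 5])
    expect_gt(hbo[i], hbo[i + 5])
  }
  # pigments strictly decreasing above 300 nm
  for (nm in c("melanin", "lipofuscin")) {
    v <- lib$components[[nm]]$values[wl >= 300]
    expect_true(all(diff(v) < 0))
  }
  # normalization contract
  for (s in lib$components) {
    expect_equal(min(s$values), 0)
    expect_equal(max(s$values), 1)
  }
})

test_that("melanin decreases across 300/600/900 nm and decays faster than lipofuscin", {
  mel <- default_lib$components$melanin
  at <- function(s, w) s$values[match(w, s$wavelength)]
  expect_gt(at(mel, 300), at(mel, 600))
  expect_gt(at(mel, 600), at(mel, 900))
  lip <- default_lib$components$lipofuscin
  expect_lt(at(mel, 600), at(lip, 600))
})

test_that("make_library is deterministic and passes overrides through", {
  expect_identical(make_library(), make_library())
  lib2 <- make_library(overrides = list(water = list(center = 980)))
  expect_equal(peak_of(lib2$components$water), 980)
  expect_identical(lib2$components$hbo$values, default_lib$components$hbo$values)
  expect_error(make_component("collagen"), "unknown component")
})

test_that("zero-absorption ensembles satisfy T + R = 1", {
  pairs <- synth_pairs(weights = c(hbo = 0), noise_sd = 0)
  tot <- pairs[[1]]$transmittance$values + pairs[[1]]$reflectance$values
  expect_equal(tot, rep(1, 801), tolerance = 1e-15)
})

test_that("noiseless synthesis round-trips through the direct calculation", {
  pairs <- synth_pairs(noise_sd = 0)
  truth <- attr(pairs, "true_mua")
  rec <- mu_a_from_measurement(pairs[[1]])
  expect_equal(rec$values, truth$values, tolerance = 1e-12)
})

test_that("ensembles are reproducible under a fixed seed", {
  a <- synth_pairs(noise_sd = 0.01, n_samples = 3, seed = 99)
  b <- synth_pairs(noise_sd = 0.01, n_samples = 3, seed = 99)
  expect_identical(a, b)
  c_ <- synth_pairs(noise_sd = 0.01, n_samples = 3, seed = 100)
  expect_false(identical(a, c_))
})

test_that("infeasible optical thickness is rejected", {
  expect_error(synth_pairs(weights = c(hbo = 25), thickness_cm = 0.1),
               "infeasible")
})

test_that("ensemble mean converges to the true spectrum roughly as 1/sqrt(n)", {
  err_for <- function(n, seed) {
    pairs <- synth_pairs(noise_sd = 0.01, n_samples = n, seed = seed)
    truth <- attr(pairs, "true_mua")
    st <- ensemble_stats(lapply(pairs, mu_a_from_measurement))
    sqrt(mean((st$mean$values - truth$values)^2))
  }
  e10 <- err_for(10, 5)
  e1000 <- err_for(1000, 5)
  expect_lt(e1000, e10 / 3)  # expected factor ~ sqrt(100) = 10
})

test_that("background_mua adds a flat offset to the constructed coefficient", {
  p0 <- synth_pairs(noise_sd = 0)
  p1 <- synth_pairs(noise_sd = 0, background_mua = 0.8)
  d <- attr(p1, "true_mua")$values - attr(p0, "true_mua")$values
  expect_equal(d, rep(0.8, 801), tolerance = 1e-12)
})
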