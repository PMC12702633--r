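test_that("reconstruct matches a per-term accumulation oracle", {
  expect_equal(reconstruct(default_lib, c(hbo = 0, water = 0))$values,
               rep(0, 801))
  expect_equal(reconstruct(default_lib, c(dna = 1))$values,
               default_lib$components$dna$values)
  w <- lung_truth
  acc <- rep(0, 801)
  for (nm in names(w)) acc <- acc + w[[nm]] * default_lib$components[[nm]]$values
  expect_equal(reconstruct(default_lib, w)$values, acc, tolerance = 1e-14)
  expect_error(reconstruct(default_lib, c(collagen = 1)), "unknown component")
  expect_error(reconstruct(default_lib, c(hbo = -1)), "nonnegative")
})

test_that("fit_components recovers noiseless weights and the zero spectrum", {
  set.seed(61)
  for (i in 1:10) {
    w <- runif(4, 0, 10)
    names(w) <- c("water", "dna", "hbo", "proteins")
    target <- reconstruct(default_lib, w)
    fit <- fit_components(target, default_lib)
    expect_equal(fit$weights, w[names(fit$weights)], tolerance = 1e-9)
    expect_lt(fit$residual_max, 1e-9)
  }
  z <- fit_components(reconstruct(default_lib, c(water = 0)), default_lib)
  expect_equal(unname(z$weights), rep(0, 4))
})

test_that("fit_components agrees with an unconstrained least-squares oracle at interior solutions", {
  w <- c(water = 0.8, dna = 2.1, hbo = 9.3, proteins = 1.7)
  target <- reconstruct(default_lib, w)
  A <- sapply(c("water", "dna", "hbo", "proteins"),
              function(nm) default_lib$components[[nm]]$values)
  ols <- coef(lm(target$values ~ A - 1))
  fit <- fit_components(target, default_lib)
  expect_equal(unname(fit$weights), unname(ols), tolerance = 1e-7)
})

test_that("duplicated components trigger a collinearity warning with an equal split", {
  lib2 <- default_lib
  lib2$components$hbo2 <- lib2$components$hbo
  target <- reconstruct(default_lib, c(hbo = 6))
  expect_warning(fit <- fit_components(target, lib2,
                                       components = c("hbo", "hbo2")),
                 "collinear")
  expect_equal(unname(fit$weights), c(3, 3), tolerance = 1e-9)
})

test_that("two-step reconstruction recovers the reference lung weights end to end", {
  mua <- reconstruct(default_lib, lung_truth)
  res <- full_reconstruction(mua, default_lib)
  expect_identical(res$method, "two_step")
  rel <- abs(res$weights - lung_truth[names(res$weights)]) /
    lung_truth[names(res$weights)]
  expect_true(all(rel < 0.01))
  # reconstructed = component sum + baseline, nonnegative everywhere
  expect_true(all(res$reconstructed$values >= 0))
  manual <- reconstruct(default_lib, res$weights)
  expect_equal(res$reconstructed$values, manual$values, tolerance = 1e-12)
})

test_that("pure pigment input yields zero non-pigment weights", {
  mua <- reconstruct(default_lib, c(melanin = 2.85, lipofuscin = 2.85))
  res <- full_reconstruction(mua, default_lib)
  expect_equal(unname(res$weights[c("water", "dna", "hbo", "proteins")]),
               rep(0, 4), tolerance = 1e-9)
})

test_that("the joint six-component fit also recovers noiseless truth", {
  mua <- reconstruct(default_lib, lung_truth)
  res <- full_reconstruction(mua, default_lib, method = "joint")
  expect_identical(res$method, "joint")
  rel <- abs(res$weights - lung_truth[names(res$weights)]) /
    lung_truth[names(res$weights)]
  expect_true(all(rel < 1e-9))
})

test_that("weight recovery error grows monotonically with noise", {
  set.seed(67)
  noise_levels <- c(0, 0.005, 0.01, 0.02)
  med_err <- sapply(seq_along(noise_levels), function(k) {
    ns <- noise_levels[k]
    errs <- replicate(50, {
      pairs <- synth_pairs(noise_sd = ns, n_samples = 1,
                           seed = sample.int(1e6, 1))
      m <- mu_a_from_measurement(pairs[[1]])
      res <- full_reconstruction(m, default_lib)
      sqrt(mean((res$weights - lung_truth[names(res$weights)])^2))
    })
    median(errs)
  })
  expect_true(all(diff(med_err) > 0))
})

test_that("noisy ensemble residual stays near the noise-induced floor", {
  pairs <- synth_pairs(noise_sd = 0.01, n_samples = 10, seed = 17)
  st <- ensemble_stats(lapply(pairs, mu_a_from_measurement))
  res <- full_reconstruction(st$mean, default_lib)
  # expected per-wavelength noise on the ensemble mean: sqrt(2)*sd/(d*sqrt(n))
  noise_floor <- sqrt(2) * 0.01 / (0.05 * sqrt(10))
  expect_lt(res$residual_rms, 2 * noise_floor)
})
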