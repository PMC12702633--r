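test_that("weight-to-concentration conversion reproduces the reference table", {
  tab <- weights_to_concentrations(lung_truth, water_fraction = 80)
  conc <- setNames(tab$concentration, tab$component)
  expect_equal(round(conc[["water"]], 2), 80.00)
  expect_equal(round(conc[["melanin"]], 2), 2.30)
  expect_equal(round(conc[["lipofuscin"]], 2), 2.30)
  expect_equal(round(conc[["dna"]], 2), 2.85)
  expect_equal(round(conc[["hbo"]], 2), 10.20)
  # proteins: the stated conversion gives 2.3434 (2.34 at 2 d.p.), commonly
  # quoted as 2.35; assert our computed value
  expect_equal(round(conc[["proteins"]], 2), 2.34)
  expect_lt(abs(conc[["proteins"]] - 2.35), 0.01)
})

test_that("concentrations always sum to 100 and water anchors exactly", {
  set.seed(71)
  for (i in 1:20) {
    w <- runif(5, 0, 10)
    names(w) <- c("water", "melanin", "dna", "hbo", "proteins")
    wf <- runif(1, 40, 95)
    tab <- weights_to_concentrations(w, wf)
    expect_equal(sum(tab$concentration), 100, tolerance = 1e-12)
    expect_equal(tab$concentration[tab$component == "water"], wf)
    expect_true(all(tab$concentration >= 0))
  }
  single <- weights_to_concentrations(c(water = 0.2, hbo = 4), 80)
  expect_equal(single$concentration[single$component == "hbo"], 20)
  expect_error(weights_to_concentrations(c(water = 1, hbo = 0)), "degenerate")
  expect_error(weights_to_concentrations(c(hbo = 1)), "include water")
})

test_that("SD propagation is zero for a zero SD spectrum", {
  mua <- reconstruct(default_lib, lung_truth)
  zero <- new_spectrum(mua$wavelength, rep(0, 801), "cm^-1")
  sds <- concentration_sd(mua, zero, default_lib)
  expect_equal(unname(sds), rep(0, length(sds)), tolerance = 1e-6)
})

test_that("noise confined to the hemoglobin bands drives the hemoglobin SD", {
  mua <- reconstruct(default_lib, lung_truth)
  wl <- mua$wavelength
  sdv <- rep(0, 801)
  for (c0 in c(412, 540, 576)) sdv <- sdv + 0.8 * exp(-(wl - c0)^2 / (2 * 10^2))
  sds <- concentration_sd(mua, new_spectrum(wl, sdv, "cm^-1"), default_lib)
  non_water <- sds[setdiff(names(sds), "water")]
  expect_identical(names(which.max(non_water)), "hbo")
})

test_that("hemoglobin fraction of blood matches the hematocrit arithmetic", {
  expect_equal(hb_fraction_of_blood(blood_model("rabbit42")), 38.95)
  expect_equal(hb_fraction_of_blood(blood_model("rabbit42"), rounded = TRUE), 39)
  expect_equal(hb_fraction_of_blood(blood_model("rabbit45")), 41.8)
  expect_equal(hb_fraction_of_blood(blood_model(hematocrit = 42,
                                                hb_fraction_of_rbc = 0)), 0)
  expect_error(hb_fraction_of_blood(blood_model(hematocrit = 1,
                                                other_cells = 1)),
               "hematocrit")
})

test_that("blood-volume chain reproduces the reference breakdown under the printed convention", {
  b <- blood_volume_chain(10.2, blood_model("rabbit42"), water_fraction = 80)
  r <- round_like_paper(b)
  expect_equal(unname(r["non_hb_blood_in_tissue"]), 15.9)
  expect_equal(unname(r["bvc"]), 26.1)
  expect_equal(unname(r["cellular_non_hb_in_tissue"]), 0.8)
  expect_equal(unname(r["plasma_in_tissue"]), 15.1)
  expect_equal(unname(r["non_plasma_water"]), 64.9)
})

test_that("blood-volume identities hold exactly at full precision", {
  set.seed(73)
  for (i in 1:20) {
    hb <- runif(1, 0, 12)
    m <- blood_model(hematocrit = runif(1, 34, 50))
    b <- blood_volume_chain(hb, m, water_fraction = 80)
    expect_equal(b$bvc, b$hb_in_tissue + b$non_hb_blood_in_tissue)
    expect_equal(b$non_hb_blood_in_tissue,
                 b$plasma_in_tissue + b$cellular_non_hb_in_tissue)
    expect_equal(b$non_plasma_water, 80 - b$plasma_in_tissue)
  }
  b0 <- blood_volume_chain(0)
  expect_equal(b0$bvc, 0)
  expect_equal(b0$non_plasma_water, 80)
  expect_error(blood_volume_chain(60, water_fraction = 50),
               "inconsistent model")
})

test_that("whole-blood composition matches the hematocrit-45 preset and conserves volume", {
  comp <- whole_blood_composition(blood_model("rabbit45"))
  expect_equal(unname(comp["hemoglobin"]), 41.8)
  expect_equal(unname(comp["rbc_membranes"]), 2.2)
  expect_equal(unname(comp["albumin"]), 2.1175)
  expect_equal(unname(sum(comp[c("hemoglobin", "rbc_membranes",
                                 "other_cells", "plasma")])), 100)
  zero_prot <- whole_blood_composition(blood_model("rabbit45",
                                                   plasma_protein_fraction = 0))
  expect_equal(unname(zero_prot["albumin"]), 0)
})
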