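---
title: "Reconstructing broadband tissue absorption spectra and reading physiology out of them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing broadband tissue absorption spectra and reading physiology out of them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuemua)
```

## The measurement model

An integrating-sphere spectrometer measures, for a thin tissue section of
thickness $d$, the total transmittance $T_t(\lambda)$ and total reflectance
$R_t(\lambda)$ as dimensionless fractions over 200--1000 nm. Whatever is
neither transmitted nor reflected was absorbed along the path $d$, which in
the direct-calculation form of the photon diffusion approximation gives the
absorption coefficient

$$\mu_a(\lambda) \;=\; \frac{1 - \big(T_t(\lambda) + R_t(\lambda)\big)}{d},$$

in cm$^{-1}$ when $d$ is in cm. The relation treats the measurement pair as
exact: specular losses and scattering escape are not modelled, and the
regime of validity is $\mu_a d \le 1$ (the synthetic generator refuses
configurations outside it). `mu_a_from_measurement()` implements this with
one deliberate nuance: noisy measurements routinely land marginally above
$T_t + R_t = 1$ at weakly absorbing wavelengths, and the resulting small
negative coefficients are *kept*. Clipping them to zero would bias every
ensemble mean, and through it every fitted weight, upward; the
nonnegativity guarantee applies to physical (noiseless) inputs.
`measurement_pair()` therefore takes a tolerance: its default (1e-9)
admits only floating-point dust, while readers of real noisy data should
pass roughly the instrument noise level (the pipeline default is 0.05).

## The component model

The spectrum of a soft tissue is modelled as a weighted sum of normalized
component spectra,

$$\mu_a(\lambda) \;=\; \sum_i p_i\, \mu_{ai}(\lambda),$$

over six chromophores: water, DNA, oxy-hemoglobin, proteins, and the
age-accumulated pigments melanin and lipofuscin. Every library component is
normalized by the same convention — displaced so its minimum is zero, then
divided by its maximum (`normalize_spectrum()`) — so the $p_i$ are
comparable across components. The weights carry no absolute scale of their
own; physiology enters only when they are anchored (below).

Fitting is done in **two steps**, mirroring how the pigment baseline is
handled in broadband tissue spectroscopy:

1. **Baseline.** Melanin and lipofuscin absorb broadly and decreasingly
   with wavelength and sit *under* the discrete bands. Their weights are
   fitted by nonnegative least squares (Lawson--Hanson, via
   `pracma::lsqnonneg`) over a *band-free window* only, then the baseline
   $p_{Mel}\mu_{a\text{-}Mel} + p_{Lip}\mu_{a\text{-}Lip}$ is evaluated on
   the full grid and subtracted.
2. **Components.** Water, DNA, oxy-hemoglobin and proteins are fitted to
   the corrected spectrum by nonnegative least squares over the full grid.

A joint six-component fit (`method = "joint"`) is provided for comparison
but is not the reference path: fitting pigments through the absorption
bands lets band area leak into the broadband terms.

### The fit window

The default window excludes everything above 900 nm (water-dominated) and a
$\pm$45 nm zone around each band center at 235, 261, 275, 412, 540 and
570 nm. The half-width matters more than it looks: the two pigment shapes
are strongly collinear (both are decaying exponentials), so even a small
amount of band tail inside the window is amplified into large, opposite
errors on $p_{Mel}$ and $p_{Lip}$. With realistic band widths (the Soret
band has $\sigma \approx 10$ nm, the ultraviolet bands 11--15 nm), a
$\pm$45 nm zone — roughly three standard deviations of the widest band —
keeps tail contamination below the 0.1% level, and noiseless end-to-end
recovery of all six weights is then better than 0.25% relative. Narrower
exclusions (e.g. $\pm$25 nm) admit Soret-tail contamination of order
1 cm$^{-1}$ just past the edge and destroy the pigment split.

### What the baseline fit cannot do

If the tissue contains broadband absorption that is *not* pigment-like —
the synthetic generator's `background_mua`, or in real tissue any flat
unmodelled absorber — the nonnegative fit will absorb part of it into the
pigment weights (mostly into lipofuscin, the slower-decaying shape) and
leave the rest as a positive flat floor in the corrected spectrum. The
floor is summarised by `flat_floor()`, the minimum over 800--850 nm, a
region free of both bands and (by construction of the window) baseline
misfit. Negative residuals after subtraction are reported, never clipped:
clipping would bias that floor upward and with it every corrected-mode
fold-ratio.

## Fold-ratios

The fold-ratio of a chromophore is the peak absorption of its band divided
by the local baseline — a content proxy that is invariant to a common
rescaling of the spectrum. Peaks are *searched*, not assumed: band centers
in tissue drift by a few nanometres from the pure substance (the protein
band right-shifts from 230 to about 235 nm), so `locate_peak()` takes the
maximum within $\pm$15 nm of the nominal center, breaking ties toward the
nominal center and then toward shorter wavelength. Before baseline removal
the denominator is the fitted pigment curve at the peak wavelength; after
removal it is the flat floor. On spectra with a broadband floor, removal
raises the fold-ratios of every band below ~600 nm (the pigment absorption
that was hiding them is gone) and lowers the water ratio at 974 nm (the
pigments contribute almost nothing there, while the denominator switches
from the small pigment value to the larger floor).

## From weights to physiology

`weights_to_concentrations()` anchors the weights to a known tissue water
content (80% is the standard estimate for lung): water is pinned at the
anchor and the non-water weights are rescaled proportionally onto the
remaining 20%, water's own fitted weight playing no role in the rescaling.
The output always sums to exactly 100%. For the reference rabbit-lung
weight vector (`rabbit_lung_weights()`) this yields melanin and lipofuscin
2.30% each, DNA 2.85%, proteins 2.34% and hemoglobin 10.20%. (Proteins are
sometimes quoted as 2.35%; the conversion of the printed weights gives
2.3434%, a rounding-level discrepancy the tests document.)

Concentration SDs are propagated spectrally (`concentration_sd()`): the
full reconstruction is refitted on mean $+$ SD, both weight sets are
converted to concentrations, and the per-component SD is the absolute
difference. The refit reuses nothing from the mean fit — baseline included —
so the SD reflects the whole two-step procedure.

The blood-volume chain (`blood_volume_chain()`) back-calculates the whole
blood volume concentration (BVC) from the fitted hemoglobin concentration.
A `blood_model()` supplies the anatomy: at hematocrit 42% with 1% of
non-red cells and hemoglobin occupying 95% of the red-cell volume,
hemoglobin is $(42-1)\times 0.95 = 38.95\%$ of blood, conventionally
rounded to 39%. A tissue hemoglobin content of 10.2% then implies
$10.2 \times 61/39 = 15.95\%$ of non-hemoglobin blood components,
BVC $= 26.1\%$, a cellular part of 0.8%, plasma of 15.1%, and — subtracting
plasma from the 80% water anchor — 64.9% of water residing outside blood.
All fields are kept at full precision, where the decomposition identities
hold exactly; `round_like_paper()` reproduces the hand-computed convention
(the first-stage ratio displayed truncated at 0.1, later stages chained
from the rounded predecessors), which is how 15.95 is carried as 15.9. Two
presets ship: `"rabbit42"` (mid-range hematocrit, used for the chain) and
`"rabbit45"` (used for the whole-blood composition, where hemoglobin is
41.8% of blood and albumin 2.1%).

## The synthetic generator, and what it does not emulate

`make_library()` builds the six components parametrically: pigments as
normalized decaying exponentials ($\tau_{Mel} = 175$ nm,
$\tau_{Lip} = 250$ nm, so melanin decays faster), water as a Gaussian at
974 nm ($\sigma = 30$ nm) with a weak deep-UV tail, DNA as a Gaussian at
260 nm on a weak decaying background, oxy-hemoglobin as Gaussians at 412
(Soret, amplitude 1), 275 (0.45), 540 (0.18) and 576 nm (0.20), and
proteins as a Gaussian at 230 nm with a 278 nm shoulder. Centers are the
standard band positions; widths are of the order of the pure-substance
bands; exact amplitudes of the minor bands are free choices of the
generator, made once.

`synth_measurements()` inverts the direct calculation: with
$\mu_a = \sum_i p_i \mu_{ai} + \text{background}$, the noiseless core is
$T_t + R_t = 1 - \mu_a d$, split between the channels by
`transmit_fraction` (default 0.5 — the direct calculation only constrains
the sum, so the split is a free parameter). Gaussian noise (default SD
0.01, in fraction units) is added independently per channel, because that
is where the instruments act, and each channel is clipped to $[0,1]$. The
default ensemble is 10 samples of 0.5 mm thickness. All randomness derives
from one integer seed.

What passing tests on this generator do **not** show about real data: there
is no scattering model (the split between $T_t$ and $R_t$ is arbitrary,
only their sum is physical), no specular losses, no wavelength-correlated
noise or drift, no deviation of real component spectra from the parametric
shapes, and no inter-animal variability beyond i.i.d. measurement noise.
The generator validates the *procedure* — round-trips, unbiasedness,
conservation — not the biology.

## Numerical choices and edge cases

* Problem sizes: tests and the acceptance script run on the full 801-point
  grid; Monte-Carlo checks use 200 single-sample replicates at 1% noise
  (about a second of compute), chosen to give standard errors small enough
  to detect percent-level bias.
* Resampling is linear interpolation; extrapolation is an error, never a
  silent clamp. Normalization requires a non-constant spectrum.
* Nonnegative least squares is deterministic; an exactly duplicated
  component is detected, warned about, and its weight split equally (the
  minimal-norm nonnegative solution for identical columns).
* Ensemble SD uses the sample ($n-1$) denominator and is all-zero for
  $n = 1$.
* Fold-ratios against a nonpositive floor are undefined and error in
  `fold_ratios()`; the pipeline reports them as `NA` instead of aborting,
  since a spectrum fully explained by the six components has a floor at
  the noise level.
* The pigment split ($p_{Mel}$ vs $p_{Lip}$) is the least identifiable
  quantity in the model: the two shapes are nearly collinear, so at 1%
  noise and $n = 10$ the individual weights wander by ~10% while their sum
  is stable. Consumers who only need the total pigment load should use the
  sum.

## Known limitations

The direct calculation inherits every idealisation of the measurement
relation: no correction for scattering escape or refractive-index
mismatch, so absolute $\mu_a$ values are only as good as that
approximation. The component model uses a single oxy-hemoglobin spectrum
(no oxygen-saturation fitting) and no lipid component. The concentration
anchor (80% water) is an assumption, not a measurement; all non-water
concentrations scale with $100 -$ anchor.
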