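---
title: "Composition uncertainty in RED-based CT-number and proton-SPR estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition uncertainty in RED-based CT-number and proton-SPR estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redspr)
```

## The problem

Proton treatment planning converts CT numbers to proton stopping-power
ratios (SPR) through a calibration curve. Because materials with different
chemical compositions can share a CT number while differing in SPR (the
degeneracy effect), and because a patient's tissue composition is unknown,
this conversion carries a range uncertainty that clinics absorb with
margins of several percent of the water-equivalent depth.

`redspr` quantifies where that uncertainty actually lives. It splits the
clinical chain into two mappings — relative electron density (RED) to
kilovoltage CT number, and RED to proton SPR — and measures how chemical
composition variation perturbs each. The repeated finding, reproduced by
this package from first principles, is that the SPR mapping is nearly
immune to composition while the kVCT-number mapping is not, which is the
physical case for determining SPR from an electron-density image such as
megavoltage CT.

## Models

**Scaled kV CT number** (CT number + 1000, so water sits at 1000) follows
the stoichiometric parameterization

$$\mathrm{HU}_{scale} = \mathrm{RED}\cdot\left(A\,\tilde{Z}^{3.62} + B\,\hat{Z}^{1.86} + C\right),$$

whose three terms model photoelectric interaction, coherent scattering and
Compton scattering. $\tilde Z$ and $\hat Z$ are power means of the atomic
number over electron fractions $\lambda_i = N_{g,i}/N_g$ with fixed
exponents 3.62 and 1.86 (these are structural constants of the
parameterization, not fit parameters), and
$N_g = N_A \sum_i \omega_i Z_i / A_i$ counts electrons per gram from the
elemental mass fractions $\omega_i$. $A$, $B$, $C$ are machine- and
energy-dependent; the packaged defaults
($A = 1.995\times10^{-2}$, $B = 1.899\times10^{-1}$, $C = 964.0$) were
determined on a 120 kVp helical scanner from an electron-density phantom,
and `fit_kv_parameters()` refits them by no-intercept least squares on the
three model regressors when substitute compositions and measured CT numbers
are available. The measured CT numbers of the 14 phantom inserts ship as
`inst/extdata/cirs_phantom_hu.csv`; the vendor's insert compositions are
proprietary and are not included, so refitting requires user-supplied
composition data and the printed coefficients are the default.

**Proton SPR** uses the ratio of Bethe stopping numbers,

$$\mathrm{SPR} = \mathrm{RED}\cdot
\frac{\ln\!\big(2m_ec^2\beta^2/(I_m(1-\beta^2))\big)-\beta^2}
     {\ln\!\big(2m_ec^2\beta^2/(I_w(1-\beta^2))\big)-\beta^2},$$

with the tissue mean excitation energy $I_m$ from Bragg additivity over
ICRU-37 elemental values, $\ln I_m = \sum_i \omega_i \frac{Z_i}{A_i} \ln
I_i \,/\, \sum_i \omega_i \frac{Z_i}{A_i}$. Shell, density-effect and
higher-order corrections are deliberately out of scope: the quantity of
interest is a ratio of similar media at therapeutic energies, where these
corrections largely cancel.

**RED** is $\rho N_g / (\rho_w N_w)$, normalized to water built from the
IUPAC 2021 atomic weights (11.19% H, 88.81% O by mass).

## Reference tissues and calibration curves

The packaged table holds 32 reference human tissues (3 fat, 18 non-fat
soft, 11 bone) with ICRP publication 23 densities and compositions; cell
nucleus (never occurring in bulk) and whole breast (a fat/gland mixture
that CT resolves into separate voxels) are not part of the set. Rows are
validated to sum to within 0.5 of 100% and renormalized multiplicatively
to exactly 100 on load — the mass-fraction formulas above assume a proper
distribution, and the same renormalization closes the simulation loop
below. (As printed, all 32 rows already sum to 100.0, so for the builtin
set this is a no-op.)

Calibration curves are segmented linear least-squares fits of the target
(HU$_{scale}$ or SPR, computed from the exact compositions) against RED,
one independent affine line per tissue category. Segmenting by category
keeps chemical composition within each line's support similar; the
segments are not forced to join at category boundaries, since nothing in
the estimation procedure evaluates a curve outside its own category. A
zero-intercept variant (`intercept = FALSE`) exists for sensitivity
checks.

## Simulated tissues

`simulate_all()` emulates biological composition variability: every
nonzero elemental weight of a parent tissue is drawn independently from
$\mathcal{N}(\mu = w_i,\ \sigma = 0.05\,w_i)$ and the resulting vector is
renormalized to 100%. The defaults — 100 samples per reference tissue
(3200 total) and a 5% relative sigma, motivated by literature estimates of
elemental weight variability (about 4.8% for H and 4.4% for Ca) — are the
study conditions and are not tuned. Density is *not* resampled: RED then
changes only through $N_g$, which isolates the composition question from
the (separately measurable) density. Negative draws are clamped to zero
before renormalization and counted in the `n_clamped` attribute; at 5%
relative sigma a negative draw sits 20 sigmas out and never occurs in
practice.

Per-tissue RNG substreams are keyed by (seed, parent name) through a
31-adic string hash, so a single tissue's draws are reproducible in
isolation and independent of table order.

What the generator does *not* emulate: correlated element fluctuations
(e.g. Ca and P moving together in bone mineral), density variation,
inter-patient systematic shifts, or any imaging-chain noise. Passing
results therefore bound the effect of independent composition noise on the
calibration curves, not the full clinical error budget.

## Uncertainty decomposition

For every tissue the truth (model value from the exact composition) and
the estimate (curve value at the tissue's RED, on its category's segment)
give a percentage deviation $100\,(\mathrm{est}-\mathrm{truth})/\mathrm{truth}$.

* **Systematic** uncertainty is the standard deviation of these deviations
  across the fixed-composition reference tissues, per category and pooled.
* **Statistical** uncertainty comes from the simulated tissues after
  subtracting each parent's own deviation, removing the systematic part of
  the signal.
* **Total** is the root sum of squares, an identity the report satisfies
  exactly before any rounding.

Standard deviations use the $n-1$ sample convention about the pooled mean
(`std_mode = "population"` switches to $n$); with near-zero-mean
deviations the two differ by far less than the two decimals reported.
Pooled rows pool the deviations themselves rather than averaging category
sigmas. All intermediate quantities stay in double precision; rounding
happens only in display code.

Two deliberate invariances pin down otherwise ambiguous constants:

* **$I_w$ invariance.** $I_w$ appears identically in truth and curve, so
  percentage-deviation statistics are invariant to rescaling it. The
  default (`iw_mode = "bragg_additivity"`) computes $I_w$ from water's own
  composition, which also makes SPR(water) exactly 1; `iw_mode = "fixed"`
  takes a tabulated value. The test suite asserts the SPR report is
  unchanged to $10^{-10}$ between $I_w = 69$ and 78 eV.
* **Proton energy.** The Bethe logarithms vary slowly with $\beta^2$, and
  the curve is refit at whatever energy is chosen, so the pooled SPR
  systematic sigma moves by well under 0.05 percentage points between 100
  and 250 MeV (asserted in the tests). The default is 175 MeV, a
  mid-range therapeutic energy.

## kV vs MV beam comparison

To contrast the two imaging regimes directly, `linearity_comparison()`
computes narrow-beam CT numbers at single effective energies — 60 keV for
a 120 kVp beam (near the tungsten characteristic x rays) and 0.8 MeV for a
2.5 MV imaging beam (near its average energy) — via the elemental mixture
rule $\mu = \rho \sum_i (\omega_i/100)(\mu/\rho)_i$ and
$\mathrm{HU}_{scale} = 1000\,\mu/\mu_{water}$.

This is the analytic expectation of an unscattered-photon counting
experiment: a photon traverses thickness $t$ uninteracted with probability
$e^{-\mu t}$, so counting survivors estimates exactly this $\mu$, with the
*total* attenuation coefficient (coherent scattering included, since a
coherently scattered photon is no longer "unscattered"). Working with the
expectation removes Monte Carlo noise without changing the estimand; a
small Bernoulli survival simulation in the test suite confirms the
equivalence to within counting statistics.

The embedded per-element $(\mu/\rho)$ values at the two energies are
generated from the same three-component cross-section decomposition the
CT-number model uses (photoelectric $\propto Z^{3.62}$, coherent $\propto
Z^{1.86}$ per electron, Klein–Nishina Compton), calibrated at each energy
against NIST reference coefficients for water and ICRU-44 cortical bone
(60 keV) and water and iron (0.8 MeV). This reproduces standard tabulated
element values to within about 2% over the low-$Z$ range that dominates
tissue. The power law fails near the iodine K-edge (33.2 keV), so the
iodine entries are taken from standard tabulations instead. Iodine enters
only thyroid, at 0.1% weight, and only in this beam model; different
published cross-section sets shift the three-point fat-category kV $R^2$
in the third decimal, which is the expected sensitivity of that statistic.
`write_element_registry()` exports every constant for audit.

## Worked run

```{r report}
report <- build_report(config = simulation_config(100, 0.05, seed = 1))
report
```

The pattern to read off: systematic uncertainty is several times larger
for the kVCT number than for SPR in every category (pooled ~0.5% vs
~0.1%); statistical uncertainty in the CT number is small for fat and soft
tissue but large for bone, where perturbing the high-$Z$ calcium and
phosphorus content moves $\tilde Z^{3.62}$ strongly; and the soft-tissue
CT-number maximum (~2.2%) is thyroid, whose 0.1% of iodine ($Z = 53$)
shifts $\tilde Z$ enough to matter at kV energies while its SPR, protected
by the logarithm in the Bethe formula, stays on the line.

```{r beams}
linearity_comparison(load_tissue_table("icrp23_reference"))
```

The MV CT number is linear in RED to four decimals in every category,
while the kV fits fall visibly short — the quantitative core of the case
for MV-based electron-density imaging in proton therapy.

## Problem sizes and runtime

The full study conditions (32 reference tissues, 3200 simulated, both
quantities) run in a fraction of a second, and the acceptance script
repeats them from scratch at an arbitrary seed. Unit tests use smaller
replicate counts (3–25 per tissue) where the property under test does not
depend on the replicate count; the statistical-uncertainty checks use the
full 100 per tissue across ten seeds.

## Known limitations

* The SPR model is the uncorrected Bethe ratio; elemental $I$-value
  uncertainty is not propagated (a 10% $I$-value shift is known from the
  literature to move tissue SPR by a few tenths of a percent).
* Imaging is represented by single effective energies: no spectra, beam
  hardening, scatter, detector response or reconstruction. The comparison
  therefore understates the kV/MV contrast, which in reality is amplified
  by the low-energy spectral component of kV beams.
* The Gaussian perturbation model treats elements independently; real
  composition variation is correlated, so the statistical numbers are a
  model of independent 5% noise, not a patient-population measurement.
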