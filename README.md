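# redspr

Quantifying how tissue chemical composition limits the estimation of
kilovoltage CT numbers and proton stopping-power ratios (SPR) from
relative electron density (RED).

## The problem

Proton treatment planning maps CT numbers to proton SPR through a
calibration curve. Different chemical compositions can produce the same CT
number but different SPR (the degeneracy effect), and patient composition
is unknown, so the mapping carries a range uncertainty that is absorbed
clinically by margins of roughly 3.5% of the water-equivalent depth.

`redspr` decomposes the problem: instead of one CT-number-to-SPR curve it
builds two — RED to kVCT number and RED to proton SPR — and measures how
composition variation perturbs each. The result is an uncertainty budget
showing that almost all of the composition sensitivity sits on the
CT-number side, which is the quantitative case for deriving SPR from an
electron-density image (e.g. fan-beam megavoltage CT, which is
Compton-dominated and therefore almost perfectly linear in RED).

## Models

With elemental mass fractions ω_i, atomic numbers Z_i, atomic weights A_i
and N_g = N_A Σ ω_i Z_i / A_i electrons per gram:

- **RED** = ρ N_g / (ρ_w N_w)
- **Scaled kV CT number** (CT number + 1000):
  `HU_scale = RED · (A·Z̃^3.62 + B·Ẑ^1.86 + C)` where Z̃ and Ẑ are
  power means of Z over electron fractions (photoelectric and coherent
  effective atomic numbers) and A, B, C are scanner-dependent constants
  fitted from phantom scans (`fit_kv_parameters()`, defaults for a 120 kVp
  scanner via `default_kv_fit()`).
- **Proton SPR**: RED times the ratio of Bethe stopping numbers
  `[ln(2 m_e c² β² / (I_m (1−β²))) − β²]` for tissue over water, with mean
  excitation energies I from Bragg additivity over ICRU-37 elemental
  values.

Calibration curves are independent per-category (fat / non-fat soft /
bone) least-squares lines of each target against RED, fitted on 32
reference human tissues (ICRP publication 23 compositions, packaged).
Composition variability is emulated by Gaussian perturbation of every
nonzero elemental weight (σ = 5% of nominal, 100 samples per tissue,
renormalized to 100%), and estimation error is decomposed into systematic
(reference tissues), statistical (simulated tissues, parent deviation
subtracted) and total (root sum of squares) components.

## Worked example

```r
library(redspr)
report <- build_report(config = simulation_config(100, 0.05, seed = 1))
report
#> Uncertainty of estimating kVCT number and proton SPR from RED (%)
#> (32 reference tissues, 3200 simulated; rel_sigma = 0.05, seed = 1)
#>
#> category  sys.HU    sys.SPR   stat.HU   stat.SPR  total.HU  total.SPR maxsys.HU maxsys.SPR
#> fat       0.32      0.24      0.10      0.22      0.34      0.32      0.37      0.27
#> soft      0.62      0.13      0.06      0.19      0.62      0.23      2.24      0.45
#> bone      0.44      0.03      0.62      0.15      0.75      0.16      1.01      0.06
#> all       0.53      0.12      0.36      0.18      0.64      0.22      2.24      0.45
```

Read: estimating the kVCT number from RED is wrong by ~0.5% (1σ) across
the reference tissues and by up to 2.24% (thyroid, whose 0.1% iodine
perturbs the photoelectric effective atomic number), while estimating SPR
from RED is an order of magnitude tighter systematically (~0.1%); under 5%
composition noise the CT number degrades sharply in bone (Ca/P
sensitivity) whereas SPR stays below ~0.2% everywhere.

```r
linearity_comparison(load_tissue_table("icrp23_reference"))
#>   beam category     slope     intercept r_squared n_points
#> 1   kV      fat 1345.3773 -3.728416e+02 0.9704372        3
#> 2   kV     soft 1007.1884 -1.193877e+00 0.9967619       18
#> 3   kV     bone 2487.4658 -1.505138e+03 0.9986972       11
#> 4   MV      fat 1001.3410 -1.520422e+00 0.9999989        3
#> 5   MV     soft  999.9899 -5.147717e-04 1.0000000       18
#> 6   MV     bone 1003.8847 -4.036938e+00 1.0000000       11
```

MV CT numbers (0.8 MeV, Compton-dominated) are linear in RED to four
decimals in every tissue category; kV CT numbers (60 keV) are not.

`run_pipeline(run_config(), "out/")` executes everything and writes the
tissue tables, calibration curves (JSON), per-tissue deviations, the
uncertainty table (CSV/JSON), the beam comparison and a manifest from
which `run_from_manifest()` reproduces the run byte-for-byte.

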