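# exchline

Three-state chemical-exchange line-shape simulation and titration analysis
for protein–peptide binding by solution NMR.

## The problem

Designed Armadillo repeat proteins (dArmRPs) bind Lys–Arg repeat peptides
with affinities down to the femtomolar range. At such affinities the
dissociation rate is minuscule, so bound-state NMR signals should be as
sharp as the free-protein signals — yet titration spectra show strongly
broadened bound-state peaks. The broadening is explained by a second,
unimolecular exchange process in the bound state: transient breakage of
individual contacts without overall unbinding. `exchline` implements the
quantitative machinery to simulate and fit this model:

```
          k1_on           k2
  P + L  <====>   PL    <====>   PL*
          k1_off          k2'
```

Transverse magnetization of the free (M_P), bound (M_PL) and transiently
unbound (M_PL*) protein evolves under the Bloch–McConnell equations

```
dM_P/dt   = (-i 2π Ω_P  - R2 - k1_on [L]) M_P  + k1_off M_PL
dM_PL/dt  = (-i 2π Ω_PL - R2 - k1_off - k2) M_PL + k1_on [L] M_P + k2' M_PL*
dM_PL*/dt = (-i 2π Ω_P  - R2 - k2') M_PL* + k2 M_PL
```

with PL* resonating at the free-protein shift and a single R2 shared by all
states. Starting magnetization is proportional to the equilibrium
concentrations, obtained exactly from the mass-action quadratic

```
k1_on A² [PL]² − (k1_off + k1_on A ([P0]+[L0])) [PL] + k1_on [P0][L0] = 0,
A = 1 + k2/k2'
```

An ideal spin echo (11 ms by default) models the losses during the INEPT
periods; the FID is then propagated by matrix exponentiation, apodized,
zero-filled and Fourier-transformed into a 1D slice. Fitting replaces
visual inspection with a least-squares objective over titration series,
multi-start optimization in log-rate space, an optional Kd constraint
(k1_off = Kd·k1_on), and identifiability diagnostics that report near-flat
directions of the objective instead of spuriously precise values.

The package also computes amide chemical shift perturbations,
CSP = sqrt((δH_f−δH_b)² + ((δN_f−δN_b)/4)²), classifies them into the
standard five bins (very strong > 1 ppm … none < 0.11 ppm), and generates
synthetic titration fixtures with known ground truth.

## Worked example

```r
library(exchline)

pr <- titration_presets()$fast_intermediate   # Kd = 300 nM parameter set
scheme_kd(pr$scheme)
#> [1] 3e-07

acq <- acquisition_settings(4000, 1024, 2)
series <- simulate_titration(pr$scheme, pr$spin, pr$P0,
                             c(0, 0.4, 0.8, 1.0, 1.3), acq)
t(sapply(series$slices, function(s) {
  pk <- measure_peak(s, c(-100, 394)); c(pos = pk$position, fwhm = pk$fwhm)
}))
#>         pos  fwhm
#> [1,]   0.0  16.3
#> [2,]   3.2  75.9
#> [3,] 267.1  94.0
#> [4,] 282.5  28.2
#> [5,] 291.2  24.6
```

One peak walks from the free position (0 Hz) to the bound position
(294 Hz), passing through a severely broadened coalescence region between
0.4 and 1.0 equivalents — the fast/intermediate-exchange fingerprint of the
300 nM complex. Even at saturation the line stays broader than the pure
relaxation width R2/π ≈ 15.9 Hz because of the bound-state isomerization
(k2 = 30 s⁻¹, k2' = 700 s⁻¹).

Fitting a synthetic noisy series and asking whether the isomerization step
is required:

```r
truth <- ground_truth(pr$scheme, pr$spin, grid = c(0, 0.5, 1.0, 1.3),
                      acq = acquisition_settings(4000, 512, 2),
                      noise_sigma = 0.01, seed = 1)
obs <- generate_series(truth)$series
cfg <- fit_config(free = c("k2", "k2_prime", "R2"),
                  start = list(k1_on = 1e9, k1_off = 300, k2 = 10,
                               k2_prime = 300, omega_P = 0, omega_PL = 294,
                               R2 = 30, scale = 1),
                  kd_fixed = 3e-7, n_starts = 2, seed = 1, maxit = 800)
model_comparison(obs, truth$acq, cfg)
#> Model comparison: two-state vs three-state exchange
#>   two-state objective   = 1.24553
#>   three-state objective = 0.446383
#>   ratio (2st/3st)       = 2.79
```

The two-state restriction (k2 = 0) cannot reproduce the line widths; the
three-state fit recovers k2 ≈ 29 s⁻¹ and k2' ≈ 687 s⁻¹ from data generated
at 30 and 700 s⁻¹.

A thin command-line wrapper is installed at
`inst/scripts/exchline-cli` with `simulate | titrate | fit | compare |
csp | synth` subcommands over the same functions; see
`inst/extdata/example_run.cfg` for the config format.

## Acceptance script

`scripts/acceptance.R` re-runs the package's central computation from
scratch: it generates noisy titration series from both published parameter
presets at the seed you pass, performs the two-state/three-state model
comparison and the Kd-constrained rate recovery, logs the results, and
writes the JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
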