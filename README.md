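# saxsmix

Decomposition of oligomeric mixtures in small-angle X-ray scattering
(SAXS) titration series.

A protein in a monomer–dimer equilibrium — such as the plant
co-chaperone SGT1, whose TPR domains dimerize at low ionic strength —
never scatters as a single species: every measured curve is a
weighted sum of the monomer and dimer contributions. saxsmix separates
a series of curves measured across a salt titration into **pure
species scattering functions** and **per-condition volume fractions**,
and characterizes each recovered species.

The chain, with everything tabular flowing as tibbles:

* **I/O** — ATSAS-style 3-column `.dat` curves (`read_dat()`,
  `write_dat()`), CSV/JSON series manifests (`load_series()`), common
  grid interpolation (`common_grid()`).
* **Reduction** — frame averaging with a radiation-damage guard,
  buffer subtraction with error propagation, I(0)-based molecular
  weight calibration against a reference standard.
* **Guinier analysis** — `fit_guinier()` fits
  ln *I*(s) = ln *I*(0) − (R<sub>G</sub>²/3) s² with automated
  linear-range selection under s·R<sub>G</sub> ≤ 1.3 and a runs-test
  diagnostic for aggregation/repulsion curvature.
* **Indirect Fourier transform** — `pr_transform()` inverts
  *I*(s) = 4π ∫ p(r) sinc(sr) dr under smoothness, non-negativity and
  zero boundaries; `dmax_scan()` locates the maximum diameter
  D<sub>max</sub> from the chi-square plateau of a diameter scan.
* **Decomposition** (the core) — `svd_analysis()` counts species via
  singular values plus the lag-1 autocorrelation of right singular
  vectors; `efa()` (evolving factor analysis) locates each
  component's emergence window and seeds the concentration profiles;
  `mcr_als()` refines D = C S + E by alternating least squares under
  non-negativity of S and C and closure (each row of C sums to one),
  with both half-steps solved as exact constrained least squares so
  the lack of fit decreases monotonically.
* **Synthetic ground truth** — lattice bead models
  (`make_species()`), exact Debye curves (`debye_intensity()`,
  I(0) = M² exactly), salt-dependent logistic mixing and counting-like
  noise (`simulate_series()`, `make_fixture()`), so every stage is
  verifiable against known truth.

Results are light S3 objects with broom-style `tidy()`/`glance()`
methods and `ggplot2::autoplot()` plots.

## Worked example

Simulate the compact-domain titration fixture (six KCl conditions,
0–800 mM, 1% counting noise) and run the full pipeline:

```r
library(saxsmix)

fx  <- make_fixture("tpr_like", noise_level = 0.01, seed = 1)
res <- run_pipeline(fx$series, run_config(seed = 1))
res
#> <saxs_pipeline> 2 component(s)
#> <mcr_result> 2 component(s) x 6 condition(s); lack of fit 1.029%; 23 iteration(s) (converged)
#> # A tibble: 6 x 3
#>   salt_mM fraction_monomer fraction_dimer
#>     <dbl>            <dbl>          <dbl>
#> 1       0           0           1
#> 2     100           0.0331      0.967
#> 3     200           0.155       0.845
#> 4     400           0.838       0.162
#> 5     600           0.992       0.00794
#> 6     800           1.000       0.0000909
#>   monomer: Rg = 1.66 nm, Dmax = 3.82 nm
#>   dimer: Rg = 2.11 nm, Dmax = 4.97 nm
```

Reading the output: the SVD stage found two significant components
(monomer and dimer); MCR-ALS converged in 23 iterations to a 1.03%
lack of fit — consistent with the 1% simulated noise, meaning the
two-species model explains the series down to the noise floor. The
dimer fraction falls monotonically from 1.00 at 0 mM to ~0 at 800 mM,
the signature of ionic-strength-dependent dimerization. The extracted
pure curves give Guinier radii of 1.66 nm (monomer) and 2.11 nm
(dimer) against generator ground truth of 1.64 and 2.06 nm — recovery
within ~2% from noisy mixtures in which neither species was ever
measured alone.

`autoplot(res$mcr)` draws the fraction-vs-salt profile;
`run_pipeline(..., out_dir = "out")` writes pure-curve `.dat` files,
fraction and SVD tables, and a `summary.json` carrying the full
configuration and seed.

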