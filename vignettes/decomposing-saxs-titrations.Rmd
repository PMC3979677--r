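---
title: "Decomposing oligomeric SAXS titrations into pure species"
author: "saxsmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing oligomeric SAXS titrations into pure species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsmix)
```

## The problem

A protein in a monomer–dimer equilibrium never scatters as one species:
every solution small-angle X-ray scattering (SAXS) curve is a
concentration-weighted sum of the monomer and dimer contributions, and
direct shape analysis of such a mixture curve is misleading. When the
equilibrium responds to a solution variable — here the ionic strength,
as for the plant co-chaperone SGT1, whose TPR domains dimerize at low
salt — a *series* of curves measured across a salt titration contains
enough information to separate the species mathematically. saxsmix
implements that separation as a transparent, fully testable chain:

1. **Component counting** (`svd_analysis()`): the series, interpolated
   onto a common momentum-transfer grid and truncated at
   $s_{max} = 2\,\mathrm{nm^{-1}}$, is stacked into an $I \times J$
   matrix $A$ and decomposed as $A = U \Sigma V^T$. A component is
   deemed real when its right singular vector is smooth — lag-1
   autocorrelation above 0.6, where white noise scores near zero — and
   its singular value exceeds a noise floor of three times the median
   trailing singular value. Both thresholds are exposed as
   configuration.
2. **Evolving factor analysis** (`efa()`): singular values of growing
   leading and trailing row blocks locate where each component
   emerges and disappears along the ordered titration; the classic
   min(forward, reversed-backward) profile combination, renormalized
   to unit row sums, is the initial concentration estimate.
3. **MCR-ALS** (`mcr_als()`): alternating least squares on
   $D = C S + E$ under three constraints — pure curves $S \ge 0$,
   weights $C \ge 0$, and closure $\sum_k C_{ik} = 1$. Each half-step
   is an exact constrained solve: per-column non-negative least
   squares for $S$, and an exact closure-constrained non-negative
   solve per row for $C$ (support-set enumeration with a KKT system
   per support; exact because the component count is small). Row
   renormalization, the common shortcut for closure, is *not* a
   descent step and can cycle; the exact solve keeps the lack of fit
   $100\sqrt{\sum E^2 / \sum D^2}$ monotonically non-increasing,
   which the tests assert.
4. **Species labeling and shape analysis**: the two pure curves are
   identified as monomer and dimer by their Guinier radii
   (`volume_fractions()`), re-attached to the grid with uncertainties
   from the residual column variance (`extract_pure_curves()`), and
   fed to Guinier (`fit_guinier()`) and indirect-Fourier
   (`pr_transform()`, `dmax_scan()`) analysis.

`run_pipeline()` wires the chain end to end and writes a
self-describing report bundle (summary JSON with the full
configuration and seed, fraction and SVD tables, pure-curve files).

## Supporting scalar analyses

**Guinier.** $\ln I(s) = \ln I(0) - (R_G^2/3) s^2$ is fitted by
weighted least squares on a window selected automatically: candidate
starting points skip non-positive and beamstop-shadowed heads, the
upper end is found self-consistently under $s \cdot R_G \le 1.3$ (the
community convention for globular particles; configurable, and worth
lowering toward 1.0 for elongated particles), and candidate windows
then compete on the coefficient of determination. On noiseless data
this competition prefers tight windows where the Guinier law is most
nearly exact; under noise it prefers wide ones where signal dominates
variance. A runs test on the residuals (p < 0.01) flags the
systematic curvature characteristic of aggregation or repulsion.

**Indirect Fourier transform.** $p(r)$ solves
$I(s) = 4\pi \int_0^{D_{max}} p(r)\,\mathrm{sinc}(sr)\,dr$ by
sigma-weighted least squares with a second-derivative Tikhonov
penalty, zero boundary values, and non-negativity enforced inside the
solver (a Lawson–Hanson active-set solve on the augmented system) —
post-hoc clipping would distort the area normalization. The
regularization weight is chosen deterministically by an L-curve
corner search over a fixed grid, making every call reproducible.
`dmax_scan()` repeats the inversion over candidate diameters and takes
the smallest one whose back-transform $\chi^2$ is within 5% of the
plateau minimum with a decayed tail (at most 5% of the area in the
last 5% of $r$); the diameter is reported at scan resolution, never
interpolated, and a flat scan (as for pure noise) raises an
ambiguous-diameter warning rather than an arbitrary answer.

**Reduction utilities.** Frame averaging guards against radiation
damage by comparing each frame to the per-point *median* across frames
(a leave-one-out mean is itself corrupted by the outlier it is looking
for) and excluding frames deviating by more than $4\sigma$ over more
than 10% of points. Buffer subtraction propagates
$\sigma = \sqrt{\sigma_s^2 + \sigma_b^2}$ and flags the result so
negative intensities become admissible. Molecular weight comes from
$I(0)/c$ against a user-supplied standard (BSA and tetrameric
xylose/glucose isomerase being the classic choices); no standard is
hard-coded.

## The synthetic ground-truth generator

No public experimental dataset accompanies the study design this
package targets, so every claim is validated against simulation with
known truth. The generator builds coarse-grained bead models on a
0.4 nm lattice, computes exact Debye curves
$I(s) = \sum_{ij} \mathrm{sinc}(s r_{ij})$ (so $I(0) = M^2$ exactly;
models beyond 512 beads use a 0.025 nm pair-distance histogram whose
error, below about $5\times10^{-4}$ of $I(0)$, is tested against the
exact sum), mixes monomer and dimer with a logistic dimer fraction
$f_d = 1/(1 + e^{(\mathrm{salt} - m)/w})$, and adds counting-like
Gaussian noise $\sigma(s) = \eta\sqrt{I(s)\,I(s_0)}$ — about $\eta$
relative at low angle and relatively larger at high angle, the
signature of buffer-subtracted counting statistics. A small intensity
floor ($10^{-6}$ of forward scattering) keeps uncertainties positive
through form-factor minima.

Deliberate design choices, fixed once:

* **Mixing weights are scattering-mass fractions.** The dimer curve is
  divided by its mass ratio before mixing, so the truth matrix
  satisfies closure exactly and the decomposition's constraint is
  exactly satisfiable. Mapping to mole fractions would need molecular
  masses and is intentionally left out of the core.
* **The titration spans near-pure end members** (default midpoint
  300 mM, width 60 mM over salts 0–800 mM: dimer fraction 0.993 at
  0 mM, under 0.001 at 800 mM). This is an identifiability
  requirement, not a convenience: under non-negativity and closure
  alone, a bilinear factorization is determined only up to a stretch
  of the concentration profiles, and when no measured condition
  approaches a pure species *no* algorithm can pin the true fractions
  from the data alone. A validation suite that scores ground-truth
  recovery must therefore simulate a titration that essentially
  completes inside the sampled window.
* **The `tpr_like` dimer is a compact globule of exactly twice the
  monomer bead count**, not two tangent spheres: two tangent equal
  spheres force $R_G$ ratios above 1.6, while compact (intertwined)
  dimerization interfaces — as reported for TPR-domain dimers, with
  radii of gyration near 1.66 and 2.04 nm — sit near 1.25.
  `make_species("dimer_of", ...)` retains tangent-contact semantics
  for side-by-side associations and is used by the elongated
  `fullength_like` fixture.
* **Fixture designs** copy the row counts of realistic experiments:
  six KCl conditions {0, 100, 200, 400, 600, 800} mM at 2 mg/mL for
  the compact-domain scene, three NaCl conditions {0, 500, 1000} mM at
  3.46/3.41/2.71 mg/mL for the elongated full-length scene.

What the generator does *not* emulate — atomic form factors and
hydration shells (CRYSOL-class accuracy), interparticle structure
factors at high concentration, polydispersity beyond two or three
discrete species, and instrumental smearing — bounds what passing
tests can say about real data: the pipeline is validated as a
*decomposition and shape-analysis* machine under realistic counting
noise, not as a forward model of a beamline.

## Numerical choices and degenerate inputs

* ALS convergence: relative lack-of-fit change below $10^{-9}$ or 500
  iterations; components canonically ordered by descending forward
  scattering, removing permutation ambiguity in tests.
* A forced two-component fit of a genuinely single-species series is
  reported with a degenerate-component warning when one fraction never
  exceeds 0.02; with `n_components = "auto"` the pipeline stops after
  the SVD stage instead, since a one-component series has nothing to
  decompose. At realistic noise a forced spurious component can absorb
  a few percent of weight, so the flag is calibrated on the noiseless
  contract.
* The Guinier fit of an exactly flat curve reports $R_G = 0$ with a
  below-resolution marker rather than failing.
* Comparisons of bead-model Debye curves against the continuum sphere
  form factor are made at the model's effective radius
  $R_{eff} = \sqrt{5/3}\,R_G$ and away from the first form-factor zero
  ($sR = 4.493$), where a fraction of a percent of discretisation
  shift makes pointwise ratios unbounded.
* Problem sizes throughout the test and validation suites — 595-point
  curves truncated to 195 columns, 100-run component-count
  calibrations, 20-seed recovery studies, $2\times10^5$-pair
  Monte-Carlo oracles — were chosen as the smallest designs whose
  pass/fail decisions are stable across seeds.

## A worked run

```{r example, eval = FALSE}
library(saxsmix)

fx <- make_fixture("tpr_like", noise_level = 0.01, seed = 1)
res <- run_pipeline(fx$series, run_config(seed = 1))

res$fractions                      # per-salt monomer/dimer fractions
glance(res$mcr)                    # lack of fit, iterations, convergence
res$guinier$dimer                  # Guinier fit of the extracted dimer
autoplot(res$mcr)                  # fraction-vs-salt profile
```

## Known limitations

* Rotational-ambiguity bands (MCR-BANDS style) are not computed; the
  identifiability discussion above explains when the point estimate is
  trustworthy.
* The component count is reliable for well-separated species up to
  about five; closely similar species (e.g. an elongated monomer and
  its side-by-side dimer observed only below 2 nm⁻¹ in a three-row
  series) can fall below the singular-value noise floor.
* The indirect transform reports diameters at scan resolution; at high
  noise the chi-square plateau criterion tends to the small side of
  the true support.
* Guinier analysis systematically under-reads strongly elongated
  particles by 1–3% even noiselessly; the cross-sectional (rod)
  variants are out of scope.
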