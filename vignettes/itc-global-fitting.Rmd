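---
title: "Global Bayesian fitting of ITC binding experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global Bayesian fitting of ITC binding experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcfit)
```

## The model

An isothermal titration calorimetry (ITC) experiment injects a titrant
(here Cu²⁺ or Ca²⁺) stepwise into a cell containing a macromolecule (here
the EF-hand protein S100A5) and integrates the heat of each shot. itcfit
models the integrated heats; raw thermogram simulation and peak integration
are out of scope, as the pipeline is meant to start where peak-integration
software ends.

Binding is described by the stepwise macroscopic binding polynomial. With
association constants $K_1 = 1/K_{d,1}$ and $K_2 = 1/K_{d,2}$ and free
titrant concentration $L$,

$$P(L) = 1 + K_1 L + K_1 K_2 L^2,$$

the fractions of macromolecule with one and two ligands bound are
$F_1 = K_1 L / P$ and $F_2 = K_1 K_2 L^2 / P$, and the mean occupancy is
$\bar n = F_1 + 2 F_2$. The single-site model is the special case
$K_2 = 0$. These are *macroscopic stepwise* constants, not site-specific
ones: the two descriptions are related but not interchangeable, and only
the macroscopic constants are identifiable from a binding isotherm without
extra structural information. All reported constants are therefore stepwise
macroscopic, kept in the canonical order $K_{d,1} \le K_{d,2}$.

After shot $i$ the total concentrations in the active cell volume follow a
discrete displacement model (each shot pushes `dV/V0` of the current
contents out and replaces it with syringe solution):

$$M_i = M_0 \prod_{j \le i} (1 - dV_j/V_0), \qquad
  L_i = L_{i-1}(1 - dV_j/V_0) + C_{syr}\, dV_i / V_0.$$

The exponential approximation $\exp(-\sum dV/V_0)$ differs from this by
well under 0.1% at the default geometry; the discrete product was chosen
because it is exactly testable by hand arithmetic. The free ligand then
solves the mass balance $L_{tot} = L + M_{comp} \bar n(L)$, the cumulative
heat content is
$Q = V_0 [M_{comp}] (\Delta H_1 F_1 + (\Delta H_1 + \Delta H_2) F_2)$, and
the observable per-shot heat adds the displacement correction and a linear
dilution background:

$$q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2}
      + \Delta H_{dil}\, n_{inj,i} + q_{int}.$$

### The fraction-competent nuisance

Each experiment carries a multiplicative factor $f_{comp}$ on the nominal
cell concentration. It absorbs error in *both* concentrations — an
under-estimated protein stock and an over-estimated titrant stock are
observationally similar — so values above 1 are meaningful and the
admissible range is $[0, 2]$. The factor multiplies the macromolecule
rather than the titrant; the two choices are nearly equivalent for these
designs, and scaling the stationary component keeps the titrant axis (which
different experiments share through their syringe stocks) untouched.

## Estimation

The global fit shares the thermodynamic block (one or two $K_d$ and
$\Delta H$ values) across all experiments while each experiment keeps four
nuisance parameters: $f_{comp}$, the per-mole dilution heat
$\Delta H_{dil}$ (kcal/mol of injected titrant), the per-shot intercept
$q_{int}$ (kcal/shot) and its Gaussian noise scale $\sigma$ (kcal).
Whether nuisances should also be shared between technical replicates is a
judgement call; itcfit keeps them per-experiment, which is the conservative
choice (replicates may genuinely differ in dilution background and stock
concentrations).

Priors are independent uniforms. $K_d$ and $\sigma$ are sampled as
$\log_{10}$ values — the scale-invariant parameterisation for positive
scale parameters — with defaults $\log_{10} K_d/\mu M \in [-3, 4]$ and
$\log_{10} \sigma/\mathrm{kcal} \in [-12, -6]$; `prior_spec(kd_scale =
"linear")` switches to linear-Kd sampling for comparison with fitters that
sample $K_d$ directly. The default dilution bounds,
$\Delta H_{dil} \in [-3, 0]$ kcal/mol and $q_{int} \ge 0$, reproduce the
constrained background model appropriate for complex two-phase titrations;
both are ordinary bounds that can be widened. One published constraint for
the intercept is quoted in units of "kcal/mol/shot", which is dimensionally
inconsistent with a constant per-shot heat; itcfit deliberately exposes the
intercept in kcal/shot with a configurable prior rather than guessing at
the intended conversion.

The sampler is the affine-invariant stretch-move ensemble: walker $j$ draws
a partner $k$ from the complementary half-ensemble and proposes
$Y = X_k + z (X_j - X_k)$ with $z \sim g(z) \propto 1/\sqrt z$ on
$[1/a, a]$, $a = 2$, accepted with probability
$\min(1, z^{d-1} e^{\Delta \log p})$. Full-scale settings are 100 walkers ×
20,000 steps with the first 10% discarded as burn-in; the test-suite and
acceptance runs use 20–40 walkers × 2,000 steps, which is sufficient for
posterior medians because the chain starts at the maximum-likelihood
estimate. Walkers are initialised as jittered copies of that start
(relative Gaussian spread 1e-3, a conventional ensemble initialisation; the
spread only needs to be small against posterior scale and nonzero).

The maximum-likelihood start matters. Two numerical choices were needed:

* **Unit-box optimisation.** The free parameters span ~10 orders of
  magnitude ($q_{int}$ is ~1e-9 kcal, enthalpies are ~10 kcal/mol), so
  L-BFGS-B with a common finite-difference step is unusable on the raw
  scale. All parameters are affinely mapped to $[0,1]$ before
  optimisation.
* **Multi-start.** The likelihood has well-separated local optima in which
  the competent fraction trades against apparent site capacity (e.g. a
  two-site system mimicked by one tight site at doubled $f_{comp}$). The
  optimiser therefore runs from a small grid: candidate
  $f_{comp} \in \{0.65, 1, 1.4\}$ × a crude data-derived $K_d$ shifted by
  $\{0.1\times, 1\times, 10\times\}$, with enthalpy starts derived from the
  early-shot heats and the total heat budget consistently with each
  candidate $f_{comp}$. The best optimum wins.

Posterior summaries are equal-tailed quantiles (2.5/50/97.5% at the 0.95
level). For the two-site model the likelihood is invariant under
relabelling the two steps, so draws are canonically reordered
($K_{d,1} \le K_{d,2}$, enthalpies swapped alongside) per draw before
summarisation; the raw chain is stored unsorted so that sampler
diagnostics (e.g. prior-only uniformity) see the untransformed marginals.

### Numerical details

* Free-ligand mass balance: closed-form stable quadratic root for the
  single-site model; safeguarded Newton (bracketed on $[0, L_{tot}]$, with
  bisection fallback) for the two-site cubic. Relative residual tolerance
  1e-10, verified against an independent bisection oracle in the tests.
* Degenerate inputs: $L_{tot} = 0$ and $M = 0$ short-circuit exactly;
  non-positive $K_d$, negative concentrations and over-full injections are
  domain errors, not warnings.
* The per-shot forward model and Gaussian likelihood are implemented twice:
  a readable vectorised R path and an Rcpp path used inside the sampler.
  A test asserts agreement to 1e-10; the R path is the reference contract.
* Seeding: every stochastic entry point takes an integer seed and drives
  R's default RNG; fits are bit-reproducible for a fixed seed.

## The synthetic-data generator

No instrument data ship with the package; the generator produces studies
with the statistical structure the fitter assumes, using reference central
parameter values for Cu²⁺ and Ca²⁺ binding to the Cys-free S100A5 variant
as ground truth:

| preset | model | Kd (µM) | ΔH (kcal/mol) | f_comp |
|---|---|---|---|---|
| `cu_apo` | single-site | 1.81 | −3.4 | 1.43 |
| `cu_plus_ca` | single-site | 0.96 | −3.6 | 1.17 |
| `ca_apo` | two-site | 0.46, 6.33 | −1.4, −4.6 | 0.66 |
| `ca_plus_cu` | two-site | 0.18, 10.46 | −1.2, −4.1 | 0.58 |
| `wildtype_aggregated` | single-site | 1.81 | −3.4 | 0.20 |

Design structure: Cu²⁺ presets emit two technical replicates, each at its
own protein concentration drawn uniformly from 50–80 µM (the stated
experimental range; per-experiment values were not recorded, so a uniform
draw is the neutral choice). Ca²⁺ presets emit four experiments at one
fixed protein concentration with titrant/titrate ratios 8×, 10×, 15× and
18×. The default geometry is a classic large-cell instrument (1.4 mL active
volume, 25 shots × 10 µL); the geometry is fully configurable and does not
affect which parameters are recoverable. The syringe concentration of the
Cu²⁺ designs is not documented anywhere, so the package default (15× the
cell concentration) was chosen once so the titration reaches ≈2.4
equivalents of the competent protein — enough past saturation to pin the
baseline. True background values default to
$\Delta H_{dil} = -0.5$ kcal/mol and $q_{int} = 1$ µcal/shot, inside the
constrained prior box.

Noise is iid Gaussian per shot. The default scales (0.75 µcal for Cu²⁺
presets, 1.0 µcal for Ca²⁺, 5× the Cu²⁺ value for the aggregated-wildtype
pathology) were calibrated once so that the posterior credibility width of
the fraction competent roughly matches the reported one. A single iid noise
scale cannot reproduce all reported widths simultaneously: real integrated
heats carry correlated baseline/integration uncertainty that widens the
$K_d$ and $\Delta H$ posteriors much more than the $f_{comp}$ posterior.
The generator therefore under-disperses $K_d$/$\Delta H$ credibility
regions relative to real data, and passing recovery tests show that the
*pipeline* recovers its generating truth — not that real thermograms are
this clean. The generator also does not emulate metal–buffer speciation,
precipitation kinetics, shot-to-shot baseline drift, or integration-error
heteroscedasticity.

The `wildtype_aggregated` preset mimics a measurement degraded by
metal-driven aggregation — most of the protein incompetent to bind
(f_comp 0.2) and five-fold noise. Force-fitting it with the single-site
model recovers a low apparent competent fraction, reproducing the
diagnostic signature of an aggregating sample; no mechanistic aggregation
model is fitted, because the point of the pathology preset is that the
standard model flags it, not explains it.

## Model choice

Model selection (single-site vs two-site) is by curve shape, as is standard
for calorimetry: a two-phase isotherm — two sign changes in the second
difference of the per-shot heats, which the `ca_apo` reference parameters
produce at a 10× ratio — calls for the binding polynomial, a single
sigmoidal phase for the single-site model. No information criterion is
computed; with nuisance-laden global fits, AIC-style comparisons would be
misleadingly precise.

## Problem sizes

The shipped test-suite and acceptance script run desk-scale studies: 10
seeded repeats per condition, 2–4 experiments of 25 shots each per study,
20–40 walkers × 2,000 steps per fit. These sizes were chosen as the
smallest at which posterior medians stabilise well inside the reported
credibility spreads; the full-scale sampler settings remain the package
defaults for real analyses.

## Known limitations

* Microscopic/site-specific constants, cooperativity decomposition and
  ternary metal–metal–protein models are out of scope; independence of two
  metals is represented by fitting identical parameters across conditions,
  not by a coupled model.
* The heat-table reader targets the package's documented plain-text dialect
  (and close variants via the dialect object), not any vendor binary
  format.
* The CD module implements only the post-processing arithmetic (scan
  averaging, blank subtraction, mean-molar-ellipticity conversion,
  denaturation-corrected extinction coefficient); instrument-specific
  scattering corrections are not implemented.
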