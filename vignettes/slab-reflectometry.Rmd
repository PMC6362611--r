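---
title: "Slab-model reflectometry: models, priors and samplers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slab-model reflectometry: models, priors and samplers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabs)
```

## The measurement and the model

Specular neutron or X-ray reflectometry measures the fraction `R(Q)` of a
collimated beam reflected from a flat, layered interface at equal incident
and exit angles, as a function of the momentum transfer
`Q = (4π/λ) sin Ω` (Å⁻¹). `R(Q)` is determined by the depth profile of the
scattering length density (SLD) ρ(z) perpendicular to the interface, on
length scales of roughly 10–5000 Å. Because the measurement loses phase
information, a single curve rarely determines a structure uniquely; the
practical remedies are (i) measuring the same structure under several
solvent contrasts and co-refining them against one model, and (ii) treating
the analysis as Bayesian inference so that the uncertainty and the
multi-modality of the answer are visible rather than hidden.

`slabs` implements the full chain: a reflectivity kernel, a composable
structural model, a Gaussian-likelihood objective with priors and
algebraic parameter constraints, least-squares and ensemble-MCMC
refinement, and a synthetic-data generator so that every analysis in the
package can be exercised without instrument data.

### The kernel

The interface is discretised into a stack of uniform slabs between two
semi-infinite media. For each medium the normal wavevector is

    k_j = sqrt( (Q/2)^2 − 4π (ρ_j − ρ_fronting) ),

with the complex principal square root; absorption enters through an
imaginary SLD component. Each interfacial Fresnel coefficient
`r_{j,j+1} = (k_j − k_{j+1})/(k_j + k_{j+1})` is attenuated by the
Névot–Croce factor `exp(−2 k_j k_{j+1} σ²)` for Gaussian roughness σ, at
every interface including those to the semi-infinite media. The curve is
assembled by the 2×2 characteristic-matrix (Abeles) product, which costs
`O(n_Q × n_layers)` and is branch-robust for lossy layers. The choice of
the principal branch (non-negative real part) matters: it is what damps
`R` below the critical edge when the backing absorbs, and keeps Fresnel
ratios bounded when an absorbing medium is optically thinner than the
fronting. The test suite pins the kernel against an independently coded
Parratt recursive-ratio oracle written in the conjugate (decaying-phase)
convention, so the two routes share no code or convention.

### Instrument resolution

What an instrument records is `R` convolved with its Q-resolution
function. Three smearing modes are provided, all expressed as full widths
at half maximum (FWHM, the convention reduction software writes into
4-column files): a constant relative width dQ/Q, a per-point width taken
from the dataset, and an arbitrary discrete kernel. Gaussian smearing is
evaluated by a fixed 17-point Gauss–Legendre rule over ±3.5 standard
deviations around each point (σ = FWHM/2.35482), with weights
renormalised for the truncated mass. The rule is deterministic and, away
from the critical-edge kink, matches adaptive quadrature to better than
1e-6 relative (the acceptance script recomputes this); directly at the
edge the integrand's kink limits any fixed rule, which is why oracle
comparisons are made above the edge.

## Structures, components and chemically meaningful parameters

A `structure_model()` is an ordered series of components — fronting medium
first, backing medium last. Components contribute slab rows:

* `slab()` — one row of uniform SLD with thickness, roughness to the
  previous component and a solvent volume fraction φ; the effective SLD is
  `(1−φ)ρ + φρ_solv`. The solvating medium defaults to the backing medium
  (the natural choice at the solid–liquid interface) and can be overridden
  per structure, because at air–liquid interfaces the backing is not the
  solvent.
* `lipid_leaflet()` — two rows (head and tail regions) parameterised by
  the area per molecule `A` (Å²), region thicknesses `t_x` (Å), summed
  scattering lengths `b_x` (Å) and partial volumes `V_x` (Å³). The lipid
  fills the fraction `V_x/(A t_x)` of its region, the rest is solvent, so
  the region SLD is `b_x/(A t_x) + (1 − V_x/(A t_x)) ρ_x,solv`. One `A`
  enters both regions, which enforces a 1:1 correspondence of heads to
  tails; packing fractions outside [0, 1] contribute −∞ to the log-prior
  rather than being clipped, so unphysical geometry is vetoed, not hidden.
  `reverse = TRUE` flips the row order for the outer leaflet of a
  supported bilayer. The assumptions are those of the parameterisation:
  one common `A` for heads and tails (violated when guest molecules
  insert), and laterally homogeneous leaflets (patchy coverage is instead
  modelled by `mixed_reflect_model()`, an incoherent area-weighted sum).
* `sld_spline()` — free-form smooth regions, discretised from a monotone
  (shape-preserving) cubic interpolant into `m` equal slices sampled at
  midpoints. Monotone interpolation is chosen over a natural cubic spline
  to avoid unphysical SLD overshoot between knots. The slice count
  defaults to one per 0.5 Å, capped at 500; the discretisation error is
  first order in `1/m` and grows with Q (deep interference minima amplify
  relative error), so free-form regions are best used with Q below about
  0.1–0.15 Å⁻¹ or with an explicit convergence check, which the test suite
  demonstrates.

`reflect_model()` wraps a structure with a `scale` (imperfect data
normalisation), a Q-independent `background` and a resolution
specification; `sld_profile()` renders the real-space ρ(z) with
error-function transitions consistent with the Névot–Croce treatment.

## Parameters, priors and linking

Every model value is a `parameter()`: a named scalar with a `vary` flag
and a prior. Parameters have reference semantics — the same object can sit
in several components or several models, and that object identity (never
the name) is what links parameters for co-refinement. Priors double as
bounds: an interval prior is the log-density 0 inside / −∞ outside (kept
unnormalised, so evidence values are relative), and `prior_normal()`
expresses an experimentally known value with uncertainty. Algebraic
constraints are built with ordinary arithmetic on parameter objects
(`set_constraint(t3, total - t1 - t2)`); a constrained parameter stops
varying and re-evaluates lazily on read, and cycles are rejected at
assignment. Constraint graphs are small, so values are recomputed on every
read rather than memoised — simpler, and never stale.

## Objective, likelihood and samplers

An `objective()` compares a model with one dataset; `global_objective()`
sums members for co-refinement, counting shared parameters once in the
flattened vector and once in the prior. With measurement uncertainties
taken as Gaussian, the log-likelihood is

    −½ Σ_n [ (y_n − y_model,n)²/σ_n² + ln(2π σ_n²) ],

evaluated — like χ² and the residuals — in the chosen fitting space
(`none`, `log10 R`, or `R·Q⁴`, with first-order uncertainty propagation).
The log-posterior is log-prior + log-likelihood, with component terms
(such as leaflet packing) added; a −∞ prior short-circuits the likelihood
evaluation.

Point estimation uses bounded differential evolution (global), L-BFGS-B
(local, run on the unit box `[0,1]^d` after mapping each parameter through
its prior bounds, because thicknesses and backgrounds differ by eight
orders of magnitude), or Levenberg–Marquardt on the residual vector
(unbounded; bounds are warned about and ignored). Prior-vetoed points
return a large finite value rather than Inf so that line searches remain
informative. Reported standard errors come from the curvature at the
optimum, probed in the same scaled coordinates.

Posterior exploration uses the affine-invariant stretch move: each walker
is updated towards a partner from the complementary half-ensemble with
scale `z ~ g(z) ∝ 1/√z` on `[1/a, a]` (default `a = 2`), accepted with
probability `z^{d−1} π(prop)/π(cur)`. The two-half update preserves
detailed balance, and the move is invariant under affine
reparameterisation — no proposal covariance to tune, which is why this
family of samplers is standard for curve-fitting posteriors. Defaults:
`n_walkers = max(2 d, 100)` (published analyses of this kind often use
200), walkers initialised from prior draws with a 1e-4 multiplicative
jitter fallback, or from an explicit `init` matrix (the usual practice of
starting near the least-squares optimum, and how a stored chain is
resumed). Parallel tempering runs one ensemble per inverse temperature β
on `prior + β·likelihood` with a geometric ladder (ratio 1/√2) and
adjacent swap moves; the per-temperature mean log-likelihoods give a
trapezoidal thermodynamic-integration estimate of the log-evidence. The
ladder is truncated at its smallest β, so evidences carry a bias that
shrinks as temperatures are added; with the unnormalised interval priors
they are in any case relative quantities, useful for model comparison, not
absolute.

Chains are summarised by the median and half of the 15.87–84.13 percentile
range per parameter (equal to the standard deviation for a normal
marginal; percentiles use linear interpolation between order statistics),
after burn-in removal and thinning; parameters are updated to the medians,
and a subset of posterior draws is exported for curve- and SLD-spread
plots.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` evaluates a model on a 120-point log-spaced grid over
0.008–0.3 Å⁻¹ with 5% constant dQ/Q — grid, range and resolution typical
of a time-of-flight neutron reflectometer — attaches uncertainties
`dR = max(0.025 R, floor)` (or Poisson-count uncertainties given a flux
function) and perturbs with Gaussian noise of exactly the reported σ.
`make_bilayer_suite()` builds the canonical solid–liquid system — silicon,
a thin oxide, inner and outer lipid leaflets sharing one area-per-molecule
parameter, solvent — for three solvent contrasts (D₂O 6.36, silicon
contrast-match 2.07, H₂O −0.56, all 1e-6 Å⁻²), with the suite's lipid
constants shipped in `dmpc_constants()` as fixture values for a
phosphatidylcholine-type lipid.

The generator's noise is exactly Gaussian with known σ, uncorrelated
between points, and its model is the same family used to fit. Real data
adds what the generator omits: mis-estimated error bars, point-to-point
correlations from reduction, imperfect footprint and normalisation
corrections, non-Gaussian resolution tails, and — most importantly — model
error (the sample is never exactly the model). Passing recovery tests on
the suite therefore demonstrates the correctness and calibration of the
inference machinery, not that any particular real system is described by
two leaflets and an oxide.

## Numerical choices

* Q = 0 returns the total-reflection limit (1 for contrasting media, 0
  otherwise) instead of dividing 0/0.
* Smearing: 17-point Gauss–Legendre over ±3.5σ; FWHM/σ = 2√(2 ln 2).
* Zero-thickness slabs are legal and contribute only their roughness
  pairing.
* Interval priors are unnormalised (log-density 0 inside); normal priors
  are proper.
* Differential evolution: rand/1/bin, F = 0.7, CR = 0.9, population
  `max(20, 10 d)`, reflection at the bounds, seeded for reproducibility.
* Percentiles: linear interpolation between order statistics
  (`stats::quantile` type 7).
* The co-refinement analyses run reduced sampling (16 walkers, 400 steps,
  burn 150, thin 2) after an L-BFGS-B stage; the acceptance script states
  the problem sizes it uses alongside each reported number.

## Known limitations

* The Névot–Croce factor is an approximation to a graded interface. Its
  agreement with an exact erf-profile calculation degrades as Qσ grows: at
  σ = 8 Å it tracks micro-slicing to ~3e-4 over Q ≤ 0.3 Å⁻¹, but at
  σ = 15 Å (Qσ = 4.5) the deviation reaches ~3e-2 where R itself is below
  1e-14. Very rough interfaces probed to high Q should be modelled with
  explicit micro-slicing (e.g. `sld_spline()`).
* No polarised/magnetic reflectivity, no off-specular scattering, no
  energy-dispersive (Ω, λ) mode.
* The evidence estimate is ladder-truncated (above) and inherits the
  arbitrary constant of interval priors.
* Spline regions are first-order accurate in the slice count; check
  convergence when they carry high-Q structure.
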