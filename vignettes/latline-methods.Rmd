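---
title: "Methods: from tracked shoals and pore outlines to mixed models and an artificial canal sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tracked shoals and pore outlines to mixed models and an artificial canal sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`latline` implements a complete analysis pipeline linking cranial
lateral-line morphology to collective behaviour in shoaling cichlids, plus
a desk-scale hydrodynamic model of an artificial lateral-line canal
sensor. This vignette is the package's own account of the methods: the
models, their assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## 1. Study structure and conventions

The emulated experiment observes 116 focal fish — 10 of a wide-canal
parental species (`parentA`), 10 of a narrow-canal parental species
(`parentB`) and 96 of their second-generation hybrids — each filmed for
one trial in laminar and one in turbulent flow with four companion fish,
giving 232 trial rows. Treatment order is counterbalanced within species.

Conventions used throughout:

* lengths are **millimetres** internally (pore areas are mm-scale,
  the arena cm-scale; one unit avoids boundary conversions);
* the arena origin is the most upstream, furthest-left point; **+x points
  downstream**, +y cross-stream;
* lost detections are explicit `NA` coordinates and propagate as
  frame-level exclusions — no interpolation is attempted.

## 2. Collective-behaviour metrics (`summarize_trial()`)

Per frame, for the focal individual:

* **nearest neighbour**: minimum Euclidean distance to any detected
  companion;
* **group radius**: distance from the group centroid (mean of all
  detected positions, focal included) to the individual farthest from it;
* **hull circumference**: perimeter of the convex hull (a collinear
  configuration degenerates to twice the path length; a single point to 0);
* **upstream nearest neighbour**: nearest neighbour with strictly smaller
  x (hydrodynamic cues cannot travel upstream, so only these neighbours
  are detectable by the lateral line);
* **field-of-flow nearest neighbour**: as above, additionally within an
  inclusive ±50 mm cross-stream band.

"Strictly less than" for upstream and "within" (inclusive) for the band
follow the literal definitions; the boundary has measure zero for real
tracking data. Frames with a missing focal fish or fewer than two
detections are excluded from all metrics; frames with no qualifying
neighbour are excluded from the directional metrics only. Trial values are
unweighted means over the frames where each metric is defined, with
per-metric `frames_used` counts reported.

## 3. Pore morphometrics

A digitized pore outline (TPS outline dialect, `read_tps()`) is a closed
curve starting at a homologous anchor (the pore's anterior limit).
`resample_semilandmarks()` places 10 points at equal arc length along the
piecewise-linear interpolant of the drawn curve — outline digitizers do
not document their internal resampling, and the piecewise-linear
interpolant is the assumption-free choice. The 10th point closes the loop
and duplicates the first; `pore_area()` discounts it and takes the
shoelace area of the remaining 9-vertex polygon. Inscribed polygons
underestimate the enclosed area — for a near-circular pore the ratio is
$\tfrac{9}{2\pi}\sin(2\pi/9) \approx 0.9207$ — but the bias is consistent
across specimens, which is what comparative analysis needs.

Canal-level predictors average pores within a canal: dentary (mandibular
pores 2–5), preopercular (ventral pores 1–4 pooled with lateral pores 5–7,
reported as a single variable), otic (2 pores), infraorbital (the digitized
pore count varies between datasets, so it is configurable rather than
enforced). Missing pores shrink the denominator and set a flag.

`gpa_pca()` performs generalized Procrustes alignment (translation to the
centroid, unit centroid size, iterative SVD rotation to the mean shape
until the mean changes by less than `1e-8`), followed by PCA on the
covariance of the aligned coordinates (the standard behaviour of
geometric-morphometrics software). Two numerical choices matter: rotations
are constrained to be proper (no reflections), and after convergence all
configurations are rotated to the principal axes of the mean shape with a
deterministic 180° tie-break, so the output does not depend on input
order. Digitization error is assessed with a fixed-effects two-way ANOVA
(`area ~ event + individual`, no interaction): with 2 events and n
individuals the event effect has (1, n−1) df and the individual effect
(n−1, n−1). A term whose sum of squares is numerically zero is reported as
F = 0 rather than the 0/0 of a perfectly fitting model.

## 4. The negative-binomial random-intercept model (`nb_glmm()`)

Each behaviour response (integer mm — responses are rounded so the NB
mass function is proper) is modelled as

$$y_{ij} \sim \mathrm{NB2}(\mu_{ij}, \theta), \qquad
  \log \mu_{ij} = x_{ij}^\top \beta + b_i, \qquad
  b_i \sim N(0, \sigma_b^2),$$

with variance $\mu + \mu^2/\theta$, a log link, and one random intercept
per focal fish (each fish contributes two trials). Fixed effects always
include species, body length, treatment and trial order; a candidate model
adds one focal morphology variable, optionally with a
morphology × treatment interaction. The null model keeps all covariates
(including body length) and drops only the focal variable.

**Likelihood.** The marginal likelihood integrates the random intercept
out per fish. `nb_glmm_loglik()` uses *adaptive* Gauss–Hermite quadrature
with 20 nodes: per fish, the conditional mode of $b$ is found by damped
Newton iteration (analytic first and second derivatives), and the rule is
recentred and rescaled by the curvature at the mode. With 2 observations
per group and a smooth integrand this is accurate to well below 1e-6 —
the test suite checks it against a 10⁴-point trapezoid rule. At
$\sigma_b = 0$ the likelihood degenerates to independent NB terms and is
evaluated directly.

**Fitting.** BFGS over $(\beta, \log\theta, \log\sigma_b)$ from a
deterministic start — a Poisson GLM for $\beta$, a moment estimate for
$\theta$, $\sigma_b = 0.2$ — so refits are bit-reproducible. Numeric
covariates are standardised internally (coefficients and their
delta-method standard errors are reported on the original scale); support
decisions are invariant to predictor rescaling. Standard errors come from
the inverse numerical Hessian. Non-convergence is flagged, not fatal; the
support table marks such cells unavailable and continues.

**Model selection.** Model support uses the small-sample Akaike
criterion, $AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with
$k = \#\beta + 2$ (dispersion and random-intercept SD count as
parameters). A candidate is *strongly supported* when its AICc undercuts
the null's by at least 2 units, boundary inclusive. `build_support_table()`
codes each response × predictor × dataset cell `+`/`−` (sign of the focal
slope) when supported, `U` otherwise, and appends `*` when the interaction
model both undercuts the null by ≥ 2 and improves on the main-effects
model's AICc — the interaction must be the distinguishing feature, not a
free rider. No multiple-testing adjustment is applied beyond the
ΔAICc ≥ 2 rule itself. A Gamma alternative to the rounded-NB response was
considered and rejected: the NB family keeps the count-likelihood
machinery exact, and rounding distances measured in mm discards
negligible information at the observed scales (~100 mm means).

## 5. Synthetic data: what it emulates, what it does not

The generators provide ground truth for every downstream stage.

* `generate_design()` reproduces the study structure (116 fish, two
  counterbalanced treatments each) with per-species body lengths drawn
  from the reported means and SDs (110.5 ± 10.3, 117.1 ± 13.4,
  117.3 ± 17.7 mm).
* `generate_morphology()` draws the six neuromast counts (negative
  binomial) and four mean pore areas (lognormal) around species
  centroids: wide-canal parents centre on large pores / fewer superficial
  neuromasts, narrow-canal parents on the opposite, hybrids on the
  midpoint with variance inflated 2× the mid-parent value so they span
  both parents. Both scale positively with body length (allometric
  exponents 0.5 for counts, 2 for areas — areas grow like length²).
  Centroid values are free parameters of the generator chosen at
  plausible cichlid scales (pore areas 0.3–2 mm², counts 15–120); the
  study reports no effect sizes or centroids, so none of these are
  treated as literature values.
* `generate_behaviour_summaries()` is the generative mirror of the model
  in §4, with an `effect_spec` holding every coefficient; defaults
  (intercept log 120 mm, θ = 8, σ_b = 0.25) give distance distributions
  at realistic shoaling scales.
* `generate_trajectories()` is an agent-based stand-in, *not* a
  hydrodynamic model: attraction to the group centroid beyond a preferred
  distance, repulsion inside it, exactly cancelling downstream drift and
  upstream station-holding, Gaussian jitter, arena clipping. A regular
  polygon at the preferred distance is a noise-free equilibrium, and mean
  nearest-neighbour distance is monotone in the preferred spacing — the
  two properties the behaviour-metric tests need.

Passing tests on these data show the pipeline recovers known effects
under NB noise and a correctly specified model; they cannot show
robustness to tracking artefacts, identity swaps, non-log-linear
morphology–behaviour relationships, or companion-fish individuality,
none of which the generators emulate.

## 6. The cylinder wake and canal sensor

The hydrodynamic study asks whether a macro-scale canal sensor
(25 × 25 × 50 mm, two pores on one face) filters steady background flow
while passing the oscillating signal of vortices shed by an upstream
cylinder (D = 100 mm, U∞ = 0.5 m s⁻¹, sensor station 200 mm downstream
and 40 mm off the cylinder axis).

**Wake solver.** A D2Q9 lattice-Boltzmann BGK scheme (Rcpp): equilibrium
inflow, zero-gradient outflow, free-slip lateral walls, full-way
bounce-back cylinder, and a small deterministic initial cross-stream
perturbation to trigger the shedding instability. The solver runs at a
reduced Reynolds number (default 150 — periodic laminar shedding, no
turbulence model needed) and rescales to physical units via U∞ and D; this
is a deliberate fidelity limit, stated rather than hidden. Defaults: 20
cells per diameter, a 22D × 10D domain with the cylinder 5D from the
inlet, lattice speed 0.1 (Mach well below stability limits,
τ ≈ 0.54), and 75 nominal shedding periods of which the first 20% are
discarded as transient (a full 400 s record adds nothing
once the shedding limit cycle is reached; `n_periods` scales
it back up). The solver is deterministic: identical configurations give
bit-identical fields. Contracts checked by tests: Strouhal number
fD/U∞ in the laminar-shedding range 0.15–0.22, normalised divergence
below the weak-compressibility tolerance, variance peak downstream and
off-centreline, free stream exactly uniform without the cylinder.

**Canal sensor.** A quasi-steady lumped-parameter model:

$$u(t) = \frac{\Delta p(t)}{A_c\,(R_{ch} + 2 R_{pore}(d))},
  \qquad R_{pore} = \frac{128\,\mu L_p}{\pi d^4},$$

with Δp the pressure difference between the two pore stations (25 mm
apart along the flow axis, wall thickness 5 mm), A_c the channel
cross-section (15 × 15 mm), μ water viscosity. The canal interior is not
resolved; R_ch is an *effective* channel resistance lumping the channel
and the haircell obstruction. Its default, 2 × 10⁶ Pa s m⁻³, is set from
the free-stream dynamic-pressure scale — a background head of
~0.15 ρU∞²/2 across the pores must drive internal flow of at most a few
per cent of U∞ — and not from any simulation output. The model is linear
in Δp, strictly monotone in pore diameter (resistance falls as d⁴), and
chokes as d → 0. The open-pore condition removes the pore-bearing face
entirely, so its response is the external streamwise velocity at the
haircell. The filtering statement "internal mean close to zero" is
operationalized as ≤ 10% of the open-pore mean, where the reference is
the external mean flow *speed* (≈ 0.4 m s⁻¹ at the sensor station)
rather than the signed mean of one velocity component. Haircell mechanics (stiffness, deflection) are
represented by the internal velocity signal only.

A physical caveat: when the sensor body itself is resolved in the flow and locally reverses it, it locally reverses the flow
and open-pore velocities turn negative; our stand-in samples the
undisturbed wake, so the open-pore mean is positive. Signs of the internal velocity follow the pressure
gradient and are reported as computed.

## 7. Problem sizes and runtime

Defaults are sized for a single CPU: the full-resolution wake
(440 × 200 cells, ~83k steps) runs in a few minutes; model-fit
Monte-Carlo suites use 100 replicates for slope recovery and 50 for
null-model calibration at the full 116-fish design (the test suite scales
recovery to 25 replicates); the quadrature check compares 100 random
parameter points on a 20-fish fixture against a 10⁴-point trapezoid
oracle. `scripts/acceptance.R` reruns all of these from scratch.

## 8. Known limitations

* The wake is 2-D and laminar (Re 150, not the physical ~5 × 10⁴); only
  trend-level and probe-mean fidelity is claimed.
* The canal model is quasi-steady and lumped; inertial (Womersley-type)
  effects in the canal are ignored, defensible at shedding frequencies
  ~1 Hz but untested beyond.
* Semilandmarks are fixed after resampling (no bending-energy sliding),
  matching workflows that convert resampled semilandmarks to landmarks
  before analysis.
* The agent-based trajectories carry no hydrodynamic interaction, so
  treatment (laminar/turbulent) has no mechanistic effect in synthetic
  trials; treatment effects enter only through `effect_spec`.
* With two observations per fish, σ_b and θ separate weakly; simulations
  show point estimates of σ_b shrink at this design size even though
  slopes and their SEs remain well calibrated.
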