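---
title: "Ratcheting of intervertebral discs under cyclic compression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratcheting of intervertebral discs under cyclic compression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discratchet)
```

## The phenomenon and the quantities

A disc specimen under a stress-controlled triangular compression wave
(valley fixed at 0 MPa, peak 0.59–1.76 MPa, rates 0.13–1.18 MPa/s) traces a
hysteresis loop per cycle. Because the loading is asymmetric and the tissue
is viscoelastic and fluid-filled, the loop does not close: its centre drifts
to higher strain every cycle. The per-cycle quantities this package
extracts are

* **ratcheting strain** `eps_r(N) = (eps_min + eps_max) / 2`, the loop
  centre of cycle `N` (1-based, so "the 400th cycle" is `N = 400`);
* **ratcheting strain rate** `d(eps_r)/dN`, computed by central finite
  differences in `N` (one-sided at both ends) — the definition gives only a
  derivative, and central differences are the symmetric discretisation;
* **strain range** `eps_max - eps_min`, which shrinks (loops densify) as
  the tissue stiffens;
* **compression stiffness**, the secant of the loading branch in machine
  units, `(F_peak - F_valley) / (d_peak - d_valley)` with `F = sigma * S`
  and `d = eps * h`. No formula for stiffness is standard in this
  literature; the peak-to-valley secant is the convention machine logs use
  and is insensitive to the loop's interior shape. It is evaluated at a
  caller-chosen cycle, default 400.

Valley and peak strains are read at the samples where the *commanded*
stress is at its valley and peak, not at the within-cycle strain extrema.
This makes the metrics robust to the hysteresis shape and exactly invariant
to resampling (the sampling grid always contains those samples, see below).
Compression is positive for stress and strain everywhere, including all CSV
output.

## The constitutive model

The ratcheting evolution is modelled by a saturating one-parameter law with
a material coefficient `K`:

$$X_r(N) = K \cdot X_{SR} \cdot \left(1 - \alpha^{-N^{\beta}}\right),
\qquad X_{SR} = k_r (e_r - e_{rth}),$$

with `e_r` the ratcheting stress (peak stress), `X_SR` the saturated
ratcheting strain, and evolution parameters linear in stress:
`alpha = a0 + a1 e_r`, `beta = b0 + b1 e_r`. The package defaults carry the
fitted relations for sheep lumbar discs, `alpha = 53.565 + 10.571 e_r` and
`beta = 0.13 - 0.035 e_r`, with `K = 0.01`.

**Functional form.** The printed form of the law is ambiguous once the
exponent nesting is lost in typesetting; the package's default parse is
`1 - alpha^(-N^beta)`. Among the candidate parses this is the only one that
is bounded in (0, 1), strictly increasing in `N`, and saturating for the
fitted parameter magnitudes (`alpha` of order 50–70, i.e. > 1, and `beta`
in (0, 1)); readings that require `alpha < 1` or produce negative strain
are incompatible with the fitted linear relations. A registry
(`urmk_forms()`) keeps an alternative saturating parse
(`1 - alpha^(-beta N)`, id `"exp_saturating"`) selectable for comparison,
but every default path uses `"power_saturating"`. An empirical
discriminator between forms is the early-accumulation fraction: under the
default parse at `e_r = 1.76` MPa, more than 40 % of the post-first-cycle
accumulation over 200 cycles has already happened by cycle 5, matching the
observed sharp-rise-then-plateau shape; the test suite checks this
analytically.

**Sub-threshold behaviour.** `X_SR` is clamped at 0 for `e_r < e_rth`; the
model is silent below threshold and a negative saturated strain has no
physical reading here.

**Unreported constants.** `k_r` and `e_rth` are deduced from data in the
original workflow but never printed; the package adopts `k_r = 1`
strain/MPa and `e_rth = 0` as defaults for both synthesis and fitting, and
both are explicit arguments everywhere they enter. With these defaults
`X_SR = e_r` numerically, so fitted amplitudes read directly as
`K * e_r`.

**Rate independence.** Stress rate appears nowhere in the law, although the
data are rate-dependent; fits are therefore kept separate per rate, and the
material-coefficient regression pools only conditions the caller passes it.

## Fitting

`fit_ratcheting_curve()` minimises unweighted least squares of
`A * f(N; alpha, beta) (+ c0)` against `eps_r(N)`. Two numerical choices
matter:

* **Variable projection.** For fixed `(alpha, beta)` the model is linear in
  the amplitude `A` (and offset `c0`), so those are profiled out by
  ordinary least squares inside the residual function and
  Levenberg–Marquardt (`minpack.lm::nls.lm`) searches over `(alpha, beta)`
  only. The transient is shallow — `f(1) = 1 - 1/alpha` is already ~0.98
  at the fitted `alpha` — which makes `A` and `c0` nearly collinear with a
  naive 4-parameter search; projection removes that failure mode.
* **Multi-start.** `beta` starts on the grid {0.02, 0.05, 0.1, 0.2, 0.5}
  (crossed with a small set of `alpha` starts, one derived from the first
  data point), bounds `alpha` in (1, 1e4], `beta` in (0, 1); the best-RSS
  converged solution wins. Ties are broken by first occurrence, which is
  deterministic because the grid order is fixed.

A near-constant curve (sd below 1e-12 of its level) is returned with a
`degenerate` flag instead of a spurious fit; fewer than 10 cycles is an
error. The offset term (`fit_offset = TRUE`, the pipeline default) is
needed for curves extracted from full stress–strain records, which carry
the elastic mean strain `dsigma / (2E)` on top of the drift; curves
generated directly from the model (the calibration path) are fitted without
it.

`fit_material_coefficient()` regresses per-condition amplitudes on
`X_SR(e_r)` through the origin, `K = sum(A_i X_i) / sum(X_i^2)` — the model
asserts proportionality, so the intercept-free slope is the estimator.
`fit_parameter_relations()` is plain OLS per parameter.
`predict_ratcheting()` evaluates the law with the relation values at the
new stress; it refuses stresses where `beta(e_r) <= 0` (the linear relation
extrapolated past its validity, at `e_r >= b0/|b1| ~ 3.71` MPa with the
default coefficients) and, by default, stresses more than 0.3 MPa outside
the training range (half the smallest gap between tested stress levels; set
`extrapolation = Inf` to disable the band).

**Identifiability under noise.** Because the transient is shallow, the
usable signal in a ratcheting curve over `N >= 1` is the last ~1.5 % of the
plateau. Per-curve `alpha`/`beta` estimates from noisy single curves
therefore scatter widely, and the Pearson correlation between a fitted
curve and noisy data is bounded by the signal-to-noise ratio of that small
variation, not by fit quality. This is a property of the model shape, not
of the optimiser; it is why the material coefficient is estimated jointly
across stress levels and why replicate averaging precedes the relation
fits in the pipeline.

## The synthetic generator

No raw test records are publicly deposited, so the package ships a
generator that produces records with the structure the analysis assumes;
every downstream stage is exercised against it. The strain response is

```
strain(t) = stress(t) / E  +  drift(N(t))  +  hysteresis(t)  +  noise
```

* **Commanded stress** is an exact triangular wave; the sampling interval
  is snapped so each ramp holds an integer number of samples (>= 20,
  default 40), so valley/peak samples are exact and the stress channel
  reproduces the command bit-for-bit.
* **Elasticity.** A secant modulus
  `E = E_ref (rate/0.59)^0.15 (dsigma/0.59)^0.3` with `E_ref = 8` MPa at
  the reference condition. The reference rate 0.59 MPa/s is the central
  tested rate. The two power laws are the minimal mechanism reproducing
  the observed stiffening with both stress rate (fluid trapped in the
  porous matrix at fast loading) and stress variation (fluid driven from
  nucleus to annulus, enlarging the load-bearing area); exponents were
  chosen once so that stiffness spans a plausible few-hundred-to-
  ~1200 N/mm range over the test matrix with `S = 394` mm², `h = 3.98` mm,
  and peak strains stay below ~0.2. With sub-linear stress stiffening
  (exponent < 1) the elastic mean strain still grows with `dsigma`, so the
  ratcheting-vs-stress-variation direction is preserved.
* **Drift.** The ratcheting drift is the constitutive law itself evaluated
  at `e_r = ` peak stress, scaled by a segment factor (default 1;
  0.8 for the more ratcheting-resistant lowest segment in cohort
  generation) and attenuated with rate as `(rate/0.59)^-0.3`, emulating
  the smaller accumulation at faster loading. Within a cycle the drift is
  flat at `drift(N)` across the loading branch and ramps linearly to
  `drift(N+1)` across unloading — incomplete recovery is where the
  residual strain accrues. This placement makes the per-cycle ratcheting
  strain of the output *exactly* `drift(N) + dsigma/(2E)` and leaves every
  loop unclosed by exactly the per-cycle drift increment, which the tests
  verify to 1e-6.
* **Hysteresis.** A half-sine per branch with amplitude
  `hysteresis_width` (default 0.005 strain), positive on loading: the
  simplest loop-opening shape whose extrema sit at the valley/peak samples
  and thus leave the per-cycle metrics untouched.
* **Noise and jitter.** Measurement noise is i.i.d. Gaussian on strain
  only (stress is commanded), default sd 1e-4 — displacement-transducer
  scale for a ~4 mm specimen. Replicate-level biology enters as log-normal
  multiplicative jitter on the modulus (sdlog 0.15) and the drift
  amplitude `K` (sdlog 0.2); log-normal keeps both positive, and the
  magnitudes are a choice — inter-specimen variance is not quantified in
  the source data — set once at roughly the 15–20 % coefficient of
  variation typical of soft-tissue moduli. Per-series seeds derive
  deterministically from the cohort seed and the condition/replicate
  indices, so cohorts are reproducible to the byte after serialisation.

**What the generator does not emulate.** There is no poroelastic fluid
mechanism, no tertiary (failure) ratcheting stage, no temperature, creep
holds or load-history effects, no within-cycle strain-range contraction
(the generated strain range is constant per series, the weak form of loop
densification), and no correlated (drift-like) measurement noise. Tests
passing on synthetic cohorts therefore demonstrate that the pipeline
recovers what was injected under realistic magnitudes and noise — not that
the constitutive law is the true tissue model; that case is made by the
original experiments.

## Statistical layer

`endpoint_table()` reads ratcheting strain and stiffness at an endpoint
cycle (default 400; configurable, since shorter tests end at 200) for every
replicate. `effect_direction_report()` computes Pearson correlations of
each endpoint against stress variation (at the modal rate) and against
stress rate (at the modal stress variation), and a one-way ANOVA between
segment labels. Two-sided tests throughout, no multiple-testing correction
(none is applied in the source workflow); segment and condition are treated
as separate one-way analyses. On default synthetic cohorts all five
directional findings hold: ratcheting strain increases with stress
variation and decreases with stress rate, stiffness increases with both,
and the lowest segment ratchets less. Correlation magnitudes on synthetic
data are data-dependent and are not calibrated to match any reported
values — only signs and significance directions are meaningful.

## Problem sizes and costs

Default analyses use 400-cycle records at 40 samples per ramp
(~32,000 samples per series), the cohort sizes of the standard ten-row
condition matrix with three replicates, and 20-seed noise studies; a full
simulate–fit–predict pass at these sizes runs in seconds. The fitter's
per-curve cost is a few hundred two-parameter LM iterations over at most
15 starts.

## Known limitations

* Per-curve `alpha`/`beta` from noisy single curves are weakly identified
  (see above); report them only as replicate/condition aggregates.
* The linear `beta(e_r)` relation caps usable prediction stress at
  ~3.7 MPa with the default coefficients; the package refuses rather than
  extrapolates.
* Engineering stress/strain only; no finite-deformation measures, and no
  force–displacement ingestion without a geometry sidecar.
* The generator's rate effects are power laws with fixed exponents, not a
  poroelastic model; do not use it to study rate dependence itself, only
  to exercise analyses that must be robust to it.
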