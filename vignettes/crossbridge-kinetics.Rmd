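---
title: "Crossbridge kinetics of permeabilized cardiac fibers: model, fitting and synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossbridge kinetics of permeabilized cardiac fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberkin)
```

## The scientific problem

Permeabilized (skinned) cardiac fiber experiments probe the actomyosin
crossbridge cycle directly: force is measured while the bathing solution
sets free Ca²⁺ (as pCa = −log₁₀[Ca²⁺]), phosphate (Pi) and ADP. Three
classes of measurement recur:

* **steady-state force–pCa curves**, summarized by a Hill fit (maximal
  force Fmax, half-activating Ca²⁺ EC50, Hill coefficient nH);
* **the rate constant of force redevelopment** after a rapid length
  release (k_F), whose dependence on added Pi reports on the Pi-bound
  transitions of the cycle;
* **activation transients** after flash photolysis of caged Ca²⁺ (rate
  k_Act) or caged ATP from Ca²⁺-rigor (k_ATP), fitted with single
  exponentials.

`fiberkin` implements a forward kinetic model for these protocols, the
corresponding fitting operations, group statistics in the field's
reporting style (mean ± SEM, Student's t-tests with Bonferroni
adjustment), densitometry ratio computations for phosphoprotein analyses,
and a seeded synthetic-cohort generator so the whole pipeline can be
validated by parameter recovery.

## The forward model

The cycle is collapsed to three pools plus, for the caged-ATP protocol, a
transient rigor pool:

* `N` — non-cycling crossbridges (detached; thin filament not yet
  permissive);
* `D` — the attached, non-force-bearing A-M.ADP.Pi state;
* `F` — the force-bearing pool AM\*.ADP.Pi + AM\*.ADP.

Transitions:

* An **activation gate** `N → D` opens at a Ca²⁺-dependent rate
  `g(Ca) = g_act_max · Ca^h / (Ca50^h + Ca^h)`. This represents the
  transition of non-cycling crossbridges into activated, cycling states.
  The Hill form is phenomenological: whether activation is cooperative
  through near-neighbour regulatory units is an open mechanistic
  question, and the package does not assert a mechanism — only a gate
  that is closed at pCa 8–9 and fast and saturated at pCa 4.5.
* The **Pi isomerization** `D ⇌ F` with forward rate `k1` and reverse
  rate `k_minus1 · φ(Pi)`, where `φ(Pi) = [Pi]/(K2 + [Pi])` is the
  Pi-bound fraction of the force pool. This follows from treating **Pi
  release as a rapid equilibrium** with constant `K2` (the model carries
  no separate forward/backward Pi-release rates): within the force pool,
  `[AM*.ADP.Pi]/[AM*.ADP] = [Pi]/K2`, and only the Pi-bound fraction can
  re-isomerize backwards. This choice reproduces exactly the saturating
  form of the observed rate (below), which is the empirical relation the
  fits use.
* A slow **recycling rate** `g_off` returns `D` and `F` to `N`
  (detachment out of the cycling population).

With the gate fast and `g_off` slow, the observed relaxation rate of the
cycling subsystem is, in closed form,

k_obs = k1 + k_minus1 · [Pi] / (K2 + [Pi])

(`relaxation_rate()`), equal to `k1` at zero added Pi, strictly
increasing in Pi and saturating below `k1 + k_minus1`. The model-internal
oracle for this reduction is `eigen_rate()`: the magnitude of the slowest
nonzero eigenvalue of the full generator matrix. The residual discrepancy
is approximately `g_off`, so the default `g_off = 0.5 s⁻¹` keeps the
closed form and the eigenvalue within 5 % relative error for all three
experimental groups over Pi ∈ [0, 30] mM (worst case: the ischemic group
at 0 mM Pi, where `k1 = 18.9 s⁻¹` gives ≈ 2.6 %).

### Parameters, units, defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `k1` | forward Pi-isomerization rate | s⁻¹ | group value (26.6 / 18.9 / 20.4) |
| `k_minus1` | reverse Pi-isomerization rate | s⁻¹ | group value (42.3 / 30.7 / 37.4) |
| `K2` | Pi-release equilibrium constant | mM | group value (39.4 / 24.5 / 29.4) |
| `g_act_max` | maximal gate opening rate | s⁻¹ | 500 |
| `ca50_act` | Ca²⁺ of half-maximal gate opening | µM | 3 |
| `h_act` | gate Hill exponent | — | 2 |
| `g_off` | recycling / gate-closing rate | s⁻¹ | 0.5 |
| `f_scale` | force per unit force-pool occupancy | mN/mm² | calibrated per group |

Conventions: pCa = −log₁₀ of molar free Ca²⁺; Ca²⁺ in µM, Pi and ADP in
mM; forces in mN/mm² (normalized to cross-sectional area assuming an
elliptical section, `fiber_csa()`); sampling default 1000 Hz.

`group_scheme_params()` calibrates `f_scale` so that the steady-state
force at pCa 4.5 / 0 Pi equals the group's measured Fmax.

**Why `g_act_max = 500 s⁻¹`.** The gate must not be rate-limiting at
saturating Ca²⁺, and simulated activation transients must be
mono-exponential enough that a single-exponential fit recovers the slow
eigenvalue. At `g_act_max = 100 s⁻¹` (only ~4× the observed rates) the
gate contributes a sigmoidal lag that biases full-record
single-exponential fits by ~14 %; at 500 s⁻¹ the bias is ~1.4 %. Since
no gate kinetics are measured by these protocols, the default encodes
the assumption "gate fast, not rate-limiting" quantitatively.

### Protocols and initial conditions

* `CA_JUMP` (caged Ca²⁺) and `LENGTH_RELEASE`: all crossbridges start in
  `N`. A rapid release produces substantially complete crossbridge
  detachment and regulatory units must re-activate, which is why k_F and
  k_Act are similar and both reflect the activation-limited pathway. The
  5 %-in-3-ms release itself is not modelled mechanically; k_F traces
  begin at the post-release force minimum.
* `ATP_JUMP` (caged ATP from Ca²⁺-rigor): the record starts at the rigor
  force, modelled as force-pool occupancy scaled so rigor force is
  `rigor_frac` (default 1/3) of the steady active force — matching the
  measured ≈ 18.4 vs 55.6 mN/mm² rigor vs total force in perfused
  fibers. On photolysis, a fraction `detach_frac = 0.3` of rigor bridges
  binds ATP and detaches rapidly (`k_detach = 300 s⁻¹`) into `D` before
  re-entering the cycle; the competition between this fast detachment
  and slower force development produces the observed small, brief dip in
  force a few milliseconds after the flash. The dip rates are not
  measured by the protocols modelled here; both values are package
  defaults chosen to make the dip "small and brief" (a few percent of
  steady force, ~3 ms).

Integration uses `deSolve::lsoda` (stiff-safe) with absolute tolerance
1e−9 on occupancies; occupancy conservation is checked at every output
step (tolerance 1e−6).

## Fitting

* `fit_single_exponential()` fits `F(t) = f_inf − (f_inf − f0)·e^{−rate(t−t₀)}`
  by self-starting asymptotic regression (`SSasymp`, rate on a log
  scale; `scaleOffset` keeps convergence well-defined on noiseless
  traces), with a Levenberg–Marquardt fallback. Noiseless traces are
  recovered to ~1e−6 relative. `detect_fit_window()` returns the full
  record, except for `ATP_JUMP` traces where the window starts at the
  force minimum within the first 10 % of the record (the post-flash
  dip); a trace whose global minimum is its final sample has no recovery
  phase and is an error. The trough rule is this package's convention —
  the window used after the dip is not otherwise specified by the
  protocols.
* `fit_hill()` fits the Hill equation by Levenberg–Marquardt with
  starts (Fmax from the data maximum, EC50 from the half-max crossing,
  nH = 2) and requires ≥ 4 points spanning a decade of Ca²⁺. The Hill
  coefficient is fitted freely; its start value 2 reflects typical
  cardiac cooperativity.
* `fit_pi_dependence()` fits the saturating relation above with bounds
  (0, 500] on all three parameters and starts k1 ← kF(0),
  k−1 ← kF(Pi_max) − kF(0), K2 ← median tested Pi. **Identifiability:**
  a fitted K2 beyond 5× the largest tested Pi means no saturation is
  detectable within the tested range (the curve is indistinguishable
  from a line); such fits are flagged `identified = FALSE`.
* `fit_stiffness()` is ordinary least squares through the
  (Δlength, Δforce) points of the standard 0.05–0.2 % release
  quadruplet; the slope is the stiffness.

### Per-fiber versus group-curve fitting

`fit_hill_cohort()` and `fit_pi_cohort()` support both modes. For Hill
fits, per-fiber fitting followed by group averaging is the default and
is well-behaved: each fiber contributes ten points spanning the
transition, and EC50 is tightly identified. For the Pi dependence the
situation differs sharply: each fiber contributes only five Pi levels,
and with realistic point noise the per-fiber K2 estimate is essentially
unidentified — its sampling distribution has a heavy right tail and
per-fiber means can overshoot the truth severalfold. Group K2 values
with few-mM standard errors can only arise from fitting the group-mean
curve, so `recovery_experiment()` fits Scheme-1 constants on the group
curve. Even then the K2 estimator is right-skewed (mean biased high,
median centred on the truth), which is why `summarize_recovery()`
reports both and the median is the recommended consensus for K2 across
replicate experiments.

## Group statistics and densitometry

`group_summary()` reports mean ± SEM; `compare_groups()` performs a
two-sided Student's t-test (pooled variance by default, matching the
classical naming; Welch via `welch = TRUE` — the underlying variance
assumption of the published analyses is not stated, so both are
provided), declaring significance at `base_alpha / m_comparisons` — with
three surgery groups and three pairwise tests this reproduces the
familiar P < 0.0167 criterion. `phosphoform_percentages()` converts
band/spot intensities (e.g. mono- and diphosphorylated TnT, P1/P2) to
percentages of total; `relative_phosphorylation()` computes
phospho/total ratios per sample and rescales them so the reference-group
mean is 100 % (the reporting convention for TnI Ser23/24 and MYBP-C
phosphorylation against perfused controls); the result is invariant to
global intensity rescaling.

## Synthetic cohorts and what they do (not) show

`cohort_config()` bundles a group's generating truth: Scheme-1 constants,
Hill truth (Fmax, EC50, nH = 2), the activation rate constant k_Act, the
measurement grids, noise magnitudes and a seed. Defaults are the
published group values; the pCa grid default
{8.0, 6.5, 6.2, 6.0, 5.8, 5.6, 5.4, 5.0, 4.5, 4.0} spans the full
activation range with denser coverage around the transition, since only
the range pCa 8.0–4.0 is specified by the protocols.

Noise defaults are calibrations, not measured facts: the published
tables print SEMs of derived parameters, not raw noise. Defaults — 2 s⁻¹
additive SD per k_F point, 3 % multiplicative force noise, 2 % trace
noise, log-normal densitometry SD 0.15, and per-fiber activation-rate
CV set from printed SEM·√n/k_Act (≈ 0.18 for perfused) — were chosen
once so that synthetic group SEMs approximate the printed SEMs.

Caged-Ca²⁺ cohorts are generated from parameters calibrated per fiber
(`calibrate_activation()` root-finds k1 so the slow eigenvalue equals
the fiber's drawn activation rate), which is what "calibrated to the
measured activation rate" means operationally here.

The generator emulates the *statistical structure* the fitters assume:
Hill-law force surfaces, the saturating k_F relation, mono-exponential
transients with the ATP-jump dip, linear release quadruplets, log-normal
signals. It deliberately does not emulate instrument artifacts
(transducer ringing, bath-change transients), fiber rundown, bi-exponential
or strain-dependent kinetics, or ADP-state kinetics (ADP conditions enter
only as separate Hill-fit datasets). Passing recovery tests therefore
show that the pipeline is unbiased and correctly propagates uncertainty
*under the model's own assumptions* — not that real fibers obey the
model.

`recovery_experiment()` runs replicate cohorts (distinct derived seeds),
fits each, and records truth vs estimate per replicate; failures and
non-identified K2 fits are recorded, never fatal. Problem sizes used in
the shipped tests and acceptance script — 7–10 fibers per cohort, 11
transients, 20 replicate cohorts — mirror the published group sizes and
give the recovery consensus a sampling error comfortably inside the
printed parameter SEs.

## Numerical choices and degenerate inputs

* Steady states solve the 3×3 linear system with the conservation
  constraint replacing one balance equation; an all-zero rate matrix is
  a model error.
* `eigen_rate()` drops the zero (conservation) eigenvalue by a relative
  1e−9 threshold.
* Fit errors are typed and early: flat traces (degenerate exponential),
  non-spanning force–pCa data, fewer than 3 distinct Pi levels, single
  release amplitudes, all-zero densitometry signals, zero reference
  forces.
* All generators draw under a locally-set seed and restore the global
  RNG state, so library calls never perturb a user's random stream;
  identical configs produce identical tables.

## Known limitations

* The activation gate is phenomenological; its Ca50 and cooperativity
  are not constrained by the modelled experiments.
* k_ATP in the model is governed by the same slow eigenvalue as k_Act
  once the gate is fast, so the model does not reproduce the observed
  k_ATP ≫ k_Act separation — distinguishing cycling-limited from
  activation-limited rates quantitatively would need an explicit
  thin-filament/crossbridge coupling, which is out of scope. The
  caged-ATP protocol is included for its trace morphology (rigor start,
  dip, recovery) and fitting behaviour.
* No strain dependence, no ADP-bound state kinetics, no free-energy
  bookkeeping; standard errors come from the fit curvature (no
  bootstrap).
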