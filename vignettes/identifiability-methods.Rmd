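---
title: "Methods: a multiscale heart model and its practical identifiability"
author: "cvident"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multiscale heart model and its practical identifiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cvident` asks a design-of-experiments question: *which combinations of
ventricular pressure and volume measurements make the parameters of a
multiscale cardiovascular model practically identifiable?* Because the
question is answered entirely in silico, the package contains both the
simulator and the full identifiability tool chain around it. This
vignette documents the model, the statistical machinery, the numerical
choices, and the limits of what the shipped analyses demonstrate.

## The model

The circulation is closed and zero-dimensional. Nine compartments are
arranged in a loop: left atrium (LA), left ventricle (LV), systemic
arteries (SA) and veins (SV), right atrium (RA), right ventricle (RV),
pulmonary arteries (PA) and veins (PV), with the interventricular
septum (S) as a ninth mechanical element shared by the two ventricles.
Blood volumes obey `dV/dt = q_in - q_out`; vascular compartments are
linear compliances `p = (V - V_un)/C`; connections are linear
resistances `q = (p_in - p_out)/R`. The four heart valves and the
vena-cava resistor are ideal diodes: they carry the resistive flow when
the upstream pressure exceeds the downstream pressure and nothing
otherwise.

Cardiac chamber pressures come from wall mechanics rather than
prescribed elastances. Each of the five walls (LA, LV free wall, RA,
RV free wall, S) carries a half-sarcomere model with two states: the
contractile element length `L_sc` (um) and a dimensionless
contractility `Gamma`. Total fiber stress is the sum of an active
crossbridge term and two passive terms,

```
G_tot = G_act(L_s, L_sc, Gamma) + G_ECM(L_s) + G_titin(L_s) ,
```

where `L_s` is sarcomere length. TriSeg-family models admit several
variants of the constituent laws; `cvident` implements one concrete
member of the family, each law behind a single function so variants
can be swapped:

* active stress `G_act = sigma_act * Gamma * (L_sc - L_sc0)+ *
  (L_s - L_sc)/L_s_iso`; the last factor encodes the force-velocity
  relation through the series-element stretch,
* series element `dL_sc/dt = ((L_s - L_sc)/L_s_iso - 1) * v_0`,
* extracellular matrix `G_ECM = sigma_pas * (r^beta_pas - r^-6)` with
  `r = L_s / L_s_pas_ref`; the `r^-6` branch is a compressive barrier
  that resists full chamber collapse,
* titin `G_titin = 0.01 * sigma_act * (r^k1 - 1)`, tied to the active
  machinery's density,
* activation `dGamma/dt` is a length-gated rise minus a post-systolic
  decay toward the resting level: the rise window follows
  `0.02 x^3 (8-x)^2 e^-x` with `x = t/tau_rise`, the decay switches on
  around `tau_sys` over a width `tau_decay`. Atrial walls run on a
  clock shifted by `tau_offset_A` so atrial systole precedes
  ventricular activation.

The atria are single spherical walls. The two ventricles and the
septum form the three-segment ("TriSeg") geometry: three spherical
caps meeting at a common circular junction. Cap midwall area,
curvature and fiber strain follow

```
eps_f = 1/2 ln(A_m / A_m_ref) - z^2/12 - 0.019 z^4 ,
z     = 3 C_m V_wall / (2 A_m) ,
T_m   = (V_wall G_tot / 2 A_m) (1 + z^2/3 + z^4/5) ,
```

and the two unknowns of the instantaneous geometry — septal cap volume
`V_mS` and junction radius `y_m` — are fixed by requiring the axial and
radial components of the three midwall tensions to balance at the
junction. Those two algebraic constraints, with 10 sarcomere states
and 8 volume states, make the model an 18-state differential-algebraic
system with 49 parameters (13 atrial + 13 ventricular sarcomere
parameters + the atrial delay, 5 wall volumes, 5 reference areas, 8
resistances, 4 compliances). The cardiac period is a configuration
constant (0.11 s, a resting mouse) rather than one of the 49.

### Numerical treatment of the constraint

The tension balance is solved inside the right-hand side by a damped
quasi-Newton iteration (finite-difference Jacobian, Broyden-updated
and reused across calls) warm-started from the previous evaluation, to
a residual below 1e-8 of the prevailing tension scale, capped at 50
iterations. When the warm start fails — cold starts, or parameter sets
far from nominal — a bracketing lattice of Newton restarts over the
feasible `(V_mS, y_m)` rectangle is tried in a center-outward order,
with a derivative-free compass search as last resort. The constraint
admits more than one root in parts of state space; continuity of the
warm start selects the physical branch, which is why all integrators in
the package track the pair across calls instead of re-solving cold.

A configuration in which a cavity volume reaches zero, or in which the
tension balance has no root, is treated as *infeasible* and raises a
classed error. This is a genuine model property, not a numerical
nuisance: sufficiently distorted parameter combinations (large wall
volumes with small reference areas, for example) cannot fill the
ventricles, and every downstream analysis has an explicit policy for
such failures (see the crash guard below).

### Integration

Two integrators are provided. The default is an adaptive embedded
Cash-Karp Runge-Kutta scheme implemented in compiled code with
per-state error weights; the whole multi-cycle integration runs
without leaving C++, which is what makes screening, profiling and MCMC
(tens of thousands of model runs) practical. The cross-check path
drives the same compiled right-hand side through `deSolve::lsoda`, a
variable-step, variable-order solver that switches to a stiff method
when needed. The two agree to better than 0.1% on matched tolerances
(this is a unit test); the system's fastest time constants (valve
resistance against chamber stiffness, about a millisecond) are mild
enough that the explicit scheme is not stability-limited in practice.
`simulate_model()` defaults to 60 cycles at tolerance 1e-12 —
deliberately conservative; the pipeline passes 1e-4 to 1e-8 depending
on the purpose, as described below.

### Nominal parameters

The package ships its own nominal parameter file
(`inst/extdata/nominal_mouse.yaml`), tuned once so that the simulated
normotensive mouse lies in the physiologic ranges reported for sham
animals: LV pressure ~105/5 mmHg, RV ~25/1 mmHg, mean pulmonary artery
pressure ~16 mmHg, stroke volume ~27 ul at a 0.11 s period, LV
end-diastolic volume ~63 ul, mean systemic arterial pressure ~90 mmHg.
All analyses treat this file as the data-generating truth, so the
study is self-consistent by construction. The tuning knobs and their
rationale:

* wall volumes and reference areas set from coherent spherical-cap
  geometry at the resting volumes (the septal reference area is much
  smaller than the free walls'; inconsistent choices make the resting
  tension balance rootless),
* `gamma_rest` very small (0.003): residual active tone at rest
  otherwise dominates diastolic pressure,
* a compliant ventricular passive law (`beta_pas = 4`,
  `Ls_pas_ref = 1.9 um`) against a stiffer atrial one (`beta_pas = 8`),
  which keeps the atria small, low-pressure reservoirs instead of
  volume sinks.

## Synthetic experimental designs

Four measurement protocols are emulated, all derived from one
simulation of the truth: `f1` dynamic RV pressure; `f2` RV pressure
and volume; `f3` adds four LV scalars (systolic/diastolic pressure,
end-systolic/end-diastolic volume — an echocardiography-style
assessment); `f4` dynamic pressure and volume in both ventricles.
Series channels are the 100-point uniform grid over the final cycle;
pressures are observed in mmHg, volumes in ul (1 kPa = 7.50062 mmHg
applied only at this boundary). Noise is additive, white and
Gaussian with variance 1 mmHg^2 on pressures and 1 ul^2 on volumes —
also for the `f3` scalars, since a single noise model is stated for
all sources. Noise is applied to the single final cycle.

The *observation simulator* — 5 warm-started cycles at tolerance
2e-4 from the cached steady state of the truth — is recorded in every
dataset and reused verbatim by the likelihood, so solver transients
cancel identically at the generating parameters and the noise-free
residual at truth is exactly zero. Forecast figures and reference
simulations use longer, tighter runs.

## Sensitivity screening and subset selection

The workflow reduces 49 parameters in stages. Eleven microscale
quantities (sarcomere reference lengths, resting contractility, the
passive reference length, the atrial delay) are fixed a priori,
leaving 38.

**Morris screening.** Elementary effects on an `l = 60`-level grid
with step `delta = l/(2(l-1)) ~ 0.51`, `K` randomized trajectories
(100 at paper scale, 20 at desk scale), outputs the squared 2-norms of
the four ventricular signals. Parameters whose combined index
`M = sqrt(mu*^2 + s^2)` falls below the across-parameter mean for
*all four* outputs are fixed. Two knobs deviate from the obvious
defaults and deserve justification. First, the screening bounds are
[0.75, 1.25] x nominal rather than +/-50%: under the wider hypercube
roughly a third of parameter combinations are infeasible (the
chamber-collapse mechanism above), which would starve the screening of
valid trajectories; +/-25% keeps failures near 2% while still
exercising strongly nonlinear responses. Second, a model failure
invalidates only the elementary effects whose endpoints touch it, not
the entire trajectory; the screening aborts if more than 20% of
effects are lost. At the shipped nominal values the rule retains about
17 of 38 parameters, stably across seeds.

**Local stage.** Centered finite differences of each design's full
observation vector at +/-1% of nominal, log-scaled (multiplied by the
parameter value) so that magnitudes are comparable, assembled into the
Fisher information matrix `F = S'S` per design. These derivatives are
computed with a deliberately tight simulator (30 warm cycles at 1e-8):
at looser tolerances the finite-difference noise acts as a full-rank
regularizer that floors the small singular values and *hides* the
ill-conditioning the stage is supposed to detect. While any design has
`cond(F) > 1e8`, the parameter with the largest component in the
smallest singular direction of the worst design is removed (ties break
toward the later parameter in canonical order). With this model's
functional forms the four condition numbers land near the 1e8
threshold and the reduction removes about one parameter (typically the
LV wall volume), leaving ~16. That count sits on a knife edge: it is
sensitive to the constitutive forms and to the sensitivity scaling
(raw, unscaled sensitivities give `cond(F) ~ 1e12` and cut the subset
to 7), so the package reports the value its own model produces rather
than engineering a preferred one.

For the inference stages the package uses the canonical 13-parameter
subset (`cv_reference_subset()`): three ventricular wall volumes,
three reference areas, the four ventricular activation/active-stress
parameters, and the three dominant hemodynamic parameters. It is a
superset-consistent selection (all 13 survive Morris screening here)
and keeps the profile and posterior analyses comparable across
designs and with the published workflow.

## Profile likelihood

For each parameter `theta_i`, `PL(theta_i)` is the minimized negative
Gaussian log-likelihood with `theta_i` fixed on a uniform grid over
+/-50% of truth and all other subset parameters free. Profiles use
noise-free data; the noise variances keep their nominal values so the
chi-squared threshold retains its scale. The optimizer is
derivative-free (Nelder-Mead in truth-relative units) because crash
penalties make the surface non-smooth; each grid point is warm-started
from its neighbour's optimum walking outward from the truth, with a
truth restart and a jittered restart. Failed points record the crash
penalty and the curve continues.

The 95% interval is `{theta_i : 2 PL <= 2 PL_min + qchisq(0.95, 1)}`
with crossings located by linear interpolation in `2 PL`; a two-sided
crossing within the grid is *identifiable*, one-sided *practically
non-identifiable*, neither *structurally non-identifiable*. Note the
classification is conservative with a finite optimizer budget: an
under-minimized profile can only rise, i.e. flatness (non-
identifiability) is the hard thing to produce spuriously. At desk
scale (11-point grids), `f4` classifies all 13 parameters as
identifiable while `f1` leaves the LV wall volume with an essentially
flat profile — the study's central contrast.

## Bayesian inference

The posterior is the same Gaussian likelihood (noise variances fixed
at their generating values, not estimated) times independent uniform
priors of +/-50% around truth. Sampling is delayed-rejection
adaptive-Metropolis: a Gaussian random walk whose covariance adapts
every 500 iterations (`2.38^2/d` scaling, 1e-10 ridge), with one
delayed-rejection stage at 1/5 proposal width. Chains start from
multi-start optimization: random prior draws refined by Nelder-Mead
on the weighted residual sum of squares, each optimum paired with a
Gauss-Newton `(J'J)^-1` proposal covariance (eigenvalue-clipped to
positive definite). Simulation crashes inside optimization or
sampling return a residual sum of squares of 1e10 — orders of
magnitude above any feasible misfit — so the chain continues with the
proposal effectively rejected; every failure is logged with its
parameter vector.

Convergence is monitored with the Gelman-Rubin potential scale
reduction factor per parameter and its Brooks-Gelman multivariate
extension against the conventional 1.1 cutoff, plus median acceptance
rates. At desk scale (3 chains x 1,500 iterations, 400 burn-in) the
diagnostics are reported but not expected to pass 1.1 — even the
full-scale configuration (12 x 50,000) does not guarantee it on this
posterior; the desk chains are
sized for stable credible-interval coverage of the truth, which they
deliver (the truth lies inside the 95% intervals for at least 12 of
the 13 parameters on `f4` data).

## Posterior-predictive forecasting

Equal numbers of post-burn-in draws per chain (50 x 12 = 600 at paper
scale, ~100 at desk scale) are simulated through the model; failed
draws are replaced by resampling from the chains (capped at 5%).
Forecasts comprise pointwise mean +/- sd envelopes of the chamber
pressures and volumes, per-wall engineering strain
`(L_s(t) - L_s(0))/L_s(0) * 100` with the cycle onset (ventricular
activation) as reference state, and five hemodynamic biomarkers: mean
pulmonary artery pressure; RV stroke volume `SV_RV = max V_RV - min
V_RV`; pulmonary arterial elastance `Ea_pa = (mean p_PA - mean
p_LA)/SV_RV`; RV end-systolic elastance `Ees_RV = p_RV/V_RV` at the
instant of minimum RV volume (the package's operational definition of
end systole); and ventricular-vascular coupling `VVC = Ees_RV/Ea_pa`,
which satisfies `VVC * Ea_pa = Ees_RV` per draw by construction.
Elastances are reported in mmHg/ul. Wall strains stay within the
physiologic envelope (below +5%, shortening to about -20%).

## Problem sizes and presets

`study_config("paper")` carries the full-scale settings (K = 100,
21-point profiles, 12 chains x 50,000, 600 forecast draws).
`study_config("desk")` — K = 20, 11-point profiles, 3 chains x 1,500,
~100 draws — is the package's standard working scale: it exercises
every code path and reproduces the workflow's qualitative conclusions
(subset counts, design-dependent identifiability, strain envelopes) in
minutes on a single core. The test suite and the acceptance script run
at desk scale. Stochastic quantities at desk scale (the Morris-retained
count, credible-interval coverage) move by one or two units across
seeds; structural quantities (counts of states and parameters, the
screening step, conservation laws) do not move at all.

## What the synthetic study does and does not show

The generator emulates catheter- and echo-style measurements with
independent Gaussian noise whose variance the likelihood knows
exactly, on data produced by the very model being fitted. Passing
tests therefore demonstrate the *internal* coherence of the workflow —
that the machinery can recover what it hid — and how information
content varies across designs. They do not demonstrate robustness to
model discrepancy, correlated or heteroscedastic measurement error,
beat-to-beat variability, or respiratory modulation, none of which are
generated. The diode valve model excludes regurgitation and inertial
valve dynamics; there is no baroreflex or volume regulation, so total
stressed volume is a hard constraint; and the septal snap-through
branch structure means extreme parameter excursions can fail rather
than gracefully degrade. Conclusions about *which* design identifies
*which* parameter are conditional on the functional forms documented
above.

## Known limitations

* The Fisher/SVD stage's removal count sits on a condition-number
  knife edge (~1e8) and is sensitive to the sensitivity scaling
  convention; both conventions are implemented, the log-scaled one is
  the default, and the resulting subset size (~16, not 13) is reported
  as computed.
* Profile classifications at desk scale use a small optimizer budget;
  identifiable/non-identifiable boundaries for the weakest parameters
  can shift with `maxit` and grid resolution.
* Desk-scale chains do not satisfy the 1.1 PSRF cutoff; posterior
  widths should be read comparatively across designs, not as
  calibrated uncertainties.
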