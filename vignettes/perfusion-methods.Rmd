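---
title: "Methods: a reduced model of myocardial perfusion and coronary flow steal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced model of myocardial perfusion and coronary flow steal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

## Overview

`perfusim` couples three reduced submodels into one forward simulator of
myocardial perfusion:

1. a closed-loop lumped-parameter (0D) circulation of the left heart and
   systemic arteries;
2. a reduced epicardial coronary network of J terminal branches;
3. a three-compartment Darcy porous-media model of the biventricular
   myocardium, discretised with continuous piecewise-linear (P1) finite
   elements.

The chain is one-way from the circulation into perfusion within a time
step (coronary flow is two to three orders of magnitude smaller than
cardiac output, so the feedback lag is second order), while the coronary
network and the Darcy model are coupled implicitly at every step.

## The 0D circulation

The left ventricle is a time-varying elastance chamber,
`p_LV = E(t) (V_LV − V0)`, with a periodic double-Hill activation between
`E_min` and `E_max`. The left atrium is passive (constant elastance): atrial
contraction mainly shapes the late-diastolic A-wave, which has little
effect on total perfusion, so we omit it. Valves are ideal pressure-driven
diodes that switch instantaneously when the transvalvular pressure
difference changes sign — this reproduces opening/closing at the ends of
the isovolumetric phases. The systemic arteries are a windkessel
(compliance `C_art`, run-off resistance `R_sys` into a fixed venous
pressure), the pulmonary veins supply the atrium at a constant 10 mmHg
through `R_pul`, and a lumped venous reservoir closes the loop so that,
with no coronary sink, total blood volume is conserved exactly by the
explicit flux-sharing update.

Time integration is semi-implicit Euler with Δt = 1 ms over two heartbeats
(T = 0.8 s); all reported quantities come from the second beat, discarding
the initial transient. Pressures are Pa internally (1 mmHg = 133.322 Pa),
volumes mL, flows mL/s.

### Calibration

The defaults of `circulation_params()` were obtained by Nelder–Mead
minimisation (on log-parameters, `scripts/calibrate.R`) of the squared
relative misfit to seven resting left-heart reference biomarkers: stroke
volume 83.0 mL, ejection fraction 54.2%, peak LV pressure 125.4 mmHg, peak
aortic flow 562.0 mL/s, peak pulmonary-vein inflow 267.2 mL/s and arterial
pressure 103.3/80.3 mmHg. Eight parameters were free (`E_max`, `E_min`,
`R_mv`, `R_ao`, `R_pul`, `R_sys`, `C_art`, `E_LA`); the calibrated set
reproduces each target to within a few percent, which the acceptance test
suite asserts at the ±10% level.

## The coronary network

Each territory j is fed by one branch with flux

`Q_j = (p_root − p̄1_j) / (R_epi,j + R_ostium,j · [aortic valve open] + 1/α_j)`

where `p_root` is the systemic arterial (aortic root) pressure, `p̄1_j` the
volume-averaged compartment-1 pressure of territory j, and `α_j` the
interface conductance of the reduced outlet coupling (the defective-boundary
integral of the 3D formulation collapses to the lumped resistance `1/α_j`).
Conductances scale with territory volume — a larger territory is fed by a
larger vessel — and the branch resistance is split 75% epicardial / 25%
interface (`alpha_share = 0.25`; the split within the series chain does not
affect the flux, only the interpretation of the two elements). The ostial
resistance is active only while the aortic valve is open, emulating
obstruction of the coronary ostia by the open leaflets; its default
(`R_ostium_factor = 1.2` times the branch resistance) makes systolic flow
roughly one third of the diastolic peak. The overall resistance scale
(`R_total_parallel = 3820 Pa·s/mL`) is calibrated so the physiological
diastolic-peak perfusion matches the target mean MBF (next section).

Branches are tagged LCA or RCA by their azimuthal position (the RCA sector
covers 35% of the circumference), so the left tree feeds more myocardium
and carries more flow.

## The three-compartment Darcy model

Compartments represent arterioles (1), small vessels (2) and capillaries
(3). In pressure form, with velocity `u_i = −K_i ∇p_i` eliminated:

`−∇·(K_i ∇p_i) + Σ_k β_{i,k} (p_i − p_k) [+ γ (p_3 − p_bed)] = g_i`

with no-flux (natural) boundaries on the whole boundary. `g_1` is piecewise
constant per territory, `Q_j / |Ω_j|`, so its volume integral equals the
total inflow exactly; `g_2 = 0` (the middle compartment exchanges no mass
with the outside); and the capillary sink `γ (p_3 − p_bed)` with

`p_bed(t) = a1 · p_LV(t) + a2,  a1 = 0.4, a2 = 1500 Pa, γ = 1e-4 1/(Pa·s)`

phenomenologically represents the coronary bed being squeezed by
ventricular contraction. Exchange is hierarchical: `β_{1,3} = 0` by default
(arterioles talk to capillaries only through the middle compartment).

Defaults: `β_{1,2} = 1.5e-5`, `β_{2,3} = 1e-5` 1/(Pa·s) (so a physiological
transcompartment drop of ~1.5 kPa yields MBF near the normal resting
range); `K = (2e-3, 1e-3, 2e-4)` mm²/(Pa·s), decreasing down the hierarchy
and small enough that territories remain distinct while fields stay smooth
at desk resolution. MBF heterogeneity across territories is produced by a
mean-one log-normal multiplier on `β_{2,3}` (sdlog 0.2, seeded), standing
in for the heterogeneous microvascular resistances of real myocardium.

### A useful exact identity

Integrating the compartment-2 and compartment-3 equations over Ω with
no-flux boundaries gives `∫ β_{2,3}(p_2 − p_3) dV = Σ_j Q_j` at every
converged instant. Hence the **spatial-average MBF equals
`6000 · Σ_j Q_j / V` exactly**, independent of `K_i`, `β`, `γ` and mesh
resolution: those parameters shape only the spatial distribution of MBF.
Calibrating the mean MBF is therefore equivalent to calibrating the
diastolic-peak total coronary inflow, which is what `R_total_parallel`
does. The same argument yields the global mass-closure invariant
`Σ_j Q_j = ∫ γ (p_3 − p_bed) dV`, which the driver records at every step
and the tests assert to 1e-8.

A corollary: in this reduced model the relative AR reduction of mean MBF
equals the relative reduction of diastolic-peak coronary inflow. In the
full 3D setting the two reference numbers differ slightly (the two peaks
are found on different fields at different instants); our AR MBF therefore
sits a few percent below the reference value, within its stated band.

### Discretisation and solvers

P1 elements on tetrahedra; stiffness with per-cell scalar coefficients,
exchange and sink terms with the *consistent* mass matrix (`∫ λ_a λ_b =
V/20 (1 + δ_ab)`), which keeps the discrete counterparts of the integral
identities above exact to solver precision. The 3N×3N block system is
symmetric positive definite (the γ mass term removes the pure-Neumann null
space; assembling with `γ = 0` is refused with an explicit message). It is
factorised once per run by sparse Cholesky — the matrix is
time-independent because the Darcy problem is quasi-static on a fixed,
non-deforming domain; time enters only through `g_1(t)` and `p_bed(t)` on
the right-hand side. Velocities are post-processed element-wise from the
pressure gradients. Verification: spatially uniform sources reproduce the
closed-form pressure chain `p_3 = p_bed + g_1/γ`, `p_2 = p_3 + g_1/β_{2,3}`,
`p_1 = p_2 + g_1/β_{1,2}` to 1e-8, and a manufactured cosine solution on a
box mesh (where homogeneous Neumann data hold exactly) converges at second
order in L².

## Coupling

Per step: (1) the circulation advances with the previous step's total
coronary outflow withdrawn from the arterial compartment; (2) the
network/Darcy fixed point is solved by iterative splitting — branch fluxes
from territory-mean p1, Darcy solve from the fluxes — with under-relaxation
0.1 on the flux update, to a relative interface tolerance of 1e-6.

Because the Darcy operator is linear, its interface action is precomputed
once as an affine response (`p̄1 = L Q + p_bed`, J+1 solves against the
cached factorisation); the relaxed subiterations on the J fluxes are then
*algebraically identical* to subiterating full-field solves, at negligible
cost. The splitting is cross-checked in the tests against the direct
(monolithic) solve of the affine interface system to 1e-8.

Numerical choices worth recording:

* the 0.1-relaxed iteration contracts at ≈0.9 per pass, so reaching 1e-6
  can take ~150 passes after a valve switching instant; the default
  subiteration cap is therefore 250 (a cap of 100 would abort mid-beat);
* the iteration is warm-started from the previous step's converged fluxes,
  and at t = 0 from the direct affine solve;
* the convergence log (subiteration count, final residual, mass-closure
  error) is recorded at every step and every accepted step must satisfy
  the tolerance — there is no silent acceptance path.

The **diastolic peak** is defined operationally as the instant of maximum
total coronary inflow while the mitral valve is open, within the reported
(second) beat; the MBF map is evaluated there by one full-field solve. We
report the spatial average at that instant (the natural reading of a
perfusion map "at diastolic peak"); time-averaged MBF can be reconstructed
from the recorded flux transients via the identity above.

## The aortic-regurgitation scenario

`apply_ar_scenario()` makes two changes, mirroring how the pathology is
prescribed upstream of the perfusion model:

* the closed aortic valve acquires a leak conductance `G = leak_coef ×
  A_orifice` with `A_orifice = 0.045 ×` annulus area (490 mm²). A linear
  conductance is used instead of a Bernoulli orifice law for robustness at
  Δt = 1 ms; `leak_coef = 6.5e-5 mL/(s·Pa·mm²)` is calibrated against the
  target diastolic coronary-flow reduction of about 25%;
* the systemic arterial pressure *as seen by the aortic interface and the
  coronary root* is scaled by 1.2 in systole and 0.8 in diastole. Whether
  the reference modification scales the whole waveform or only its plateaus
  is underdetermined; we blend the two scales smoothly with the normalised
  LV activation, which scales the systolic and diastolic portions piecewise
  with continuous transitions. The windkessel state itself integrates
  unscaled, keeping the PH and AR arterial dynamics comparable.

Both mechanisms reduce the diastolic perfusion drive `p_root − p_bed`: the
lowered diastolic aortic pressure directly, and the leak by re-filling the
ventricle (raising `p_LV`, hence `p_bed`) while stealing aortic volume.
Notably, the prescribed −20% diastolic pressure modification alone already
accounts for most of the flow reduction; the leak conductance adds the
ventricular side of the mechanism and the retrograde transvalvular jet.

## The synthetic domain

`generate_biventricle()` builds a truncated-ellipsoid shell (outer semi-axes
40×40×60 mm, inner 29×29×51 mm, basal cut at z = 18 mm, wall volume
≈150 mL) as a stand-in for an image-based biventricular mesh. The grid is a
structured azimuth/meridian/transmural lattice triangulated by the
Kuhn/Freudenthal split, which is globally conforming (including across the
periodic seam and the collapsed apex) and fully deterministic; the analytic
shell volume provides an exact oracle for the discretised volume. Perfusion
territories are Voronoi cells of J seed points (golden-angle lattice on the
epicardium) with deterministic lowest-index tie-breaking; J is not fixed by
the reference setting, so it is a configuration parameter, default 20
(study size) and 4 (tiny test size).

What the synthetic domain does *not* emulate: the real septal/free-wall
asymmetry and right-ventricular cavity, fibre anisotropy (permeabilities
are isotropic scalars; tensorial input is accepted but no fibre model is
provided), wall deformation (the domain is fixed; contraction enters only
through `p_bed`), and anatomically derived coronary territories. Passing
tests therefore demonstrate the correctness of the numerics and the
mechanism-level behaviour (diastolic dominance, LCA/RCA asymmetry, AR flow
steal), not patient-specific accuracy.

## Problem sizes and determinism

The study configuration (`default_config(level = "small")`) uses a mesh of
roughly 6000 tetrahedra (target edge 7 mm), J = 20 territories and 1600
time steps (two beats at Δt = 1 ms); a full coupled scenario solves in a
few seconds on one core, and the test suite runs two study-size scenarios
plus the verification problems in well under a minute. The `tiny` level
(target edge 12 mm, J = 4) is used for the invariant-heavy tests. The only
random input is the per-territory `β_{2,3}` multiplier, drawn under a fixed
seed without touching the caller's RNG stream; two runs with the same
configuration and seed produce bitwise-identical transients.

## Known limitations

* No right heart or pulmonary dynamics; the pulmonary-venous pressure is a
  constant source, so atrial loading is simplified.
* The elastance surrogate has no mechano-electric feedback; heart rate and
  activation shape are fixed inputs.
* Quasi-static, non-deforming Darcy domain: no poromechanics, no oxygen
  transport, no autoregulation — coronary resistances are constant within a
  valve state.
* The AR leak law is linear; very large orifices would need a Bernoulli
  (quadratic) law and a finer-grained valve model.
* Calibrated parameters are a point estimate reproducing population-level
  reference biomarkers; no identifiability or uncertainty analysis is
  attempted.
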