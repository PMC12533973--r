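---
title: "A reduced-order model of thromboembolus transport from carotid stenosis to the brain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of thromboembolus transport from carotid stenosis to the brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emboflow)
```

## The scientific question

Emboli released from a stenosed carotid artery usually occlude a cerebral
vessel in the same hemisphere — but not always. Because the Circle of Willis
(CoW) joins both internal carotids and the basilar artery into one ring,
flow (and with it emboli) can be rerouted across the midline when one
carotid is narrowed. Clinically this matters: if an embolus from a mildly
stenosed carotid lodges in the hemisphere of the *severely* stenosed
contralateral carotid, the wrong vessel looks symptomatic. `emboflow`
provides an in silico laboratory for this mechanism: a parameterized
heart-to-brain arterial network with bilateral NASCET-graded carotid
stenoses, pulsatile network hemodynamics, and individual embolus transport
from carotid and cardiogenic (aortic root) sources to the eleven outlets of
the tree.

Everything is synthetic and reduced-order. The package does not attempt
patient-specific 3D computational fluid dynamics; it reduces the vasculature
to a one-dimensional network with analytic in-vessel velocity profiles, so
that the *network* mechanisms — differential cervical flow recruitment,
proximal collateral routing through the CoW communicators, contralateral
embolus transport — can be exercised, tested and reasoned about on a desktop.

## The synthetic vasculature

`network_template()` / `build_baseline_network()` create a single-inlet,
eleven-outlet tree: aortic root inlet; outlets at the descending aorta,
left/right subclavian, left/right external carotid, and six cerebral
arteries (M1, A2, P2 on each side); a complete CoW (anterior communicator,
both posterior communicators, both P1 segments). Segments are straight
capsules with linearly tapering radii at anatomically plausible dimensions
(aorta 12.5–9.5 mm radius, common carotids 3.5 mm, internal carotids
3.0 mm, CoW communicators 0.6–1.2 mm). Left and right vessels are
identical in length and caliber distal to the carotid bifurcations; the one
deliberate asymmetry is the aortic arch branching order — the
brachiocephalic trunk takes off first (most proximal), so any
right-preferential recruitment of cardiogenic emboli emerges from geometry
rather than being hard-coded. Side branches attach at the parent vessel's
*wall* (ostium placement), not its centerline, which matters for how much
of the parent's core flow a branch can capture. A perfectly mirror-symmetric
variant (`symmetric_arch = TRUE`) exists for symmetry oracles.

Stenoses are applied to the proximal internal carotid as a cosine taper over
the stenosis length, reaching throat radius `r_ref * (1 - severity/100)`
(NASCET is a diameter criterion, so the radius ratio carries the severity).
The stenosis length grows in proportion to severity,
`L = k * (severity/100) * L_ICA` with `k = 0.5` by default — a documented
stand-in satisfying the qualitative requirement that more severe stenoses
are longer; both `k` and the site are configurable. Severity 100% marks the
segment occluded: zero lumen, zero flow, excluded from particle transport,
with downstream territory reachable only through the CoW.

The default experiment family pairs each mild severity {10, 25, 40}% with
each moderate/severe severity {50, 70, 85}% on each side (18 bilateral
models) and adds contralateral carotid occlusion (CCO) models — one carotid
at 100% against each of the six severities on the other side (12 models).
Each non-CCO model admits three release sources (left carotid wall, right
carotid wall, aortic root), CCO models two, giving 78 experiments; at the
default 5,500 emboli per source that is ~429,000 trajectories.

## Hemodynamics

Flow is solved on the network as a quasi-static nonlinear resistive circuit.
Each segment's Poiseuille resistance is the integral of `8*mu/(pi*r(s)^4)`
along its radius profile; stenosed segments carry an additional
Young–Tsai-type quadratic loss
`dP = K_t * rho * (A_ref/A_throat - 1)^2 * Q|Q| / (2*A_ref^2)`
(`K_t = 1.52` by default), without which severe stenoses would not reroute
flow realistically. The inlet is driven by a periodic waveform (cycle
0.83 s, cardiac output 79 mL/s): an offset half-sine systolic pulse with
systole occupying 36% of the cycle and diastolic flow at 25% of the mean,
discretely normalized so the cycle mean is exact. The waveform shape is a
package choice (the underlying MRI shape is not published) and is
configurable.

Outlet boundary conditions are resistances to a zero reference pressure.
They are estimated by the standard procedure: total arterial resistance
TAR = MAP/CO with MAP = 93.33 mmHg (from 120/80 mmHg); target flow
fractions — 65% of CO to the descending aorta, per-outlet cerebral
fractions, and the residual split over external carotids and subclavians in
proportion to outlet area — initialise `R_i = MAP/(CO*f_i)`; iterative
steady solves with multiplicative updates `R_i <- R_i * (Q_i/Q_target_i)`
converge every outlet to within 1% of target (usually 2–3 iterations).
The cerebral per-outlet fractions default to MCA 3.4%, ACA 1.8%, PCA 2.0%
of CO per side (total cerebral blood flow ~14.4% of CO), a physiologic
MCA > ACA ~ PCA ordering chosen so that the baseline cervical split comes
out near the cohort-averaged MRI values (LICA/RICA/BA ~ 39/37/24% of tCBF);
they are configurable. Once tuned on the baseline, the resistances are held
fixed across all stenosis models, so flow rerouting is driven purely by the
stenosis geometry.

Because the network is purely resistive (no compliance or inertance), each
time step is an independent nonlinear solve and the periodic regime is
reached immediately: `solve_unsteady()` computes one cycle at a 1 ms step
and labels it the converged (third-cycle) solution; cycle-to-cycle
transients vanish identically. Interior-node mass residuals are tracked and
stay below `1e-9` of the cardiac output. Degenerate inputs — an outlet
disconnected from the inlet (e.g. by occluding all paths) — are rejected
with the offending node named.

## The velocity field

Particle forcing needs a space-time velocity field, not just segment flows.
Inside each segment the axial velocity is the Poiseuille profile
`u_z = 2 Q(t)/(pi R(s)^2) * (1 - (rho/R)^2)` along the centerline tangent,
plus the exact first-order radial component demanded by mass conservation
where `R(s)` varies (`u_rho = u_z * rho * R'(s)/R`); the in-segment field is
divergence-free by construction and satisfies no-slip exactly. Velocity
gradients are analytic. Profiles are quasi-steady (Poiseuille rather than
Womersley): at particle Stokes number ~0.005 the embolus fate is dominated
by flow splits and near-wall shear, not by profile phase lag.

Where segments meet, the field switches to an explicit junction model:
within a sphere at each interior node (radius 1.5 times the largest
adjacent end radius, capped at 0.4 of the shortest adjacent segment), the
velocity is a mass-conserving potential flow of softened point
sources/sinks placed at the segment ports, with strengths equal to the
instantaneous signed segment flows. This routes emboli across branch points
in proportion to the flow split — the physical mechanism on which
source-to-destination mapping rests — and removes the stagnation dead zones
that a naive blend of extrapolated segment fields produces beyond a
terminating parent vessel. Outside the junction spheres, overlapping
segment capsules are blended with containment-depth-squared weights, each
segment's contribution fading over one radius of axial overshoot past its
end; gradients reuse the blend weights (gradient-of-weight terms are
dropped, an approximation confined to junction neighbourhoods). The sphere
surface acts as the wall inside a junction zone.

`cross_section_flux()` integrates the sampled axial velocity over a lumen
cross-section (Gauss–Legendre in radius, uniform in azimuth) and recovers
the solved segment flow to quadrature accuracy (0.1%) inside segment cores;
this is also how the communicator flow maps and cycle-averaged cervical
fractions are checked against the network solution.

## Embolus dynamics

Each embolus is a rigid 500 um sphere, density 1.15 g/cc — chosen so the
bare-Stokes momentum response time `tau = rho_p d^2/(18 mu)` equals the
0.004 s characteristic of such emboli in 4.0 cP blood (Stokes number
0.005 against the cardiac cycle), and within reported thrombus density
ranges. One-way coupling throughout: the field drives the particle; the
particle never modifies the field.

The equation of motion is a modified Maxey–Riley form with the classical
canonical expressions for each named force:

* Stokes drag `(u - v)/tau`, scaled by `rho_p/(rho_p + C_m rho_f)`;
* undisturbed-flow plus pressure-gradient force
  `(1 + C_m) * rho_f/(rho_p + C_m rho_f) * Du/Dt`, with the material
  derivative from the analytic field gradients;
* Saffman-type shear-gradient lift
  `F_L = 1.615 d^2 sqrt(mu rho_f / |omega|) (u - v) x omega`, divided by
  the added-mass-corrected particle mass. Near a wall, a lagging particle
  feels lift directed away from the wall.

The Basset history force is omitted (standard at these Stokes numbers), as
are gravity/buoyancy (near-neutral density; flag available) and margination
forces (excluded deliberately: the embolus is far larger than blood cells).
Every force term can be toggled individually for ablation tests.

Wall collisions use an impact-Stokes-number restitution law standing in for
elastohydrodynamic lubrication: with impact Stokes number
`St_n = rho_p d v_n/(9 mu)`, the effective restitution is
`e_eff = e0 * max(0, 1 - St_c/St_n)` (`e0 = 0.8`, `St_c = 10`). Slow
impacts are fully damped by the lubrication film — the embolus deposits and
creeps tangentially along the wall — while fast impacts approach the dry
restitution. Contact is frictionless; the tangential velocity is preserved;
the centre is projected back to the wall-offset surface (wall distance =
embolus radius) after every contact.

Trajectories are integrated with explicit Euler at a 0.05 ms step, three
orders of magnitude below the momentum response time. The periodic flow
cycle is stitched end-to-end over 10 cardiac cycles; if more than 10% of a
batch is still recirculating, all unresolved trajectories are extended once
by another 10 cycles, and any experiment still above the threshold is
flagged in its record rather than extended indefinitely.

## Monte Carlo experiments

Carotid releases sample the stenosis-length wall patch uniformly in arc
length and azimuth, offset inward by the embolus radius (so the particles
start in contact-free positions); cardiogenic releases sample the aortic
root inlet disc uniformly in area inside a rim offset of one embolus
radius. Release times are uniform over one cardiac cycle — the maximum
entropy choice, since no phase information is available — and the initial
embolus velocity is the local fluid velocity. All sampling is
seed-controlled; experiment seeds are derived deterministically from a base
seed. Batch integration is particle-independent, so batch results are
identical to particle-by-particle integration.

`run_campaign()` tunes the outlet resistances once, reuses them across all
models, isolates per-experiment failures, writes per-experiment JSON
records plus a manifest with a content hash, and skips completed
experiments on re-runs (resumable, bit-identical replay).

## Analytics

`outlet_distribution()`, `hemisphere_split()`, `contralateral_fraction()`
and `cca_recruitment_split()` turn trajectory records into the summary
quantities of interest. The contralateral fraction is normalized by the
emboli reaching the six cerebral outlets (not all released emboli): it is
the probability that a brain-bound embolus lands in the hemisphere opposite
its release carotid. The denominator convention is documented and
switchable by working from the raw counts. Statistical comparisons use the
Wilcoxon signed-rank test against a hypothesized median (the canonical
reading of a "one-sample Wilcoxon test"), the Mann–Whitney rank-sum test,
and the Shapiro–Wilk normality check, with exact small-sample p-values
where available.

## What the model reproduces, and what it cannot

With the default family the package reproduces the directional findings
that motivate it:

* severe unilateral stenosis shifts cervical recruitment: the ipsilateral
  ICA fraction of tCBF falls monotonically with severity while the
  contralateral ICA and basilar fractions rise;
* the AcoA routes flow toward the severely stenosed or occluded side, with
  magnitude growing in severity, and reverses when the sides are swapped;
* mild-side carotid releases cross to the contralateral hemisphere far more
  than severe-side releases (Mann–Whitney direction), CCO models cross more
  than bilateral models on average, and the mild-side crossing fraction
  trends upward with contralateral severity;
* cardiogenic emboli preferentially recruit into the right common carotid
  on the default arch, an emergent consequence of the branch-first
  geometry.

Known limits of the reduction, documented here deliberately:

* **Severe-side crossings vanish.** In the quasi-static resistive network
  the AcoA never reverses toward the mild side within the cycle, so a
  release from the *severe* carotid has strictly zero probability of
  crossing. The small (0.5–4%) severe-side crossings seen in 3D
  patient-specific simulations come from jet and recirculation dispersion
  at the stenosis, which a 1D field cannot represent.
* **Crossing magnitudes are exaggerated.** Monte Carlo outlet fractions
  differ from flow fractions at CoW branch points (near-wall release bias
  plus the junction caricature); mild-side contralateral fractions here run
  tens of percent where a patient-specific geometry produced 6–10%.
  Directions and orderings are meaningful; magnitudes are not calibrated.
* **Cardiogenic hemisphere splits vary more than in the 3D study.** The
  compensation that keeps hemispheric distribution nearly constant in the
  patient geometry is only partially captured; the coefficient of variation
  across models is several-fold larger here.
* **Individual fates near branch-basin boundaries are step-size
  sensitive.** As in any chaotic advection problem, trajectories that pass
  close to a junction basin boundary diverge under infinitesimal
  perturbation; halving the particle time step flips the exit outlet of a
  substantial fraction of such emboli. The Monte Carlo deliverable — the
  fate distribution — is step-size robust within binomial sampling error,
  and that is what the test suite asserts.

## Numerical choices and problem sizes

Flow solver step 1 ms (830 steps per cycle), nonlinear stenosis losses by
warm-started fixed point to `1e-12` relative residual; particle step
0.05 ms; junction transition shell 5% of the sphere radius; port softening
half the port radius; resistance tuning tolerance 1% per outlet. The test
suite runs the full 78-experiment design at 250 emboli per source (with
binomial-noise-tolerant assertions) and individual physics oracles at
60–1,000 particles; the shipped configuration defaults remain the full
5,500-per-source design.

## Worked example

```{r example, eval = FALSE}
net <- build_baseline_network()
wf <- cardiac_waveform()
rs <- tune_outlet_resistances(net, target_flow_splits(net), wf)
sol <- solve_unsteady(net, wf, rs)
round(communicator_flow_map(sol, net)$cervical_fractions, 3)

spec <- list(label = "10L85R", left = 10, right = 85,
             source = "left_carotid", n = 1000, seed = 1)
er <- run_experiment(spec, net, rs, wf)
er$record
contralateral_fraction(er$record, "left", net$hemisphere_map)
```
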