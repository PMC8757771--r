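---
title: "Modelling printability of shear-thinning hydrogel inks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling printability of shear-thinning hydrogel inks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelprint)
```

## The problem

Extrusion bioprinting of soft, water-rich inks — here self-assembling
peptide hydrogels — succeeds or fails on three questions that can all be
answered from rheometry before any material is wasted:

1. **Can the printer push the ink through the needle?** The pressure the
   piston drive can deliver must exceed the pressure drop of the ink flowing
   through the syringe-plus-needle train.
2. **Will embedded cells survive the transit?** The wall shear stress in the
   needle must stay below a damage threshold.
3. **Will the printed structure hold its shape?** A soft lattice creeps under
   its own weight; if it slumps, a sacrificial support bath (bioplotting) is
   needed.

`gelprint` implements this workflow end to end: power-law rheology fitting,
closed-form non-Newtonian pipe flow, lead-screw hardware capacity, a
cell-safety screen, and a transient Kelvin–Voigt finite-element model of
scaffold collapse.

## Rheology

Flow-sweep data are described by the Ostwald–de Waele power law

$$\eta(\dot\gamma) = K\,\dot\gamma^{\,n-1},$$

with consistency index $K$ (Pa·s$^n$) and behaviour index $n$ ($n<1$: shear
thinning). `fit_power_law()` log-transforms both axes and fits an ordinary
least-squares line — slope $n-1$, intercept $\log K$ — exactly the standard
procedure for the power-law region of a flow sweep; no weighting is applied.
A fit with $R^2 < 0.95$ triggers a warning rather than an error, since the
decision of whether a power law is adequate belongs to the analyst. The
default fit window is the full measured range (for these gels,
0.01–2000 s$^{-1}$); a narrower window can be passed when a low-shear yield
plateau contaminates the data.

The reference gels span $K$ = 5.78–41.98 Pa·s$^n$ and $n$ = 0.02–0.12 over
two peptide concentrations (20, 30 mg/ml) and three pH values (3.7–4.9);
`f9_fixtures()` is the single in-package source of these constants.

For the collapse model, low-shear oscillatory moduli are lumped into a
Kelvin–Voigt solid: spring $E$ from the storage modulus $G_0'$ and dashpot
$\eta_0$ from the low-shear viscosity. Elasticity theory gives
$E = 2(1+\nu)G_0'$, but the tabulated lumped parameters of the reference
characterization follow $E = 2G_0'$ for every entry, including at
$\nu = 0.49$ where the two differ by a factor 1.49.
`kelvin_voigt_from_moduli()` therefore exposes both conversions; the default
(`"tabulated"`) reproduces the tabulated spring constants so that downstream
simulations are comparable with the published ones, and `"poisson"` applies
the textbook relation.

Yield stress is estimated by a Herschel–Bulkley fit
$\tau = \tau_y + K\dot\gamma^n$ (Levenberg–Marquardt, `minpack.lm`). It is a
convenience number read off a plateau that is often barely resolved; the
package clamps negative estimates to zero with a warning and labels the
result approximate.

## Extrusion flow

The piston imposes the flow rate, so the mean needle velocity follows from
continuity alone, $v_\text{out} = v_\text{in}(R_\text{piston}/R_\text{needle})^2$,
independent of the ink. Flow in each segment is treated as fully developed
laminar power-law pipe flow:

* velocity profile
  $u(r) = \frac{3n+1}{n+1}\,\bar v\,[1-(r/R)^{(n+1)/n}]$;
* wall shear rate via the Rabinowitsch–Mooney correction
  $\dot\gamma_w = \frac{3n+1}{4n}\cdot\frac{8\bar v}{D}$ and wall stress
  $\tau_w = K\dot\gamma_w^{\,n}$;
* cylinder pressure drop $\Delta p = 2\tau_w L/R$; conical tapers are
  integrated axially under the lubrication approximation (locally fully
  developed flow, 400 midpoint slices by default — halving the slice width
  changes the result by well under 0.01%).

The plug-like core is defined as the radial span where $u \ge 0.95\,u(0)$;
for the power-law profile this is $(1-0.95)^{n/(n+1)}$, a function of $n$
only. The 95% threshold is a modelling choice (the criterion is rarely
stated in the literature); with it, every reference gel ($n \le 0.12$) has a
plug exceeding 70% of the section, and the plug shrinks monotonically as
$n \to 1$.

Three rheological models of increasing fidelity are compared, because a
Newtonian surrogate is often convenient in quick estimates: model 1 takes
viscosity $=K$; model 2 takes the power-law viscosity at the average needle
shear rate $8\bar v/D$ (one constant viscosity applied to the whole train);
model 3 is the power law itself. The signed percent deviation
(`modeling_error()`) of model 2 in the needle has the closed form
$100[(4n/(3n+1))^n-1]$: between −5% and −12% for the reference gels, while
model 1 overshoots by roughly two orders of magnitude. An independent
quadrature oracle (`radial_quadrature_oracle()`) integrates the shear-rate
field $\dot\gamma(r) = (\Delta p\, r/2LK)^{1/n}$ numerically and inverts the
closed-form $\Delta p(Q)$ relation to well under 0.1%, which is how the
closed forms are verified in the test suite.

**Limitations.** Entrance effects are neglected (each segment is fully
developed), so absolute pressure drops differ from a full axisymmetric CFD
solution near the taper; wall shear stress and plug fraction in the needle,
which dominate the printability verdict, are unaffected. Gravity and inertia
are neglected (creeping flow), and there is no yield-stress flow solution —
the Herschel–Bulkley description is used only for yield-stress estimation,
not for the flow field.

## Hardware capacity

A stepper (stall torque 0.40 N·m) drives the piston through an M5 lead screw
(pitch 0.8 mm, efficiency 0.5). The standard screw work balance gives the
axial force $F = \eta\,2\pi T/p \approx 1571$ N; the conversion without the
$2\pi$ (a literal torque-over-pitch budget, 250 N) is selectable as
`convention = "literal"` for comparison. Using 80% of the stall force on the
12 mm syringe bore yields an available pressure of about 11 MPa — three
orders of magnitude above the kPa-scale drops of these shear-thinning gels,
which is why every reference gel/needle combination is extrudable.

## Scaffold collapse

A wood-pile lattice (alternating 0°/90° strand layers) is reduced to its
repeating cross-section: in-plane layers appear as full-width slabs of one
layer height, out-of-plane layers as strand cross-sections spaced by the
inter-fiber distance, with half a strand at each lateral symmetry edge. The
default slicing (0.77 mm strands, 0.55 mm layers, 2.57 mm spacing — 30%
infill) with 6 layers gives a 3.3 mm tall, 2.57 mm wide unit cell meshed
into ~600 linear triangles at the default element size; filling the pores
with support-bath elements adds ~300 more.

Each subdomain is a Kelvin–Voigt solid in plane strain: total stress
$\sigma = C(E,\nu):\varepsilon + C(\eta_0,\nu):\dot\varepsilon$, where the
viscous operator reuses the elastic constitutive matrix with the dashpot
viscosity substituted for the modulus. This makes the per-subdomain damping
matrix proportional to the stiffness matrix ($D = (\eta_0/E)K$), so a
homogeneous body relaxes with the exact one-dimensional Kelvin–Voigt time
constant $\tau = \eta_0/E$ — the lumped limit used as an oracle. Gravity is
a volumetric load; the bottom edge is fixed, lateral edges are symmetry
rollers, the top is free; the gel–support interface is perfectly bonded
(one conforming mesh). The quasi-static system $Ku + D\dot u = f$ is stepped
by backward Euler (default $\Delta t = 0.5$ s over 0–200 s; halving
$\Delta t$ changes the final displacement by far less than 1% because every
material time constant here is under 8 s, so the window reaches
equilibrium).

Two analytic oracles pin the solver down:

* a **uniform column** under self-weight between the lateral guides settles
  to $\rho g H^2/(2M)$ with constrained modulus
  $M = E(1-\nu)/[(1+\nu)(1-2\nu)]$; at $\nu=0$, $M=E$ and the classic
  $\rho g H^2/(2E)$ applies (for $E=30$ Pa, $H=3.3$ mm: 1.78 mm). The FE
  solution matches within 2% at $\nu=0$ *and* at $\nu=0.49$ — confined
  compression is exactly representable by linear triangles, so this test is
  immune to volumetric locking;
* a **single element** under constant traction follows the lumped creep law
  within 1% at every output time (with a step small relative to $\tau$).

The monitored point A is the upper outer corner node of the top strand (the
top layer is an out-of-plane strand layer for an even layer count; for an
odd count the mid-span of the top slab — the point of maximum sag — is used
instead). Its displacement is reported over time and the final value divided
by the structure height is the collapse strain.

**Design choices and limitations.** The kinematics are small-strain linear
even though the softest gel reaches strains far beyond 20%; printed reports
flag such strains as beyond linear validity, and absolute displacements at
large strain are order-of-magnitude indicators, not predictions (no contact,
no geometric nonlinearity, no fluidization of the support during nozzle
travel). Near-incompressibility ($\nu=0.49$) with constant-strain triangles
under-predicts bending-dominated deformation somewhat; the quantities the
recommendation relies on — the monotone ranking of gels by stiffness and the
with/without-support ratio — are insensitive to this, which is what the
property tests assert. The default density is 1000 kg/m³ and
$g = 9.81$ m/s².

## Printability verdict

`generate_report()` composes the stages. The recommendation logic uses a 5%
final-strain cutoff: `bioplotting_required` when the free-standing strain
exceeds 5% while the embedded strain does not; `not_extrudable` when the
required pressure exceeds the available pressure; `direct_print` otherwise.
The 5% figure is a package choice sitting between the best free-standing
case of the reference gels (~4%) and the "negligible" embedded strains
(≤3.5%); it is configurable. The cell-safety threshold defaults to 80 Pa
(below which reported cell damage is negligible even at long residence
times) and the comparison is inclusive at the boundary.

Printed line width is predicted by the volumetric slicing convention,
`width = flow_multiplier × nozzle_diameter`, independent of print speed —
this is a statement about how piston-driven printers with slicer-imposed
flow rates behave, not a fluid-mechanical die-swell model.
`width_correlations()` checks the same structure on measured tables:
width–nozzle correlation stratified by speed and width–speed correlation
stratified by nozzle. Correlations default to replicate-level data within
each stratum: with only three conditions per stratum, correlating the three
condition means would leave the null distribution of Pearson's $r$
U-shaped (three points), making a "no correlation" verdict meaningless;
`level = "means"` is available for comparison.

## Synthetic data

The generators exist so the entire pipeline is testable with no measured
input. `gen_flow_curve()` draws a Herschel–Bulkley stress curve
$\tau = \tau_y + K\dot\gamma^n$ on a log-spaced grid over 0.01–2000 s$^{-1}$
(the measured span for these gels) with multiplicative lognormal noise,
default CV 2% — a realistic repeatability for a modern rotational rheometer
in this range, and small enough that parameter-recovery tests are meaningful
yet not trivial. `gen_line_width_table()` emulates the line-width design
(nozzles 0.34/0.40/0.47 mm × speeds 7.5/10/20 mm/s × 15 replicates) under
the speed-independent null model with 5% measurement CV, a plausible optical
line-width repeatability. Both are deterministic for a fixed seed and leave
the global RNG state untouched. The generators emulate the *statistical
structure* of the measurements (positive-valued multiplicative noise,
factorial designs), not instrument artefacts such as inertia corrections,
slip, thixotropic history or image segmentation error — so passing recovery
tests demonstrates correctness of the estimators under the stated noise
model, not robustness to every failure mode of real data.

Note on speeds: print speeds are carried in mm/s throughout; the m/s values
occasionally quoted for desktop printers are dimensionally implausible by
three orders of magnitude.

## Problem sizes used in the checks

The shipped test-suite and acceptance computations use the reference
conditions throughout: six gels × (0.4 mm needle) plus four needle radii for
the softest-n gel, 50-point flow curves (200 seeds for the noisy-recovery
study), the ~600-element unit-cell mesh with 400 backward-Euler steps, and
the 3×3×15 line-width design. These sizes were chosen to match the study
conditions; all run in seconds on a single core.
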