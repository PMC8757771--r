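# gelprint

Printability prediction for extrusion bioprinting of shear-thinning
hydrogel inks — peptide gels and similar soft, water-rich materials —
entirely from their rheological fingerprint. For bioprinting and
tissue-engineering labs who want to replace trial-and-error printing with a
desk calculation: can this ink be extruded by this printer, will embedded
cells survive the needle, and will the printed lattice hold its shape or
does it need a sacrificial support bath (bioplotting)?

## What it computes

**Rheology.** Flow-sweep data are fitted to the Ostwald–de Waele power law
η = K·γ̇ⁿ⁻¹ by ordinary least squares in log–log space (slope n − 1,
intercept log K). Yield stress is estimated by a Herschel–Bulkley fit
τ = τ_y + K·γ̇ⁿ. Low-shear moduli (G₀′, η₀) are lumped into a Kelvin–Voigt
solid (spring E in parallel with dashpot η₀) for the collapse model.

**Extrusion flow.** Fully developed power-law pipe flow through the
syringe → taper → needle train: velocity profile
u(r) = ((3n+1)/(n+1))·v̄·[1 − (r/R)^((n+1)/n)], plug-fraction
(1 − 0.95)^(n/(n+1)), Rabinowitsch–Mooney wall shear rate
γ̇_w = ((3n+1)/4n)·8v̄/D with wall stress τ_w = K·γ̇_wⁿ, and pressure drop
Δp = 2τ_w L/R per cylinder (cones by lubrication-approximation quadrature).
Three rheological models are compared (viscosity = K; Newtonian at the
average shear rate 8v̄/D; full power law), with the signed percent modeling
error of the simpler models against the power-law reference.

**Hardware and safety.** Lead-screw piston capacity
F = efficiency·2πT/pitch, available pressure from the duty force over the
piston area, wall-shear cell-safety screen (default threshold 80 Pa) and
needle residence time.

**Collapse.** Transient plane-strain finite-element model of the wood-pile
unit cell as a Kelvin–Voigt solid (σ = C(E,ν):ε + C(η₀,ν):ε̇) under
gravity, backward-Euler in time, with and without a support bath filling the
pores, reporting the monitored corner displacement and final strain.

## Worked example

Fit a synthetic flow sweep of the stiffest reference gel and assess its
printability on the default printer (5-ml syringe, 12 mm bore, 0.4 mm
needle, lead-screw piston drive):

```r
library(gelprint)
fx <- f9_fixtures()

fc  <- gen_flow_curve(K = 41.98, n = 0.02, noise_cv = 0.02, seed = 11)
fit <- fit_power_law(fc)
print(fit)
#> Power-law fluid: K = 41.7 Pa.s^n, n = 0.02048 (R^2 = 1.0000)
#>   shear thinning

report <- generate_report(fit, system = fx$system, hardware = fx$hardware,
                          gel = fx$kv$C30_pH4.9, support = fx$kv$support,
                          cell = fx$cell)
print(report)
#> Printability report
#>   ink: K = 41.7 Pa.s^n, n = 0.02048
#>   required pressure:       9.132 kPa
#>   available pressure:  1.111e+04 kPa -> extrudable
#>   max wall shear stress: 48.9 Pa (threshold 80 Pa) -> cell-safe
#>   residence time in needle: 1.78 s
#>   collapse strain: 1.61% free-standing, 0.118% embedded
#>   recommendation: direct_print
```

Reading the numbers: the shear-thinning ink needs only ~9 kPa of driving
pressure against an available ~11 MPa, so extrusion is trivially feasible;
the wall shear stress in the needle (~49 Pa) stays under the 80 Pa
cell-damage threshold during the 1.8 s transit; and this stiff gel slumps
only 1.6% of its height free-standing, so it prints directly without a
support bath. Re-running with the softest gel (`fx$kv$C20_pH3.7`, E = 30 Pa)
produces a ~40% free-standing strain and the recommendation flips to
`bioplotting_required`.

A thin CLI wraps the same functions
(`inst/cli/gelprint fit|capacity|flow|collapse|report|simulate-data`), with
a ready-made configuration in `inst/extdata/default_printer.yaml`.

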