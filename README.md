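# hemoclear

Structure-aware modeling of hollow-fiber hemodialyzer clearance.

Hemodialysis removes low-molecular-weight uremic toxins — urea, creatinine
and inorganic phosphate — by diffusion across a bundle of hollow-fiber
polymer membranes. `hemoclear` predicts the clearance a dialyzer delivers
from the *structure* of its membrane, for membrane developers and dialyzer
engineers who want to reason about porosity and pore arrangement instead of
purely phenomenological permeabilities.

## The model

**Transport.** Solute transport across the stack
DBL&nbsp;|&nbsp;membrane&nbsp;|&nbsp;DBL (DBL = diffusion boundary layer,
thickness δ = d_hf/3 for a hollow fiber of bore d_hf) is one-dimensional
electro-diffusion with reaction:

- Nernst–Planck fluxes `J_i = -β D_i (∂C_i/∂x + z_i C_i (F/RT) ∂φ/∂x)`
  with β = 1 in solution and β = ξ in the membrane,
- electroneutrality `Σ z_i C_i = 0` and zero current `Σ z_i J_i = 0`
  (the latter eliminates the potential gradient in closed form),
- material balance `∂C_i/∂t = -∂J_i/∂x` plus the homogeneous kinetics of
  the phosphate (`H2PO4⁻ ⇌ HPO4²⁻ + H⁺`, pK 7.184 at 37 °C) and water
  (`Kw = 10⁻¹⁴`) equilibria,

integrated by an explicit Euler scheme (compiled core) under the CFL
stability limit until the membrane fluxes are quasi-steady.

**Structure.** A single-conducting-phase microheterogeneous description
links the measurable structure to transport: porosity from gravimetric
water content, `fp = ρW / (1 + (ρ-1)W)`; diffusion permeability
`P = fp^{1/α} · Ds`, where α ∈ (0, 1] grades the pore arrangement from
random (α → 0) to parallel to the transport axis (α = 1). The factor
`ξ = fp^{1/α}` is the tortuosity coefficient that rescales every solute's
diffusivity inside the membrane.

**Clearance.** The quasi-steady mass-transfer coefficient `L_j = J_j/ΔC_j`
feeds the counter-current fiber-bundle formula

```
CL_j = QA (1 - e^{θ L_j}) / (1 - (QA/QB) e^{θ L_j}),
θ    = -π d_hf N_hf l_hf (1 - QA/QB) / QA,
```

bounded by the blood-side flow `QA`.

**Fitting.** `fit_alpha()` estimates α from permeability-versus-NaCl
concentration curves (log-space least squares); `fit_xi()` estimates the
tortuosity coefficient of a commercial membrane family jointly from
datasheet clearance records. Seeded generators (`synth_permeability()`,
`synth_clearance()`) support parameter-recovery studies.

## Worked example

A 90-fiber laboratory dialyzer (190 µm bore, 140 µm wall, 15 cm fibers,
DBL 63 µm) with a polysulfone/PVP hollow-fiber membrane characterized by
water content 0.73:

```r
library(hemoclear)

membrane_structure(W = 0.73)        # porosity from the water content
#> Membrane structure
#>   water content W: 0.730 (rho = 1.24 g/cm3)
#>   porosity fp:        0.770
#>   ...

membrane <- membrane_structure(fp = 0.77, alpha = 0.083)
spec <- lab_dialyzer_spec()
spec
#> Dialyzer: 90 fibers, dhf 190 um, wall 140.0 um, length 15.0 cm
#>   Smb 80.6 cm2, DBL 63.0 um

ops <- operating_conditions(QA_ml_min = 2, QB_ml_min = 4)
simulate_clearance(membrane, spec, ops, solutes = c("Ur", "Crn"),
                   config = solver_config(horizon_s = 300))
#>   solute       L_cm_s CL_ml_min converged
#> 1     Ur 5.605254e-05 0.2459223      TRUE
#> 2    Crn 3.509195e-05 0.1594947      TRUE
```

The mass-transfer coefficients `L` (cm s⁻¹) are the quasi-steady fluxes per
unit concentration difference; at a feed flow of 2 mL min⁻¹ this membrane
clears about 0.25 mL min⁻¹ of feed of urea and 0.16 mL min⁻¹ of creatinine
— the ordering follows the aqueous diffusivities.

Fitting the pore-arrangement parameter back from a noisy synthetic
permeability characterization:

```r
dat <- synth_permeability(fp = 0.67, alpha = 0.081, noise_cv = 0.05, seed = 42)
fit_alpha(dat, fp = 0.67)
#> Fit of alpha: estimate = 0.0813708 (RSS = 0.004797 over 4 points, ...)
```

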