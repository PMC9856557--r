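---
title: "Modelling ultrasound-triggered nanoparticle drug release: acoustics, bioheat, and DLVO stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ultrasound-triggered nanoparticle drug release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipusdlvo)
```

## The physical problem

Citrate-capped gold nanoparticles (GNPs) carrying a non-covalently bound
doxorubicin payload are colloidally stable because electrostatic
repulsion between the charged particle surfaces outweighs the van der
Waals attraction at all separations: the total interaction potential has
a positive maximum (an *energy barrier*) that thermal motion rarely
crosses. Mild hyperthermia produced by low-intensity pulsed ultrasound
(LIPUS) weakens that barrier in two ways: directly, through the
temperature dependence of the electrostatic term, and indirectly,
because heating reduces the magnitude of the particles' zeta potential.
When the barrier falls to the order of the thermal energy the particles
aggregate and the payload is released.

This package chains three models to predict release for a given
transducer setting:

1. **Acoustics.** The time-harmonic pressure field of a baffled piston
   transducer in an axisymmetric water/tissue domain, from the
   variable-density Helmholtz equation
   $$\nabla\!\cdot\!\Big(\tfrac{1}{\rho}\nabla p\Big) +
     \frac{\omega^2}{\rho c^2}\,p = 0,$$
   with absorption folded into a complex wavenumber
   $k = \omega/c + i\alpha$ and perfectly matched layers (PML) on the
   open boundaries.
2. **Bioheat.** The transient temperature field from the Pennes
   equation in ex vivo mode (zero perfusion and metabolism),
   $$\rho C\,\partial_t T = \nabla\!\cdot\!(k\nabla T) + Q_\mathrm{ext},
     \qquad Q_\mathrm{ext} = 2\alpha I\,\mathrm{Rect}(t),
     \quad I = \frac{|p|^2}{2\rho c},$$
   where Rect(t) is the duty-cycle pulsing of the source.
3. **Colloid stability.** The DLVO potential of the suspension,
   $$V(h) = V_\mathrm{vdw}(h) + V_\mathrm{elec}(h),$$
   with the unretarded sphere–sphere Hamaker form for
   $V_\mathrm{vdw}$ and the linear superposition approximation (LSA)
   for $V_\mathrm{elec}$, valid for $\kappa a < 5$ where $\kappa$ is
   the inverse Debye length and $a$ the particle radius. The barrier is
   the global maximum of $V$ in units of $k_BT$, and release is
   predicted when it is at or below a calibrated threshold
   (default 0.24 $k_BT$, the after-exposure barrier at which release
   was experimentally confirmed).

The coupling is one-way (acoustics → heat → DLVO): media properties are
treated as temperature-independent over the few-degree hyperthermia
range, so the pressure field does not feed back on itself and the
chamber temperature only enters the DLVO stage.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| transducer frequency | Hz | 1e6 | device drive frequency |
| element diameter | m | 24e-3 | active aperture |
| element displacement | m | 24.944e-9 at 8.40 W | calibration point; a piston with this displacement radiates exactly 8.40 W into water |
| acoustic power, duty | W, – | 8.40, 0.5 | the device's release-inducing setting; powers scale the displacement as $\sqrt{P/P_\mathrm{ref}}$ |
| pulse period / insonation | s | 1e-3 / 300 | pulsing period and 5-min exposure |
| attenuation | dB/(cm·MHz²) | water 0.0022, tissue 0.780 | quadratic-in-frequency absorption; converted to Np/m internally |
| GNP radius $a$ | m | 3.7e-9 | half the measured 7.4 nm diameter. The LSA and Hamaker forms are written in the radius; using the diameter here would not reproduce the measured stability |
| Hamaker constant $A_H$ | J | 2.5e-19 | literature average for gold across water |
| zeta potential $\psi_0$ | V | −30.3e-3 before, −15.8e-3 after | measured surface potential of the intact and exposed suspensions |
| ionic strength $I$ | mol/m³ | 0.4052 | citrate-capped GNP suspensions; note the SI unit. The Debye expression $\kappa^2 = 2e^2N_AI/(\varepsilon k_BT)$ takes $I$ in mol/m³ directly; forms quoted with a factor 2000 assume mol/L and must not be combined with mol/m³ inputs, which would double-count the conversion by $10^3$ |
| water permittivity | C²/(N·m²) | $\varepsilon_r(T)\,\varepsilon_0$ | handbook cubic fit for $\varepsilon_r(T)$, 0–100 °C. An explicit `permittivity_override` exists for reproducing analyses that used a different value, but the physical model is the default and is what reproduces the measured stability |
| release threshold | $k_BT$ | 0.24 | calibrated: the after-exposure barrier at which release was observed; `calibrate_threshold()` sets it from a new observation |

## Geometry assumptions

The experiment is idealised as a 2D axisymmetric domain: a piston
transducer at the top of a water tank, a tissue block below it holding
a small water-filled GNP chamber at its centre, and a 3 mm PML on the
outer radial and bottom boundaries. The rectangular tissue block
(60 × 73 × 25 mm³) and chamber (10 × 10 × 5 mm³) are mapped to
cylinders of equal cross-sectional area, which preserves the heated
volume.

Three lengths are genuine assumptions because they are not part of the
published configuration: the tank radius (default 40 mm), the
transducer standoff above the tissue (default 10 mm), and the water
layer between the tissue bottom and the PML (default 10 mm). The tank
radius and bottom layer are benign — enlarging the domain by 50%
changes the chamber pressure maximum by under 2% and the chamber
temperature negligibly. The standoff is not: the chamber sits in the
near field of the 24 mm piston, where the axial interference pattern
moves with the source position, so the simulated chamber mean
temperature depends on the standoff at the degree level. Every report
therefore carries its configuration hash, and results should be quoted
alongside these three values. All of them are configurable through the
`geometry` section.

## Numerical choices

**Acoustic solver.** Second-order finite volumes on the cylindrical
Laplacian, with the axis node regularised by the half-cell flux balance
(equivalently the L'Hôpital limit of the $1/r$ term), harmonic
averaging of $1/\rho$ across material interfaces, and quadratic
complex-coordinate-stretching PMLs terminated by a homogeneous
Dirichlet condition. Three refinements matter at the default five
points per wavelength:

- the mass term uses the modified wavenumber
  $(2/\Delta z)\sin(k\Delta z/2)$ squared, which makes axial plane
  waves dispersion-free;
- the radial couplings are scaled by $\sin(k\Delta z)/(k\Delta z)$,
  which extends that to $O(k_r^4)$ accuracy for near-axial (paraxial)
  waves — the regime of a piston beam;
- the piston row is normalised so that the *discrete* outgoing plane
  wave has amplitude exactly $\rho c\omega d$, and the rim node is
  area-weighted so the effective piston radius is not quantised to
  whole cells.

With these, the on-axis field of a lossless-water piston agrees with
the closed-form Rayleigh solution to within 5% (relative to the window
maximum) beyond the last axial null at 14 points per wavelength, with
on-axis peak amplitudes accurate to a fraction of a percent; the sharp
near-field nulls converge more slowly because their positions shift
with the accumulated phase of oblique edge waves. The complex system is
solved as the equivalent real system of twice the size by a sparse
direct factorisation.

**Bioheat solver.** Symmetric finite-volume conduction operator
(exact axisymmetric cell volumes, harmonic-mean face conductivities)
and implicit Euler stepping with the system matrix Cholesky-factorised
once and reused; the default step is 0.5 s over the 300 s exposure in
duty-averaged mode. Explicit Rect pulsing uses the exact on-fraction of
each step, so the scheme is correct for any step size; sub-millisecond
steps are only needed when the pulsing itself is being resolved. The
discretisation conserves energy exactly in insulated domains and obeys
the discrete maximum principle. The tank boundary (outer wall, bottom,
and top surface) is a Dirichlet condition at the 37 °C bath
temperature; whether the physical bath is better described as Dirichlet
or convective is unknowable from the published setup, so the choice is
a documented default. The chamber contents are water; the GNP volume
fraction is far too small to alter density, heat capacity or
conductivity.

**Mesh rule.** The grid spacing never exceeds one fifth of the
wavelength in the slowest medium (configurable). Material boundaries
snap to the nearest grid line, so interface positions move by up to
half a cell between refinement levels; this makes point quantities such
as the chamber pressure maximum oscillate by a few percent across
resolutions while integral quantities (chamber mean temperature)
are stable at the 0.1 °C level. A finite-element discretisation with
boundary-fitted cells would converge more smoothly; the
finite-difference choice keeps the package dependency-free and every
property that feeds the release prediction is an integral one.

**DLVO engine.** Potentials are evaluated on 2000 log-spaced
separations between 0.1 and 100 nm (configurable); the barrier is the
grid maximum refined by continuous optimisation in the bracketing
interval, with ties broken toward smaller separation, and agrees with a
$10^6$-point brute-force scan to better than $10^{-3}\,k_BT$. The
contact singularity ($h \le 0$) is excluded by validation. A curve that
is attractive everywhere reports `exists = FALSE` and height zero —
aggregation is then unhindered. $k_BT$ normalisation uses each state's
own temperature, and the $\kappa a < 5$ guard rejects parameter sets
outside the LSA's validity rather than silently extrapolating
(the Hogg–Healy–Fuerstenau regime is out of scope).

**Degenerate inputs.** Zero displacement or zero acoustic power gives
an identically zero field and an unheated domain; zero zeta gives zero
electrostatic repulsion; zero-length sweeps return empty tables without
fits; inconsistent duty folding between the intensity field and pulse
schedule is an error rather than a silent double-count.

## What the configuration fixtures emulate — and what they do not

`generate_fixtures()` writes the baseline configuration (tabulated
media and transducer calibration, measured suspension parameters,
documented geometry assumptions) and a reduced coarse configuration for
fast tests. These reproduce the *published study conditions*, not real
tissue in its full complexity: the model is axisymmetric, one-way
coupled, linear (no cavitation, no acoustic streaming, no radiation
force, no nonlinear propagation), monodisperse in particle size, and
purely thermal in its release mechanism. Passing tests therefore show
that the solvers implement the stated equations correctly and that the
stated parameters reproduce the stated stability behaviour — not that
non-thermal release pathways are absent in real exposures, and not that
the unprinted geometry assumptions match the physical apparatus.

## Problem sizes used by the test-suite

Solver unit tests run on a reduced domain (14 mm tank radius, 10 mm
tissue cylinder, 2 mm PML) at five points per wavelength; the Rayleigh
oracle comparison uses 14 points per wavelength on a 23 × 28 mm
domain; the full-pipeline checks use the baseline geometry at five and
seven points per wavelength (about 2.3 × 10⁴ nodes at five); the
explicit-pulsing equivalence check integrates 1 s of exposure at 0.1 ms
steps. These sizes were chosen as the smallest at which each property
is cleanly exhibited.

## Known limitations

- The LSA electrostatic model restricts the parameter space to
  $\kappa a < 5$; strongly screened or large-particle systems need the
  Hogg–Healy–Fuerstenau form, which is not implemented.
- The near-field chamber pressure maximum is sensitive both to the
  unprinted standoff and to grid snapping; it is reported for
  orientation, not as a validated point value. The time-averaged
  intensity can be quoted per cycle or cycle-averaged (the
  `duty_folded` flag); both conventions appear in the literature, and
  reports state which was used.
- Blood perfusion and metabolic heating are carried as structural zeros
  (ex vivo mode); an in vivo prediction would need both, plus drug
  transport after release.
- Aggregation is treated as a threshold event on the barrier height;
  no kinetics (collision rates, fractal growth) are modelled.
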