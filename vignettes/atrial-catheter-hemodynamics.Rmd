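---
title: "Modelling right-atrial haemodynamics around dialysis catheters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling right-atrial haemodynamics around dialysis catheters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Central venous dialysis catheters sit with their tip in the right atrium
(RA), returning filtered blood through a venous lumen and drawing blood away
through an arterial lumen. Their performance is judged by haemodynamic
surrogates: the *recirculation fraction* (how much just-filtered blood is
immediately drawn back into the intake; the design requirement is below 1
percent), the shear-stress burden near the tip (sustained stresses of the
order of 10 Pa can activate platelets and seed thrombosis), and how the
catheter jet alters the chamber's native flow (vorticity, wall shear
stress). `atriaflow` implements a desk-scale version of this analysis: a
transient, generalized-Newtonian, incompressible chamber-flow solver with a
tracked "filtered blood" phase, plus the complete set of derived metrics and
convergence/validation tools, and seeded synthetic generators so every
operator can be tested against analytic ground truth.

## Flow model

Blood is an incompressible generalized-Newtonian fluid with density
$\rho = 1060$ kg m$^{-3}$. The apparent viscosity follows the Bird–Carreau
shear-thinning law

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
  \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2},$$

with $\mu_0 = 0.056$ Pa s, $\mu_\infty = 0.00345$ Pa s, $\lambda = 3.313$ s
and $n = 0.3568$; a Newtonian comparator uses $\mu = 0.004$ Pa s. The law is
finite at $\dot\gamma = 0$ (it equals $\mu_0$ there), so no regularization
is needed and zero shear rate is a valid input. The shear rate entering the
law is identified with the strain-rate magnitude
$|\epsilon| = \sqrt{2\,\epsilon_{ij}\epsilon_{ij}}$,
$\epsilon_{ij} = \tfrac12(\partial_i u_j + \partial_j u_i)$ — the standard
generalized-Newtonian convention, which reduces exactly to the 1-D law
$\tau = \mu(\dot\gamma_0)\,\dot\gamma_0$ for simple shear.

Boundary Reynolds numbers $Re = \rho U D/\mu$ use the patch-averaged
velocity magnitude over one cycle and the patch-and-time-averaged apparent
viscosity; flows with $\max Re < 2300$ are treated as laminar. With the
defaults all chamber boundaries sit well below that threshold.

## The chamber abstraction

The published analyses of this problem run on anatomically realistic 3D
atrium reconstructions for tens of hours on ~100 cores; those absolute
results are out of reach of a desk-scale re-implementation by design. The
package therefore solves an *idealized* chamber that preserves every
modelled mechanism — pulsatile venous inflow, jet–chamber interaction,
phase-fraction transport, all the derived metrics — at verification scale:

* a 2D rectangle (default $8 \times 6$ cm, $h = 2$ mm) with the superior
  and inferior vena cava (SVC, IVC) as inlet slots on one wall and the
  tricuspid valve (TV) as the outlet slot opposite;
* each port carries an out-of-plane depth chosen so its area equals the
  physiological target (SVC diameter 17.06 mm, IVC 16.89 mm, TV area
  9.95 cm$^2$), and the interior slab depth is set so the chamber volume is
  175.27 mL. Continuity is enforced on these depth-weighted fluxes, so port
  flow rates are true volumetric flows (ml/min) while the interior solve
  remains a standard 2D projection;
* the catheter is represented by boundary source/sink patches rather than a
  resolved solid — a venous jet patch whose prescribed speed is the lumen
  flow over the lumen area ($400$ ml/min over $7.8$ mm$^2 \approx 0.855$
  m/s for the symmetric design), an arterial sink at the design's operating
  flow, and, for the step design with side holes, venous sub-patches that
  split the flow (default: half through the end hole). Tip placements are
  defined by their described relations: `position1` mid-chamber,
  `position2` translated toward the wall, `position3` mirrored about the
  tip axis (asymmetric designs only). Reverse mode swaps the venous and
  arterial port ordering.

Only the 2D chamber is solved; 3D analytic fields are fully supported by
the metric operators and synthetic generators, which is where the
third dimension actually matters for verification (helicity, curl
identities).

## Boundary conditions

The venous inlets carry a two-peaked periodic pressure waveform (a- and
v-wave morphology) over a 0.8 s cardiac cycle split into 0.5 s diastole and
0.3 s systole, spatially uniform, with a default mean of 3 mmHg (the normal
RA mean) and 2 mmHg pulse amplitude; users can supply a sampled waveform as
CSV instead. Because a pure pressure-driven formulation is under-determined
without the full 3D geometry, inlets are velocity-driven by default: the
waveform pressure maps to inflow velocity through a configurable linear
admittance (default $5\times10^{-4}$ m s$^{-1}$ Pa$^{-1}$). The TV outlet
absorbs the instantaneous volumetric imbalance — with rigid walls all
inflow must leave through the valve at every instant, which makes the
pressure projection exactly compatible and gives discrete mass balance to
round-off. The wall is no-slip; pressures are gauge, referenced to the
outlet.

## Numerics

The solver is a fractional-step (projection) method on a staggered (MAC)
grid:

* **advection** first-order upwind, **diffusion** explicit with the
  cell-wise apparent viscosity. An implicit diffusion solve would buy
  nothing here: at chamber scales the diffusive stability limit
  ($\sim h^2/\nu$) is orders of magnitude above the advective CFL limit
  that binds the step anyway, and the variable-viscosity matrix would need
  re-assembly every step. A single stability number
  $\max(\text{CFL}, \tfrac{16}{3}\nu\,\Delta t/h^2)$ is capped (default
  0.45); steps exceeding it are subdivided automatically (or abort if
  adaptivity is disabled).
* **pressure projection** by a direct sparse Cholesky solve of the cell
  Laplacian (gauge pinned at one cell), factorized once per geometry;
  continuity residuals are checked against the $10^{-4}$ tolerance every
  step and in practice sit at round-off.
* **no-slip walls** use quadratic ghost cells,
  $u_g = (u_2 - 6u_1)/3$, which impose the zero wall value to second
  order. With linear ghosts the discrete steady channel solution carries an
  $O(h^2)$ offset that degrades the wall-shear gradient to first order;
  with quadratic ghosts the discrete plane-Poiseuille solution reproduces
  the analytic parabola at the nodes, and the verification errors below are
  pure quadrature.
* **phase fraction**: the published two-phase (filtered vs unfiltered
  blood) model uses two Eulerian phases with *identical* material
  properties, which is exactly a single-momentum flow plus one advected
  bounded scalar $\phi_r$ — sourced at 1 on the venous patch, 0 at the
  SVC/IVC, free outflow elsewhere. Transport uses dimensionally split
  sweeps: first-order upwind in a non-conservative convex form (provably
  bounded for any face velocities), optionally sharpened by a van
  Leer-limited antidiffusive correction that is flux-limited cell-wise
  (Zalesak) so the result stays within local bounds and hence in $[0,1]$;
  only floating-point round-off is clipped. The sweep order alternates each
  step.
* time step defaults: 0.005 s single-phase, 0.001 s with phase tracking;
  4 cycles are run and the last is the analysis cycle.

Determinism: the solver has no stochastic elements; a seed is still carried
in the settings (and drives every synthetic generator), so identical
configurations reproduce runs bit for bit.

## Derived metrics

* **Vorticity** $\omega = \nabla\times u$ and kinetic helicity density
  $u\cdot\omega$ (identically zero for planar fields) by central
  differences, second-order one-sided at edges. The helicity definition is
  a package choice (the field literature sometimes uses relative helicity);
  it serves visualization support only.
* **Wall shear stress**: one-sided second-order wall gradient of the
  tangential velocity, $u'(0) = (9u_1 - u_2)/(3h)$, times the apparent
  viscosity at the wall shear rate; exact for parabolic profiles.
* **Recirculation fraction**: per arterial-patch facet the time-averaged
  phase fraction $\bar\phi_k = \frac1T\int_0^T \phi_r\,dt$ and mass flow
  $\dot m_k = \rho(u_k\cdot A_k)$, combined as the mass-weighted average
  $R_f = \frac{1}{\dot m_T}\sum_k \bar\phi_k\,\dot m_k$ in percent. The
  facet monitor is recorded every step (snapshots at an output stride would
  alias the cycle). $R_f$ is exactly invariant to density rescaling and
  facet reordering.
* **Tip shear burden**: volume-averaged $\bar\tau = \frac1V\int \tau\,dV$
  over a rectangular prism anchored at the venous tip (per-design prism
  dimensions; for the side-hole design the prism encloses all orifices),
  and the prism-volume percentage with $\tau \ge 10$ Pa, a
  platelet-activation surrogate. The threshold comparison is taken as
  $\ge$; the difference against a strict inequality is measure-zero on
  continuous fields and untestable.
* **Time averages** use the trapezoid rule over exactly one cycle (the last
  full cycle when a series is longer); Pearson correlations use the
  standard sample estimator and error on zero-variance input; percent
  changes are signed, $(v - r)/|r|\cdot 100$.

## Convergence and validation

Cycle-to-cycle (temporal) convergence and mesh convergence both use the
relative error $E = |(v_B - v_L)/v_L|\cdot 100\%$ against a reference
solution (last cycle, finest mesh). Mesh acceptance uses the thresholds
established for this class of chamber model: below 0.5 % for surface
averaged WSS and below 3 % for a probe velocity. Literature validation
bands (volume-averaged velocity $0.174\pm0.027$ m/s, vorticity 37–54
s$^{-1}$, mean RA pressure 0–5 mmHg) are *reported* against, never
asserted: a 2D desk-scale chamber is not expected to land inside clinical
bands, and `validate_bands()` flags rather than fails.

`recompute_supplementary()` reads per-timestep series tables (CSV; the
schemas mirror the published supplementary spreadsheets, whose exact
internal layout is not printed — hence the explicit column contract and
named schema errors) and recomputes the summary statistics: per-cycle
convergence errors, WSS–vorticity Pearson correlation (full series or one
cycle — both are exposed because the published choice is not stated),
cycle-averaged vorticity, flow-rate maxima and per-model tip shear. XLSX
originals are accepted after CSV conversion.

## Synthetic data: what it shows and what it does not

The generators produce every input class with known ground truth:
analytic fields (plane Poiseuille, rigid rotation, Taylor–Green, uniform
jet, simple shear, 3D ABC/Beltrami eigenfields, seeded random linear
fields) for the differential operators; outlet phase patterns with a
planted recirculation fraction (mass-weighted zero-sum perturbations plus
zero-time-mean oscillations, so the planted value is recovered to
round-off); multi-cycle series with exactly planted per-cycle errors; and
pairs with exactly planted Pearson correlation (Gaussian mixing with
orthogonalization). Supplementary-schema mocks plant the published summary
statistics so the full reader-plus-statistics path is round-trip testable —
they are labelled synthetic and demonstrate the *recomputation machinery*,
not the published CFD fields themselves.

Passing these tests shows the operators are implemented correctly and the
solver converges on problems with known solutions. It does not show that a
2D idealized chamber reproduces patient haemodynamics: no valve motion, no
wall motion (both acknowledged limitations of even the full 3D rigid-wall
model), no anatomical geometry, and absolute per-design metric values at
desk scale are indicative only. Comparative trends (e.g. step-tip reverse
mode recirculating more than a symmetric tip) are the meaningful output.

## Problem sizes and tolerances used by the test-suite

Chosen as the package's verification scale: channel verification at 8, 16
and 32 cells across the gap (flow-rate and WSS errors at 16 cells are
≈0.2 % and ≈4×10⁻⁵, halving the grid improves errors by ≈4×); chamber runs
at $40\times30$ (default) or $20\times15$ cells for one cardiac cycle;
Taylor–Green operator convergence at $32^2$ vs $64^2$; curl identities on
$16^3$ 3D grids; planted-statistics recovery at $n = 1000$. Continuity
residual tolerance $10^{-4}$ (direct solves land near machine precision);
planted-value recoveries asserted at $10^{-9}$; closed-form operator
identities at $10^{-10}$ or tighter.

## Worked example

```{r example}
library(atriaflow)

geom <- chamber_geometry()
wave <- build_default_waveform()
run <- solve_transient(geom, fluid_properties(), wave,
                       catheter = catheter_config("D"),
                       settings = solver_settings(n_cycles = 2))
summary(run)
recirculation_fraction(run$arterial_monitor)
tip_statistics(run)$tau_bar_avg
```

## Known limitations

Two-dimensional chamber (no out-of-plane mixing); no tricuspid-valve
function, atrial contraction or fluid–structure interaction; catheter as
boundary patches, not a resolved solid; velocity-driven inlet mapping in
place of pure pressure boundaries; first-order momentum advection.
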