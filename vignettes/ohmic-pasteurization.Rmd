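---
title: "Modelling ohmic pasteurization: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ohmic pasteurization: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohmicheat)
```

## The model

`ohmicheat` simulates pasteurization of a solid cylindrical food heated by
the direct passage of electric current. Three submodels are coupled:

**Electrics.** On the timescale of the thermal transient the electric field
is quasistatic: at every instant the potential satisfies
$\nabla \cdot (\sigma(T)\, \nabla V) = 0$ with $V = V_0$ on one electrode,
$V = 0$ on the other, and no normal current through the lateral surface.
The dissipated power density is $Q = \sigma |\nabla V|^2$. Because
$\sigma$ rises steeply with temperature (for mashed potato it grows
3.5-fold between 5 and 85 °C), heating accelerates as the sample warms,
and any spatial temperature nonuniformity redistributes the source: along
the current path (axially) a cold layer dissipates *more* (fixed current
density, $Q = J^2/\sigma$), while across parallel paths (radially) a cold
ring dissipates *less* (fixed field, $Q = \sigma E^2$).

**Thermal.** The heat balance is
$\mathrm{VHC}(T)\, \partial T/\partial t = \nabla\cdot(\lambda(T)\nabla T) + Q$,
where VHC is the volumetric heat capacity $\rho C_p$ (measured as a
product; the factors are never needed separately). Boundaries are either
perfectly insulated or exchange heat by Newton cooling
$q = U (T - T_\infty)$, with $U$ an *overall* coefficient lumping the cell
wall, electrode backing and external convection. Losses act on all
exterior faces (both electrode ends and the lateral surface) by default:
reported cold areas at the electrode/lateral junctions imply both surface
families leak. Each family can be disabled individually since the true
split is apparatus-specific.

**Microbial.** Inactivation follows first-order (log-linear) kinetics.
A form of the population balance sometimes printed in the literature,
$dN/dt = 2.303\,D\,N$, is dimensionally inconsistent (it would grow, and
$D$ belongs in the denominator); we implement the decay
$dN/dt = -(\ln 10 / D(T))\,N$, which integrates exactly to
$\log_{10}(N_0/N) = F/D_\mathrm{ref}$ with
$F(t) = \int_0^{t} 10^{(T - T_\mathrm{ref})/z}\,dt$. $F$ is accumulated per
cell, and the cell of minimum $F$ — not the instantaneous minimum
temperature — defines the cold spot, because pasteurization credit is the
time integral, not a snapshot.

## Discretisation

The geometry, loading and boundary conditions are rotationally symmetric,
so the solution is too; the solver therefore works on the 2-D $(r, z)$
half-section with annular finite volumes ($2\pi r\,\Delta r\,\Delta z$,
exact at mid-point radii). Design choices:

* **Harmonic-mean face conductivities** for both $\sigma$ and $\lambda$:
  flux continuity is preserved across property jumps, and the scheme is
  nodally exact for piecewise-constant 1-D profiles (the two-layer
  series-resistor test exploits this).
* **Energy-consistent Joule reconstruction.** $Q$ is rebuilt from the face
  fluxes so that each internal face contributes half of
  $G\,(\Delta V)^2$ to both neighbours and each electrode face its full
  half-cell dissipation. The volume integral of $Q$ then equals the
  electrode power $V_0 I$ identically, which the test suite checks to
  $10^{-8}$ relative for arbitrary positive conductivity fields.
* **Backward Euler with lagged coefficients.** Properties are frozen at
  the step's start temperature; at the default $\Delta t = 0.5$ s the
  per-step temperature change (a few tenths of a kelvin) makes the
  associated linearisation error negligible, and the implicit step is
  unconditionally stable. An optional within-step fixed-point iteration
  (tolerance $10^{-3}$ K, for convergence studies) changes the default
  results by less than 0.05 K.
* **Robin faces in series.** The boundary conductance combines $U$ with
  the half-cell conduction path, $G = A/(1/U + \tfrac{d}{2}/\lambda)$, so
  refining the mesh does not change the physical surface resistance.
* **Direct sparse solves** (`Matrix`) of the two symmetric
  positive-definite systems per step; both satisfy discrete maximum
  principles, and the per-step energy balance closes to solver precision
  (the `energy_audit()` function exposes this as a runtime check).
* **Boiling guard.** The property table and the single-phase model are
  invalid past 373.15 K, so any cell crossing it aborts the run with an
  explicit error rather than extrapolating into nonsense.

Coupling is loose — one potential solve per thermal step — because the
quasistatic field adapts instantly and the property drift per step is
small.

## Parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| applied voltage $V_0$ | 100 V (RMS-equivalent) | reference drive of the modelled process |
| initial temperature $T_0$ | 279.15 K | refrigerated sample |
| process time / step | 150 s / 0.5 s | reference process window; $\Delta t$ is a convergence knob |
| grid | 16 × 16 | doubling the grid and halving $\Delta t$ moves the externally cooled end state by < 0.2 K (tested) |
| cylinder | radius 0.010 m, gap 0.20 m | assumed laboratory cell, see below |
| $U$ | 0 (insulated) / 5 / 15 W m⁻² K⁻¹ | insulated ideal; 5 is the experimentally fitted value, 5–10 the typical range; 15 a deliberately lossy case |
| $T_\infty$ | 286.15 K or 314.15 K | cold vs warm surroundings |
| kinetics | $z = 10$ °C, $D_\mathrm{ref} = 60$ s at 60 °C, target 12D | see below |

**The assumed cell.** The dimensions of the laboratory cell this model
emulates are not published, so the geometry is this package's calibrated
assumption, chosen once against the behaviour that *is* reported for such
cells: the 150 s reference
process must stay below boiling, all seven scenario 12D times should land
in a plausible 50–600 s band, a ±10 % conductivity change must move the
12D time by about ∓10 %, and strong losses into cold air (C6) must be the
slowest case of all seven. The last constraint is the discriminating one:
the corner lethality deficit that delays C6 grows roughly with the square
root of process time, so short fat cells under-weight surface losses. A
0.010 m × 0.20 m cell (field 500 V m⁻¹) satisfies all four; users with a
real apparatus should override `cylinder_geometry()`. Absolute 12D times
depend on this assumption — the relative scenario comparisons do not.

**Kinetics references.** Only the z-value (10 °C) of *E. coli* O157:H7 is
fixed by the scenario definitions; $D_\mathrm{ref}$ and $T_\mathrm{ref}$
are free inputs. We default to $D = 60$ s at 60 °C, the classic
literature magnitude for this organism in solid foods, and keep both
configurable. Scenario orderings and percent changes are insensitive to
this choice; absolute 12D times scale with it.

## Drive modes

Constant voltage holds $V_0$ fixed, so total power grows as the sample
warms. Constant power rescales $Q$ each step to a set point (reporting the
equivalent voltage $V\sqrt{P_\mathrm{target}/P}$); by default the set
point is the first step's power. For the classical comparison of the two
drives the interesting case is *energy-matched*: a constant generation
equal to the constant-voltage run's mean power delivers the same total
energy, hence (insulated) essentially the same final temperature, along a
measurably different path — constant power runs hotter early, constant
voltage catches up late. A constant-power run pinned at the *initial*
power cannot reproduce that equivalence, since the constant-voltage drive
delivers far more energy over the window; the acceptance script therefore
uses the energy-matched target.

## Scenarios and cold-spot classification

`builtin_cases()` defines the seven sensitivity cases: C1 insulated
control, C2/C3 conductivity ±10 %, C4/C5 moderate losses
($U = 5$ W m⁻² K⁻¹) into cold/warm air, C6/C7 strong losses ($U = 15$)
into cold/warm air. `run_suite()` extends each run past the base process
time until the minimum log reduction reaches 12 (cap 3600 s) and reports
the 12D time, its percent change against C1, and the cold-spot class.

Classification uses the accumulated-lethality field: a relative spread
below 1 % is **uniform** (for an ideally insulated cell no colder area can
meaningfully be identified — with a uniform start the field is uniform to
round-off); otherwise a minimum in the outermost radial ring within the
outermost ⅛ of axial layers is an **exterior corner** (electrode/lateral
junction), and a minimum in the innermost ring is **on-axis**. Warm
surroundings above the sample's early temperature first warm the shell and
only late in the run start draining it, which is why the warm-air cases
keep their lethality minimum on the axis while cold-air cases pin it to
the corner.

## Verification

The test suite exercises each layer against an independent oracle rather
than against itself:

* potential: exact linear and two-layer closed forms, a dense 1-D
  finite-volume oracle, grid convergence on a smooth-conductivity profile,
  current conservation and the $V_0 I$ power identity on random fields;
* thermal: exact equilibrium and lumped-rise identities, the small-Biot
  exponential cooling limit, maximum principles, per-step energy closure;
* kinetics: closed-form D/F identities and a stiff ODE integration of the
  survivor equation;
* coupled: the insulated PDE run against the 0-D lumped ODE
  $\mathrm{VHC}(T)\,dT/dt = \sigma(T)(V_0/L)^2$ (agreement within 0.2 K
  over the 150 s window at 16 × 16), the conductivity time-scaling law
  (scaling $\sigma$ by $c$ scales all times by $1/c$), and the
  energy-matched drive comparison.

What passing these tests does *not* show: the property table is a 5-point
piecewise-linear model of one food (interpolation behaviour between and
beyond the measured points is our choice — linear with clamped
extrapolation — not data); electrode contact impedance, evaporation,
moisture migration and non-thermal inactivation effects are all outside
the model; and the absolute 12D times inherit the assumed geometry and
kinetics reference discussed above. Problem sizes throughout (16 × 16
cells, $\Delta t = 0.5$ s, one 32 × 32 refinement check) are the package's
accuracy/cost compromise, supported by the convergence tests.
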