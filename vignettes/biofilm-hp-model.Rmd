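---
title: "A one-dimensional model of biofilm tolerance to continuous hydrogen peroxide dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A one-dimensional model of biofilm tolerance to continuous hydrogen peroxide dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system

`biofilmHP` simulates a glucose-limited biofilm growing on a surface of
area $A$ inside a continuous stirred-tank reactor of volume $V$ fed at
flow rate $Q$, while hydrogen peroxide (HP) is dosed through the
influent. The film is treated as one-dimensional: every state variable
depends only on the height $z$ above the substratum, $0 \le z \le
L_f(t)$, and the film thickness $L_f$ itself is a dynamic variable.

Two *particulate* components (live biomass $L$ and dead biomass $D$,
concentrations $X$, g/m$^3$) and two *solutes* (glucose $G$ and HP $H$,
concentrations $S$, g/m$^3$) are tracked both in the tank and across
the film. The kinetics are deliberately minimal:

* live biomass grows at the Monod rate
  $\mu(S_G) = \mu_{max} S_G/(K_M + S_G)$, consuming glucose at yield
  $Y_{GL}$;
* HP kills live cells at a first-order rate $k_{dis} S_H X_L$,
  converting them to dead biomass with no loss of mass;
* both live **and dead** biomass neutralize HP (catalase-type
  disproportionation does not require a viable cell):
  $R_{S:H} = -(k_{B:L} X_L + k_{B:D} X_D) S_H$.

The last point is the scientific heart of the model. Dead cells at the
top of the film keep destroying the biocide, shielding the living
stratum beneath; growth below continuously resupplies the shield. This
feedback makes the dose response sharply non-linear: a film can persist
(indeed thicken) under doses orders of magnitude beyond what kills
suspended cells, until a threshold concentration collapses it entirely.

## Governing equations

Tank balances (well-mixed CSTR):
$$\frac{dX_{t:j}}{dt} = -\frac{Q}{V}X_{t:j} + J_{det:j}\frac{A}{V} + R_{X:j},
\qquad
\frac{dS_{t:k}}{dt} = \frac{Q}{V}(S_{in:k}-S_{t:k}) + J_{dif:k}\frac{A}{V} + R_{S:k}.$$

The influent HP concentration $S_{in:H}(t)$ is piecewise constant: 0
before `time1`, `dose1` on `[time1, time2]`, `dose2` afterwards.
Detachment releases particulates from the film surface at
$J_{det} = v_{det} X_b|_{z=L_f}$ with $v_{det} = K_{det} L_f^2$.

Inside the film, particulates are advected by the growth velocity and
solutes diffuse and react:
$$\frac{\partial X_{b:j}}{\partial t} = -\frac{\partial (v X_{b:j})}{\partial z} + R_{X:j},
\qquad
\frac{\partial S_{b:k}}{\partial t} = D_{b:k}\frac{\partial^2 S_{b:k}}{\partial z^2} + R_{S:k},$$
with zero-gradient conditions at the substratum and, for solutes, a
flux-matching condition at the surface: the in-film diffusive flux
equals the flux through a stagnant boundary layer of thickness $L_L$
with the aqueous diffusivity. The growth velocity accumulates the
volumetric biomass production below each height,
$$v(z) = \int_0^z \frac{1}{P_{tot}} \sum_j \frac{R_{X:j}}{\rho_j}\,dz',
\qquad P_{tot} = \sum_j X_{b:j}/\rho_j,$$
and the thickness obeys $dL_f/dt = v(L_f) - v_{det}$.

Because $v$ divides by $P_{tot}$, the total particulate volume fraction
is a material invariant: it stays at its seeded value (0.08) in every
cell at all times. This is the single most sensitive correctness check
of the spatial scheme, and the test suite enforces it to $10^{-3}$
relative.

## Parameters

All defaults are the standard base case (units m, day, g/m$^3$):
$\mu_{max} = 9.6$/d, $K_M = 5$ g/m$^3$, $Q = 1$ m$^3$/d, $V = 0.1$
m$^3$, $A = 1$ m$^2$, $k_{dis} = 0.5$ per (g/m$^3$) per day,
$Y_{GL} = 0.26$, $S_{in:G} = 100$ g/m$^3$, $k_{B:L} = k_{B:D} = 10$,
$\rho_L = \rho_D = 2.5\times 10^5$ g/m$^3$, film diffusivities
$D_{b:G} = 1.3\times10^{-5}$, $D_{b:H} = 6.52\times10^{-5}$ m$^2$/d,
aqueous diffusivities $5.2\times10^{-5}$ and $1.09\times10^{-4}$
m$^2$/d, $L_L = 10$ µm, $K_{det} = 10^4$ /(m·d), $L_f^0 = 50$ µm,
seeded live volume fraction 0.08. The dilution rate $Q/V = 10$/d
exceeds $\mu_{max}$, so suspended cells wash out of the tank unless
resupplied by detachment — the tank population is biofilm-derived.

A note on units of $k_B$: the neutralization law is implemented exactly
as written above, so $k_B$ carries units of per (g biomass/m$^3$) per
day — that is what makes $R_{S:H}$ come out in g$_H$/m$^3$/d. The
printed unit "(g$_H$/m$^3$)$^{-1}$/d" seen for this coefficient in
standard tabulations is not dimensionally consistent with the rate law;
the numeric values are used as given.

## Numerical method

The moving domain is mapped onto the fixed normalized coordinate
$\zeta = z/L_f \in [0,1]$ with $N_z = 50$ uniform finite-volume cells,
so the ODE system keeps a fixed size (5 + 4$N_z$ states) while the
physical domain moves. The chain rule introduces a grid-motion
advection $\zeta\, \dot L_f\, \partial_z(\cdot)$; for particulates it
is folded into a conservative upwind flux at the velocity *relative to
the grid*, $w = v - \zeta \dot L_f$, plus a uniform dilation term
$-X \dot L_f/L_f$; for solutes it is applied as an upwinded
one-sided difference (it vanishes at steady state). First-order upwind
was chosen for particulates because it preserves positivity and the
profiles of interest are smooth at this resolution; the companion
refinement test shows the steady thickness changes by well under 1%
between $N_z = 50$ and 200. The solute second derivative is the
standard central three-point stencil; the surface cell closes with a
Robin condition obtained by equating the half-cell in-film flux to the
boundary-layer flux, which also yields the film–tank exchange flux
$J_{dif}$ used in the tank balance.

Integration uses `deSolve::lsodar` (adaptive, automatic stiff/non-stiff
switching) with `rtol` $=10^{-6}$ and per-component absolute
tolerances: $10^{-6}$ g/m$^3$ on concentrations and $10^{-10}$ m on
$L_f$. A single scalar `atol` either over-resolves the solutes or
under-resolves the thickness, and near film collapse (where
$D/\Delta z^2$ diverges as $\Delta z \to 0$) scalar tolerances caused
error-test thrashing; the split tolerance integrates cleanly through
collapse. The horizon is partitioned at the dosing switch times so the
integrator never steps across the influent discontinuity. Rate laws
evaluate concentrations clamped at zero so transient solver undershoots
cannot flip reaction directions; the state itself is never mutated.

Two thickness guards: a floor of $10^{-8}$ m in the right-hand side
avoids the $1/L_f$ singularity, and a root function terminates the
integration the moment $L_f$ crosses $10^{-6}$ m (1 µm) — far below
any surviving steady state — which is reported as *eradicated*, a
normal terminal outcome.

Steady state is declared when both the thickness and the areal live
biomass change by less than $10^{-3}$ (relative) over the final 10% of
the horizon; otherwise the horizon doubles, capped at 2000 d. The cap
matters: the dead fraction near the film base equilibrates on a
timescale of hundreds of days, so stratification metrics (mean live
fraction, interior profiles) are read from 2000-day runs, while the
thickness itself settles within a few days.

## Scenarios, sweeps and thresholds

The named cases map onto schedule/parameter overrides: no dosing;
continuous 500 g/m$^3$ from day 2; a 4-day pulse; a continuous-dose
sweep; the two neutralization knockouts ($k_{B:L}=0$, $k_{B:D}=0$); and
an influent-glucose sweep. "Continuous" is expressed as
`dose2 = dose1`, so treatment never switches off — for any horizon the
trajectory is identical to one with `time2` beyond the horizon, and it
keeps the pulse case as the only place `time2` matters.

Sweeps restart every point cold from the standard initial condition
(each dose is an independent experiment, not a continuation), which
also makes every point exactly reproducible in isolation. Threshold
searches bisect the axis down to a fixed resolution — 100 g/m$^3$ on
dose axes, 1 g/m$^3$ on the glucose axis — and return the bracket
midpoint. One subtlety: the "thicker than baseline" predicate is
non-monotone over the full dose axis (equality at dose 0, eradication
at high dose), so its bracket must start inside the thickened regime;
the standard 500 g/m$^3$ dose is used as the lower end.

## Operational definitions

Several reported quantities have no unique operational definition, and
the package fixes them as follows:

* **Percent live / mean live volume fraction** — the depth-average of
  $X_L/(X_L + X_D)$ over the cells, uniformly weighted in $\zeta$,
  expressed in percent. Because $P_{tot}$ and the densities are
  constant this coincides with the areal live share.
* **Log reduction at steady state** — $\log_{10}$ of untreated over
  treated *areal* live biomass ($\int X_L\,dz$), reference being the
  undosed steady state.
* **Log reduction after one day of treatment** — $\log_{10}$ of the
  *mean viable concentration* ($\frac{1}{L_f}\int X_L\,dz$) at dose
  onset over its value one day later. The areal quantity is unusable
  here: the film thickens during the first treatment day, so areal live
  biomass *rises* even while the viable fraction falls; the
  concentration-based ratio is the definition that measures killing.
* **Penetration depth** — depth below the film–liquid interface at
  which a solute first falls under 5% of its top-cell value, linearly
  interpolated between cell centers (configurable threshold).
* **Mean bulk concentration** — trapezoidal time-average of a tank
  solute; windows that begin at the dosing onset should be sampled
  densely (the bundled scripts use 0.01 d) because the tank HP
  transient after switch-on is fast.

## What the scenario generator does and does not emulate

All inputs are synthetic by construction — the study *is* a simulation
campaign and no external data exists. The default parameter set defines
the study conditions; runs at those defaults emulate a mesotrophic,
rapidly dividing, catalase-positive film under aggressive dilution.
What the model deliberately omits: induction of extra catalase under
oxidative stress (an adaptive response that would only increase
tolerance), dormancy/persister physiology, attachment of suspended
cells to the film, EPS as a separate phase, and any lateral structure.
Passing tests therefore demonstrate internal correctness of the stated
model, not fidelity to any particular organism; the mechanism
(dead-biomass neutralization sustaining a protected growing stratum) is
the claim under test.

## Worked example

```{r example}
library(biofilmHP)

p <- biofilm_params()
untreated <- run_to_steady_state(p, dose_schedule())
dosed <- run_to_steady_state(p, dose_schedule(dose1 = 500, dose2 = 500),
                             t_init = 100, t_cap = 2000)
steady_state_metrics(untreated)
steady_state_metrics(dosed,
  reference_live = areal_biomass(biofilm_state(untreated))[["live"]])

# threshold dose beyond which the film no longer out-grows baseline
find_threshold("thicker_than_baseline", axis = "dose",
               lo = 500, hi = 20000, resolution = 100)$threshold
```

## Problem sizes and runtime choices

The production resolution ($N_z = 50$) integrates a century of model
time in a few seconds. The bundled test-suite and the acceptance script
use: 100-day horizons for thickness-level quantities, one 2000-day run
for stratification metrics, a 200-cell refinement run, and bisections
of about ten steady-state runs each. These sizes were chosen as the
smallest at which the reported quantities are converged (grid
refinement < 1%, horizon doubling criterion met), and they keep the
full campaign in the minutes range on one core.

## Known limitations

* First-order upwinding smears steep particulate fronts at the
  resolution used; quantities tied to front position (e.g. the exact
  collapse dose) inherit a few-percent discretization sensitivity.
* Near the eradication threshold the outcome depends on the horizon
  cap: a film that is still slowly declining at 2000 d is reported as
  surviving. The threshold bracket, not the point value, is the robust
  statement.
* The model has no representation of biofilm mechanical failure,
  sloughing, or chemical attack on the matrix — detachment is smooth
  erosion only.
* Tank biomass kinetics use the same rate laws as the film; at high
  doses the suspended population is annihilated within minutes of
  model time, which is why the stiff integrator is not optional.
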