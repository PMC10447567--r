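# biofilmHP

Why does a biofilm survive — and even thicken — under continuous dosing
with hydrogen peroxide (HP) at concentrations that sterilize planktonic
cultures within minutes? `biofilmHP` is an R package that answers this
with a one-dimensional dynamic model of a live/dead biofilm in a
continuous stirred-tank reactor. Its central mechanism is
viability-independent catalase activity: dead cells at the film surface
keep neutralizing the biocide, forming a reactive shield over a
protected growing stratum that continuously resupplies the shield. The
model predicts a sharply non-linear dose response with a distinct
threshold concentration for film elimination, which is the practically
relevant output for disinfection and biofouling control.

## The model

State variables: tank concentrations of live/dead biomass
$X_{t:L}, X_{t:D}$ and glucose/HP $S_{t:G}, S_{t:H}$; film profiles
$X_b(z), S_b(z)$ on $0 \le z \le L_f(t)$; and the film thickness $L_f$.

Kinetics (identical in tank and film):

- growth: $\mu(S_G) = \mu_{max}\,S_G/(K_M + S_G)$, glucose consumed at
  yield $Y_{GL}$;
- disinfection: live → dead at rate $k_{dis} S_H X_L$ (mass conserved);
- neutralization: $R_{S:H} = -(k_{B:L} X_L + k_{B:D} X_D)\,S_H$ — dead
  biomass destroys HP too;
- transport: solute diffusion with a boundary-layer (Robin) surface
  condition; particulate advection at the growth velocity
  $v(z) = \int_0^z P_{tot}^{-1} \sum_j R_{X:j}/\rho_j\,dz'$;
- thickness: $dL_f/dt = v(L_f) - K_{det} L_f^2$.

The moving film is mapped to a fixed normalized coordinate with 50
finite-volume cells and integrated with a stiff solver
(`deSolve::lsodar`, with an implicit Runge-Kutta fallback through film
collapse). See the methods vignette
(`vignettes/biofilm-hp-model.Rmd`) for the full equations, numerical
choices and operational definitions.

## Worked example

```r
library(biofilmHP)

p <- biofilm_params()                       # standard parameter set
untreated <- run_to_steady_state(p, dose_schedule())
m_u <- steady_state_metrics(untreated)
m_u
#> Steady-state thickness:     142.5 um
#> Areal biomass (live|dead):  2.85 | 0 g/m2
#> Mean live volume fraction:  100.0 %
#> Penetration (glucose|HP):   38.2 | 0.0 um
#> Tank solutes (G|HP):        24 | 0 g/m3

dosed <- run_to_steady_state(p, dose_schedule(dose1 = 500, dose2 = 500),
                             t_init = 100, t_cap = 2000)
steady_state_metrics(dosed, reference_live = m_u$areal_live)
#> Steady-state thickness:     181.0 um
#> Areal biomass (live|dead):  2.04 | 1.58 g/m2
#> Mean live volume fraction:  56.4 %
#> Log reduction vs reference: 0.145
#> Penetration (glucose|HP):   58.4 | 56.0 um
#> Tank solutes (G|HP):        70.3 | 43.8 g/m3
```

Reading this: the untreated film settles at 142.5 µm, fully viable,
with glucose depleted below the top ~38 µm. Under continuous 500 g/m³
HP the film does not die — it grows to 181 µm, keeps 56% of its volume
alive in an interior stratum, and the cumulative kill is a mere 0.145
log. Because killed surface cells consume less glucose, the bulk
glucose rises (24 → 70 g/m³) and the nutrient penetrates deeper
(38 → 58 µm).

Threshold behavior:

```r
# dose beyond which the film no longer out-grows the untreated baseline
find_threshold("thicker_than_baseline", axis = "dose",
               lo = 500, hi = 20000, resolution = 100)$threshold
#> [1] 3432.617

# knock out dead-cell neutralization and a tiny dose kills the film
run_to_steady_state(biofilm_params(k_B_D = 0),
                    dose_schedule(dose1 = 200, dose2 = 200))$eradicated
#> [1] TRUE
```

Scenario runners (`run_case("A")` … `run_case("G")`), sweeps
(`dose_sweep()`, `neutralization_sweep()`), serialization
(`write_timeseries()`, `write_profiles()`, `write_metrics()`) and
figure functions (`plot_thickness()`, `plot_solute_profiles()`,
`plot_stratification()`, `plot_dose_response()`) cover the full
campaign; `inst/scripts/biofilmsim.R` exposes them as a command-line
tool (`run`, `sweep`, `threshold`, `campaign`) driven by a YAML
configuration (`inst/extdata/example-config.yaml`).

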