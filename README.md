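# p2dsensor

Pseudo-two-dimensional reaction–diffusion modelling of nanozyme glucose
biosensors with laterally heterogeneous catalytic surfaces.

## The problem

Nanozyme glucose sensors read glucose through a two-step surface cascade at
the bottom of a quiescent diffusion layer: glucose oxidase converts glucose
to H₂O₂, and peroxidase-like catalytic sites (e.g. Pt clusters on an MXene
support) consume the H₂O₂, driving a colorimetric or amperometric signal.
The catalytic sites are not uniformly distributed, and the apparent kinetic
parameters extracted from calibration curves mix intrinsic chemistry with
transport limitation and lateral heterogeneity. This package is for sensor
modellers who want to separate those contributions quantitatively.

The model solves Fick diffusion of glucose and H₂O₂ on
$0 \le x \le L,\; 0 \le y \le H$ with all chemistry confined to $y = 0$:

$$\partial_t C_i = D_i \nabla^2 C_i, \qquad
  D\,\partial_y C\big|_{y=0} = j_{\max}\, g(x)\,\frac{C_s}{K_m + C_s},$$

with a Dirichlet bulk boundary at $y = H$, no-flux lateral walls, the
sinusoidal site-density modulation
$g(x) = 1 + A_\Gamma \cos(2\pi x/\lambda + \varphi)$, and a first-order
enzymatic H₂O₂ source $k_{GOD}\,\delta_{enz}\,C_{\mathrm{Glu},s}$. From the
solutions it extracts the sensor-level observables: effective surface
concentration $C_s^{\rm eff}$ and flux $J_{\rm eff}$, apparent
Michaelis–Menten parameters $K_m^{\rm eff}, V_{\max}^{\rm eff}$ (fitted
against *surface* concentration, so the uniform 1D model returns intrinsic
values exactly), the 99%-recovery diffusion-layer thickness $\delta_{99}$,
response times $t_{90}$, amperometric current, LOD and linear range, and a
one-at-a-time parameter sensitivity table. The maximal areal rate is
calibrated so the uniform 1D model gives $C_s/C_b = 0.17$ at 10 mM
(Damköhler number $Da = j_{\max}H/(D K_m) = 8.20$); the enzyme-layer
thickness is calibrated from the 1D near-surface H₂O₂ peak ($0.05\,C_b$ at
10 mM). See the methods vignette (`vignettes/pseudo2d-model.Rmd`) for the
model, the calibration, the numerics and the limitations.

## Worked example

```r
library(p2dsensor)
cfg <- scenario()          # calibrated preset
cfg
#> <scenario> pseudo-2D nanozyme biosensor model
#>   mode        : colorimetric
#>   domain      : L = 10 um, H = 100 um
#>   diffusion   : D_glu = 6.7e-10, D_h2o2 = 1.5e-09 m^2/s
#>   kinetics    : Km = 2.5 mM, j_max = 0.0001374 mol m^-2 s^-1 (Da = 8.202)
#>   heterogeneity: A = 0.50, lambda = 10 um, phase = 0.00 rad
#>   GOD source  : kGOD = 0.015 /s, delta_enz = 0.001192 m
#>   sweep       : 12 points, 0.01-12 mM

solve_steady_1d(cfg, 10)   # uniform reference at 10 mM bulk glucose
#> <steady_1d> C_bulk = 10 mM: C_s = 1.7 mM (0.1700 of bulk), J = 5.561e-05 mol m^-2 s^-1
#>   surface H2O2 = 0.5 mM (0.0500 of bulk glucose)

solve_steady_2d(cfg, 10)   # heterogeneous pseudo-2D solve, 64 x 160 grid
#> <steady_2d> glucose, C_bulk = 10 mM, grid 64 x 160
#>   C_eff_s = 1.7121 mM (0.1712 of bulk), J_eff = 5.5529e-05 mol m^-2 s^-1
#>   residual 4.37e-13, conservation error -9.46e-12, 7 Newton iterations

effective_kinetics(cfg)    # sweep + apparent Michaelis-Menten fits
#> <effective_kinetics> apparent parameters from the steady sweep
#>   1D uniform   : Km_eff = 2.5 mM, Vmax_eff = 0.00013739 (normalized 1)
#>   pseudo-2D    : Km_eff = 2.55 mM, Vmax_eff/1D = 1.0060, R_sat/1D = 0.9986
```

Reading the numbers: the uniform reference depletes surface glucose to 17%
of bulk (the calibration anchor) and the apparent fit returns the intrinsic
$K_m = 2.5$ mM exactly. The 50% site-density modulation shifts the effective
surface concentration and apparent $K_m$ by under 2% — at a heterogeneity
wavelength of 10 µm under a 100 µm layer, lateral diffusion homogenizes the
surface faster than the kinetics can exploit it, so the heterogeneity
penalty is almost entirely erased (the vignette quantifies this and its
consequences). Consistently, `validity_report(cfg)` classifies
$\lambda/H = 0.1$ as the breakdown edge of the pseudo-2D scale separation:

```r
validity_report(cfg)
#> <validity_report> pseudo-2D scale separation
#>   lateral_equilibration    0.1        (threshold 0.01): FAIL
#>   lateral_diffusion_ratio  0.01       (threshold 0.01): FAIL
#>   cluster_size             0.0005     (threshold 0.01): ok
#>   coverage                 0.25       (threshold 0.05): ok
#>   regime: breakdown
```

Transients (`solve_transient_1d()`, `solve_transient_2d()`) give the
surface-H₂O₂ response to a glucose step, with $t_{90} = 54.6$ s (1D) and
54.9 s (pseudo-2D) at the preset; `sensitivity_sweep()` produces the
Km/LOD/linear-range table over ±50% parameter variations; `run_scenario()`
executes a pipeline from a YAML config and writes CSV/JSON plus a run
manifest; `inst/scripts/p2dsensor-cli.R` wraps these as shell subcommands
(`steady`, `transient`, `colorimetric`, `fit`, `sensitivity`,
`validate-regime`, `fixtures`).

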