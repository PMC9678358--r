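# nocimech

Biophysical modelling of how *Drosophila* larval nociceptors sense
localized poking.

Class IV dendritic arborization neurons (c4da) tile the larval body wall
with dense planar dendritic arbors and trigger defensive rolling when the
cuticle is poked with millinewton-scale forces — for instance by a wasp
ovipositor. `nocimech` implements, as reusable and tested R code, the
chain of computations needed to study this system quantitatively:

* **Sphere–surface contact mechanics.** For a rigid spherical probe of
  radius *r* pressed a depth *d* into a compliant surface with effective
  modulus *E\** = *E*/(1 − ν²), the Hertz model gives the force
  *f* = (4/3) *E\** r<sup>1/2</sup> d<sup>3/2</sup>, contact radius
  *a* = √(r d), central pressure *P₀* = 3f/(2πa²), spherical-cap contact
  area *A*<sub>c</sub> = 2πr(r − √(r² − r d)) and the pressure profile
  *P(x)* = *P₀*√(1 − x²/a²). Device calibration arithmetic (piezo step
  minus beam deflection, water-drop gauge calibration) is included.
* **Layered tissue stress fields.** An axisymmetric linear-elastic
  finite-element contact solver (bilinear elements with B-bar treatment of
  the near-incompressible layers, active-set contact under displacement
  control) computes the surface fields a probe produces on a cuticle
  (10 μm) bonded to a PDMS pad (1 mm): the perpendicular pressure
  *P*<sub>P</sub> and the lateral (in-plane) surface tension
  *T*<sub>L</sub>. A closed-form Hertz half-space oracle validates the
  homogeneous limit.
* **Morphology.** SWC input/output, total dendritic length, modified
  Sholl analysis (intersections divided by ring circumference),
  distance-to-nearest-dendrite maps, and stimulus-position sampling
  (proximal/distal/dendrite-off/uniform).
* **Synthetic data.** A calibrated space-filling growth model generates
  c4da-like arbors (≈19,560 μm total length, near-uniform Sholl density
  to ~200 μm, ≥95 % of the territory within 20 μm of a dendrite) and
  sparse cut-knockdown/c3da-like variants; Boltzmann presets simulate
  force–response experiments.
* **Activation probability.** A Monte-Carlo simulation overlays the
  *P*<sub>P</sub>/*T*<sub>L</sub> maps on arbors at random positions,
  excites dendritic sub-segments above 10 % of each field's peak, and
  reports the probability that the excited length reaches a dendritic
  coverage threshold *C*<sub>d</sub> (20/200/400 μm) under three
  sensitivity scenarios: pressure only, tension only, or both.
* **Force–response fitting.** Boltzmann fits
  *R(f)* = *A*/(1 + e^((f₀−f)/w)) of ΔF/F₀ versus force, with derived
  half-activation (*f₅₀*) and full-activation (*f₉₀*) forces.

## Worked example

```r
library(nocimech)

## Hertz arithmetic for a 60 um probe pressed 20 um into PDMS
probe  <- probe_spec(60)                     # radius 30 um
medium <- elastic_medium(2.6, 0.45)          # PDMS
f <- contact_force(effective_modulus(medium), probe, 20)
f                                            # 2.13 mN
central_pressure(f, contact_radius(probe, 20))  # 1.70 MPa

## Stress fields on the layered cuticle-on-PDMS preparation
sol <- solve_indentation(default_layer_stack(), probe_spec(60), 20)
sol
#> surface stress profile: 219 radial nodes to 600 um
#>   total force 2 mN, contact radius 21.7 um (6 contact iterations)
#>   P_P peak 1.77 MPa at rho = 0.759 um; T_L peak 0.0637 MPa at rho = 22.5 um

## Monte-Carlo activation probability on synthetic c4da arbors
arbors <- lapply(1:5, function(s) generate_arbor("c4da_wt", seed = s))
field  <- radial_to_map(sol, pixel_size = 1, extent = 150)
activation_probability(arbors, field, activation_config(seed = 7))
#> activation probability over 5 cell(s):
#>   C_d =   20 um  both     1.00 +/- 0.00
#>   C_d =   20 um  P_only   0.99 +/- 0.01
#>   C_d =   20 um  T_only   1.00 +/- 0.00
#>   C_d =  200 um  both     1.00 +/- 0.00
#>   C_d =  200 um  P_only   0.53 +/- 0.10
#>   ...

## Boltzmann force-response fit of simulated wild-type data
fit <- fit_boltzmann(generate_response_curves(response_preset("wt_60um"),
                                              seed = 1))
fit
#> Boltzmann force-response fit: R(f) = A / (1 + exp((f0 - f)/w))
#>   A = 1.03, f0 = 2.98 mN, w = 0.5 mN (rms residual 0.0169)
#>   half-activation f50 = 2.98 mN, full-activation f90 = 4.07 mN
```

Three things the example shows: the pressure field under the probe is
confined to the ~22 μm contact patch while the lateral tension peaks just
outside it and decays slowly, so a tension-sensitive dendrite "feels"
probes tens of micrometres away; on dense wild-type arbors that lateral
sensitivity rescues activation when many excited micrometres of dendrite
(*C*<sub>d</sub> = 200 or 400 μm) are required; and simulated
force–response data are summarised by forces of half- and full-activation
(here ≈3 and ≈4 mN for the 60 μm probe).

## Layout

* `R/` — contact mechanics (`contact.R`), finite-element solver
  (`fem.R`, `fields.R`), morphology (`morphology.R`), synthetic
  generators (`synthetic.R`), activation simulation (`activation.R`),
  response fitting (`response.R`).
* `vignettes/nocimech-methods.Rmd` — model assumptions, parameter
  choices, numerical design and limitations.
* `tests/testthat/` — unit, property and end-to-end tests.
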