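---
title: "Models and numerical methods in nocimech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in nocimech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nocimech` models how a dense planar mechanonociceptor — the larval c4da
neuron — responds to poking with spherical probes. This vignette records
the models, the parameter choices that matter, and the numerical design,
in enough detail that a reader can judge what the package's passing tests
do and do not establish.

Throughout, the internal unit system is micrometres, megapascals and
millinewtons. These are consistent through the identity
1 MPa · μm² = 1 μN, so Hertz-type expressions evaluated in (MPa, μm)
yield micronewtons and are divided by 1000 exactly once, in a single
utility. Water-drop gauge calibration uses density 1 g/mL and
g = 9.8 m/s², so a 100 μL step weighs exactly 0.98 mN.

## Sphere–surface contact model

For a rigid sphere of radius $r$ (probes are quoted by tip *diameter*;
the constructor stores $r = \text{diameter}/2$) indenting a compliant
half-space of effective modulus $E^* = E/(1-\nu^2)$ to depth $d$:

$$f = \tfrac{4}{3} E^* r^{1/2} d^{3/2}, \quad a = \sqrt{rd}, \quad
P_0 = \frac{3f}{2\pi a^2}, \quad
P(x) = P_0 \sqrt{1 - x^2/a^2},$$

with the spherical-cap contact area
$A_c = 2\pi r (r - \sqrt{r^2 - rd})$. The model is only meaningful for
$d < r$, and every operation raises an error beyond that bound — in the
experiments this regime also marks where probes start to rupture the
cuticle, which the model deliberately does not cover (no adhesion,
viscoelasticity or plasticity either). The pressure profile is defined
as 0 outside the contact patch ($x > a$): no traction is transmitted
beyond contact. These formulas satisfy
$\int_0^a P(x)\, 2\pi x\,dx = f$ exactly, which the tests verify by
quadrature to 0.1 %.

Gauge calibration is an ordinary least-squares line with a free
intercept; the device literature does not force the line through the
origin, and with a free intercept a zero offset is recovered when
present.

## Layered indentation solver

The tissue preparation is modelled as bonded linear-elastic layers —
cuticle (10 μm thick, ν = 0.45) on PDMS (1000 μm, 2.6 MPa, ν = 0.45) —
with the bottom face fixed and a frictionless rigid spherical indenter
under displacement control. The much softer muscle layer (~10 kPa) is
omitted. Kinematics are small-strain linear even though the default
indentation (20 μm) exceeds the cuticle thickness; this mirrors the
linearly-elastic treatment standard for this preparation and keeps the
solution superposable.

**Discretization.** Axisymmetric bilinear quadrilaterals on a structured
grid. Near ν = 0.5 these elements lock volumetrically, so the volumetric
part of the strain operator is replaced by its element mean (B-bar /
selective reduced integration). The radial grid is uniform at
$h = \sqrt{rd}/70$ across twice the estimated contact radius and grows
geometrically (ratio 1.06) to the domain edge at 600 μm; the element
height starts at $h/2$ at the free surface and grows geometrically
(ratio 1.35) downwards, with layer interfaces always on grid lines. The
600 μm lateral extent matters: truncating at 300 μm with a free side
boundary costs ~5 % of the total force in the homogeneous benchmark.
The default solve has ~220 surface nodes (~45 across the contact patch)
and ~12,000 degrees of freedom; mesh-halving changes the recovered
tension-peak position by less than one cell, which is the package's
convergence evidence.

**Contact.** Active-set iteration on the surface gap: nodes whose gap
closes are constrained to the indenter profile, the sparse system is
re-solved (Cholesky via `Matrix`), nodes with tensile reactions are
released and penetrating nodes added until the set is stable (typically
5–8 iterations; failure to converge raises an error with diagnostics,
as does a contact patch resolved by fewer than 8 nodes).

**Outputs.** The perpendicular pressure $P_P$ is recovered from nodal
contact reactions divided by consistent nodal areas (the integral of the
linear surface shape function against $2\pi\rho$ — a plain midpoint
tributary area is wrong by 4/3 at the axis). The lateral tension $T_L$
is defined as the maximum tensile in-plane principal stress at the top
surface, clipped at zero where compressive; with axisymmetry the
in-plane principal stresses are $\sigma_{rr}$ and
$\sigma_{\theta\theta}$. These are recovered from the *surface
displacement field* plus the known surface traction ($\sigma_{zz} = -p$
under the indenter, 0 outside), eliminating $\varepsilon_{zz}$
analytically. This avoids differentiating the near-incompressible field
in $z$, which dominates the error of naive element-stress recovery here.
Radial derivatives use three-point stencils that are one-sided on each
side of the contact edge, keeping the stress kink there sharp to one
cell.

**Validation oracle.** In the homogeneous limit (both layers the same
material) the solution must approach the closed-form Hertz half-space
result: the pressure ellipse inside contact and the tensile surface
radial stress $(1-2\nu)a^2P_0/(3\rho^2)$ outside. The oracle tests run
the solver with its *paraboloid* indenter-profile option
($g_0 = \rho^2/2r$), which is the geometry the Hertz closed form
actually assumes, at $d = 5$ μm; the production solves use the exact
spherical profile. Agreement required by the tests: pressure within 5 %
of $P_0$ in $L_\infty$ over $\rho \le 0.9a$, total force within 5 %,
tension peak at the contact edge to one grid cell.

**Cuticle modulus.** Reported larval cuticle moduli span 1–10 MPa, and
the value behind published stress-field figures for this preparation is
not stated. The choice matters qualitatively: a film stiffer than the
substrate develops a bending-dominated tension peak well outside the
contact edge (≈28 μm at 3.16 MPa, drifting to ≈33 μm at 10 MPa for the
60 μm probe at 20 μm depth), whereas for a film matching the substrate
the peak sits at the contact edge, 20–25 μm out — which is where this
preparation's tension peak is reported to lie, and which also leaves
about a third of the peak tension at 40 μm, consistent with responses
persisting when the probe lands 40–60 μm from a dendrite. The default
is therefore `E_cuticle = 2.6` MPa, calibrated within the printed range
to reproduce that behaviour, and overridable in `default_layer_stack()`.

## Morphometrics

Sholl analysis counts crossings of each straight segment with each
concentric circle as roots of the segment–circle quadratic, with segment
parameters in the half-open interval $[0, 1)$ so a shared endpoint of
chained segments is counted exactly once, and a tangent touch counts
once (tie-break decisions). Density is crossings divided by ring
circumference; ring spacing defaults to 10 μm.

Distance maps rasterize segments at quarter-pixel spacing and apply a
Euclidean distance transform (`EBImage::distmap`), giving errors below
about one pixel (2 μm at the default pixel size); an exact
point-to-segment function (`dist_to_arbor`) serves as the in-package
oracle and is used where exactness matters (dendrite-off sampling).

The dendritic territory is the disc of radius 220 μm about the soma —
just beyond the 200 μm ring used for distal stimuli. Dendrite-off
sampling is rejection sampling with a ±2 μm acceptance band and a capped
proposal budget; on a dense wild-type arbor, targets beyond the largest
dendrite-free distance (~15 μm) correctly fail with a sampling error.

## Synthetic arbors: what they emulate, and what not

The generator grows tips in 4 μm steps with heading noise (sd 10°), a
radially outward bias, and branching gated by clearance: a new branch
needs `1.25 ×` the mean inter-branch spacing implied by the target
length ($s = \pi R^2 / L$, about 7.8 μm for the wild-type target), while
mere elongation needs only `0.6 ×` that spacing so fresh sibling
branches can diverge. The two-radius scheme is what makes the model
space-filling: branching keeps inserting branches until the spacing
constraint binds, which pins the realized density at a near-uniform
value. The branch-gate factor 1.25 and branch probability 0.8 were
calibrated once so that five seeds yield a mean total length near the
19,560 μm wild-type target, and then frozen. Cut-knockdown arbors use
identical growth to 100 μm and then stop branching and let tips die
(3 %/step), reproducing preserved proximal density with distal decay.

The generated arbors reproduce the *statistics* the downstream
simulation is sensitive to — total length, radial density profile,
coverage of the territory — not the biology of real arbors: there is no
tiling against neighbours, no branch-order taper, no terminal dynamics,
and territory boundaries are hard discs. Tests passing on these arbors
therefore establish that the activation machinery behaves correctly on
dense uniform arbors, not that real c4da arbors produce identical
probabilities.

Simulated force–response curves add Gaussian noise (sd 0.1 of the
plateau) to a Boltzmann curve and truncate at zero, since ΔF/F₀ cannot
be negative; no indicator kinetics or imaging noise are modelled. The
wild-type presets pin $f_{50}/f_{90}$ at 3/4 mN (60 μm probe, plateau 1)
and 0.7/1.5 mN (30 μm probe, plateau 1.5 — the relative plateau is a
modelling choice, since only figure-read values exist for it). Mutant
presets are qualitative fixtures only.

## Activation simulation

A dendritic sub-segment (1 μm discretization; segments are split into
equal pieces so lengths sum exactly) is excited when the local field
value reaches 10 % of that field's own global peak — a relative
threshold, not an absolute stress. The cell activates when the excited
length reaches the coverage threshold $C_d$; the defaults 20, 200 and
400 μm are 0.1 %, 1 % and 2 % of the mean total dendritic length rounded
to one significant figure. Probe positions are uniform over the
territory disc (the stimulation protocol says "random positions" without
a law; uniform is the natural choice and is what the tests assume), and
probabilities are aggregated per cell first, then summarised as
mean ± sd across cells. Under the combined scenario a sub-segment
excited by either channel counts once.

The end-to-end test conditions are five generated wild-type arbors × 100
positions × three scenarios against the default layered 60 μm-probe
field, which runs in seconds; the exhaustive-grid oracle on a toy cross
arbor checks the probability computation itself against closed-form
chord lengths.

## Boltzmann fitting

The three-parameter sigmoid $R(f) = A/(1+e^{(f_0-f)/w})$ with a zero
lower asymptote (responses start near zero at zero force) is fitted by
Levenberg–Marquardt (`minpack.lm`), by default to per-force means across
cells — matching how force–response plots are summarised — with
per-point fitting available. Initialisation: $A$ from the maximum
response, $f_0$ by linear interpolation to half-maximum, $w$ as a
quarter of the force span; non-convergence reports these starting
values. Derived quantities: $f_{50} = f_0$,
$f_{90} = f_0 + w\ln 9$, and generally
$f_q = f_0 + w \ln(q/(1-q))$, so the fitted slope at $f_0$ is $A/4w$.
Flat data and fewer than four distinct force levels are rejected.

Zero-truncation of the simulated data slightly raises the low-force
means (by about $0.4\,\sigma$ per cell at forces where the true response
is ~0), which biases $f_0$ down by a few hundredths of a millinewton at
the default noise level — well inside the ±10 % recovery tolerance the
tests use.

## Known limitations

* The solver is linear and axisymmetric: no cuticle prestress, rupture,
  friction, hemolymph pressure or non-axisymmetric loading.
* $T_L$ is evaluated at the top surface only; mid-plane stresses differ.
* The 30 μm probe cannot be driven to 20 μm depth within the contact
  model's validity ($d < r = 15$ μm); small-probe fields should be
  computed at smaller depths.
* Activation is purely geometric — no channel gating, calcium dynamics
  or dendritic signal propagation; it addresses coverage, not kinetics.
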