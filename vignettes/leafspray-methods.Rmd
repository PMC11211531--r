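---
title: "Droplet-leaf interaction modelling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet-leaf interaction modelling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(leafspray)
```

## The problem

Stem-and-leaf herbicides only work if the spray stays on the weed. For a
small broadleaf weed (an *Amaranthus retroflexus*-like plant, about 35 mm
tall) under an intra-row cone nozzle, the droplets' impact force bends the
leaves downward. Retention is best when a leaf is deflected *just* to
horizontal: less deflection leaves the blade steep and sheds liquid toward
the stem; more deflection ("strong impact and drainage") opens a channel
and the herbicide passes through to the soil. `leafspray` models this
interaction end to end: spray ballistics, leaf deflection, the nozzle
operating window, a reduced-order dynamic simulation, and the coverage
statistics used to evaluate the outcome.

## Static model

**Ballistics.** The spray is discretized into particles leaving the nozzle
at the Bernoulli speed $v_0 = \sqrt{2P/\rho}$ and flying drag-free:

$$v_1 = \sqrt{(v_0\sin\theta_d)^2 + (v_0\cos\theta_d + g t)^2}, \qquad
l_w = \sqrt{(v_0 t\sin\theta_d)^2 + (v_0 t\cos\theta_d + \tfrac12 g t^2)^2},$$

with $\theta_d$ the nozzle tilt from the downward vertical. No flight time
is ever prescribed: it is always recovered by numerically inverting the
travel distance (`time_to_distance()`, unique root because $l_w$ is
strictly increasing). Air drag during free flight is deliberately omitted
here; drag appears only in the dynamic simulation's particle model.

**Impact force.** $F_0 = \pi\rho R v_1^2 V / 2$ with particle radius $R$,
liquid density $\rho$ and spray volume $V$. The reference radius is the
printed 1 mm, although real droplets at a few bar are considerably
smaller; it is exposed as a parameter everywhere. Two volume conventions
are provided because the source formulation does not fix one:
`single_droplet` ($V = \frac43\pi R^3$, the per-particle reading) and
`aggregate` ($V = Q\,\Delta t/\rho$, the liquid delivered over an
accumulation window $\Delta t$). The self-weight of the spray bearing on a
leaf is kept at the literature constant $G = 3\times10^{-4}$ N rather than
$\rho V g$, which would be two orders of magnitude smaller for one 1 mm
droplet.

**Leaf deflection.** Each leaf is a uniform rectangular-section cantilever
(length $l$, width $b$, thickness $h_l$, $I = b h_l^3/12$) inclined at the
leaf angle $\beta$; the leaf-stem angle is $\theta = 90^\circ - \beta$,
computed from $\beta$ rather than hard-coded (the quoted
$\theta = 56.788^\circ$ differs from $90 - 33.222 = 56.778^\circ$ in the
third decimal). The published deflection model integrates the combined
impact/gravity load twice with boundary conditions $y(0) = 0$,
$y'(0) = \theta$ (so $C_1 = \theta$ in radians, $C_2 = 0$; the degree-to-
radian conversion is centralized). Its double integral
$\int_0^l\!\!\int_0^b \cdots \,db\,dl$ is divergent as printed — the
integrand carries $b$ and $l$ in its denominator — so the package offers
two interpretations of the load-induced deflection:

* `literal` (default): the integrand evaluated at the full blade
  dimensions, multiplied by the blade area $A = bl$ — the engineering
  shorthand consistent with the model's use of the total leaf area:
  $$y_F(x) = \frac{2F_0\sin\theta\cos\theta_t\,x^4 +
  G\cos\beta\,x^2}{4 E b h_l^3\cos^2\theta}.$$
* `beam`: the textbook Euler-Bernoulli cantilever under the equivalent
  uniform line load $w = qb$, $q = (F_0\sin\theta\cos\theta_t +
  G\cos\beta)/(A\cos^2\theta)$, with tip deflection $w l^4/(8EI)$.

The two differ by a constant factor at fixed inputs; the factor is
computed and attached to every profile (`mode_ratio`) so the choice is
auditable. Both scale identically with $F_0$, $E$ and $h_l^3$.

**Parallel-to-ground criterion.** The optimum deflection is stated
verbally in the source; we operationalize it as a tip descent of
$l\sin\beta$ — the drop that brings a straight leaf from inclination
$\beta$ to horizontal.

**Deformation index.** $\xi = (x_d - x_i)/x_i$, the relative gain in the
leaf's ground-axis extent. For an inextensible straight leaf this is
bounded by $1/\cos\beta - 1 \approx 0.195$ at $\beta = 33.22^\circ$,
reached exactly at horizontal. Reported continuum-simulation values up to
0.427 exceed this ceiling, implying an extent measure (arc-length
projection of a curved blade) that a rigid-rotation frame cannot
reproduce; the package flags this rather than rescaling. The dynamic
simulation maps tip descent to $\xi$ through the rigid-rotation frame
(`rigid_deformation_index()`), so its indices are capped at the ceiling.

## Nozzle design and the operating window

The geometric chain is elementary and exact: cone angle
$\gamma = \arctan(d/h_1)$ (200 mm lateral range, 300 mm clearance →
$33.69^\circ$), rounded *up* to the 5-degree nozzle granularity (35°);
reach range $(h_1,\ h_1/\cos\gamma)$ → 300-366 mm; incidence interval
$(\beta,\ \beta + \gamma)$ → (33.22°, 68.22°). The discharge law
$Q = C_d A_1\sqrt{2\Delta P/\rho}$ is treated as volumetric and multiplied
by $\rho$ to report kg/s, with $\Delta P$ equal to the gauge pressure.
Note that with the printed $C_d = 0.6$ and $R_1 = 0.5$ mm this evaluates
to ≈0.0130-0.0131 kg/s over 0.383-0.389 MPa, not the printed
0.011-0.0113 kg/s; the package reports what the law gives and does not
tune constants to match.

`solve_operating_pressure()` finds, for the two matched cone endpoints
(shortest reach with smallest incidence, longest reach with largest
incidence), the pressure at which the predicted tip descent equals
$l\sin\beta$, by bisection on log-pressure over a fixed bracket
(100 Pa, 10 MPa) to a 1 Pa residual. The chain per trial pressure is
$P \to v_0 \to t \to v_1 \to F_0 \to$ tip descent.

Under the per-droplet volume the criterion is unreachable: one millimetre
droplet cannot carry the momentum to hold a leaf at horizontal at any
pressure below 10 MPa (the requirement sits around $10^{11}$ Pa), and the
solver raises a typed no-solution error. The solver therefore defaults to
the aggregate volume with a 5 s accumulation window — chosen once as an
order-of-magnitude pass-duration figure and not revisited. Under that
interpretation the solver brackets a finite window a little above the
megapascal scale, roughly an order of magnitude above the printed
0.383-0.389 MPa; the per-endpoint chains are returned (`tidy()`) so the
deviation is visible, and the window's monotone response to $E$, $h_l$
and $R$ (the directions elasticity theory requires) is what the test
suite asserts.

## Reduced-order dynamic simulation

The full finite-element/CFD coupling (tetrahedral meshes, k-epsilon
turbulence) is out of scope; `run_simulation()` replaces it with a
reduced-order model:

* **Leaves.** One modal coordinate per leaf (first bending mode):
  $M\ddot s + C\dot s + K s = F$ with static tip stiffness $K = 3EI/l^3$
  and tip-equivalent mass $M = \tfrac{33}{140} m_{leaf}$, whose natural
  frequency matches the exact first cantilever mode within 1.5%. The
  damping matrix is undefined in the source; we use proportional damping
  with ratio $\zeta = 0.05$ (configurable), which produces the damped
  swinging behaviour after peak deformation. Integration is Newmark
  average-acceleration (implicit, unconditionally stable); the test suite
  holds it to the analytic damped-oscillator solution within 0.5% over
  0.5 s at 1 ms steps.
* **Particles.** Force balance
  $m_p\dot v_p = m_p(v_c - v_p)/t_r + m_p g(\rho_p-\rho_c)/\rho_p + F$,
  integrated with the exact exponential-relaxation solution per step. The
  relaxation time defaults to the Stokes value $t_r = \rho_p d^2/(18\mu)$
  (≈12.4 s for a 2 mm droplet — gravity-dominated flight, as expected).
  The continuous phase is a constant downward jet inside the spray cone
  and still air outside; no turbulence field is reconstructed, so the
  reported CFD velocity/turbulence maps are excluded from any comparison.
* **Impacts.** Step segments are intersected with the rectangular leaf
  patches (first crossing wins). First impacts partition by normal speed:
  above 15 m/s splash, between 1 and 15 m/s rebound, below 1 m/s deposit;
  rebounding/splashed droplets reflect with restitution $e = 0.3$ and may
  only deposit or reach the ground afterwards. All three constants are
  configurable since no values are published; the defaults express the
  spring-mass reading of droplet impact.
* **Films and load transfer.** Deposits grow a per-leaf thickness map
  following the profile $h = h_0 + (x^2+y^2)/2R$ about each centre,
  truncated at the stain spread radius and normalized so film volume
  equals deposited volume exactly (the profile's "+ velocity" correction
  term is dimensionally inconsistent and off by default). Pressure
  transfer to the leaf is proportional to thickness — physically, the
  film's weight $\rho g h$. Because momentum reaches the structure
  through this film rather than as point impulses, droplet impulses are
  low-pass filtered into the modal force with a 20 ms response time
  (`film_response_time`); without this, a single 1 mm droplet hitting a
  20 mm top leaf near the tip would ring the lumped mode past horizontal,
  which the distributed continuum does not do.
* **Stages.** Targeted movement until the first impact; contact and
  diffusion until $\xi$ reaches half its parallel-to-ground value;
  continuous coverage until the tip descent exceeds $l\sin\beta$; strong
  impact and drainage beyond. Stages are monotone by construction.

The mass ledger (airborne / deposited / rebounded / splashed / ground /
escaped) partitions the sprayed mass exactly at every step; droplets
leaving the lateral domain outlets are booked as `escaped`. Identical
seeds give bit-identical outputs.

## Synthetic data

`plant_template()` carries the measured template: height 35 mm, 12 leaves
in two layers (8 bottom at 45-degree azimuth spacing, 4 top offset 45
degrees), leaf angle 33.222°, thickness 0.4 mm, bottom blades 35 × 15 mm,
top blades 20 × 8 mm, stem 3 mm, density 700 kg/m³, modulus 222.85 MPa
(the 272.5 MPa literature figure remains the static-model default; the
two are not reconciled in the source, so both are explicit presets).
Leaf mass is spread uniformly over the rectangular blade — the
along-blade mass distribution is not published. `build_plant()` with
multiplicative uniform jitter emulates plant-to-plant variability (only
means of five plants are published, so the distributional choice is
ours). `sample_droplets()` emits droplets at the Bernoulli speed,
uniformly over the cone solid angle, at regular times, with the count set
by the mass flow — the emitted rate matches $Q$ to within one droplet.
`render_paper()` produces binary water-sensitive-paper images over the
three 15 × 30 mm assessment strips (test strip under the plant, controls
either side; 30 mm is the bottom leaf's 29.28 mm ground extent rounded
up), either stamping stains at simulated ground hits (stain radius twice
the droplet radius — the wet-stain magnification is not published) or
placing stains until target coverages are met within half a pixel.

What the generator does *not* emulate: real leaf shape and taper, canopy
occlusion by the crop, droplet size spectra, evaporation and drift, and
the colorimetry of real water-sensitive paper (the coverage contract is a
binary grid; a scanned image must be thresholded upstream). Passing tests
therefore certify the mechanics and accounting of the pipeline, not
field-level predictive accuracy.

## Numerical choices and degenerate inputs

* Units are SI internally (m, s, Pa, kg); exports use mm and MPa where
  conventional. Coverages are fractions internally, percentages at I/O —
  the only convention under which the inter-area variance reproduces the
  published 5-11% band.
* The inter-area variance is the population (divide-by-3) variance
  exactly as defined, not the sample variance; the NMAE normalizes by the
  *simulated* value, exactly as printed, and its asymmetry is preserved.
* Root-finding: travel-time inversion via `uniroot` to 1e-13; pressure
  bisection on log-P to 1 Pa. Ties in impact detection resolve to the
  first crossing along the step segment.
* Degenerate inputs raise typed errors (`leafspray_domain_error`,
  `leafspray_no_solution`): $\theta = 90^\circ$ leaf-stem configurations,
  zero-area patches, unreachable distances with $v_0 = g = 0$, coverage
  rectangles containing no pixels, particles crossing more than one
  domain length per step.
* Problem sizes: the default simulation (0.5 s at 1 ms steps, ≈1600
  droplets at 0.4 MPa) was chosen to resolve every leaf's first mode with
  ≥10 steps per period while keeping a full run under a second of compute;
  property suites use 50-1000 randomized cases under fixed seeds.

## Limitations

Small-deflection linear beam theory with a single mode per leaf; no leaf
taper, torsion, or turgor dependence; no droplet breakup or coalescence;
no reconstructed turbulence field (reported turbulence intensities and
peak fluid velocities from the continuum simulation are not reproducible
here and are excluded); the deformation index is capped at the
rigid-rotation ceiling, below the largest continuum-simulation values;
and the operating-pressure window depends on the documented aggregate
volume interpretation whose accumulation window is a modelling constant,
not a measured quantity.
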