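---
title: "Models and methods behind magwire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magwire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magwire)
```

magwire models a microfluidic immunoassay platform in which the solid phase
is assembled magnetically: antibody-functionalized superparamagnetic beads
are captured on a glass-coated soft magnetic microwire strung along each
channel axis, a sandwich ELISA is run by flowing sample and reagents over
the bead coating, and the beads are finally released and read per event in
a flow cytometer. This vignette records the models, their assumptions, the
parameter choices that matter, and the places where the design was
genuinely open.

## 1. Magnetostatics

### Applicator

The field applicator is a pair of identical neodymium block magnets
(default 38.1 mm x 76.2 mm x 6.35 mm, remanence Br = 1.3 T, magnetized
through thickness) facing each other across a 34 mm gap with like-directed
magnetization, so their fields add between them. Each magnet's field is the
exact charge-sheet (surface-charge) solution for a uniformly magnetized
prism — closed-form log/arctan expressions — rather than a numerical
discretization. A brute-force dipole-grid discretization
(`dipole_grid_field()`) is kept purely as an independent oracle; the test
suite requires agreement within 1% at points 2 mm or more outside the body.

The magnet dimensions are not part of the published device description;
they decode the vendor part code as 3.0 x 1.5 x 0.25 inch. Orientation was
an open choice: we place the 38.1 mm side along the device's short axis
(x, across the five channels at 0, ±5, ±10 mm) and 76.2 mm along the
channels. This orientation reproduces the design gradient landscape — the
field decreases from the midplane center toward the device edges with
|∇H| growing monotonically to ~4.5e3 kA/m² at x = ±12.5 mm against the
design value 5.2e3 kA/m² — whereas the other orientation gives edge
gradients more than an order of magnitude too small.

With Br = 1.3 T the analytic midplane-center field is 118.8 kA/m, about
12% above the design figure H0 = 106 kA/m (obtained by the original
device's own numerical simulation, whose grade/discretization settings are
unknown). Both numbers are kept: the pole-face surface field reproduces its
design value "about 120 kA/m" within ~1%, while H0 is verified loosely
(15%). Because the wire's transverse magnetization curve is pinned to the
published operating anchor (106 kA/m -> 524 kA/m), the design-check and the
force calibration evaluate the wire at the *nominal* operating field
(`config$wire$operating_H`, default 106 kA/m); the capture simulation, by
contrast, uses the field the analytic applicator actually produces.

### Microwire

The wire (soft FeCuNbSiB core, diameter 25 µm, glass-coated to 55 µm) is
modeled, when transversely magnetized with magnetization M, as a 2-D
dipole line: at radius r >= a and angle θ from the magnetization direction

$$h_r = \frac{M a^2}{2 r^2}\cos\theta,\qquad
  h_\theta = \frac{M a^2}{2 r^2}\sin\theta,$$

so the magnitude M a²/(2r²) is independent of angle and decays as r⁻².
At the operating point (M = 524 kA/m) the glass-surface field is
54.1 kA/m and the radial gradient M a²/r³ = 3.9e6 kA/m² — roughly 900x the
applicator's maximum in-plane gradient, which is why bead actuation is
wire-dominated. The design description quotes a surface gradient "about
7e6 kA/m²", 1.8x the dipole-line closed form; the evaluation convention
behind that number is not recoverable, so it is reported but not used as a
hard target.

## 2. Materials

Hysteresis is ignored throughout: the wire core is magnetically very soft
(near-complete demagnetization at zero field) and the beads are
superparamagnetic, so M(H) is single-valued, monotone, and clamped at
saturation. Measured curves can be supplied; the defaults are
piecewise-linear through the published design anchors:

* **Wire (transverse):** origin -> (106 kA/m, 524 kA/m) -> saturation
  (300 kA/m, 954 kA/m).
* **Bead:** origin -> (160 kA/m, 0.8 Msat) -> saturation (400 kA/m, Msat).

The bead curve's middle knot deserves a note. The design states that beads
reach ~80% of saturation at the operating point, and that the holding force
at the wire surface is Fm0 = 13 nN. The wire-surface field is
H0 + h0 ≈ 160 kA/m; anchoring the curve at (160 kA/m, 0.8 Msat) makes the
"operating-point" moment policy (moment capped at 0.8 Msat) exact there. A
curve rising linearly to saturation at 400 kA/m alone — with no 80% anchor —
would put the bead at only 40% of saturation at 160 kA/m and could not
reproduce the design force.

The bead saturation magnetization itself is not published and is
back-calibrated so that a bead at 0.8 Msat in the surface gradient feels
exactly 13 nN: Msat ≈ 232 kA/m. This is several-fold larger than typical
vendor figures for 3 µm polymer-matrix beads (tens of kA/m); either the
original force figure used a different gradient convention (see the 1.8x
gradient question above) or a different effective moment. We keep the
calibration — it makes the force, capture and retention numbers mutually
consistent — and flag it here as the package's largest physical
uncertainty.

## 3. Transport

Bead dynamics are overdamped: a 3 µm bead in water has a momentum
relaxation time of microseconds, so velocity = fluid velocity + mobility x
force with Stokes mobility 1/(6πηR), η = 1 mPa·s by default. The duct flow
is the no-slip rectangular-channel Fourier-series profile (400 µm x 600 µm
cross-section), scaled so its exact closed-form integral equals the
volumetric rate; the wire's perturbation of the duct profile (an annular
correction) is ignored — a stated fidelity limit that mostly matters within
a few wire radii where the magnetic term dominates anyway.

The capture integrator uses the wire-dominated field: the applicator
contributes a locally uniform bias (setting the wire and bead operating
points) while the force gradient is the wire's analytic r⁻³ form. Steps
adapt so a bead never moves more than 20% of its remaining radial distance
per step, which also guarantees trajectories cannot cross the wire
envelope (glass radius + bead radius = 29 µm, center-based contact).
Brownian motion and bead-bead interactions (chaining) are neglected —
deterministic dilute-limit transport.

Retention under wash flow compares Stokes drag, evaluated one bead radius
off the wire surface on the fast (widthwise) side, against the magnetic
holding force at contact; with the calibrated defaults the holding force
(≈12 nN) exceeds drag (≈0.4 nN) even at the highest protocol rate
100 µL/min, consistent with the reported high retention. A friction-
coefficient multiplier is exposed for sensitivity studies since no
mechanistic retention model was given. The reported "up to 85%" retention
at 100 µL/min is treated as a qualitative benchmark (the simulation's
capture fraction at that rate is ~0.9-1.0 depending on seeding and
duration); whether the original figure refers to capture during loading or
retention during washes is ambiguous, so both observables are exposed.

## 4. Protocol

The pump model is a syringe pump at Q0 = 50 µL/min feeding a distribution
valve that cycles across n = 5 channels with period T = 3 s; each channel
flows for T and rests 4T, so the duty-cycle average rate is Q0/5 =
10 µL/min. Bead extraction runs at Qf = 6·Q0 = 300 µL/min producing a
300 µL suspension per channel. The default step table is the published
twelve-step protocol totalling 151 min. One bookkeeping inconsistency in
the published protocol table — wash steps state 300 µL per channel in 10 min, while
the duty cycle delivers 100 µL per channel in that time — is left exposed
rather than resolved: buffer-line dead volume (350 µL per line) is a
`pump_program` parameter, and the timeline reports programmed (pumped)
volumes.

## 5. Cytometry

Events are (FSC, SSC, FL4) rows; FL4 is in ERF (equivalent reference
fluorophores), treated as the native calibrated unit. Gating is polygonal
in the FSC-SSC plane and **boundary-inclusive** (events on an edge count as
inside), which makes membership deterministic for grid-valued synthetic
data. G2 (doublets) is a subset of G1 (all beads); aggregates are treated
strictly as doublets — higher multiplets are out of scope.

The doublet correction N_tot·I/(N_tot+N₂) is an identity, not an estimate:
if every doublet event is the sum of two bead fluorescences, dividing the
gate's total fluorescence by the bead count N_tot+N₂ gives the exact
per-bead mean (the test suite checks this against brute-force expansion of
doublets into bead lists). This also forces I to be the arithmetic mean —
a median would break the identity — which resolves an ambiguity in the
published description.

Background subtraction uses the mean of (by default three) stock-bead
replicate measurements; negative results are *not* clipped by default so
the (0, 0) calibration anchor stays unbiased (clipping is opt-in).

CSV (header `FSC,SSC,FL4`, full precision) is the interchange format. A
minimal FCS 3.0 list-mode reader/writer (float data, standard keyword
parsing, channel mapping via configuration) is included because no FCS
package exists in the supported dependency set; it is round-trip tested
but intentionally not a general FCS implementation.

## 6. Calibration and quantification

The model I(C) = A(1 − e^(−BC)) is fitted two ways:

* `fit_full()` — nonlinear least squares for (A, B) excluding
  zero-concentration points, via `nls` (port algorithm; `scaleOffset`
  handles the zero-residual case), initialized at A₀ = 1.1·max(I) with B₀
  from the lowest-concentration point. Standard errors come from the
  linearized covariance.
* `fit_A_fixed_B()` — the within-run strategy: B frozen (default
  0.069 ± 0.006 mL/ng), A by closed-form linear least squares on the
  regressor g(C) = 1 − e^(−BC), with the (0, 0) anchor appended as an
  ordinary point.

Inversion is the exact algebraic inverse C_x = (k/(BD))·ln(A/(A−I_x)),
implemented with `expm1`/`log1p` so forward/inverse round-trips hold to
1e-12 across the full range. The error budget is first-order quadrature
with analytic partials (∂C/∂B = −C/B, so B's relative contribution is
exactly ΔB/B = 8.7% with the defaults — below the design's "almost 10%"
bound); an I_x term is included when an uncertainty is supplied (the
workflow uses the standard error of the gated mean combined with the stock
replicate scatter). The detection limit is the inversion of the
negative-control fluorescence; smaller results are flagged out of range.
Saturated samples (I_x ≥ A) are flagged and also marked out of range — a
saturated measurement is not quantifiable.

One documented inconsistency: evaluating the inversion at the published
worked-example inputs (A = 355.7, B = 0.069, I_x = 267, D = 0.1, k = 1.6)
gives 322.0 ng/mL, not the quoted 241 ng/mL, and no single input
can be adjusted to reconcile them. The package reports the direct
evaluation; nothing is tuned toward the quoted result.

## 7. The synthetic world

`gen_event_cloud()` draws three Gaussian clusters in FSC-SSC — a low-lying
noise cloud, a central singlet disk, and a smaller doublet cluster at the
upper right — with doublet FL4 constructed as the *sum of two independent
singlet draws*, making the doublet correction unbiased for the singlet
mean by construction. FL4 noise is normal truncated at zero (means are
large relative to spreads in the modeled regime, so truncation is
negligible; lognormal is selectable). Cluster geometry and the default
G1/G2 polygons are published in `inst/extdata/synthetic_config.json` so
gate membership in tests is stable.

Values the design description does not state, chosen once as a realistic
stated world and not revisited: per-event singlet FL4 spread 25 ERF, stock
background 100 ERF (replicate-mean jitter 1 ERF), per-cloud counts 300
noise / 2000 singlets / 200 doublets (~9% doublet events), calibration
truth A = 355.7 ERF, B = 0.069 mL/ng, reference channels at 40/60/75 ng/mL
and a neat sample at 250 ng/mL with D = 0.1, k = 1.6.

What a green end-to-end test establishes — and what it does not: generated
data follow the saturation model exactly (no matrix effects, no
channel-to-channel A variation, no instrument drift, no spillover), and
the frozen B equals the generating B, so the ΔB error term is
conservative. Recovery coverage on this world therefore validates the
*pipeline arithmetic and its error bookkeeping*, not the immunochemistry.

## 8. Numerical choices

* Gradients of |H|: central differences, step 10 µm at applicator scale,
  0.1 µm within ten wire radii of the wire (closed-form gradients are used
  where available: the wire's r⁻³ law).
* Capture integration: explicit Euler with the 20%-of-remaining-distance
  radial cap; far-field step 1 ms in tests (0.1 ms default headroom);
  halving the step changes capture fractions by <1%.
* Duct series: 25 odd terms; the normalization integral is closed-form, so
  truncation affects only the profile shape (<0.05% on the rate check).
* Degenerate inputs: empty gates are flagged rather than NaN-propagated;
  a fixed-B fit whose plateau is indistinguishable from zero (dA ≥ A)
  invalidates quantification (all samples out of range) instead of
  producing meaningless concentrations.
* Seeds: every generator is a pure function of spec + seed (RNG state
  saved/restored), so runs are byte-reproducible.

## 9. Known limitations

The duct profile ignores the wire's hydrodynamic perturbation; bead
magnetization defaults are force-calibrated rather than vendor-measured;
aggregates beyond doublets are not modeled; ERF is taken as-is with no
inter-lot standardization; and the magnetics assume ideal uniformly
magnetized blocks (no demagnetization, no temperature dependence).
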