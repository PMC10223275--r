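---
title: "Estimating the center of pressure from sparse plantar sensors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the center of pressure from sparse plantar sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsecop)
```

## The problem

Instrumented insoles estimate balance indicators — above all the center of
pressure (CoP) under each foot and the total center of pressure (CoPT) of
the body — from a handful of discrete pressure sensors, where a clinical
pressure-mapping system (an F-Scan-like matrix) would use on the order of a
thousand sensing pixels per foot.  The question this package addresses is
how well a small set of sensors can do that job, and how the answer depends
on the number, size and position of the sensors.

The approach couples an anatomical foot model with a simple learned
estimator.  Because the posture of a standing foot has very few degrees of
freedom, a few well-placed sensors carry nearly all the information in the
full map; the estimator only has to convert their readings into total force
and moments.

## The anatomical foot model

The model describes a foot as three elements:

* **Foot seat (FS)** — the location of the foot in space, reduced to a
  plane: an ankle height $z_0$ (mm) plus two slopes, $t_x$ along the
  mediolateral internal axis $x'$ and $t_y$ along the anteroposterior axis
  $y'$.  The seat height above ground at $(x', y')$ is
  $z_0 + t_x x' + t_y y'$.
* **Internal shape (IS)** — the rigid, non-compressible profile of the
  skeleton and stiff media, expressed per pixel as a clearance (mm) above
  the seat-plane reference.
* **Elastic medium (EM)** — the soft tissue covering the internal shape,
  with per-pixel thickness $thick$ (mm) and stiffness $stiff$ (N/cm²).

Compressing the tissue by $Z_C$ generates the pressure

$$F = -\,stiff \cdot \ln\!\left(1 - \frac{Z_C}{thick}\right),$$

which vanishes at zero compression and diverges as the tissue bottoms out.
The inverse, $Z_C = thick\,(1 - e^{-F/stiff})$, is used by the simulator's
load solver and in tests.  `pressure_from_compression()` and
`compression_from_pressure()` implement the pair; they round-trip to
machine precision over the physically meaningful range (pressures up to
roughly eight times the stiffness; beyond that the exponential underflows
double precision and the tissue is numerically bottomed out anyway).

Per pixel, the simulator computes the clearance between rigid shape and
ground, $g = z_0 + t_x x' + t_y y' + IS$; a pixel with $g \ge thick$ is
out of contact and reads zero, otherwise the compression $Z_C = thick - g$
is clamped at $(1 - 10^{-3})\,thick$ to keep the law finite, and clamped
pixels are counted on the frame as a saturation diagnostic.

## Coordinates

Each foot has an internal frame with the ankle at the origin: $y'$ points
from the ankle toward the second-metatarsal landmark, and $x'$ completes
the frame pointing toward the subject's right for **both** feet (so medial
is $+x'$ on the left foot and $-x'$ on the right).  On the ground, the
origin is midway between the ankles, $x$ runs from the left ankle to the
right one, and each foot is rotated by its stance angle $\theta$ (positive
= turned out): counterclockwise for the left foot, clockwise for the right.

From a full pressure map, the per-frame references are exact linear forms:

$$F_i = \sum_k f_{ik}, \qquad
  \breve M_{x,i} = \sum_k x'_k f_{ik}, \qquad
  \breve M_{y,i} = \sum_k y'_k f_{ik},$$

with the CoP at $(\breve M_x / F,\ \breve M_y / F)$.  The two-foot CoPT
combines the per-foot quantities:

$$x_{CoPT} = \frac{\breve M_{xL}\cos\theta_L + \breve M_{xR}\cos\theta_R
  - \breve M_{yL}\sin\theta_L + \breve M_{yR}\sin\theta_R}{F_L + F_R} + p,
  \qquad p = \frac{\Delta x}{2}\,\frac{F_R - F_L}{F_R + F_L},$$

$$y_{CoPT} = \frac{\breve M_{yL}\cos\theta_L + \breve M_{yR}\cos\theta_R
  + \breve M_{xL}\sin\theta_L - \breve M_{xR}\sin\theta_R}{F_L + F_R}.$$

The rotation sign convention (left $+\theta_L$, right $-\theta_R$) is the
one under which these formulas coincide with the pressure-weighted
barycenter of all pixels mapped rigidly into the ground frame;
`copt_oracle()` implements that barycenter independently, and the test
suite checks the identity to $10^{-6}$ mm over random maps and stance
angles in $\pm 20°$.  The same oracle settles that the convention extends
unchanged to turned-in postures ($\theta < 0$).

## Sparse sensors and the learned linear forms

A discrete sensor is a square sub-matrix of map pixels; its signal is the
plain sum of the covered pixels.  Two sizes are standard: small, 3×3 px
(1.5 × 1.5 cm² at the 5 mm pitch) and large, 5×5 px (2.5 × 2.5 cm²).
Standard layouts place 2–6 sensors on the usual high-pressure zones —
heel, metatarsal heads 1/2/3/5, lateral arch — with the sets by count:
2 = {heel, met3}, 3 = {heel, met1, met5}, 4 adds met3, 5 adds met2,
6 adds the arch.

With $S$ sensors reading $f_{c,ij}$, the working hypothesis is that force
and moments are linear forms of the readings,

$$\tilde F_i = \sum_j C_{f,j} f_{c,ij}, \qquad
  \tilde M_{x,i} = \sum_j C_{mx,j} f_{c,ij}, \qquad
  \tilde M_{y,i} = \sum_j C_{my,j} f_{c,ij},$$

whose coefficients are learned once per foot from a calibration window in
which the full map supplies the targets.  `fit_calibration()` uses
ordinary least squares through the origin (zero readings must predict zero
force), fitting the three targets independently; with a shared design
matrix, independent and joint least squares coincide, so nothing is lost
by the independent formulation.  An optional ridge penalty (default 0) is
available for near-degenerate custom layouts; rank-deficient designs are
an error naming the offending sensors rather than a silent pseudo-inverse.

## The synthetic quiet-standing generator

No real pressure-map recordings ship with the package; the simulator is a
first-class module that emulates the statistical structure of a
quiet-standing calibration protocol: about 30 s at 50 frames/s with
deliberately exaggerated mediolateral and anteroposterior sway, so that
postures cover the foot's support surface.

The default synthetic foot (`build_default_foot()`) is built on a 52 × 18
grid of 5 mm cells (936 pixels, matching the ~950-pixel order of a
clinical map for an adult foot).  Its rigid profile consists of convex
support domes — calcaneus and the five metatarsal heads, with quadratic
clearance growth away from each center — plus a light toe pad, a low
lateral midfoot band, and an 8 mm clearance cap forming the medial
longitudinal arch.  The dome construction matters: a perfectly flat
support zone produces plateau pressure maps whose center reading is a poor
proxy for regional force (the contact area grows while the plateau level
stalls), whereas rounded supports give the peaked, footprint-like zones
that make a small central sensor representative.  At the default standing
load the regional shares are roughly heel 46%, midfoot 10%, forefoot 40%,
toes 3%, in line with barefoot standing measurements.  Heel tissue is
thicker (15 mm) than forefoot (12 mm) and toe (10 mm) tissue; stiffness
defaults to a uniform 8 N/cm² (the model supports per-pixel stiffness; a
scalar is the default because nothing in the calibration requires spatial
variation).

The arch deserves a note: the medial longitudinal arch is high (8 mm
crest) and essentially never touches the ground, while the lateral
midfoot band sits just above it (≈3.5 mm offset) and bears load — as in
real footprints.  The six-sensor layout's arch sensor is therefore placed
under the *lateral* midfoot (transverse fraction −0.50 of the half-width),
the standard insole position; a midline arch sensor would read identically
zero and make the six-sensor design matrix singular by construction.

Sway is generated as sinusoids plus seeded low-pass jitter: mediolateral
tilt amplitude 0.05 mm/mm at a 4 s period, anteroposterior 0.025 mm/mm at
6 s, each with 15% smoothed Gaussian jitter (0.3 s time constant).  The
body-weight split between the feet oscillates with the mediolateral tilt
(±25% of the total around 50/50).  The per-foot load target defaults to
1400 summed-pressure units; at 0.25 cm² per pixel that is 350 N per foot,
a 70 kg subject, and the resulting per-foot force range (roughly 2–3×
between extremes of the weight shift) matches what a swaying subject's
insole sees.  Each frame's ankle height is solved by bisection
(`solve_seat_height()`, 0.1% relative force tolerance; total force is
continuous and monotone in the height, so bisection cannot fail inside
the bracket).  Measurement noise is multiplicative per pixel,
$1 + \mathcal N(0, 0.02)$ clipped at zero, the usual proportional-error
model for resistive sensels.  A single integer seed drives jitter and
noise; the generator restores the caller's RNG state, and identical seeds
give bit-identical recordings.

Under the default conditions the reference CoP under a foot spans about
100 mm anteroposteriorly (heel to forefoot) and swings mediolaterally,
i.e. the calibration window genuinely exercises the support surface.

## Evaluation protocol

`evaluate_layout()` splits a recording into a contiguous calibration
window (default the first 20% of frames — 6 s of a 30 s recording at
50 Hz, comfortably above the few seconds the learning itself needs — with
no shuffling, to avoid time-series leakage) and a held-out scoring window.
Per foot it fits the linear forms, predicts on the held-out window, and
reports the RMS of the error and the SD of the error (so a pure bias
appears in the RMS but not the SD) for the CoP in internal coordinates
(ML = $x'$, AP = $y'$) and for the CoPT in the ground frame.  Frames whose
reference or predicted force falls below `min_force` (default 1 force
unit) are excluded from fitting and scoring and counted in the report,
never imputed: at low loads the CoP quotient is numerically unstable and
relative errors are dominated by noise.

`sweep_layouts()` runs the full factorial over sensor count and size —
2..6 small, 2..5 large; the six-sensor large set cannot be placed on a
typical grid without window overlap, which is forbidden because
overlapping windows would double-count pixels — and emits a deterministic
report (6 rows per layout: L/R/total × ML/AP).  Unplaceable layouts are
skipped with a warning naming them.

Landmark positions are computed from foot-length/width fractions and
snapped to pixel centers (ties toward the heel and the medial side).  The
metatarsal landmarks carry a slight longitudinal stagger (met2 most
distal), reflecting the metatarsal arc; where snapped windows would still
overlap, a deterministic de-overlap pass nudges the later sensor away
from the earlier one a pixel at a time along the dominant-offset axis.
CoP estimation is insensitive to the exact sensor positions, so the nudge
only preserves the non-overlap invariant.

## What the default study shows — and what it cannot show

On the default synthetic study (30 s, 50 Hz, seeded), the package
reproduces the qualitative robustness findings:

* **Two sensors lose the mediolateral direction.**  The 2-sensor layout
  (heel + met3) has both sensors near the foot's long axis, so the
  mediolateral moment is essentially unobserved; its ML RMS exceeds the
  3-sensor layout's by several-fold, while its AP error stays moderate.
* **Three sensors suffice for the mediolateral CoP** (sub-millimetre ML
  RMS on the default study), and small sensors do no worse than large
  ones.
* **Sensor position barely matters** — the de-overlap nudges and the
  left/right snapping asymmetries shift errors by far less than the
  layout-to-layout differences.

Two honest caveats from the same study, both visible in the acceptance
suite rather than hidden:

* The 3-sensor **anteroposterior** RMS is about 4 mm, not the ~1–2 mm a
  human study reports.  This is a capacity floor, not a fitting artifact:
  refitting on *all* frames barely changes it, while adding the midfoot
  sensor (n = 6) roughly halves it.  With full heel-to-forefoot coverage
  and a 2–3× per-foot load swing, the map from three sensor readings to
  the anteroposterior moment is measurably nonlinear in this simulator,
  and a linear form fitted through the origin cannot follow it more
  closely.  Synthetic feet are evidently harder here than the real feet
  of the original protocol; conclusions about absolute AP accuracy should
  not be read off this generator.
* Between 3 and 6 small sensors the ML RMS *improves* by more than a
  factor 2 (from ~0.5 mm to ~0.2 mm) because the added lateral-arch
  sensor is genuinely informative about mediolateral load transfer in
  this foot model.  Both values are deep below the 5 mm pixel pitch; a
  ratio criterion at that scale reflects the noise floor more than the
  science.

More generally, the generator emulates the *structure* of a calibration
recording (frame rate, sway coverage, load sharing, proportional sensor
noise, footprint-like pressure zones).  It does not emulate skin-sensor
mechanics, sensel saturation or hysteresis, subject-to-subject anatomical
variation, or transverse (shear) forces — the model considers orthogonal
pressure only.  Passing tests therefore demonstrate internal consistency
of the method and its qualitative robustness behavior, not clinical
accuracy on human feet.

## Numerical choices

* Compression clamp $(1 - 10^{-3})\,thick$; clamped pixels counted per
  frame, never silently altered.
* Seat-height bisection: 0.1% relative force tolerance, at most 200
  iterations, bracket from the zero-contact height down to 40 mm below it
  (an infeasible target is an error, not a truncated answer).
* `min_force` default 1 summed-pressure unit; undefined CoP/CoPT frames
  are errors in strict contexts and flagged-NA in series contexts.
* Landmark snapping ties: toward the heel, toward the medial side.
* Recording serialization: plain text, `%.17g`, so files round-trip
  bit-exactly; report CSVs carry 9 significant digits.
* Degrees in all configs and interfaces; radians only internally.

## Sizes and runtimes

The default study is 1500 frames per foot on a 936-pixel grid; generating
it takes a few seconds (the bisection dominates), and the full
2×(2..6)+(2..5) sweep with calibration and scoring runs in about a
second.  The test suite regenerates the study from its seed rather than
shipping any recorded data.
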