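---
title: "Bioheat modelling and thermographic screening of thyroid nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioheat modelling and thermographic screening of thyroid nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thyrotherm` asks a clinical feasibility question with two linked
computational studies: *can a malignant thyroid nodule be seen from outside,
as a skin-temperature anomaly?* The first study answers it with physics — a
steady-state Pennes bioheat model of a neck cross-section — and the second
with image analysis: a screening pipeline that turns an infrared thermogram
into candidate nodular regions via contralateral asymmetry, plus the
augmentation and evaluation machinery needed to train a classifier on the
resulting crops.

## The bioheat model

Tissue temperature obeys the Pennes balance

$$\rho c \frac{\partial T}{\partial t} \;=\; k\nabla^2 T
  \;+\; w_b\rho_b c_b\,(T_b - T) \;+\; Q_{met} \;+\; Q_e,$$

where the perfusion term is a relaxation toward arterial blood temperature
$T_b = 37\,°C$ with volumetric rate $w_b\rho_b c_b$ (W m^-3 K^-1), $Q_{met}$
is metabolic heat and the external source $Q_e$ is zero throughout this
work. We report the steady state ($\partial T/\partial t = 0$); the
backward-Euler transient solver exists as a consistency tool (a cold start
relaxes to the steady field) rather than as a reported quantity.

Two derived constants organise all the intuition:

* the **perfusion ceiling** $T_b + Q_{met}/(w_b\rho_b c_b)$ — the
  temperature a uniformly perfused tissue approaches far from boundaries;
* the **thermal penetration length** $\sqrt{k/(w_b\rho_b c_b)}$ — the
  distance over which a boundary disturbance decays inside a perfused
  tissue.

### Geometry

The neck is a half-disc on a flat chord (the posterior cut, Dirichlet at
core temperature 37 °C), with concentric layers from the inside out: a
muscle-tissue interior, a 1.0 cm muscle layer, a fat layer (0.1 / 0.6 /
1.2 cm in the sweep) and 0.2 cm of skin, cooled by Robin convection
($h = 3.6$ W m^-2 °C^-1, ambient 20 °C). The trachea is a circular hole
(radius 1.0 cm) tangent to the chord on the midline, with an insulated
boundary; the thyroid is a crescent band hugging the trachea anteriorly
over ±70° about the midline. An elliptic malignant nodule sits in the left
lobe; the four studied sizes are 0.5×0.78 to 2.0×3.14 cm (minor×major
diameter).

Two geometric constants are calibrations rather than printed values, and
both are configurable:

* **Core radius 3.87 cm.** Chosen once so that with skin 0.2 + muscle 1.0 +
  fat 1.2 cm the semicircular skin arc is $\pi \times 6.27 = 19.7$ cm, the
  reported arc length of the fattest configuration.
* **Gland extent and nodule anchor.** The gland band spans from the trachea
  wall to the core boundary (the thyroid is a superficial organ lying
  directly under the strap muscles), and the default nodule anchor puts the
  ellipse centre on the gland's anterior face, half the band's angular
  extent to the left of the midline — a palpable anterior nodule whose
  overgrowth bulges into the muscle plane. The gland region is defined as
  band ∪ nodule ellipse: a nodule is an *increase* in gland volume, and the
  two largest studied sizes are simply thicker than a normal lobe. The
  containment rule rejects nodules whose centre leaves the band or whose
  ellipse reaches the fat layer, the chord or the trachea.

Layer boundaries follow a half-open convention (the outer layer owns the
shared boundary), so tissue lookup partitions the domain exactly.

### The perfusion-unit question

The published tissue table prints perfusion in 1/s. Taken literally, the
tumour value $w_b = 0.465$ clamps the nodule to a ceiling of
$37 + 55386.6/(0.465 \cdot 1050 \cdot 3770) = 37.03\,°C$ — a nodule
*colder* than the reported 38.4 °C and incapable of any skin signature.
The package therefore exposes the unit interpretation explicitly
(`tissue_properties(perfusion_units = ...)`):

* `"literal"` — all values in 1/s (the default; faithful to the table);
* `"per_min"` — all values in 1/min;
* `"calibrated"` — the physiological reading: the three layer tissues keep
  their classic per-second perfusions (0.00196, 0.000501, 0.000708 1/s are
  textbook skin/fat/muscle values), the thyroid keeps 0.098 1/s — high, but
  the thyroid genuinely is one of the most perfused organs, at roughly
  5 mL min^-1 g^-1 — and only the tumour's 0.465 is read as 1/min
  (0.0078 1/s, a typical solid-tumour perfusion; 0.465 1/s would be five
  times the normal gland's blood flow).

The calibrated reading reproduces the reported interior field remarkably
well: the muscle interior plateaus at its per-second ceiling of 37.40 °C
(the printed interior value), the strongly clamped contralateral lobe reads
37.0 °C against the printed ~37.2 °C, and the radial profile through the
nodule drops ≈0.54 °C across the muscle layer and ≈1.60 °C across the fat
layer against printed drops of 0.5 and 1.8 °C.

One printed number is *not* reproducible under any defensible unit reading:
the 38.4 °C nodule centre. The reason is a bath limit, not a solver
artefact. With the nodule's surroundings capped at the muscle ceiling
(37.4 °C), the centre excess over the bath is bounded by roughly
$Q_{met}\,ab/(4k)$-type self-heating, which for this $Q_{met}$ and a
1.0×1.57 cm ellipse is ≈0.4–0.5 °C for *any* perfusion value — the excess
is $Q_{met}$-limited at low perfusion and ceiling-limited at high
perfusion. Our solve gives 37.87 °C. Reaching 38.4 °C requires the
*surrounding gland itself* to run hot (its perfusion read as 1/min, ceiling
39.35 °C), but that configuration drives the contralateral lobe to ≈38.3 °C,
over a degree above its printed value, and inflates both profile drops.
The two printed numbers 38.4 (nodule) and 37.2 (contralateral lobe) are
mutually incompatible in this model family; we chose the reading that gets
the lobe, the plateau and both layer drops right and report the
nodule-centre temperature the physics actually yields (the reference
simulation ships both the literal and calibrated runs, and the acceptance
suite documents the one discrepant quantity rather than tuning it away).

### Discretisation

The solver is a finite-volume scheme on a **polar grid** $(r, \theta)$ over
the half-disc. This is deliberate: the skin arc, the flat chord and every
concentric layer interface are grid-aligned, the Robin surface has exactly
its physical area (a Cartesian staircase overestimates a circle's boundary
by up to $4/\pi$, which directly distorts the convective heat loss and the
19.7 cm arc), and an even angular cell count with explicitly mirrored
coordinates makes a nodule-free problem symmetric to machine precision.
Conductivity is harmonically averaged across cell faces (half-cell series
resistances), so material jumps are handled conservatively. The assembled
system is symmetric positive definite and solved by sparse Cholesky
factorisation; the relative residual is checked against 1e-8 and is in
practice ~1e-16. The same face-based assembly runs a one-dimensional
Cartesian slab, which is how the solver is verified against the closed-form
multilayer solution (interface-continuity constants solved exactly, with
row equilibration and one step of iterative refinement; agreement is within
1e-3 °C at 0.01 cm resolution, and interface flux continuity holds to
machine precision).

Default resolution is 0.025 cm (≈160 k unknowns, ~2 s per solve); the
solver refuses grids that put fewer than 4 cells across the skin layer.
Halving the step from 0.05 to 0.025 cm moves the nodule-centre temperature
by ~0.002 °C. The 4×3 sweep runs at 0.05 cm — 12 solves trade a few
millikelvin for a 10× speedup, far below the 0.05 °C camera-perceptibility
threshold used to flag contrasts. Field sampling is bilinear in $(r,
\theta)$ with weight renormalisation next to the unsolved trachea hole;
skin-surface temperatures are Robin-extrapolated from the outermost cell.

The transient scheme is backward Euler with the operator factorised once;
it is unconditionally stable, its fixed point is the steady solution, and a
cold start at ambient temperature approaches the steady field monotonically
(the suite checks a 4-hour simulated horizon; full convergence below
0.01 °C needs roughly a day of simulated time because the deep tissues
equilibrate on an $L^2/\alpha$ scale of hours).

## The screening pipeline

A thermogram is a real-valued 640×480 temperature matrix $M$ with a neck
ROI mask. Screening proceeds exactly in the published order: map in-ROI
temperatures linearly to grey levels [1, 255] (background 0; a constant ROI
maps to 255 by convention); take the ROI centroid as the vertical mirror
axis; form the asymmetry parameter
$P_A(x, y) = M(x, y) - M(2o_x - x,\, y)$ on pixels whose mirror is also in
the ROI; keep pixels with $P_A > l$ (hot-side selection — the mirror
partner carries the negative value and never triggers); clean with a
morphological opening (disc, default radius 3 px); extract 8-connected
components with tight bounding boxes; crop, bilinearly resize to 224×224,
replicate to 3 channels and scale to [0, 1].

Numerical conventions worth stating:

* The mirror column is `round(2 * o_x) - x`. Doubling before rounding keeps
  the lookup a pure pixel difference while preserving half-integer axes
  exactly (a symmetric ROI with $o_x = 2.5$ must pair columns 1↔4 and 2↔3;
  rounding $o_x$ first would pair 2 with itself). $P_A$ is computed from
  $M$, never from the 8-bit grey image.
* The default threshold $l = 0.3\,°C$ is the published dysfunction level
  for the asymmetry parameter; the operational value used in the source
  study is unprinted, so `l` is an explicit argument everywhere.
* Opening uses a disc element; note a solid square is *not* open-stable
  under a disc — corners are rounded (3 px per corner at radius 3), which
  the tests pin against a brute-force erosion/dilation oracle.
* Components are 8-connected (in-package labelling; the available library
  routine is 4-connected and would split diagonally linked blobs).
* A minimum-area filter exists but defaults to off, keeping the extraction
  faithful to the printed steps.

Antisymmetry $P_A(x,y) = -P_A(\text{mirror})$ holds exactly on every
defined pixel; a perfectly symmetric matrix yields zero candidates at any
positive threshold; raising $l$ shrinks the candidate mask monotonically;
and mirroring the thermogram mirrors every bounding box (pipeline
equivariance). These are the invariants the suite enforces.

## Augmentation bookkeeping

Each augmentation operation doubles the working set: the operation is
applied to *every* current element (including earlier outputs) and the
results are unioned in. A plan of $n$ operations therefore multiplies the
set size by $2^n$ structurally, with no deduplication — that arithmetic is
what makes 16 nodular crops into $16 \cdot 2^4 = 256$ images (flip + three
stretches) and 68 non-nodular crops into $68 \cdot 2^2 = 272$ (flip + one
stretch), 528 in total. The stretch percentiles are unpublished; the
defaults (1,99), (2,98), (5,95) are distinct so no two operations are
literally identical, and (2,98) serves the non-nodular plan. Augmentation
is fully deterministic, never changes spatial dimensions (rescaling is
deliberately not available — it would distort nodule size), and each output
carries a provenance chain.

## The synthetic-data generator

Patient thermograms are not public, so the generator produces the
*statistical situation* the pipeline assumes: an elliptic neck ROI on black
background; a smooth base field that is mirror-symmetric about an integer
centre column by construction; an optional nodular hot ellipse — a
truncated Gaussian with peak `delta_t`, the smooth diffusion-like footprint
Study-1 physics predicts, with the ellipse support as ground-truth mask;
optional benign elongated warm streaks (the normally hypervascular regions
that survive screening as non-nodular candidates, needed to populate the
second class); a low-order antisymmetric drift (default amplitude 0.1 °C)
standing in for imperfect patient symmetry; and i.i.d. Gaussian sensor
noise, default σ = 0.04 °C, a typical uncooled-microbolometer sensitivity.
All randomness flows from one master seed through deterministic per-patient
derivation, and a fixed seed reproduces the matrix bit for bit.

What passing tests on this generator do *not* show: robustness to real
acquisition artefacts (clothing, hair, emissivity variation, ROI
segmentation error), to non-elliptic lesions, or to inter-patient anatomy;
the ROI shape family and the drift model are modelling choices, exposed as
parameters rather than asserted as truths. Classifier results on synthetic
crops likewise say the harness works, not that the published accuracies
transfer.

## Classification harness

The deep transfer-learning path of the source study needs the undeposited
patient images, so the package ships a deterministic baseline: intensity
summary features (moments, quantiles, centre-vs-periphery excess, gradient
energy) into a logistic regression, behind the same train/score interface a
heavier model would use. `evaluate()` computes the confusion matrix at a
0.5 threshold (configurable), precision, recall, and threshold-free ROC/PR
curves with trapezoidal areas; a single-class truth reports an undefined
ROC AUC as `NA`. The published confusion matrix (25 test cases: 32 % TP,
8 % FN, 0 FP, 60 % TN) evaluates to accuracy 92 %, precision 100 %, recall
80 % — the worked example in the test suite. The published AUC values
(0.14 ROC / 0.33 PR) are inconsistent with that same perfect-precision
matrix under standard conventions (they suggest an inverted score
orientation); the harness computes standard AUCs and leaves the discrepancy
documented rather than emulated. Cross-validation is intentionally absent
by default, matching the source protocol.

## Problem sizes and runtimes

The reference solve (0.025 cm, ~160 k unknowns) takes ~2 s; the 12-solve
sweep at 0.05 cm under a minute; screening a full 640×480 frame ~0.5 s; the
complete test suite about a minute. The acceptance script
(`scripts/acceptance.R`) performs one reference solve and reports the five
study quantities.

## Known limitations

* Two-dimensional cross-section only; no carotid/jugular advection, which
  the source itself lists as future work.
* The nodule-centre temperature question discussed above: the printed
  38.4 °C is unreachable while the printed lobe/profile values hold.
* The trachea insulation is applied on the hole boundary (the plausible
  reading of an ambiguous statement).
* The screening ROI is taken as given; automatic neck segmentation is out
  of scope.
* The baseline classifier is a harness, not a claim about CNN performance.
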