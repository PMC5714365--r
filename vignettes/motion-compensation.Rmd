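---
title: "Respiratory-motion compensation for scattered proton therapy: models and methods"
author: "proton4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory-motion compensation for scattered proton therapy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Proton dose is deposited up to a sharply defined range and almost not at all
beyond it. The range in tissue is governed by the water-equivalent path
length (WEPL), the line integral of relative stopping power (RSP) along the
beam. For a liver-dome tumor the beam path crosses the lung-liver interface,
and breathing translates that interface cranio-caudally by 0.5-1.3 cm: the
same geometric ray can gain or lose several millimetres of water-equivalent
depth between inspiration and expiration. A plan computed on a single CT
therefore systematically misses part of the target during parts of the
breathing cycle. `proton4d` implements and compares the four standard
single-CT planning strategies for passively scattered (double-scattering)
proton therapy:

* **AVG** - plan on the per-voxel mean of the 4D CT phases;
* **MIP** - plan on the per-voxel maximum (density envelope);
* **OVR** - AVG with the PTV density overridden to the average gross-tumor
  density;
* **mAVG** - the AVG plan with a *field-specific distal margin*: each
  field's distal range and modulation are increased by that field's
  MIP-minus-AVG fitted range difference, keeping all other hardware frozen.

Each strategy is judged by recomputing its dose on every breathing phase
with frozen hardware, evaluating the PTV dose indices D95%, D99% and D100%
(the minimal dose covering x% of the target), and requiring all index
changes to stay within an inclusive +/- 2 percentage points of the 3D
apparent plan - per phase and for the equal-weighted 4D composite dose.

## The synthetic phantom

No patient 4D CT ships with the package; `generatePhantom()` builds a
deterministic analog:

* **Anatomy.** A planar liver-dome flank ascends from posterior-right
  toward an anterior-left dome plateau (`domeTop`, default 160 mm), with
  lung above the surface, liver below, a soft-tissue body wall (10 mm) at
  the lateral faces, and solid liver below `liverFloor`. A spherical tumor
  (24 mm, 60 HU) sits beneath the flank, abutting the diaphragmatic surface
  as dome lesions do.
* **Motion.** Liver, surface and tumor translate rigidly and cranially by
  `amplitude * (1 - cos(2*pi*phase/100))/2` - zero at the 0% phase
  (end-inspiration), the full peak-to-peak amplitude (default 1.3 cm, the
  upper end of clinically reported liver-dome motion) at the 50% phase.
* **Densities.** Liver 100-130 HU (an axial gradient moving with the
  liver), lung -900 to -300 HU (static gradient), wall 40 HU. A single
  seeded Gaussian noise field (sd 10 HU) is added to *every* phase, so the
  series is bit-reproducible and a zero-amplitude series is identical
  across phases.

The *planar* flank is a deliberate idealization. Crossing a plane, every
ray of a coplanar field sees the same motion-induced WEPL swing
(`displacement / slope` times the lung-liver RSP contrast, about 0.2 cm per
field at the defaults). A single per-field distal margin is then exactly
the right compensation - which is the regime the field-specific margin
method addresses, and the regime clinical liver fields are planned into by
beam-angle selection. A strongly curved interface crossed tangentially
would produce per-ray swings that no single margin can cover; the phantom
deliberately does not model that failure mode (see *Limitations*).

What the phantom does **not** emulate: deformation (the liver translates
rigidly), hysteresis and irregular breathing, anterior-posterior or lateral
motion components, realistic CT texture, and beam paths that graze a curved
dome apex tangentially. Tests passing on this phantom therefore demonstrate
the mechanics of the method - range arithmetic, margin construction,
composite evaluation - not its clinical performance on deformable anatomy.

```{r}
library(proton4d)
series <- generatePhantom(phantomConfig())       # 96^3 voxels at 2 mm
structures <- buildStructureSet(series, ptvMargin = 5)
```

## From CT numbers to dose

**Calibration.** `huToRSP()` applies a piecewise-linear HU-to-RSP curve,
clamped at its end breakpoints. The default anchors
(-1000 -> 0.001, -700 -> 0.29, -300 -> 0.71, 0 -> 1.00, 60 -> 1.04,
120 -> 1.07, 1600 -> 1.85) put water at 1 and give representative liver
3-4 times the stopping power of representative lung, the contrast that
drives the range perturbation. Any two-column CSV can replace it.

**Pristine peaks.** `pristineBragg()` uses a power-law stopping
approximation (exponent p = 1.77 of the range-energy relation): dose
proportional to `(R-z)^(1/p-1) + k*(R-z)^(1/p)` before the peak, convolved
with a Gaussian range-straggling kernel `sigma = 0.012 R^0.935` cm. The
singular term is integrated analytically over each depth bin. An optional
`rangeSpread` (added in quadrature) models beamline energy spread; the
planning layer defaults it to 0.12 cm, which widens the 80-20% distal
falloff from about 0.25 cm (pure straggling) to about 0.35 cm - typical of
double-scattering systems and important for how partial range errors grade
into dose.

**SOBP synthesis.** `buildSOBP(R, M)` spaces pristine peaks at 0.4 times
the 80-20% falloff and solves nonnegative least squares against a flat unit
target. The distal range and modulation are *defined* on the 90% isodose
levels, so the deepest nominal range and the plateau start are calibrated
iteratively (with a short line search to resolve the discreteness of the
peak comb) until the measured distal 90% depth equals R within half a depth
step (0.025 cm) and the 90-90 width equals M within about one step. The
flat target stops one falloff width short of the deepest peak - pushing it
further creates a least-squares "horn" before the falloff. Plateau
flatness (+/- 2%) is asserted between the shoulder regions: the rise from
the 90% level to the plateau and the falloff back to it span a few falloff
widths and belong to the 90-90 definitions, not to ripple. At near-full
modulation (M close to R) the entrance dose reaches the 90% level and the
proximal-90% depth degenerates to the surface; the width identity is then
reported against the surface.

**Broad-beam dose.** Beams are parallel (no divergence) and restricted to
the four cardinal axial directions; the default pair is posterior (180)
plus right-lateral (270), orthogonal and coplanar. `traceWEPL()` cumulates
RSP along each ray to the voxel center. The aperture is the beam's-eye-view
PTV projection dilated by 1 cm (Euclidean); the compensator gives every
PTV-crossing ray thickness `R - WEPL(distal PTV surface)`, rays in a 1 cm
border ring take the minimum neighbouring thickness (border smoothing), and
no smearing margin is applied. A voxel's dose is the SOBP evaluated at
`WEPL + compensator thickness`, zero outside the aperture (an optional
Gaussian penumbra, sigma 3 mm, is off by default so that range behaviour
stays exact). Plan doses are normalized so the minimum PTV dose is exactly
95% of prescription.

```{r}
plans <- buildMAVGPlan(series, structures)   # AVG, MIP and mAVG in one call
ovr <- buildPlan("OVR", series, structures)
report <- acceptabilityReport(plans$mavg, series)
report
```

## Design choices where the design was open

* **PTV margin.** A configuration parameter, default 5 mm, recorded in the
  `StructureSet`.
* **Override volume and value.** The OVR override is applied to the PTV,
  and the override value is the *per-phase gross-tumor density*
  (`grossTumorDensity()`: mean HU over each phase's GTV on that phase's
  scan, averaged), not the mean over the smeared ITV on the AVG scan. The
  ITV average is contaminated by every low-density voxel the tumor track
  sweeps through and can sit hundreds of HU below the tumor's actual
  density, which defeats the override's purpose. Both conventions are
  available in `overridePTVDensity()`.
* **mAVG construction.** The margin widens the SOBP (`R <- R + dR`,
  `M <- M + dR`): the proximal 90% depth is unchanged, so the plan keeps
  the AVG plan's proximal coverage and acquires the MIP plan's distal
  coverage. Compensators and apertures are inherited unchanged, and the
  plan is re-normalized for comparability.
* **4D composition.** Rigid voxel-wise averaging with uniform phase weights
  on the common grid. The phantom's known motion field is deliberately not
  used for dose warping: the package mirrors the clinical situation in
  which no deformable 4D dose tool is available.
* **Acceptability bound.** Inclusive at exactly 2.0 percentage points of
  prescription; each strategy's deltas are taken against its own 3D
  apparent plan.
* **Dose indices.** Sort-based order statistics with linear interpolation
  at non-integer ranks; D100% is the structure minimum. The conformity
  index counts the total over target volume receiving at least the 95%
  level (the coverage level plans are normalized to).

## What the default experiment shows

The acceptance suite runs the full workflow on the default phantom
(96^3 voxels, 1.3 cm amplitude, two fields; about a minute on one CPU) and
verifies the pattern the strategies are known for: the AVG plan fails the
+/- 2 point criterion at end-expiration with the dominant violation in
D100% (tens of points - the distal target surface falls beyond the
under-estimated range), its 4D composite fails as well, while the mAVG
plan - whose per-field margins at the defaults are about 0.2 cm - passes
the criterion on all three indices of the 4D composite. A zero-motion,
homogeneous-density control collapses all four strategies onto one plan
with vanishing deltas. `scripts/acceptance.R` recomputes the two headline
numbers (the mAVG 4D composite deviation and the AVG end-expiration D100%
drop) from scratch.

## Known limitations

* The pure ray-casting engine has no lateral scatter: range errors turn
  into dose errors voxel-by-voxel, more sharply than a pencil-beam or
  Monte Carlo engine would show.
* The global modulation (`M = R` minus the minimum proximal-surface WEPL
  over all rays, per field) is generous whenever the shallowest proximal
  surface and the longest target chord occur on different rays - true for
  any target poking into lung. After compensation no PTV voxel then sits
  near the proximal 90% shoulder, so the engine does not reproduce the
  proximal underdose that MIP-based clinical plans show at full
  inspiration; on the phantom the MIP plan stays within tolerance at every
  phase.
* For the same reason the density override cannot rescue the phantom's
  coldest expiration voxels: their range error accumulates on the flank
  band *upstream* of the PTV, which the override does not touch, while
  overriding the liver-dense target with the (lighter) tumor density
  slightly shortens every fitted range. On this phantom OVR therefore does
  not improve the end-expiration D100%; the override can only help when
  the dominant range error accumulates inside the motion-diluted target
  volume itself, a configuration this phantom's margin-exact geometry
  excludes by construction.
* Compensator border smoothing uses a minimum filter over the smoothing
  ring; clinical systems' exact smoothing operators differ.
* All evaluation is physical dose in % of prescription; no RBE weighting,
  fractionation, or interplay effects.
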