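---
title: "Design-based stereology on synthetic tissue: models, probes and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based stereology on synthetic tissue: models, probes and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereofract)
```

## The problem

Design-based stereology estimates 3D quantities — total particle number,
total fiber length, structure volume — from systematically sampled 2D or
thin-3D probes placed on serial histological sections. The estimators are
unbiased by construction (they rely on the sampling design, not on shape
assumptions), which makes them the reference method for quantifying neurons,
glia and axons in brain nuclei. `stereofract` implements the three probes
used in a stereological study of the bottlenose dolphin auditory brainstem
(the inferior colliculus with its central nucleus CN and external cortex EC,
and the ventral cochlear nucleus VCN), together with the downstream
bookkeeping and a synthetic-tissue simulator that supplies ground truth,
since no raw coordinate data are available for the real material.

## The estimators

**Cavalieri volume.** On every k-th section a square point grid with a
uniform random offset is laid over the traced contour and the hits are
counted: \(\hat V = d \cdot a(p) \cdot \sum_i P_i\), with \(d\) the distance
between sampled sections (section period × cut thickness) and \(a(p)\) the
squared grid spacing.

**Gundersen–Jensen CE.** The precision of a systematic-sample total is
estimated from the covariogram terms of the per-section counts
\(A=\sum c_i^2\), \(B=\sum c_i c_{i+1}\), \(C=\sum c_i c_{i+2}\):
\[\mathrm{Var}_{SRS} = \frac{3(A-\nu) - 4B + C}{240}, \qquad
\mathrm{CE} = \frac{\sqrt{\mathrm{Var}_{SRS} + \nu}}{\sum c_i},\]
for smoothness class m = 1 (divisor 12 for m = 0). The nugget
\(\nu=\sum c_i\) models local Poisson counting noise; it is on by default
for disector counts and off for planimetric Cavalieri points, both
exposed as an argument. A negative variance contribution (possible for
very short, rough count sequences) is clamped to zero.

**Optical fractionator.** Disector counts inside unbiased counting frames
are scaled by the inverse sampling fractions:
\(\hat N = \sum Q \cdot \frac{1}{ssf} \cdot \frac{1}{asf} \cdot
\frac{1}{tsf}\), with ssf = 1/k, asf = frame area / grid-cell area, and
tsf = disector height / **mounted** thickness. Using the mounted
(post-collapse) thickness matters: the disector lives in the mounted
section, and a cut-thickness denominator would scale every estimate by
the collapse factor (×2.5 here).

**Spaceballs.** Fiber length density follows from transversal crossings of
sphere surfaces: \(\hat L_v = 2\sum I / (n \cdot S)\). A full 36 µm sphere
cannot fit a 20 µm mounted section, so the probe surface is the sphere
truncated to the disector slab — a spherical zone whose area is
\(S = 2\pi r\,\min(h, 2r)\) by Archimedes' hat-box theorem. Total length is
\(\hat L_v \times\) reference volume.

## Default sampling design

The defaults are the study's probe parameters; all are constructor
arguments of `sampling_design()`.

| parameter | IC | VCN | unit |
|---|---|---|---|
| section period k | 30 | 20 | — |
| cut thickness | 50 | 50 | µm |
| mounted thickness | 20 | 20 | µm |
| SRS grid | 2000 × 2000 | 1000 × 1000 | µm |
| frame (neurons) | 150 × 150 | 150 × 150 | µm |
| frame (glia) | 30 × 30 | 30 × 30 | µm |
| disector height | 18 | 18 | µm |
| guard zones | 1 + 1 | 1 + 1 | µm |
| Spaceball radius | 18 | 18 | µm |
| Cavalieri spacing | 2000 | 1000 | µm |

Two of these are package decisions rather than study givens:

* **Mounted thickness (20 µm).** No measured post-processing thickness is
  reported; an 18 µm disector with two 1 µm guards forces at least 20 µm.
  We take exactly 20 µm (z-collapse 0.4 from 50 µm cut) as the default and
  expose it as a parameter.
* **Cavalieri point spacing.** Not reported either. 2000 µm on an IC-sized
  structure yields ≈ 227 points over every-30th-section sampling — inside
  the conventional 150–250 range and consistent with the reported CE
  bound (< 0.09). The VCN default halves the spacing to keep a similar
  total on the smaller structure.

Whether the first sampled section was chosen at random or arbitrarily is
not reported; `run_probe()` draws it uniformly from `[0, k)` but accepts an
explicit `section_offset`.

## The synthetic-tissue model

`make_region()` defines an ellipsoidal (or voxel-mask) nucleus of known
volume. Cell fields are homogeneous Poisson point processes at a stated
intensity (`simulate_neuron_field()`, `simulate_glia_field()`), with
immunoreactivity compartments (nuclear / cytoplasmic / both / none) drawn
i.i.d. from a stated mixture; glial cells are cytoplasmic-only. Fibers are
stationary isotropic segment processes of constant segment length with
Poisson midpoints and uniform orientations (`simulate_fiber_field()`).
`section_stack()` cuts the content into 50 µm coronal sections (half-open
z intervals, so the sections partition the region exactly), collapses
within-section z to the mounted thickness, scales x–y by the in-plane
shrinkage factor, and can truncate caudal sections — emulating the
specimen whose caudal VCN third was missing.

Simulator choices worth knowing:

* **Each cell is one representative point.** Whether real counts targeted
  somata or nucleoli is not reported; for point items the half-open frame
  rule is exactly the inclusion/exclusion-line rule, so the distinction
  does not affect the estimators here.
* **Poisson, not hard-core.** Estimator unbiasedness holds for any
  stationary field; interaction would only change variances. Realism of
  cell spacing is deliberately secondary.
* **Fiber edge handling.** Segments are generated in a dilated bounding
  window and clipped, so in-region length density is exactly the target
  with no boundary deficit. For probes whose surface can reach past the
  traced contour (Spaceballs at boundary sites), `dilate_um` generates the
  field in an enlarged clip region, emulating the continuous tissue that
  surrounds a real subnucleus; without it the estimator shows a small
  negative edge bias on small regions.
* **`z_window` marginalisation.** When only every 30th section is probed,
  generating fiber material solely in the sampled slabs (dilated by half a
  segment length) reproduces the distribution of the full-region process
  restricted to those slabs, at a fraction of the cost. This is an exact
  property of the Poisson construction, not an approximation.

What the simulator does **not** model: staining intensity, detection
failure, cell profiles with extent (lost-cap effects), vascular geometry,
anisotropic or inhomogeneous cell distributions (unless you build them),
and deformation other than uniform linear shrinkage. Passing recovery
tests therefore validates the estimator arithmetic and sampling logic —
not robustness to the biological messiness of real sections.

## Counting rules and numerical choices

* Half-open intervals everywhere (`[z_0, z_0+t)` sections, `[x_0,x_0+f_w)`
  frames) avoid double counting at faces exactly.
* SRS sites are grid translates whose *origin* falls inside the contour,
  which makes the expected site count exactly area / grid-cell area (the
  Cavalieri identity). Probe tallies apply the counting frame at every
  grid translate, so a design with all fractions 1 is an exact census; a
  frame that partially leaves the contour still counts the items inside
  it. A `rule = "frame"` option includes boundary sites whose frame merely
  intersects the contour.
* Sphere crossings solve the segment–sphere quadratic; tangencies
  (discriminant ≤ 0) count zero, and crossing points must lie inside the
  half-open disector slab.
* Length probes run on stacks with identity z-collapse: an anisotropic
  z-compression would destroy the isotropy the Spaceballs estimator
  assumes, and the study's length densities are referenced to Cavalieri
  volumes measured in the same cut-thickness z scale. Number probes are
  insensitive to this choice (counts are preserved by the collapse).
* Estimates store their multiplicative components; `value` is defined as
  `prod(components)`, so every reported number is reproducible from its
  record by one multiplication chain.
* Printed-style percentages round half-up (`round_half_up()`), matching
  how the study's integer percentages behave (35.5 → 36).

## Known reporting inconsistencies in the reference values

`dolphin_reference_values()` ships the study's printed numbers for the
worked examples. Three printed values are mutually inconsistent and are
carried with notes rather than silently corrected: the VCN neuron total
appears as both 3.16 million and 316.38 thousand (only the latter matches
density × volume; the package treats it as the consistent value), the VCN
density prints 2455 against 316380/129 = 2452.6, and one specimen's IC
shrinkage ratio prints 84% although the tabulated volumes give 63.5%.
Reports built with `subnucleus_report()` keep such caveats in a `notes`
field.

## Problem sizes used in validation

The recovery checks simulate the full-scale synthetic CN (1362 mm³ at
3561 neurons/mm³, i.e. ≈ 4.85 million cells per draw) for the
fractionator and label-mix targets, averaging 20 seeds in the acceptance
script and 6 in the test suite; Spaceballs runs at the printed
1.69 m/mm³ with 100 µm segments in the sampled slabs only (20 and 5
seeds respectively); the CE target uses 50 random offsets. Unit and
property tests run on millimetre-scale toy regions with hundreds of
seeds, sized so the suite finishes in a few minutes on one core; all
stochastic assertions use standard-error-scaled bounds under fixed seeds.

## Limitations

* Contours exist only for ellipsoidal regions (the cross-section is
  analytic); voxel-mask regions support volumes and point fields but not
  contour-based probes.
* Extended-object frame rules (forbidden-line logic for cell profiles),
  physical disector pairs, and nucleator/rotator probes are out of scope.
* The frame-intersection site rule is approximate for contours with
  features smaller than the frame.
* The Spaceballs estimator assumes isotropy; the test suite demonstrates
  (and quantifies) the bias for a fully z-aligned fiber field rather than
  correcting it.
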