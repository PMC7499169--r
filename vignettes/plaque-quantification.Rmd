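---
title: "Quantifying dental plaque from fluorescein UV images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dental plaque from fluorescein UV images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquant)
```

## The measurement problem

Fluorescein binds to dental plaque and fluoresces green under ultraviolet
light, while clean enamel fluoresces bright blue and the oral background
stays dark. On an 8-bit RGB photograph of a disclosed dentition this
produces a strong, nearly one-dimensional contrast: the signed difference
`G − B` is positive on plaque and clearly negative on clean enamel.
plaquant turns that contrast into planimetric measurements — per-class
areas, a combined area-and-intensity index, and growth parameters over a
longitudinal series of *plaque moments* (one patient, one timepoint, one
or more views), each measured against the patient's *reference moment*
("moment 0", typically right after professional cleaning).

The pipeline assumes: (i) images are 8-bit RGB with the dentition
occupying a substantial share of the frame; (ii) illumination is
consistent enough within a patient's series that channel means are
comparable; (iii) the reference moment is essentially plaque-free.
Nothing in the method fits a statistical model — every step is a
deterministic image transform — so the same inputs always reproduce the
same outputs, a property the tests assert down to the byte.

## Dental-area segmentation

Teeth are bright in blue and red relative to everything else, so the
per-pixel sum `B + R` (range 0–510) is thresholded at its
`background_fraction` quantile: with the default 0.75, the darkest 75% of
pixels are background and the brightest 25% are candidate foreground.
The quantile is taken over *pixel values* (the sorted value at rank
`ceiling(0.75 N)`), not over the value range; with a dark background and
a bright dentition the threshold lands between the gingiva and enamel
intensity blocks. Membership is strict (`B + R > threshold`), so ties at
the threshold fall on the background ("darkest") side.

Cleanup then proceeds in a fixed order: near-white specular highlights —
pixels whose *minimum* channel reaches `artifact_intensity_floor`
(default 240) — are removed first, since saliva and enamel reflections
are bright in all three channels while genuine dental signal is blue- or
green-dominated; isolated pixels (no foreground 8-neighbor) are dropped;
and finally connected components are filtered. A component survives only
if its pixel count strictly exceeds `min_region_size` (default 2000 px)
and its solidity strictly exceeds `min_solidity` (default 0.5). Solidity
is the standard regionprops quantity — component area divided by the
pixel area of its convex hull — which discriminates compact tooth crowns
from straggly remnants of gingiva or lips. Connectivity is 8-connected
throughout (both the isolated-pixel rule and labeling): the choice keeps
thin enamel ridges connected and matches common imaging practice.

Numerical details worth knowing:

* The convex hull is the hull of pixel *centers*, rasterized back onto
  the grid (a pixel counts as hull area if its center lies inside or on
  the polygon, with a 1e-9 tolerance on the half-plane tests).
  Degenerate hulls — all pixel centers collinear, e.g. a 1-pixel-wide
  line — get solidity 1 by convention.
* A constant image raises a degenerate-image warning and yields an empty
  foreground (nothing is strictly above the threshold); an empty
  post-filter mask raises a classed empty-dental-area error. In batch
  runs these abort only the affected image.
* An optional axis-aligned crop (0-based, half-open rectangle) replaces
  interactive cropping; it is applied before any processing.
* Images whose raw payload `H × W × 3` exceeds `max_image_bytes`
  (default 5e6) are block-averaged by the smallest integer factor that
  fits, preserving aspect ratio.

## Pixel classification

With the dental mask in hand, every dental pixel gets exactly one label
from its `G − B` value and two non-positive thresholds `l ≤ δ ≤ 0`:

| label | condition | meaning |
|---|---|---|
| `VISIBLE` | `G − B > 0` | visible plaque |
| `NV1` | `δ ≤ G − B ≤ 0` | non-visible plaque, short-term risk |
| `NV2` | `l ≤ G − B < δ` | non-visible plaque, medium-term risk |
| `NONPLAQUE` | `G − B < l` | no risk in the medium term |

Both boundary values belong to the upper class: `G − B = δ` is NV1 and
`G − B = l` is NV2 — the inequalities are taken exactly as printed above,
so sweeping δ moves pixels only across the NV1/NV2 boundary (a property
the test suite asserts). Dental pixels with `G = 0` or `B = 0` are
excluded from the risk classes and labeled `NONPLAQUE`: the non-visible
first approximation is defined only where both channels carry signal.

`δ` can be set by the user (always ≤ 0) or resolved automatically as
`−|mean(B) − mean(G)|` over the dental area. The sign convention is
fixed here once: the magnitude is an absolute difference, but the
threshold acts on the non-positive side of the `G − B` axis, so it is
stored negative.

`l` is resolved by comparing the current moment's histogram of
non-visible-plaque pixels (`G − B ≤ 0`, `G > 0`, `B > 0`, integer bins of
width 1 from −255 to 0) against the same histogram of the paired
reference image: scanning from −255 upward, `l` is the first value where
the current count strictly exceeds the reference count. Scanning upward
from the most negative value makes `l` the *left* boundary of the
region where the current distribution has grown — the crossing point of
the two histograms. When no bin qualifies (e.g. the reference compared
against itself) `l` falls back to `δ` and the NV2 class is empty; this
fallback also defines the reference moment's own labeling. Both the
resolved `δ` and `l` of every image are recorded in the run manifest and
in the measurement table.

## Clinical indices

All areas are expressed as percentages of the dental pixel count, which
makes them invariant to image scale; cross-moment pixel-count
normalization is therefore recorded as a ratio
(`reference dental px / current dental px`) rather than performed by
resampling, which would perturb the `G − B` histogram.

* **API index** (area per intensity, 0–100):
  `API = (visible fraction) × (mean visible G−B / 255) × 100`, and 0 when
  no visible plaque exists. The product form is a reconstruction — the
  method the package reimplements names the index and its 0–100 bounds
  but prints no formula — chosen as the simplest expression that
  respects the bounds and is monotone in both plaque extent and stain
  intensity. Treat absolute API values as internally consistent rather
  than comparable with other implementations.
* **Area growth index** (% of dental area per hour):
  `(area_now − area_ref) / elapsed_hours`, measured against the
  reference moment (not consecutive moments), whose area is ≈ 0 after
  professional cleaning. Negative rates are legitimate (plaque removal).
* **Area time index** (days): `(100 − area_now) / rate / 24`, the linear
  extrapolation to full coverage at constant rate; 0 if the area is
  already ≥ 100%, and not computable (NA) for non-positive rates. The
  "100%" refers to the whole dental area. Both growth and area-time come
  in a visible-only and a *total* (visible + NV1 + NV2) variant.

For moments with several views, image *k* is paired with reference image
*k* when it exists and with the reference's frontal (first) image
otherwise; measurements are reported per image, never averaged across
views.

## The synthetic scene generator

Because no public corpus of disclosed-plaque UV photographs exists, the
package ships a generator that emulates the *contrast structure* of such
images: near-black background, a dim reddish gingiva band, elliptical
teeth with `B ≈ 200` and clean-enamel `G − B ~ N(−60, 8)`, plaque patches
with `G − B ~ N(+60, 8)`, optional near-white specular discs, and i.i.d.
Gaussian pixel noise (sd 4). Teeth cover roughly a quarter of the canvas
so the default 75% threshold separates enamel from everything else —
mirroring framed clinical photographs. Plaque patches grow coherently
from an anchor inside their tooth (the patch is the programmed fraction
of the tooth's pixels nearest the anchor), so patch area is exact by
construction and component filters see realistic compact shapes.
Rendering is bit-identical for a fixed seed and never touches the global
RNG state.

`render_series()` emulates a regrowth experiment: the first timestamp is
a plaque-free reference and visible coverage grows at `rate` percent of
the dental area per hour (default study design: five moments at 24-h
spacing over 96 h at 0.75 %/h, the canonical regrowth protocol this
method targets). The clean-enamel `G − B` mean also drifts mildly upward
(0.05 intensity units/h) so successive histograms flatten and shift the
way real series do.

What the generator does *not* model: photorealistic texture, gradients
of illumination, fluorescein photobleaching, camera optics, tooth-shape
variety, or plaque that spills onto gingiva. Passing tests therefore
demonstrate the pipeline's correctness and its recovery of programmed
ground truth under the stated contrast assumptions — not clinical
accuracy on real photographs, which requires clinical validation data.

## Verification strategy and problem sizes

The test suite checks every vectorized operation against a deliberately
naive oracle (per-pixel conditional loops, an independent convex-hull
inclusion test, exhaustive threshold scans), asserts the partition and
monotonicity invariants on randomized inputs, and runs the pipeline end
to end on synthetic series: segmentation must recover ground-truth
dentitions (Dice ≥ 0.95 over 50 seeded scenes at 240×360 px) and the
recovered growth index must match the programmed rate within 5%.
Determinism is asserted at the byte level on rerun CSVs. The sizes —
256×256 random rasters for oracle equivalence, 240×360 scenes, 5-moment
series — were chosen so the whole suite exercises every claim in tens of
seconds; all properties are size-free.

## Known limitations

* The API formula is a reconstruction (above); growth and area-time use
  linear extrapolation, which overstates long-horizon predictions since
  real regrowth saturates.
* The bright-artifact rule is a single min-channel floor; severe flash
  artifacts with colored fringes may survive it.
* `δ` auto-resolution uses channel means, which drift if illumination
  changes within a series; the parameter can be fixed manually in the
  experiment config when acquisition is not standardized.
* Group-level statistics are deliberately out of scope: the measurement
  CSV is the interface to whatever analysis a study design requires.
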