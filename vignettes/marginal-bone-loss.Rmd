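---
title: "Measuring peri-implant marginal bone loss: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring peri-implant marginal bone loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mblq)
```

# The measurement problem

Marginal bone loss around a dental implant shows on an intraoral
radiograph as a radiolucent (dark) band along the coronal part of the
screw, between the healthy bone and the implant–crown junction. The
clinically meaningful quantity is the *fraction of the screw length* no
longer supported by bone, banded into severity classes. `mblq` turns a
radiograph plus rough crown/screw bounding boxes into that fraction,
edge by edge, through a sequence of classical image-understanding
steps. This vignette explains each model, the tunable parameters, the
places where the design was genuinely open and what we chose, and what
the synthetic validation does and does not demonstrate.

Coordinates throughout: origin at the upper-left pixel, x growing
right, y growing down, 0-based; boxes are half-open
`[x, x+w) × [y, y+h)`. The vertical calibration defaults to 0.063 mm
per pixel, the scale of a standard periapical sensor at 410 × 340 px;
it multiplies pixel distances only at the reporting stage, so every
internal computation is in pixels.

# Gating: jaw, associations, contrast

Crowns sit coronally: if the mean box-centre height of crowns is above
that of screws the implants are in the lower jaw, and conversely. A
tie, or a missing class, leaves the jaw `unknown` and the image is
excluded from measurement rather than guessed at. Images containing
implants in both jaws are not detected as such (the rule uses class
means); they are outside the intended use.

A screw is paired with a crown when, after stretching the screw box
along y until the crown's far edge, the intersection exceeds 30% of
the crown-box area. When two crowns qualify, the larger overlap wins
and ties go to the nearest crown centre — the rule is deliberately
greedy and local because detector boxes are rough by construction.
Unpaired boxes take no further part.

Contrast quality is the population standard deviation of intensities
inside the union of the unit boxes, normalized by `sigma_max = 98`
gray levels (the scale observed on high-contrast radiographs) and
capped at 1. Images at or above 0.4 are high contrast; below that the
linear stretch (next section) is switched on. The threshold is
inclusive at 0.4; the choice of side matters little in practice
because the metric is continuous.

# Enhancement and edge extraction

Gamma adjustment `out = 255·(in/255)^1.5` darkens mid-range tissue
while keeping the metallic implant near white, widening the very
gradient the later profile scan relies on. For low-contrast images an
affine stretch maps `[m − σ, m + σ]` (image mean and standard
deviation) onto `[0, 255]` first; on such images the screw edges
otherwise come out of the edge detector broken and branched.

Canny edge detection uses Gaussian smoothing at `σ = √2` px, Sobel
gradients, quantized non-maximum suppression and hysteresis. The high
threshold is the 90th percentile of the positive gradient magnitudes,
**floored at 15% of the maximum magnitude**; the low threshold is 0.4
of the high. The floor is a deliberate addition: a radiograph is flat
over most of its area, so a bare percentile collapses to the noise
level and admits every noise ripple as an edge. The floor ties the
threshold to the strongest real structure instead. All three values
are exposed in `mbl_config()` under `canny`.

Edges are then restricted to the screw boxes expanded by 10% per
dimension (top-left floored, size ceiled, so the original box is
always contained) and dilated with a 3 × 3 structuring element to
close single-pixel gaps. Morphology is implemented by exact
shift-union rather than convolution, so the binary results carry no
numerical fuzz.

# Edge description

The masked edge map feeds a polar Hough transform,
`ρ = x·cosθ + y·sinθ`, with bins of 1 px and 1°, θ ∈ [−90°, 89°]. The
16 strongest peaks are taken greedily with a 5 × 5 bin suppression
window; ties go to the smallest θ then smallest ρ bin, which makes
peak selection fully deterministic. Peaks also need at least
`min_votes = 15` so sparse maps do not admit noise lines. Slopes are
recovered as `m = −cosθ/sinθ`, `d = ρ/sinθ`, with `sinθ = 0` flagged
as a vertical line instead of converted. Lines flatter than 30° from
horizontal are discarded: the targets are near-vertical screw edges.

Each retained line collects the edge pixels within 2 px perpendicular
distance; runs along the line direction are split at gaps over 3 px
and dropped when shorter than 10 px. The union of surviving piecewise
segments is dilated with a 1 × 5 horizontal element, labeled with
8-connected components, and intersected with the masked edge map to
recover full pixel alignments; groups under 30 px are dropped. These
four constants (`line_band`, `min_seg_len`, `max_gap`,
`min_group_px`) are not forced by any formula; they were chosen once
so that a screw contributes one group per side on rendered phantoms,
and they are all in the configuration.

Two post-processing rules earn their keep on real geometry:

* **Side splitting.** A group that wraps around the apex tip (the two
  side edges meet at the screw tip, and under inclination the
  connecting pixels survive the segment filter) spans both sides of
  the screw; such groups are split at the box centre x.
* **Trimmed refit.** Each side's pixel set is cleaned by trimming
  against the *straight-line* fit first (tolerance `max(2·fit_trim,
  6)` px) and only then against the degree-2 curve (tolerance
  `fit_trim = 3` px, twice). The quadratic is flexible enough to bend
  toward high-leverage contamination at the group ends (tip stubs,
  crown-junction corners); the stiff line is not, so it anchors the
  first pass.

Fits model x as a polynomial in y — the only orientation that is well
posed for near-vertical edges — by ordinary least squares. The
pipeline always measures on the degree-2 curve `x = a + by + cy²`.
Degree selection (used when fitting ground-truth control points in the
evaluation module) compares degrees 1–3 by nested F tests at
`alpha = 0.01`: a higher degree is accepted only when its residual
reduction is statistically significant. A raw minimum-MSE rule would
always prefer degree 3 by a chance margin; the F criterion keeps
collinear points at degree 1 and a noisy parabola at degree 2.

# Critical points

The degree-2 curve is traversed from the apical end (maximum y for
lower-jaw implants, minimum y for upper) toward the crown in unit
steps. At each step, 10 intensity samples per side are read by
bilinear interpolation along the unit normal of the straight-line fit,
starting 3 px away from the curve so the bright edge itself is never
sampled; `extent = 10` px is about 2.5% of the standard image width
and scales with it for other resolutions. With `L` and `R` the side
means and `D = L − R`, the accumulated profile takes the darker flank:
`Cum = L` if `D < 0`, else `R` — elementwise, `Cum = min(L, R)`. The
darker flank is the tissue side; the brighter is the metal.

**First critical point.** Healthy bone holds the profile at a bright
plateau; the defect drops it abruptly to a dark level that persists
until the crown. We operationalize "drops abruptly below the profile's
statistical mean" as follows. The profile values are partitioned into
a bright and a dark class (an Otsu split, each class required to hold
at least 5% of samples and 3 absolute, so a couple of stray values
cannot form a class); the threshold is the midpoint of the class
means, which coincides with the overall mean for a balanced two-level
profile. The onset is the first run of `persist = 3` consecutive
samples below the threshold, subject to three validity conditions,
each of which exists to kill a concrete failure mode we observed on
rendered images:

* the two class means must differ by at least `min_drop = 30` gray
  levels — bone texture and sampling noise produce apparent splits of
  up to ≈ 20 levels on defect-free edges, while genuine
  defect-to-bone contrast is ≈ 50 levels even for small defects;
* the traversal must *start* in the bright class — otherwise the
  partition reflects some other structure (e.g. residual crown
  brightening at the scan's far end) and there is no degradation to
  date;
* the onset run must reach the dark level (its first five samples at
  or below the midpoint between the dark mean and the threshold) —
  shallow transient bands from bone texture are skipped in favour of
  the real drop.

A profile failing these conditions yields no first point: the edge is
reported `none`, which is the correct clinical answer for an implant
without measurable resorption. With `min_drop = 0` and a balanced
profile the rule reduces to the plain below-mean test.

When crown boxes are available, profile rows falling inside a crown
are cut off the coronal end of the scan before any of this: the
tissue profile ends at the crown, and bright crown rows would bias the
two-class split.

**Reference level and second critical point.** `R_av` is the mean of
the five profile values immediately after the onset — the dark
reference of the defect. Crown entry is the first run of
`run_len = 5` consecutive profile values above
`R_av · run_factor + min_rise` (defaults 1.0 and 10 gray levels; the
additive margin keeps defect-level noise from ever qualifying). The
profile value remains the darker-flank `Cum`: it clears the reference
only when *both* flanks are bright, which is precisely full entry
into the crown — at the junction the darker flank switches sides, so
a rule that switched to the opposite flank explicitly would instead
read the bright screw interior and fire immediately. Because the
fitted group ends at the screw–crown junction, the traversal may
continue past the group's coronal end along the extrapolated curve, by
at most `extend_px = 60` rows and never past the crown box's far edge
or the image border; the stored scan itself always spans exactly the
fitted range, and the first point and its statistics use only that
scan.

The second point can optionally be verified against the crown boxes
(`verify_crown`); a point inside no crown downgrades the edge to
`first_only`. This is off by default — jittered detector boxes make it
a coin flip near the junction — but it is the right guard when box
quality is known to be good.

# From landmarks to clinical quantities

The resorbed span is the discrete arc length of the curve between the
two critical points: `Σ √(1 + (dx/dy)²)·Δy` over unit steps with the
derivative at interval midpoints — exactly additive over integer
subdivision, and within 0.1% of adaptive quadrature on the curvatures
that occur here. The denominator is the arc length over the full
fitted span; when the physical implant length is known (it usually is,
from the surgical record), `known_length_mm / mm_per_px` replaces the
visible span, which is the right denominator when the apical tip is
occluded. Percentages are clamped to [0, 100] and banded: normal
≤ 10%, early (10, 25%], moderate (25, 50%), severe ≥ 50% — the closed
ends at 10 and 50 follow the band definitions' explicit ≤ and ≥
marks, and the interior boundaries are half-open to make the
classification total and unambiguous.

# Evaluation statistics

Against ground-truth edges (stored polynomials, or control points —
at least 10 per edge — fitted with the F-test degree selection), the
per-edge matching score is `ms_e = Σᵢ (X_Gᵢ − X_Aᵢ)² / (Y_M − Y_m)`
over integer y in the vertical overlap `[Y_m, Y_M]`. The denominator
is the span while the sum has span + 1 terms; we implement the
definition literally as printed and additionally report
`rms_e = √ms_e`, since summaries of edge-fit quality are naturally
read in linear pixel units. Under a constant offset Δ over span S the
score is exactly `Δ²(S+1)/S`, which the test suite checks.

Each deviation sequence `x_e = X_G − X_A` is tested against zero mean
with a one-sample Student t test (sample standard deviation, df =
n − 1, two-sided p). The summary reports the mean and standard
deviation of the per-edge RMS deviations, the mean p value, the mean
per-edge standard deviation, and the share of edges whose deviation
is *not* rejected at α = 0.05. Perfect matches (identically zero
deviations) are scored p = 1 rather than erroring on zero variance.

Resorption-percentage errors E = A − G, with undetected edges
excluded, are partitioned into 10 batches (contiguous in input order;
a seeded shuffle is available) and t-tested per batch; the summary
averages the batch p values, the batch mean absolute errors and the
batch error standard deviations.

# The phantom generator

`render_phantom()` draws, in a 410 × 340 canvas: a screw whose two
side edges are exact quadratics (linear taper to 55% half-width at
the apex plus a 1.5 px outward mid-screw bulge — enough curvature
that a straight line is genuinely wrong), perturbed by a sinusoidal
thread (amplitude 2 px, period 8 px — visually plausible while
keeping the degree-2 fit the best smooth description); a crown
adjacent at the coronal end overhanging the screw by 15 px; a bone
slab flanking the screw from each side's defect apex down to below
the implant apex; and a darker soft-tissue/defect background. The
per-side defect fraction *is* the ground-truth resorption, and the
stored truth (smooth edge polynomials, critical points, tight boxes)
is exact by construction. Bone receives a low-pass Gaussian texture
(σ 1.5 px kernel, 12 gray levels), the whole image Gaussian noise of
6 gray levels. Upper-jaw phantoms are exact vertical mirrors of
lower-jaw renders, which makes the pipeline's flip-equivariance
testable to the pixel.

Default gray levels are crown 235, screw 205, bone 112, defect 55:
the clinical brightness ordering, with enough implant-to-tissue
contrast that the bounding-box σ metric reads ≈ 0.45–0.5 — a
high-contrast radiograph — at every defect level including zero. The
`low_contrast` preset (160/150/122/100) compresses the levels so the
metric falls well below 0.4 and the linear-stretch path is exercised.
`emit_detections()` jitters the true boxes uniformly (±2 px in the
standard suites) and draws detector-like confidence scores.

What the phantom does *not* emulate — and hence what green tests do
not demonstrate about clinical images: 3D anatomy projected to 2D
(gradual instead of abrupt profile transitions, a known error source
of the approach), overlapping neighbouring teeth and restorations,
real trabecular bone structure, exposure artifacts, detector failure
modes beyond jitter and score (missed or hallucinated boxes), and
occluded apical tips. Results on phantoms bound the method's
geometric and statistical behaviour, not its clinical accuracy.

# Problem sizes and runtime choices

The test suite's recovery experiment uses 100 phantoms spanning
10–50% per-side resorption, ±10° inclination and both jaws, plus 20
defect-free phantoms; `scripts/acceptance.R` re-runs a 60 + 20 study
with the same distributions. These sizes give standard errors well
below the pass margins (mean landmark error ≈ 2 px against a 3 px
bound; mean percentage error ≈ 2 points against 5) while an entire
run stays within a couple of minutes on one core. The degree census
in the acceptance study fits 12 control points per edge with 0.5 px
placement noise — the floor of the "at least 10 points" annotation
protocol; with so few points the F test at α = 0.01 is conservative,
so the census understates the degree-2 share relative to densely
sampled edges.

# Known limitations

* The two-class split assumes the visible tissue profile has at most
  two levels (bone, defect). A third sustained level (e.g. a long
  bright restoration fragment along the flank) would bias the
  threshold; the start-level and deep-onset guards catch the cases we
  could construct, but not provably all.
* Resorption below ≈ 3% of the screw length (shorter than the
  persistence run) is reported as `none` by design.
* The denominator of the percentage is the *visible* fitted span
  unless the implant length is supplied; with a strongly occluded
  apex the default percentage overestimates.
* Smooth, gradual profile transitions (projection of 3D defects)
  shift the detected onset; no correction is attempted.
* The jaw rule cannot flag mixed-jaw images; they should be excluded
  upstream.
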