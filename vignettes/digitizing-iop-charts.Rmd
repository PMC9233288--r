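---
title: "Digitizing hand-drawn 24-hour IOP charts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digitizing hand-drawn 24-hour IOP charts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iopcharts)
```

## The problem

In German-speaking ophthalmology, patients with glaucoma are admitted for
nycthemeral (24-hour) intraocular pressure (IOP) profiles: applanation
readings at 10 am, 2 pm, 5 pm, 9 pm and midnight, recorded by hand on a
standardized paper form. The form has a nonlinear time axis (uneven intervals
between measurement times, up to six day columns) and a nonlinear pressure
axis, linear from 0 to 40 mmHg and compressed to half density above 40. By
convention the right eye (OD) is charted in blue, the left eye (OS) in red.
Decades of such charts exist only as paper or scans; `iopcharts` turns a
scan into a per-eye, timestamped IOP table and computes the clinical
statistics used to evaluate whether these profiles carry diagnostic value.

## Pipeline

### Preprocessing

The scan is converted to grayscale (Rec. 601 luma) and binarized with
**adaptive Gaussian thresholding**: a pixel is ink iff its intensity falls
below the Gaussian-weighted mean of its 27 x 27 neighborhood minus a constant
offset of 10 gray levels. The window and offset are the pipeline's reference
parameterization; both are exposed (`window`, `offset`). Borders are handled
by edge replication, and the Gaussian sigma follows the usual
kernel-size-derived convention, so the operation is reproducible to the pixel
by an independent per-pixel implementation (the test suite holds one).

The **main frame** is the largest connected contour in the binary image,
measured by convex-hull area; anything smaller than 20% of the scan
(`min_frame_fraction`) is rejected. Its hull is simplified with the
Douglas-Peucker algorithm, starting at a tolerance of 1% of the hull
perimeter and doubling until at most four vertices remain. Four-vertex
approximations are then refined: pixels within 2.5 px of the hull outline are
assigned to the four sides, each side gets a total-least-squares line, and
adjacent lines are intersected. The fit is iterated with shrinking inlier
tolerance (6, 4, 3, 2, 2 px). This refinement is what recovers true corners
when a corner region is missing from the scan: the surviving straight edges
extrapolate to their intersection. A quadrilateral whose interior angles
deviate more than 10 degrees from 90 (`angle_tol_deg`) raises
`FrameNotRectangular` rather than silently producing a skewed calibration.

The frame interior is then **perspective-warped** (4-point homography,
bilinear resampling) onto a canonical raster. A plain crop would suffice for
perfectly flat scans; the warp additionally makes fixed-pixel arithmetic
valid under mild skew and arbitrary scan resolution. The canonical size is
1200 x 800 px, chosen so that the template's grid positions are integral and
a full 200-chart evaluation batch runs in minutes on one core; it is a config
value (`canonical_width`, `canonical_height`), not a constant.

### Value extraction

Vertical **time gridlines** are found by Canny-style edge detection (Sobel
gradients, non-maximum suppression, hysteresis) followed by a Hough transform
restricted to lines within 5 degrees of vertical -- which simultaneously
discards horizontal rulings and handwritten horizontal strokes. Votes are
accumulated per (angle, x-intercept); peaks supported by at least 40% of the
plot-band height are merged when closer than 8 px and snapped to the nearest
template slot within 10 px. Fewer than three calibrated slots raises
`CalibrationError`.

**Color masks** separate the eyes in HSV space: blue = hue 200-260 degrees,
red = hue at most 20 or at least 340 degrees, both requiring saturation at least 0.30
and value at least 0.20. The hue bands are disjoint, so no pixel can belong to both
eyes. The thresholds are deliberately wide: ballpoint and fountain pen blues
vary, and the saturation floor is what excludes pencil and black ink.

Within plus or minus 40% of the local inter-slot spacing around each calibrated line
(`vicinity_frac`), connected components of the eye's mask are candidate
marks. Components taller than 6 mmHg of axis extent (`stroke_max_mmhg`) are
connecting-polyline strokes, not marks: dots and ticks are compact, while the
lines clinicians draw between consecutive readings are tall. When a mark is
drawn on top of a steep stroke the two merge into one tall component; in that
case pixels are filtered by horizontal run length (a steep stroke crosses
each row in runs of a few pixels, a mark core in runs of 6 or more) and the
largest contiguous row block is kept if it is compact. The largest surviving
component per (line, eye) becomes the entry; its y-centroid maps through the
template's piecewise-linear axis to a value kept at 0.1 mmHg resolution.
Additional surviving components are *retained and flagged* `"extra"` rather
than dropped -- they surface as false positives in evaluation and as review
flags in the CLI, replacing the interactive correction step with an auditable
report.

Midnight is charted after 9 pm and treated as slot "00:00" of the following
day index. Multi-day charts carry an explicit day index per slot; single-day
extraction is the default.

### Header metadata

The examination date is handwritten. Ink components inside the template's
date region are segmented and ordered left to right; a component is a
*delimiter* (the dots of `12.03.2018`) if its area is below 25% of the median
digit area or it is flatter than 1:2 -- at most two delimiters are accepted.
Digit glyphs are normalized MNIST-style (bounding-box crop, 20 px rescale,
center-of-mass placement in 28 x 28) and classified by a pluggable
classifier. The default is a small softmax network (`nnet`, 16 hidden units,
14 x 14 mean-pooled features) trained at first use on synthetically rendered
digits -- two built-in dot-matrix font variants with rotation up to 12
degrees, aspect jitter and pixel noise -- so the package needs no downloaded
training corpus and tests are fully self-contained. A convolutional model
trained on a handwritten-digit corpus can be dropped in through the same
`predict_glyph` contract and would be the better choice for real
handwriting; the built-in classifier is calibrated to the renderer's glyph
distribution, not to human script. Digits are grouped by delimiter position
into day.month.year (German convention); two-digit years expand into the
plausible range 1950-2030 (`yy <= 30` becomes `20yy`, else `19yy`). Illegal
dates raise `DateInvalid` instead of guessing.

Patient names are machine-printed labels; optical character recognition is an
external engine supplied as a function, never re-implemented here.
`extract_names()` applies a Unicode-aware `Surname, Givenname` pattern
(umlauts and diacritics match) to the OCR text. Output identifiers are
pseudonymized by default (12-hex-digit SHA-256 prefix); plain names require
an explicit flag, mirroring how identifying stickers are blacked out on real
charts.

## The synthetic generator

`render_chart()` draws the full form -- frame strokes centered on the
canonical rectangle, uneven time gridlines, 10-mmHg rulings, a printed-label
mock, a handwritten-style date -- plots ground-truth entries as blue/red
dots (or crosses/ticks) with optional connecting polylines, and then applies
corner cut-off, rotation and additive scanner noise. Everything stochastic
derives from one seed; identical configs render byte-identical images. The
default *noise model* used in evaluation is sigma = 8 gray levels of
luminance noise, rotation drawn from plus or minus 3 degrees, and mark jitter up to
2 px.

What the renderer does *not* emulate: staples, coffee stains, crumpled or
folded paper, ink bleed-through, free-text annotations, medication arrows,
or genuinely human handwriting (glyphs are perturbed font renders). Passing
round-trip tests therefore demonstrates the pipeline's geometric and
chromatic logic under controlled degradation -- not field performance on
arbitrary archive scans, for which the reported real-scan error rates of the
kind of study this supports remain the benchmark.

`simulate_cohort()` generates patients matching the study conditions: mean
24-hour IOP T_avg ~ 15.2 +/- 4.0 mmHg and nycthemeral variation
IOP_var ~ 6.9 +/- 4.2 mmHg, both truncated to physiologic bounds (0-80 mmHg;
the location parameter is moment-matched by root finding so the *realized*
mean equals the configured one despite truncation). The daily peak slot is
drawn with 48% mass on 10:00 -- the observed share of 10 am acrophases --
and the remainder spread by wrapped-normal weights (SD 8.4 h) over the other
slots; the published "acrophase spread" statistic has no stated definition,
so it is used here only as a shape parameter. Given a drawn (T_avg, IOP_var,
peak slot), five slot values are constructed with the realized range exactly
equal to IOP_var (peak = T_avg + w * IOP_var, trough = T_avg -
(1 - w) * IOP_var at the circularly opposite slot, w ~ U(0.35, 0.65)) and
interior slots interpolated along circular distance with noise, recentered
so the realized mean equals T_avg; infeasible draws are resampled with a
retry cap. No within-day covariance structure is claimed -- the construction
exists for testability, not physiology. Mean arterial pressure is drawn with
mean 103.9 and SD 12.7 mmHg, back-derived from the reported perfusion
pressure MOPP = 59.1 +/- 8.9 via MOPP = (2/3)(MAP - T_avg); systolic and
diastolic are reconstructed from a drawn pulse pressure so that
MAP = diastolic + pulse/3 holds exactly. Progression labels are Bernoulli
with logit = logit(0.42) + a * z(T_max) + a * z(IOP_var); the association
strength `a` defaults to 0 because the study found none.

## Evaluation metrics

A *curve* is one eye on one chart. Matching is slot-exact: a detection can
only match the truth entry at its (eye, day, slot), the nearest-value
detection wins, and leftovers are false positives (including every
`"extra"`-flagged blob); unmatched truth entries are false negatives. No
value tolerance enters matching -- values only contribute to the distance
metric. The report derives `fp_rate = fp_per_curve / mean_entries_per_eye`,
`fn_rate` analogously, and `mean_relative_error = mean_distance /
mean_true_value`, printing FP at two decimals and FN as an integer percent,
matching the convention of the published evaluation.

## Clinical statistics

* `summarize_profile()`: T_max, T_min, T_avg, IOP_var = T_max - T_min, and
  the acrophase defined as the slot of peak IOP (ties resolved to the
  earliest slot). The `"outpatient"` filter keeps 10:00, 14:00 and 17:00
  before summarizing, enabling 24-hour vs office-hours comparisons. A cosine
  (cosinor) fit is deliberately not offered: five samples per day cannot
  support one.
* `compute_mopp()`: MAP = diastolic + pulse pressure / 3 (the standard
  estimate; the source material uses MAP without defining it), and
  MOPP = (2/3)(MAP - T_avg).
* `align_acrophases()`: circular shift of each 5-slot day so all peaks land
  on the reference slot, then per-slot mean and SD. Alignment is circular
  over the day because the charts carry no information about how day
  boundaries were handled.
* `cutoff_contingency()`: test-positive means *strictly greater* than the
  cutoff (equality at the cutoff is negative; "above" is ambiguous and the
  strict reading is fixed here), 2 x 2 counts, sensitivity = TP/(TP+FN),
  specificity = TN/(TN+FP). Degenerate label sets return NaN with a warning
  instead of failing.
* `roc_curve()`: threshold sweep over distinct scores with ties grouped,
  trapezoid AUC, optional exclusion of low scores (used to drop nycthemeral
  variations under 5 mmHg). Cross-checked against an established ROC
  package in the test suite.

## Numerical choices and degenerate inputs

* The pressure axis map is linear interpolation between three anchors
  (0, 40, top); round trips are exact to < 0.01 mmHg and pixels outside the
  calibrated band raise `RangeError` rather than extrapolating to negative
  pressures.
* Line-fit refinement requires at least 10 inlier pixels per side; if any
  side has fewer, the unrefined Douglas-Peucker corners are kept.
* Blob acceptance requires 9 px of area, suppressing salt noise without
  rejecting small pen ticks.
* Ties in the Hough accumulator resolve to the earlier angle bin; merged
  line clusters use the support-weighted mean x.
* All stochastic components (renderer, simulator, classifier training) seed
  their own RNG scope and restore the caller's state afterwards.

## Problem sizes used in the shipped checks

The round-trip evaluation runs 100 noiseless and 100 default-noise charts;
oracle agreement uses 50 random images (at most 32 x 32) and 30 random
matching instances; the null-association ROC uses n = 500 patients and
parameter recovery n = 200; the date round-trip uses 200 rendered headers
and digit accuracy 500 glyphs. These sizes keep the full suite in the
minutes range on a single core while leaving the stochastic bounds
(3 standard errors for means; 0.07 around a null AUC of 0.5) meaningful.

## Known limitations

* The extractor assumes the standard form; other layouts need a custom
  `chart_template()` (loadable from YAML).
* Overlapping blue and red marks at the same slot: the later pen stroke
  covers the earlier, and a fully covered mark is unrecoverable from the
  image -- the generator's evaluation fixtures therefore keep the eyes at
  least 2 mmHg apart at each slot.
* Marks in colors other than blue/red, handwritten free text, and
  medication arrows are out of scope.
* The default digit classifier is trained on rendered glyphs; real
  handwriting needs a drop-in model trained on a handwriting corpus.
* Wall-clock benchmarking of the original system is out of scope: timing
  ratios are hardware-bound and not a property of the method.
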