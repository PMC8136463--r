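---
title: "Measuring the left ventricle from keypoints: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the left ventricle from keypoints: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echodim)
```

## The problem

Linear measurements of the left ventricle in the parasternal long-axis
view — septal thickness (IVS), internal diameter (LVID) and
posterior-wall thickness (PW) — are defined by four landmarks placed on
one line crossing the ventricle: the anterior and posterior septal
borders and the endocardial and epicardial posterior-wall borders.  An
automated measurer of these dimensions is naturally built as a keypoint
localizer, and it must be validated against human experts.  But expert
opinions themselves disagree, so a single expert is a noisy reference:
the appropriate standard is a *consensus of many experts*, and the
appropriate analysis quantifies (a) how far any one measurer — machine or
human — sits from that consensus, and (b) *where in space* the keypoint
disagreement lives.

`echodim` implements this validation end to end, together with a
synthetic study generator so that every stage is exercised and tested
without any image download.

## Measurement geometry

All distances are Euclidean and computed in physical millimetres:
pixel coordinates `(x, y)` (column, row; 0-based; origin at the top-left
pixel centre) are scaled per axis by the pixel spacing before any
distance is taken, so anisotropic rasters are handled correctly.  A
dimension is missing exactly when either of its two keypoints is
missing, and no plausibility clamping is applied — the agreement
statistics must see raw values.

## Heatmap targets and image conventions

Keypoint localizers of the kind validated here regress, per landmark, an
image whose intensity is 1 at the landmark and decays as a Gaussian with
SD 4 pixels; coordinates are recovered as the *peak* of the predicted
map.  The codec in `encode_heatmap()` / `decode_heatmap()` fixes the
conventions precisely:

* the value at pixel `q` for point `p` is `exp(-||q-p||^2 / (2*4^2))`;
  the map is *not* renormalised after boundary truncation, so the peak
  stays exactly 1;
* a missing keypoint encodes to the all-zero map, and the all-zero map
  decodes back to missing;
* decoding takes the maximum, with ties broken at the smallest row-major
  index — a deterministic, testable rule;
* no sub-pixel refinement is attempted, since the decoded coordinate is
  defined as the peak.

`center_crop()` implements the 640×640 inference crop with zero padding,
assigning the odd leftover pixel to the trailing side of each axis; the
returned spec maps coordinates both ways and inverts exactly.
`loss_weights()` zeroes the loss of keypoints an expert could not place.
`augment_frame()` applies a random affine transform identically to image
and keypoints, a gamma change `I^gamma`, and rectangular erasure.  The
augmentation parameter ranges (rotation ±15°, scale 0.9–1.1, translation
±5%, erased area ≤10%) are package defaults of typical magnitude; an
erased rectangle deliberately does *not* invalidate a keypoint, because
erasure is a regulariser, whereas expert missingness is ground truth
about the annotation.

## The consensus reference and agreement statistics

The reference standard for each dimension on each frame is the **median
of the experts' per-expert measurements**, where an expert's own
measurement is the median of their available blinded readings (with two
readings, their mean; with one, that reading).  Even-count medians take
the mean of the middle two.  A reference requires at least
`min_experts = 3` contributors, else it is missing.  Two deliberate
choices here:

* The phrase "median of the experts' measurements" can be read
  per-expert-median-first or with all readings pooled; the two differ
  when readings are collapsed before or after the across-expert median.
  The per-expert-median-first rule is the default; the pooled rule is
  available via `consensus = "pooled"`.
* The consensus *includes* the expert being evaluated, which flatters
  each expert slightly (the consensus is biased toward their opinion).
  This mirrors how multi-reader consensus panels are normally scored;
  `leave_one_out = TRUE` provides the sensitivity analysis, and the test
  suite verifies the direction of the self-inclusion effect.

Agreement per (method, dimension, phase ∈ {ED, ES, pooled}) is reported
as: **bias** (mean signed deviation, measurement − reference),
**precision SD** (sample SD of signed deviations, n−1 denominator), the
50/80/90/95% **quantiles of absolute deviation** (linear interpolation
between order statistics, R's default type-7 convention), and
**ICC(2,1)** — two-way random effects, absolute agreement, single rater —
with the F-based 95% confidence interval of McGraw & Wong.  No ICC
variant is canonical for agreement-with-a-reference problems; ICC(2,1)
is the standard choice when absolute agreement with a reference matters,
and the variant is recorded in the report.  SDs are compared with the
variance-ratio F test (`var.test`); paired absolute errors with the
Wilcoxon signed-rank test (their differences are folded-normal-like, so
a rank test is appropriate; exact null up to 25 informative pairs,
continuity-corrected normal approximation above).  The significance
threshold is α = 0.05 with no multiplicity adjustment.

## Decomposing the keypoint error

The central observation the decomposition serves: measured *dimensions*
agree far better than the *keypoints* that define them.  For each frame
the consensus keypoint locations (coordinate-wise medians, in mm, of
per-expert median positions — a geometric median would also be
defensible; the coordinate-wise rule is simple, robust and is the
documented choice) define a consensus line per measurement.  Every
rater's keypoint deviation is then projected onto that line's frame and
normalised by its length — equivalent to rotating and rescaling the image
so the consensus line is vertical with length 1:

* **transverse** = component along the measurement direction (it
  perturbs the dimension), positive toward the line's end point;
* **longitudinal** = component perpendicular to it (a slide along the
  myocardium that barely affects the dimension), positive on the +90°
  side in image (y-down) orientation, i.e. `unit_perp = (u_y, -u_x)`.

Each structure decomposes against its *own* consensus line: LVID
endpoints against the LVID line, septal points against the IVS line,
posterior-wall points against the PW line; the shared keypoints
(posterior septum, posterior-wall endocardium) therefore contribute one
row per measurement they define.  Component SDs are reported in percent
of line length per method, phase and point end, pooled and separately —
whether a headline pooled number or per-phase numbers are wanted is a
reporting choice, so the summary emits both.  The decomposition
satisfies Pythagorean closure (`length² (t² + l²) = ||deviation||²`) and
is invariant under global similarity transforms; both are enforced at
tolerance 1e-9 in the tests.

## The synthetic study generator

The generator emulates the *structure* of a multi-reader validation
study: 100 studies, each contributing one end-diastolic and one
end-systolic frame; 13 experts reading every frame twice, blinded (26
evaluations per frame); one AI rater reading once.  True dimensions are
drawn per study from LVIDd ~ N(47.0, 6.4²) mm, LVIDs ~ N(37.7, 7.3²) mm,
IVSd ~ N(11.7, 2.4²) mm, PWd ~ N(11.0, 1.6²) mm, truncated positive,
with LVIDs resampled until smaller than LVIDd.  Systolic wall
thicknesses are not separately specified, so the diastolic draws are
scaled by 1.3 (ordinary systolic thickening) — a package choice.

The phantom image is deliberately simple — two bright myocardial bands
and a dark cavity along a randomly tilted axis, plus additive
speckle-like noise — because it only has to support codec, geometry and
augmentation tests, not realism.  Rater noise is applied in mm space in
the frame of each keypoint's own measurement line: Gaussian with SD
`transverse_sd_frac × L` along the line and `longitudinal_sd_frac × L`
perpendicular to it.  Default presets set the AI to 15%/7%
(longitudinal/transverse) and experts to 20%/10% with 2% independent
per-keypoint missingness — magnitudes of the kind multi-reader keypoint
studies report, used as *presets, not fitted values*.  `bias_mm` shifts
each keypoint outward along its own line by half the bias, so a positive
bias lengthens a measurement by exactly `bias_mm`; with the collinear
phantom the net effect falls on the LVID (shifts of the shared wall
endpoints cancel within each wall).

Two things the generator does **not** emulate, hence what passing tests
do and do not show: no speckle physics, shadowing, or image-quality
gradients (so nothing here validates a localizer's robustness to real
acoustic artefacts), and no correlated missingness or per-expert
idiosyncrasy beyond the shared noise preset (so expert heterogeneity
statistics on real panels will be wider than the simulation suggests).
What the simulation *does* establish is that the analysis pipeline is
correct: with zero noise every statistic closes to exactly zero, and
with known anisotropic noise the decomposition recovers the generating
SD fractions — over 200 frames, within ±15% relative, a tolerance fixed
by pilot Monte-Carlo runs of the recovery variance.

One emergent effect is worth knowing about when reading simulated
biases: a keypoint displaced longitudinally lengthens the chord between
the endpoints (`E[chord − L] ≈ σ_l²/L`), so raters with larger
longitudinal scatter systematically measure slightly *longer* dimensions.
The expert consensus inherits the experts' inflation, so a less-noisy AI
shows a small *negative* bias against it (about −0.5 mm for the default
presets).  This is real geometry, not an implementation artefact.

## Numerical and degenerate-input choices

* Seeds: every stochastic routine takes an explicit integer seed;
  sub-seeds are derived with a fixed 32-bit mixing rule, so study
  generation is byte-identical for a given seed and configuration.
* Truncated sampling is by resampling, preserving exact distributional
  shape above zero.
* A ventricle that does not fit the raster (with a 2-pixel margin) is an
  error naming the offending dimension, not a silent clip.
* Zero-variance strata: the F test and ICC refuse degenerate inputs at
  the function level; the orchestrator converts these into `NA` entries
  in the report so a noiseless study still produces a complete bundle.
* Thin strata (n < 2) are marked unavailable rather than dropped, so
  report cardinality is predictable.
* Ties: heatmap decoding uses smallest row-major index; medians of even
  counts average the middle two.

## Problem sizes used in the tests

The suite exercises the full default study shape (200 frames, 27
readers) where the counts themselves are the property under test, and
the recovery of anisotropic noise on the same 200-frame default; other
properties run on 2–10 study configurations and small rasters, which is
ample for exact geometric identities.  The F-test type-I rate is checked
over 2000 replicates of n = 25 samples.

## Limitations

* The phantom is collinear: all four true keypoints lie on one axis, so
  rotational disagreement between structure lines, present in real
  anatomy, is absent.
* The AI here is a simulated rater; nothing in the package trains or
  runs a network.  The heatmap codec and augmentation operators define
  the data interface such a network would be trained against.
* DICOM support is metadata-only: explicit-VR little-endian PixelSpacing
  extraction, refusing anything it cannot parse unambiguously.
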