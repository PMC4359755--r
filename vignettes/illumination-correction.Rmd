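---
title: "Retrospective illumination correction: model, estimator and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective illumination correction: model, estimator and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(illumfield)
```

## The problem

A fluorescence microscope does not illuminate, or detect, the field of view
evenly.  Vignetting, uneven excitation and optical misalignment make the
measured intensity of an object depend on where in the frame it happened to
land; in routine plate-based acquisitions the response varies 10--30% across
a single image even after the instrument's own white-referencing correction.
For visual inspection this is harmless.  For quantitative single-cell
readouts it is not: every intensity feature carries a position artefact,
control and treated wells become harder to separate, and multivariate
profiles acquired on different plates stop being comparable.

`illumfield` implements the standard retrospective remedy and the apparatus
to judge whether it worked.

## The estimator

For each experimental batch — by default all images of one channel from one
multi-well plate — the illumination correction function (ICF) is estimated
in three fixed steps:

1. **Mean projection.** Pixelwise average of all images in the batch
   (`mean_projection()`), accumulated in double precision.  Cells are sparse
   and positioned independently of the optics, so averaging hundreds of
   fields leaves the smooth illumination response plus residual cellular
   texture.
2. **Median-filter smoothing** (`median_smooth()`) with a large square
   window removes that residual texture.  The median (not a Gaussian) is
   used because cellular residue is spiky and asymmetric; the filter is
   exact (a rank-transformed sliding-histogram median in C++, exact for
   arbitrary real pixels), with reflect padding
   (mirrored without repeating the edge pixel) at the borders — zero
   padding would fabricate a dark frame at the window sizes involved,
   roughly 40% of the image.
3. **Rescaling** (`rescale_icf()`) divides by the field minimum, so the ICF
   has minimum exactly 1 and correction by division only ever attenuates.
   The absolute scale of an ICF is unidentifiable from the data (any
   constant cancels between numerator and denominator downstream); min-one
   keeps corrected intensities bounded by the raw ones and makes ICFs from
   different batches directly comparable as percent-variation maps.

Correction itself (`correct_image()`, `correct_batch()`) is pixelwise
division, written out as 32-bit float TIFF so downstream intensity readouts
are not re-quantized.

### The window size

The window is the one tunable parameter that matters.  Too small and the
ICF is "blotchy" — local cellular intensities still dominate; too large and
the filter flattens genuine illumination structure.  The package follows
the published ladder: for a canonical 1280 x 1024 acquisition the default
is 501 px (the classic 500 px choice, standardized to odd so the window has
a well-defined centre); for other shapes, 40% of the shorter dimension.
`select_window_size()` automates the visual procedure: start at ~25% of the
shorter dimension, grow in ~10% steps, and stop as soon as the smoothed
result is smooth overall, as judged by `roughness_metric()` — the 99th
percentile of the relative residual against a re-smoothed copy (probe
window 10% of the shorter dimension), with a default tolerance of 0.005 —
residual relief below about half a percent of the local field, an order of
magnitude under the anomalies being estimated.
Non-convergence at the image-size cap is flagged, not an error.  One
caveat: the heuristic trusts the batch mean, so on *small* batches (a few
dozen images) the residual texture pushes it to very large windows that
begin to flatten genuine illumination structure; for such batches the fixed
default window is usually the better choice, and the validation studies use
the heuristic only at full batch sizes.

Even windows are rejected rather than silently adjusted.  All derived
windows use `odd(x) = 2 * floor(x/2) + 1`.

### Known numerical limitations

Two biases of the median filter are worth knowing about, and both are
visible in this package's own validation numbers:

* **Curvature bias.**  The median of a curved field over a window is not
  the centre value: at an illumination hot spot the estimate is pulled
  down by roughly the field's drop at half-window distance.  At the
  windows the heuristic selects on a 256 px field (65--117 px) this is a
  2--4% centre bias, which is also why the flattening residual below
  plateaus at a few percent rather than at zero.  The bias shrinks with smaller windows, but
  the window cannot shrink below the scale of cellular texture.
* **Border bias under reflect padding.**  Near a border the window sees
  mirrored interior values; for a field that is still sloping at the
  border the median there is biased toward the interior.  If the field's
  *minimum* sits on such a border, the bias propagates through the min-one
  rescale as a global scale error.  Fields that plateau before the frame
  edge (the common case for real vignetting, and the package's simulator
  default) do not suffer from this.

## Quality control

`variation_percent()` is the headline statistic: `100 * (1 - min/max)` of a
positive field, 0 for a flat one, and the number behind the "10--30%"
regime.  `roughness_metric()` quantifies blotchiness as described above; by
construction (a 99th percentile against a probe-median) it responds to
*distributed* cellular texture covering at least ~1% of the field, not to
one isolated blob — which is what matters for window selection.
`icf_outlier_scores()` automates the "one of these ICFs does not look like
the others" check across batches: each ICF is scored as one minus its
median Pearson correlation with the others and flagged beyond a
median + 3 MAD fence (absolute backstop 0.2); a single image with intense
debris is the classic cause.  `cell_density_map()` checks the assumption
that cells are uniformly distributed across the field of view by averaging
per-image Otsu masks; its uniformity score applies `variation_percent()` to
the smoothed mean-mask map offset by +1, so it reacts to dense systematic
patterns (the offset keeps the ratio metric defined on near-empty maps,
at the price of insensitivity to sparse ones).

## Univariate assay scoring

`evaluate_assay()` reproduces the screening view: the readout of a control
well is the median across its cells of per-cell total intensity in the
readout channel, and separation between positive and negative control wells
is scored by the Z'-factor

$$Z' = 1 - \frac{3(\sigma_+ + \sigma_-)}{|\mu_+ - \mu_-|}$$

and by a one-tailed variant designed for the asymmetric, roughly lognormal
distributions of image-based readouts: with group medians $m_+$ and $m_-$,
each group's spread is the root-mean-square deviation from its own median
computed only over its *facing tail* — the values lying between the two
medians (inclusive) — giving
$1 - 3(s_+ + s_-)/|m_+ - m_-|$.  For symmetric distributions the facing-tail
RMS estimates the full standard deviation and the one-tailed value converges
to the ordinary Z' (a property the test suite checks at n = 2000); for
heavy-tailed data it ignores the unhelpful far tail.  A Welch two-sided
t-test on the well values accompanies the Z' statistics.  Degenerate inputs
are defined: equal means/medians are errors at the statistic level, and
`evaluate_assay()` reports the one-tailed value as `NA` with a warning when
a facing tail is empty (indistinguishable controls).

## Profiling evaluation

The multivariate chain is deliberately minimal — its purpose is to measure
the *effect of correction*, not to reproduce a full feature bank:
Otsu-threshold segmentation of the nuclear channel on a lightly smoothed
copy (sigma 2 px, threshold computed on the 99.5%-clipped histogram so one
extreme nucleus cannot erase all others), 8-connected labelling with a
minimum area, per-cell area and per-channel total/mean intensity
(`segment_cells()`, `measure_cells()`), per-plate z-scoring of every
feature against the plate's control cells (`normalize_features()`; features
constant in controls are dropped study-wide), mean profiles per treatment
pooled after normalization (`treatment_profiles()`), and
leave-one-compound-out nearest-neighbour MOA classification
(`nn_classify_loco()`) with cosine distance (Euclidean behind a flag) and
deterministic lexicographic tie-breaking.  Excluding *all* profiles of the
query's compound prevents same-compound leakage.  `compare_correction_effect()`
runs the identical chain on raw and corrected images and reports both
accuracies.

## The simulator

`simulate_study()` emits a complete study with ground truth, and is the
package's validation instrument.  Its model: cells are truncated Gaussian
spots (sigma = radius/2, truncated at 2.5 sigma) placed uniformly at
random, with lognormal peak intensities shared across channels up to
per-channel gains and treatment effects; the camera sees
`field * (background + cells) + dark_offset + read noise`, clipped at zero
and quantized to 16 bits.  The anomaly is multiplicative only — matching
the premise of division-based correction; `dark_offset` (default 0) exists
to probe what an additive component does to a method that assumes there is
none.  Shading fields come in three parametric families with exact
amplitude contracts (`max = 1`, `min = 1 - amplitude`); the default is a
centred Gaussian vignette with width 25% of the shorter dimension — a hot
centre with corners that plateau, the shape of typical wide-field
acquisitions, and one on which the median estimator's border bias (above)
is negligible.  Per-plate fields are jittered by default, reflecting the
observation that ICFs differ meaningfully between plates; a flag disables
this.  All randomness derives from one seed via per-site substreams, so any
image is reproducible in isolation and metadata/truth files are
byte-identical across runs.

Default study conditions: one 96-well plate, 2 sites/well, 256 x 256 px
images (a scaled-down field with the same window-to-image geometry as the
canonical acquisition), ~40 cells per site of radius ~6 px, background 50,
lognormal intensity sigma 0.6, read noise 3, positive-control effect 1.6 on
the readout channel, field amplitude 0.25.

What the simulator does *not* emulate — and what passing tests therefore do
not show about real data: cell morphology and texture (spots only), optics
(no PSF), focus drift, photobleaching, debris, plate-edge evaporation
effects, and CellProfiler-grade segmentation with declumping.  The
validation shows the estimator recovers a known multiplicative anomaly and
that correction propagates into better downstream statistics under this
model; absolute accuracies and Z' values are not comparable to any
published screen.

## Validation studies (run by the acceptance suite and script)

* **ICF recovery.**  One simulated plate (96 wells x 2 sites, amplitude
  0.25, centred vignette), ICF estimated with the window heuristic: Pearson
  r vs the true field > 0.95 and max relative error < 5% inside the
  half-window border margin, across 3 seeds.  The heuristic picks 65 px
  here; the fixed 40% default would leave a ~8--10% curvature bias — the
  heuristic exists for a reason.
* **Flattening.**  Variation of the smoothed corrected batch mean falls
  from ~24--25% (amplitude 25%) to ~6%.  The residual is the curvature
  bias discussed above; the package documents it rather than hiding it —
  a sub-3% residual is not achievable with this estimator at this
  window-to-field geometry.
* **Z' improvement.**  24 + 24 control wells at the default 2 sites/well,
  effect 1.6, lognormal sigma 0.6, amplitude 0.25, full segmentation chain:
  the one-tailed Z' improves under correction in 4/5 seeds (mean
  improvement ~ +0.1).  The mechanism
  is nonlinear: a global Otsu threshold on a vignetted image truncates or
  loses dim corner cells, inflating well-level spread; correction removes
  that.
* **MOA classification.**  4 MOAs x 3 compounds, each compound on one of 3
  plates with plate-specific fields of amplitude 0.3, subtle effects
  (12--15% intensity/area shifts, lognormal sigma 0.3): classification must
  compare profiles across plates, and per-plate normalization cannot absorb
  the nonlinear (segmentation-mediated) part of the field distortion.
  Correction never hurts and strictly helps in 2/3 seeds (e.g. 58% to 83%).
  Effect sizes were chosen so the task operates below saturation — a
  ceiling-accuracy study cannot show an improvement, the same logic that
  leads screeners to validate on a readout with headroom.

Problem sizes throughout (256 px images, tens of wells, 1--2 sites) are the
package's chosen validation scale; the estimator itself is
dimension-agnostic.

## Degenerate inputs and edge policies

Single-image groups are allowed with a warning (their ICF is that image's
own content — the QC roughness score will be large).  Blank images
segment to zero cells and are excluded from well readouts upstream (a well
with no cells has no readout).  Non-positive pixels in a smoothed mean are
a data error at `rescale_icf()` — they indicate dark-frame input or
over-aggressive smoothing, not something to patch silently.  Corrected
output is never clipped or re-quantized; with min-one ICFs it cannot exceed
the input range.  Ties: medians use midpoint interpolation; facing-tail
membership includes values equal to either median; nearest-neighbour ties
break lexicographically by treatment identifier.
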