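# illumfield

Retrospective illumination correction for high-content screening, with the
statistics to prove it worked.

Wide-field fluorescence images are unevenly illuminated: measured intensity
routinely varies 10–30% across the field of view even after the
instrument's own white-referencing, so every per-cell intensity readout
carries an artefact of where the cell sat in the frame.  `illumfield`
implements the standard data-driven remedy for plate-based experiments: for
each batch (usually all images of one channel from one multi-well plate)
the illumination correction function (ICF) is estimated as

> ICF = rescale( median_filter( mean(images in batch), window ) ),

rescaled to minimum 1, and every image is corrected by pixelwise division,
`corrected = raw / ICF`.  The median window follows the published
heuristic: start near 25% of the image's shorter dimension and grow in
~10% steps until the result is smooth overall (501 px for a canonical
1280 × 1024 acquisition).

Around the estimator the package provides:

* **QC of the estimated functions** — percent variation
  `100·(1 − min/max)`, a residual-relief "blotchiness" score, cross-batch
  outlier flagging (median ± 3 MAD on pairwise correlations), and a
  cell-density uniformity check of the assumption behind batch averaging.
* **Univariate assay scoring** — per-well medians of per-cell total
  intensity, the Z′-factor `1 − 3(σ₊+σ₋)/|μ₊−μ₋|`, and a one-tailed Z′
  for asymmetric readouts whose spreads are facing-tail RMS deviations
  about each control's median.
* **A minimal image-based profiling chain** — Otsu segmentation,
  per-cell intensity/area features, per-plate z-scoring against control
  cells, mean treatment profiles, and leave-one-compound-out
  nearest-neighbour mechanism-of-action classification with confusion
  matrices — used to quantify how much correction improves downstream
  classification.
* **A ground-truth simulator** — multi-plate studies with parametric
  multiplicative shading fields, spot-like cells, treatment effects and
  camera noise, the instrument on which every claim above is validated.

Tables in, tibbles out: image-set metadata, cell features, well readouts
and profiles are tibbles; results have `tidy()`, `glance()` and
`autoplot()` methods.  A thin CLI (`inst/cli/illumfield`) exposes the
stages (`simulate`, `estimate-icf`, `correct`, `qc`, `zprime`, `profile`,
`classify`, `run`) for shell use.

## Worked example

Simulate a small vignetted plate (24 wells × 2 sites, two channels,
25% shading amplitude), estimate and apply the correction, and score the
control assay:

```r
library(illumfield)

cfg <- sim_config(
  plate_layout = make_plate_layout(n_rows = 4, n_cols = 6,
                                   n_negative = 8, n_positive = 8),
  sites_per_well = 2,
  positive_effect_factor = 2,
  seed = 42
)
study <- simulate_study(cfg, "demo_study")

icf <- estimate_icf(study$images, channel = "tubulin")
icf
#> <illum_icf> 256x256  channel=tubulin  plate=P01  window=103 px  n_images=48
#>   range [1.0000, 1.3349]  variation 25.1%
variation_percent(study$truth$fields[["P01/tubulin"]])
#> [1] 25

icfs <- estimate_icfs(study$images)
corrected <- correct_batch(study$images, icfs, out_dir = "demo_corrected")
icf2 <- estimate_icf(corrected, channel = "tubulin", window_px = icf$window_px)
variation_percent(icf2)
#> [1] 8.75

cells <- measure_image_set(study$images, nuclear_channel = "DAPI")
glance(evaluate_assay(cells, channel = "tubulin"))
#> # A tibble: 1 × 5
#>   zprime_two_tailed zprime_one_tailed p_value_mean_difference n_pos n_neg
#>               <dbl>             <dbl>                   <dbl> <int> <int>
#> 1            -0.494            -0.179              0.00000739     8     8
```

Reading the numbers: the estimated ICF varies 25.1% across the field,
matching the simulated 25% anomaly to within the residual cellular texture
of a 48-image batch.  Re-estimating an ICF from the *corrected* images
finds a residual anomaly of 8.8% at this small batch size; with full
96-well batches the residual drops to ~6% (the remainder is the median
filter's curvature bias at the vignette hot spot, discussed in the
vignette).  The assay
glance shows why a screener would care: a positive-control effect of 2× on
tubulin intensity yields a one-tailed Z′ of −0.18 here, and correction
shifts Z′ upward on average (quantified across seeds by the acceptance
script below).  `autoplot(icf)` renders the field for the recommended
visual review; `plot_well_readouts()` shows the control separation.

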