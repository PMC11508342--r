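# angioflow

Color-coded parametric angiography by two independent pathways: mask
subtraction (ccDSA) and temporal variance (ccDVA).

## What it is for

In endovascular treatment of peripheral artery disease, color-coded
parametric imaging condenses an angiographic run into one image — hue
encodes the contrast arrival time (red earliest, blue latest), brightness
the signal amplitude — and yields quantitative time parameters from
regions of interest (ROIs) placed along the vessel:

* **TTP** (time to peak): time from the start of acquisition to the
  maximum of the ROI's time-density curve,
* **passage time**: `TTP(ROI4) − TTP(ROI1)`, the bolus transit across the
  treated segment,
* **change in passage time**: pre- minus post-intervention passage time,
  an index of treatment efficacy.

The classical pathway reads these from the mask-subtracted series (DSA).
Digital variance angiography (DVA) instead maps the per-pixel temporal
standard deviation of the raw, unsubtracted series — a completely
different algorithm with a much lower radiation footprint in practice.
`angioflow` implements both pathways end to end, plus a synthetic
contrast-bolus phantom with exact ground truth, and quantifies how well
the variance pathway reproduces the subtraction pathway's time parameters
via grouped Pearson agreement reports
(`r`, Fisher-z 95% CI, `R²`, two-tailed `p`).

For users of the package: interventional imaging researchers who want a
tested, reproducible reference implementation of both pathways and a
phantom to probe when they agree.

## Worked example

```r
library(angioflow)

spec <- stenosis_phantom_spec(frame_rate = 4, stenosis_factor = 0.45)
sim  <- simulate_acquisition(spec)
sim$series
#> <frame_series> 48 frames of 128 x 128 px @ 4 FPS (12.00 s, origin: acquisition_start)

dsa <- compute_dsa(sim$series, mask_frames = 2)          # subtraction pathway
dva <- compute_dva_series(sim$series, window_length = 3) # variance pathway

ttp <- lapply(spec$rois, function(r) compute_ttp(extract_tdc(dsa, r)))
ttp[[4]]
#> <ttp_result> ROI 4: TTP = 6.500 s (frame 26, peak 0.4301)

p <- compute_passage_time(ttp[[1]], ttp[[4]], "pre")
p$passage_time          # 4.25 s, vs true transit integral 4.16 s
true_passage_time(spec) # 4.1567

sapply(spec$rois, function(r) compute_ttp(extract_tdc(dva, r))$ttp)
#> 2.25 3.00 4.50 6.50    (identical frames as the subtraction pathway here)
sim$truth$roi_true_ttp
#> 2.098 3.038 4.426 6.322 (continuous-time ground truth)
```

Both pathways land within one frame interval (0.25 s at 4 FPS) of the
ground-truth ROI peak times; here they quantize to the very same frames.
`render_parametric_image(dsa)` turns the series into the color-coded map
and `write_parametric_png()` saves it with an embedded color bar.

The full simulated comparison — 22 paired pre/post acquisitions, mixed
4/7.5 FPS, 4 ROIs each (three acquisitions with 3), both pathways on
identical ROI sets — is one call:

```r
report <- run_study(study_config(seed = 1, out_dir = "study_out"))
report$comparison
#> Pearson correlation of time parameters between pathways
#>   TTP 4 FPS              (n=106)  r = 0.9995  [0.9993, 0.9997]  R2 = 0.9991  p < 1e-15
#>   TTP 7.5 FPS            (n= 64)  r = 0.9996  [0.9994, 0.9998]  R2 = 0.9993  p < 1e-15
#>   TTP ROI1               (n= 44)  r = 1.0000  [1.0000, 1.0000]  R2 = 1.0000  p < 1e-15
#>   TTP ROI2               (n= 44)  r = 0.9954  [0.9916, 0.9975]  R2 = 0.9909  p < 1e-15
#>   TTP ROI3               (n= 44)  r = 0.9993  [0.9987, 0.9996]  R2 = 0.9986  p < 1e-15
#>   TTP ROI4               (n= 38)  r = 0.9997  [0.9993, 0.9998]  R2 = 0.9993  p < 1e-15
#>   TTP all ROI            (n=170)  r = 0.9995  [0.9994, 0.9997]  R2 = 0.9991  p < 1e-15
#>   Delta passage time     (n= 19)  r = 0.9987  [0.9966, 0.9995]  R2 = 0.9975  p < 1e-15
```

`study_out/` receives the TTP/passage/delta CSVs, the agreement table as
CSV and Markdown, scatter plots by protocol and ROI position, and a JSON
manifest that reproduces the run.

## Design notes

The methods vignette (`vignettes/parametric-angiography.Rmd`) documents
the image-formation model, the bolus model and why its front is
sub-frame, the choice of a short trailing window for the time-resolved
variance signal, estimator conventions (population SD, earliest-tie
argmax, Fisher-z CIs), the cohort parameter ranges, and what the phantom
does and does not emulate.
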