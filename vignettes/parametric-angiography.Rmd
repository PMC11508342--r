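---
title: "Color-coded parametric angiography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-coded parametric angiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioflow)
```

## The problem

During endovascular treatment of peripheral artery disease the operator
needs an intraprocedural, quantitative read-out of how fast a contrast
bolus crosses the treated segment. Color-coded parametric angiography
condenses an angiographic run into a single image: for every pixel, the
arrival time of the contrast agent is mapped to hue (red = earliest,
blue = latest) and the signal amplitude to brightness. From circular
regions of interest (ROIs) placed along the vessel, time-density curves
(TDCs) yield the time to peak (TTP: time from the start of acquisition to
the curve maximum), the passage time (TTP at the distal ROI minus TTP at
the proximal ROI) and the change in passage time with intervention, which
indexes treatment efficacy.

Two processing pathways can feed these parameters:

* **ccDSA** — classical digital subtraction angiography. A mask built from
  pre-contrast frames is subtracted from every frame, leaving only the
  contrast signal; the TDC is the mean subtracted signal in the ROI.
* **ccDVA** — digital variance angiography. No mask is used: the signal is
  the per-pixel *temporal standard deviation* of the raw, unsubtracted
  series. The package extends the full-series standard-deviation map to a
  time-resolved signal by a sliding window, so TDCs and TTPs can be read
  from the variance pathway exactly as from the subtracted one.

The two algorithms are entirely different, so their agreement on
time-related parameters is an empirical question. Patient acquisitions
behind the published comparison are not publicly deposited; this package
therefore ships a synthetic phantom generator with exact ground truth and
reproduces the comparison as a simulation study.

## Image formation model

The phantom models the detector value at pixel $x$ and time $t$ as
Beer-Lambert attenuation of a uniform background $B$:

$$ I(x,t) = B\,e^{-a(x)\,g\!\left(t - \tau(x) + T_r\right)} + \varepsilon, $$

where $\tau(x)$ is the pixel's bolus arrival (concentration-peak) time,
$a(x)$ the peak attenuation scaled by the chord depth through the
cylindrical vessel, and $g$ a normalized gamma-variate
$g(u) = (u/T_r)^k e^{k(1-u/T_r)}$ peaking at exactly $u = T_r$. Arrival
along the centerline is the injection delay plus the arclength integral of
$1/\text{velocity}$; a stenosis reduces velocity (and lumen radius) from
the lesion onward, and treatment restores it. Noise is scaled-Poisson
photon noise plus Gaussian readout noise, both seeded. Working in
negative-log space makes the injected attenuation exactly recoverable, so
the subtraction pathway can be validated against a closed-form oracle.

Ground truth records the per-pixel concentration-peak time and, per ROI,
the continuous-time argmax of the ROI-averaged noise-free concentration —
the quantity a TTP estimator is supposed to recover, evaluated on a 2 ms
grid rather than through the imaging pipeline.

## The bolus model and why its front is sub-frame

The gamma-variate is parameterized by a rise time $T_r$ (onset to peak)
and an effective duration (decay to 5% of peak). Defaults: $T_r = 0.08$ s,
duration 2.4 s (cohort draws 2–3 s). The short rise models a selective
intra-arterial injection at 2–6 mL/s through an end-hole catheter: the
opacification front passes a fixed point almost instantaneously, while
washout is slower.

This choice is also what makes the two pathways commensurable. A windowed
standard deviation peaks where the pixel intensity *changes* fastest,
whereas the subtracted TDC peaks at maximum attenuation. For a bolus whose
rise spans several frames the variance pathway systematically marks the
rising edge — in phase-scan experiments with a 0.2–0.3 s rise, the
windowed-sd argmax sat 1–2 frames before the concentration peak at both
4 and 7.5 frames/s, for every window length and alignment tried. Only when
the front passes within a frame interval do the "maximum change" and
"maximum attenuation" instants coincide at the frame grid, which is
exactly the regime a selective injection produces.

## Window length and alignment of the variance series

The sliding window has two free choices, and both defaults were fixed by
measurement before the acceptance experiments were written:

* **Alignment: trailing (causal), not centered.** With the earliest-frame
  tie rule, a centered window systematically attains its maximum one frame
  *before* arrival: at a near-step transition the window ending at the last
  pre-contrast frame and the window ending at the first post-contrast frame
  see mirror-image samples with identical standard deviation, and the tie
  resolves early. Scanning arrival phases at both frame rates gave
  worst-case timing errors of 1.05–2.25 frames for every centered
  configuration, violating the one-frame recovery requirement, versus
  0.5–0.7 frames for a short trailing window.
* **Length: 3 frames.** Longer trailing windows (5, 7) keep pre-contrast
  frames in view after arrival and shift the maximum early by up to 2.5
  frames; 3 frames is the shortest window that still averages some noise.

Both alignments and any length remain available in
`compute_dva_series()`; the defaults are what `run_study()` uses. Edge
frames use truncated windows by default; an alternative `"shift"` policy
slides the window inward so every frame uses the full window length (with
the window equal to the whole series this reproduces the full-series map
at every frame).

## Estimator conventions

* Standard deviations use the population convention (divisor $N$),
  documented and fixed; the choice only scales the variance signal and is
  invisible to TTP.
* TTP is the frame-quantized argmax; ties resolve to the earliest frame.
  No subframe interpolation by default — an optional three-point parabolic
  refinement exists but is off, so reported TTPs are multiples of the
  frame interval, as in clinical read-outs.
* Mask subtraction defaults to the negative-log (attenuation) domain with
  a 2-frame mean mask; linear-domain subtraction is available by flag.
* ROIs are circular; a pixel belongs to the ROI when its center lies
  within the radius. Acquisitions with only three ROIs are carried through
  TTP analysis and excluded from passage-time bookkeeping.
* Pearson reports use the product-moment formula, a two-tailed p from the
  $t$ transform on $n-2$ degrees of freedom, and a 95% CI by Fisher
  z-transform with the 1.96 normal critical value. Degenerate inputs
  (fewer than 3 pairs, zero variance) raise explicit errors; $|r| = 1$
  collapses the CI to $r$.

## The synthetic cohort

`make_study_cohort()` emulates the structure of the clinical comparison:
22 paired pre/post-intervention acquisitions, 14 at 4 frames/s and 8 at
7.5 frames/s, with the first three 4-FPS pairs carrying only ROIs 1–3.
Per pair the generator draws, once, from ranges chosen as plausible for
critically ischemic limbs and frozen before any acceptance experiment was
run:

| parameter | default / range | meaning |
|---|---|---|
| field of view | 128 x 128 px | one image scale for the whole study |
| base velocity | U(20, 38) px/s | bolus front speed proximal to the lesion |
| stenosis factor (pre) | U(0.25, 0.55) | velocity multiplier from lesion start onward |
| stenosis factor (post) | U(0.80, 1.00) | restored flow after treatment |
| lesion | start U(0.35, 0.50), length U(0.08, 0.22) of arclength | treated segment |
| injection delay | U(0.5, 3.5) s | injector-to-acquisition timing spread |
| bolus duration | U(2, 3) s, rise 0.08 s | contrast transient at a fixed point |
| peak attenuation | U(0.4, 0.8) | contrast dose / vessel caliber |
| ROI offsets | U(15, 35) px | proximal/distal ROI distance from the lesion |
| ROI radius | 2.5 px | a small ROI covering one vessel cross-section |
| noise | Poisson scale 0.2, readout sd 5 on background 2000 | ~1% detector noise |

Because treatment always increases the velocity factor within a shared
geometry, the true passage time strictly decreases in every pair.

## What the phantom does and does not emulate

It emulates: frame-rate-limited sampling at 4 and 7.5 FPS, a propagating
bolus with flow limitation distal to a stenosis, pre/post hemodynamic
change, static anatomical background, photon and readout noise, and the
exact ROI bookkeeping of the comparison (three-ROI acquisitions, shared
ROI sets between phases and pathways).

It does not emulate: patient motion (an explicit non-goal; the comparison
assumes motion-corrected series), scatter or detector MTF, pulsatile flow,
vessel branching, contrast recirculation, or pharmacokinetics beyond the
gamma-variate transient. Passing the agreement suite therefore shows that
the two estimators agree *given* clean, motion-free acquisitions — it
cannot certify robustness to motion artifacts or complex anatomy.

## Numerical choices and degenerate inputs

Windowed sums run on per-pixel mean-centered data to avoid catastrophic
cancellation in the running-sum variance; the full-series map uses a
two-pass computation. Rendering normalizes amplitude at its 99th
percentile, blanks pixels below 5% of it, and maps TTP linearly to hue
between red and blue over the selected pixels' time range; a degenerate
range (all pixels peaking simultaneously) renders single-hue with a
warning. The exact hue channel is kept in the map object alongside the
8-bit RGB rendering. Log-domain subtraction refuses non-positive detector
values, naming the first offending frame and pixel.

## Problem sizes

The shipped experiments run the full 22-pair cohort (170 matched ROI
pairs, 19 passage pairs) in under half a minute on one core; unit and
property tests use a 48 px phantom with the same structure. These sizes
were chosen so the whole suite replays quickly while keeping every count
of the emulated study intact.

## Known limitations

* The two pathways' TTPs can disagree by one quantized frame when arrival
  times are staggered across an ROI (slow flow, large ROI): the subtracted
  aggregate weights late arrivals slightly more than the variance
  aggregate. At the study's noise level this occurs in a few percent of
  ROI pairs and is the main reason noise-free correlations are extremely
  high yet not exactly 1.
* TTP resolution is one frame interval by construction; protocols below
  4 FPS would quantize away much of the hemodynamic signal, which is why
  such rates are not part of the study conditions.
* The variance pathway's timing fidelity depends on a sub-frame bolus
  front. For slowly rising enhancement (e.g., parenchymal blush) the
  windowed-sd TTP marks the fastest-change instant, not peak enhancement,
  and the two pathways measure genuinely different quantities.
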