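---
title: "Vision-based confluency monitoring and adaptive subculture: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vision-based confluency monitoring and adaptive subculture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confluency)
```

## The problem

Deciding *when* to passage an adherent culture is traditionally a visual
judgement call: an operator eyeballs the dishes, estimates how much of the
surface is covered ("confluency"), and splits the cells when the culture
looks "about half full". For stem-cell-like populations the stakes are
real — C2C12 myoblasts, for example, begin fusing into myotubes once
confluency exceeds roughly 0.5, irreversibly depleting the proliferating
pool — yet the judgement is subjective, operator-dependent, and must be
made around the clock.

This package implements the computational half of an automated alternative:
phase-contrast time-lapse frames are segmented into binary *confluency
masks*, the covered-area fraction is averaged over the imaged fields of
view, a sliding-window polynomial model forecasts when the culture will
cross a confluency threshold, and an idempotent notifier issues a one-time
advance alert (default 4 h ahead) plus a one-time reminder when the
measured value itself reaches the threshold. A passage calculator then
plans how many serial 1:8 subcultures are needed to reach a target cell
yield. A synthetic-data module stands in for the microscope so that every
stage is testable end to end.

## Segmentation: restore, threshold, dilate, measure

Phase-contrast optics trade staining for two characteristic artifacts: a
bright *halo* ring surrounding each dark cell body, and *shade-off* — a
smooth drift of the background intensity across the field. Both defeat
naive global thresholding, so frames are first *restored*:

1. **Invert.** Cell bodies are dark on a mid-gray background; inversion
   makes them the bright foreground. Halos become sub-background dips.
2. **Background subtraction.** The smooth background of the inverted frame
   is estimated by grayscale morphological opening with a large disc
   (`background_kernel_px`, default 40 px at quarter scale) and
   subtracted. Opening absorbs any structure wider than the disc —
   including shade-off gradients — while bright blobs narrower than the
   disc (the cells) survive subtraction.
3. **Clip negatives.** Halo dips and noise excursions below the background
   go to zero.

The result is a non-negative response map that is ~0 on background and
positive on cell bodies. Because every step commutes with adding a
constant to the input, the pipeline is invariant to global illumination
offsets (a tested property). This restoration is deliberately simple; it
reproduces the two artifact-removal effects that matter for thresholding,
and it sits behind a plugin registry (`register_restoration()`) so a
physics-based restoration can replace it without touching the rest of the
pipeline. Whether the simple version matches a full restoration's accuracy
on real instrument images is untested here by design.

The restored map is thresholded by Otsu's criterion on a 256-level
histogram (a `fixed` threshold is available). Otsu misbehaves on
background-only frames — it will happily split pure noise — so a dynamic
range floor (`min_dynamic_range`, default 0.02) declares such frames empty.

Finally the binary mask is **dilated** with a disc structuring element
(default radius 8 px at instrument scale, 1392×1040 px at 1.3 µm/px).
Thin processes — filopodia, lamellipodia — are nearly invisible against
the background, and dilation reclaims a margin around each thresholded
body to cover them. A dilation "factor of 8" admits several readings
(radius, iterations, area factor); this package reads it as a disc of
radius 8 px, the most common convention, and keeps it a parameter so the
alternatives are one flag away. When working at the quarter-scale default
geometry of the synthetic module (348×260 px), the radius should scale
with the frame: 2 px.

Confluency is then the exact set-pixel fraction of the mask, and the
per-time-point value is the arithmetic mean over the imaged fields of view
(12 on the source instrument: 3 per dish × 4 dishes).

## Evaluation

Computer masks are scored against reference masks pixel by pixel: TP where
both mark cell, FP computer-only, FN reference-only, TN neither;
precision = TP/(TP+FP), recall = TP/(TP+FN). `evaluate_masks()` reports
both the per-image mean ± SEM (the headline aggregation, appropriate when
the reference set is a handful of manually traced images) and pooled-pixel
metrics on the summed counts, since either aggregation is defensible and
they differ when image difficulty varies. Reference masks are ingested as
binary PNGs; digitising marker tracings is out of scope.

On the packaged synthetic suite (3 nominal coverage levels {0.15, 0.30,
0.45} × 5 seeds, quarter scale, dilation radius 2) the pipeline's
per-image mean precision and recall are asserted at ≥ 0.75 and ≥ 0.50 in
the test suite. Note the asymmetry against real data: synthetic truth
marks *body* pixels only, so dilation necessarily costs precision and
recall is near 1, whereas human tracings include the thin processes, which
moves error into recall instead. The synthetic suite is therefore a
regression guard, not a reproduction of real-image accuracy.

## Growth forecasting

The monitor fits the trailing `window_frames = 300` observations (25 h at
5-min sampling) with a 2nd-order polynomial in the frame index, evaluates
the fit one horizon ahead (`horizon_min = 240`), and solves for the
earliest time the fitted curve reaches the threshold (default 0.5).

Numerical choices:

* **Conditioning.** Raw frame indices in the hundreds make a raw-basis
  quadratic normal-equations solve ill-conditioned, so time is centred and
  scaled within the window before solving; coefficients are mapped back to
  the frame-index scale for reporting. Results are identical in exact
  arithmetic (tested against a raw-basis normal-equations oracle).
* **Families.** `poly1`–`poly3` (polynomials in frame index `k`),
  `logarithmic` `α·ln(k − k0 + 1) + β` with `k0` the window start, and
  `exponential` `α·e^{βk}` fitted by Gauss–Newton from a log-linear start.
  The last two functional forms are this package's documented choices; the
  labels alone do not pin them down.
* **Crossing search.** Polynomial crossings come from closed-form root
  finding on the scaled basis (earliest real root in `(now, now+horizon]`);
  other families, and any degenerate polynomial solve, use a 1-min grid
  scan refined by bisection. If the curve is already at threshold "now",
  the crossing is "now". Forecast values are clipped to [0, 1] for
  reporting only; root finding uses the unclipped polynomial.
* **Short windows.** Early in a run the window is clipped to what exists;
  fits are attempted from 10 points. Notifications are separately gated by
  the warm-up (below), so early low-quality fits cannot alert.

### Forecast reliability and the variance trace

Each frame's 4-h-ahead forecast is later compared with the observation it
targeted; the signed errors feed a trailing-window (48-frame = one
horizon) *sample variance* trace. Per-frame squared errors are also
logged, since a per-frame squared error is an equally plausible reading of
a "variance" trace; the windowed sample variance is the primary statistic
because it is stable enough to threshold. On quadratic-truth series with
noise σ = 0.005, the trace drops below 0.001 once ~200 frames have
accumulated, which motivates the warm-up gate `min_frames = 200`: before
that, forecasts and crossing estimates are treated as unreliable.

### Model-family comparison

`compare_models()` ranks families by the RMSE of horizon-ahead forecasts
against the later observations — the operationally relevant error. In-window
RMSE cannot do this job: nested polynomials never fit worse in-window, so
`poly3` would always tie or beat `poly2`.

Only forecasts issued after the warm-up (`warmup_points = 200` observed
frames at the forecast origin) enter the comparison. The rationale mirrors
the monitor's own reliability rule: forecasts from 10–60-point windows are
flagged unreliable and never acted upon, and including them lets their fit
*variance* dominate the ranking — on quadratic-truth noisy data it
rewards whichever family has the fewest parameters rather than the right
shape, inverting the selection. With the gate, the comparison measures the
regime the monitor actually operates in, and on quadratic-truth noisy
series (σ = 0.005) `poly2` wins the five-way comparison in 20/20 seeded
replicates of the test conditions.

`subsample_compare()` applies the same machinery to every-`stride`-th
frame (window scaled to the same time span, warm-up scaled by the stride
so both rates cover the same portion of the run). At stride 6 (30-min
sampling) the forecast RMSE changes by well under 25 % on the noisy
quadratic fixture: a 5-min acquisition interval is comfortably denser than
the forecasting task requires.

## Notification semantics

Two event kinds per culture run, each at most once:

* `PRE_ALERT` — first time the predicted crossing lies within the horizon
  *and* the warm-up has passed (`frame_index ≥ min_frames`).
* `THRESHOLD_REACHED` — first time the *measured* average confluency
  reaches the threshold. No warm-up gate: it is a measurement, not a
  forecast. No re-arming on noise-driven oscillation around the threshold:
  first touch wins.

On noise-free in-family growth the alert leads the measured crossing by
(horizon − one frame, horizon] — 4 h to the nearest hour at the defaults
(a tested invariant). State persists to JSON, so the at-most-once contract
survives process restarts, and `dispatch()` additionally refuses duplicate
delivery per (run, kind). Channels are pluggable; the package ships an
always-available log-file channel and a configuration-gated SMTP stub that
never sends in automated runs. Per-channel failures are reported, never
fatal.

## The expansion calculator

`expansion_start()` / `record_harvest()` track a serial expansion: at each
passage the total harvest is `dishes × cells_per_dish`; if it meets the
target the run stops ("Stop experiment"), otherwise every dish is split
1:`ratio` (default 8) and the passage counter increments ("Continue
experiment"). The *latest* harvest is compared with the target — cells are
re-plated, not banked — which is the reading that reproduces the
three-passage expansion to 50×10⁶ cells from 4 dishes at either published
per-dish yield (19.92×10⁴ or 22.71×10⁴); a cumulative-total variant is
noted but not implemented. `passages_to_target()` gives the closed form
`min{p : dishes·ratio^(p−1)·yield ≥ target}` via a logarithm ceiling,
corrected against the exact inequality and tested against iterated
simulation.

## The synthetic-data module

The generator exists to make the pipeline testable without a microscope.
It emulates exactly the features the algorithms must cope with:

* elliptical cells (semi-axes uniform in `cell_radius_px`, default 8–20 px
  at quarter scale ≈ 40–100 µm half-axes at instrument resolution,
  a plausible spread-myoblast size) rendered as uniformly dark bodies
  (`body_contrast = −0.25` on a 0.5 background);
* a bright halo ring just outside each body (Gaussian radial profile,
  amplitude 0.15, width 3 px);
* a smooth low-order polynomial shade-off field (amplitude 0.08) and
  additive Gaussian pixel noise (σ = 0.01);
* ground truth: the union of body pixels — coverage, not cell count;
  overlaps allowed (optional rejection sampling bounds them when a
  calibrated coverage is needed).

Growth curves come from a quadratic family (the monitor's own model class,
defaults `a2 = 10⁻⁶`, `a1 = 10⁻⁴` per frame, `c0 = 0.05`, which crosses
0.5 near frame 620 ≈ 52 h) or a logistic family for saturating behaviour,
plus clipped Gaussian noise. `generate_timelapse_dataset()` ties the two
together: per field of view a seeded cell pool is revealed cumulatively so
true coverage tracks the clean series, three fields of view per dish.

What the generator does **not** emulate: real phase-contrast optics
(defocus, contrast transfer), cell migration, division, shape change, or
any image-level dynamics — coverage is driven by the series, and cells
only appear, never move. Texture inside cells is absent, so Otsu's task is
easier than on real frames. Passing tests therefore demonstrate the
pipeline's internal consistency and its artifact-suppression logic, not
field accuracy on real cultures.

## Problem sizes and determinism

All randomness flows through explicit integer seeds (`with_seed` keeps the
global RNG state untouched), so every fixture, dataset and test is
bit-reproducible. The test and acceptance workloads use quarter-scale
frames, series of 400–800 frames, 3-seed variance sweeps, 20-seed
model-selection sweeps and a 15-image segmentation suite — sizes chosen so
the full suite exercises every code path in about a minute while keeping
the statistical checks comfortably powered.

## Known limitations

* The simplified restoration assumes cells narrower than the opening disc;
  confluent sheets wider than the kernel leak into the background estimate
  and lose response. On near-confluent frames the measured fraction is
  accordingly conservative.
* Otsu assumes a bimodal response histogram; at extreme coverage (empty or
  nearly full frames) only the dynamic-range floor protects it.
* A 2nd-order polynomial describes a smoothly accelerating culture over a
  25-h window; it has no notion of lag phases after thawing, contact
  inhibition, media changes or other perturbations, and will forecast
  poorly across them. Model choice should be re-validated per cell type.
* The notifier trusts the averaged confluency; it has no outlier rejection
  across fields of view beyond skipping unreadable frames.
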