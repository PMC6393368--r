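---
title: "Tracking vessel diameter in pressure-myograph image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking vessel diameter in pressure-myograph image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotracer)
```

## The measurement problem

In pressure myography a small artery is cannulated, pressurized through
columns of physiological saline, and imaged in transillumination with its
long axis roughly horizontal. Only the mid-plane of the vessel is in focus,
so a cross-section perpendicular to the axis sweeps five intensity zones:
bright background, dark near wall, brighter lumen, dark far wall, bright
background. Vascular reactivity assays (agonist contraction, myogenic
responses to pressure steps, spontaneous vasomotion, flow-mediated dilation)
all reduce to tracking the outer diameter (OD) and inner, lumen diameter
(ID) of this pattern over time.

`myotracer` implements that tracking for recorded stacks. Its pipeline is
deliberately simple and fully inspectable: intensity profiles along scan
lines, derivative-peak edge detection, robust per-line outlier rejection,
calibrated averaging, and a gated session layer with telemetry and CSV/TIFF
export.

## Edge detection on a scan line

A scan line is an image column restricted to the region of interest (ROI).
Its profile is processed as:

1. **Transverse integration** (`integration_px`, default 25 px). The
   profile is the mean of a band of neighbouring columns centered on the
   scan line, shrunk symmetrically near the ROI's x-limits. Averaging
   *across* columns suppresses pixel noise by ~5x while leaving the profile
   perfectly sharp *along* the scan direction. The alternative — a 25 px
   moving average along the profile itself — was rejected after analysis:
   whenever the wall is thinner than the window (e.g. a 19 µm wall at
   1.3 µm/px is 14.6 px), the smoothed derivative's extremum becomes a
   plateau whose midpoint sits (window − wall)/2 ≈ 5 px *outside* the true
   edge, i.e. a systematic +13 µm error on OD. Since accurate tracking of
   exactly such vessels at 4x magnification is the instrument's documented
   use, the integration must act transversely. A standalone
   `smooth_profile()` (centered moving average, odd window, default 25,
   symmetric shrink at the ends) is still provided for users who want
   along-profile smoothing explicitly.
2. **Light along-profile smoothing** (`smooth_px`, default 5 px, odd). With
   transverse integration already in place this only regularizes the
   derivative; 5 px is far below any wall thickness of interest, so it
   shifts no edges.
3. **Derivative**: central differences at interior samples (exact for
   linear ramps), one-sided at the two ends.
4. **Peak detection** (`min_prominence_frac`, default 0.15). Local extrema
   of both signs are kept when their topographic prominence reaches 15 % of
   the profile's maximum absolute derivative — a scale-free criterion robust
   to illumination changes. Runs of exactly equal derivative values
   (plateaus, the generic result of noise-free step edges under symmetric
   filters) count as one extremum at the plateau midpoint; single-sample
   extrema are refined to subpixel position by a three-point parabolic fit
   clamped to ±0.5 px. A derivative below `1e-9` gray/px everywhere is
   treated as flat (guards against floating-point jitter on uniform
   images).
5. **Classification.** The four-edge pattern has signs (−, +, −, +). With
   `mid` the midpoint of the span covered by the detected peaks: the
   strongest falling peak in the upper half (position ≤ `mid`) is the
   outer-top edge, the strongest rising peak in the lower half the
   outer-bottom edge, and the strongest rising/falling peaks strictly
   between those and `mid` are the inner edges. Magnitude ties break toward the outermost candidate for
   outer roles and the innermost for inner roles, making classification
   deterministic. Outer and inner validity are tracked separately, so a
   line with poor lumen contrast still contributes OD.
6. **Contrast gate** (`min_gradient`, default 2 gray/px). Because
   prominence is relative, a line of pure background noise would otherwise
   hallucinate edges; a line whose derivative never reaches 2 gray/px is
   marked invalid. Real edges at the weakest supported contrast
   (50 gray levels over a 2 px blur) give peaks an order of magnitude above
   this floor.

OD per line is the outer-edge separation, ID the inner-edge separation, and
wall thickness is reported per side, (OD − ID)/2, the conventional
myography reading (`wall_total = TRUE` switches to OD − ID).

## Outlier rejection and averaging

Side branches, clots and adherent debris corrupt individual scan lines. Per
frame, the OD series and ID series are screened independently with the
modified z-score, Mᵢ = 0.6745 (xᵢ − median)/MAD; when MAD is zero the
mean-absolute-deviation fallback Mᵢ = (xᵢ − median)/(1.253314 · meanAD) is
used, and when that is also zero all scores are zero. Lines with |Mᵢ| > 3.5
(the conventional cutoff for this statistic) are excluded, and the
unflagged remainder is averaged and scaled by the projected pixel size.

One property of this filter is worth stating precisely. On clean frames the
per-line spread is so tight (MAD ≈ 0.05 px) that an ordinary line deviating
by ~0.3 px occasionally scores above 3.5; excluding it moves the 20-line
mean by at most ~0.15 µm (a ≤ 2 px in-cluster deviation spread over the
remaining lines), in a random direction. The filter's guarantee is
therefore: gross corruption is removed (improving accuracy by its full
contribution), while on clean data it perturbs the mean by less than the
measurement precision. The test suite asserts exactly this bounded form,
not literal per-frame non-degradation, which no median-based rule can
promise.

## Calibration, sessions and export

Pixel scale comes either directly (µm/px) or as sensor pixel / objective
magnification; the bundled instrument arithmetic (5.2 µm sensor: 1.3 µm/px
at 4x, 0.52 µm/px at 10x; 1024 px ≈ 1.33 / 0.53 mm of field height) is
checked by the acceptance suite. Sessions gate frames greedily to a
sampling rate (default 2 Hz, mirroring the live instrument's processing
headroom; `allow_fast = TRUE` lifts the cap for offline work), join
telemetry by nearest timestamp within 0.5 s (half the default sampling
interval — beyond that a channel is recorded absent rather than guessed),
snapshot event notes from the latest timepoint (no interpolation, matching
live data-entry semantics), and compute % tone against a user-set reference
diameter. Export is RFC-4180 CSV (times at 1 decimal, physical quantities
at 2 — below the measurement precision), with absent values as empty
fields, plus 8-bit TIFF frames with blue/red/black overlays.

## The phantom: what it emulates, what it does not

The synthetic generator renders the three-level radial intensity model
(lumen intermediate, wall dark, background bright) around a possibly tilted
centerline, then Gaussian blur, hard-disk debris blobs, additive Gaussian
noise, and 8-bit quantization — the simplest model that reproduces the
four-peak derivative structure the detector relies on. Dynamics laws
provide ground truth: constant, a diameter step at a set time (pressure
step), or sinusoidal OD modulation (vasomotion; a single frequency makes
amplitude recovery directly testable). Unless a step specifies both
diameters, ID co-varies with OD conserving wall cross-sectional area
(OD² − ID² constant), a physically plausible default for a passive wall.

Defaults are the documented study conditions: OD 185 µm / ID 147 µm at
1.3 µm/px (a typical cerebral artery at 60 mmHg under the 4x objective),
blur 1.5 px, noise sd 3 gray levels, vasomotion amplitude 10 µm with a 60 s
period at 2 frames/s. Contrast levels (60/140/220) are chosen for
testability; real preparations vary and are not modelled. The phantom has
no optics beyond Gaussian blur, no flow or active wall mechanics, no
fluorescence, and debris blobs are hard disks — so passing tests certify
the *algorithm* under controlled degradation, not performance on any
particular preparation.

Test and acceptance runs use 160 x 200 px frames (the vessel plus
generous margins): recovery statistics are identical to full 1280 x 1024
frames because the algorithm only ever reads the scan-line bands, and small
frames keep 600-frame sequences cheap to render.

The telemetry simulator integrates a first-order thermal plant
(dT/dt = −(T − ambient)/τ + r·u) under bang-bang control — heater on exactly
while the measured temperature is below the setpoint — with Euler steps
dt < τ/10. The heating rate must exceed (setpoint − ambient)/τ or the bath
plateaus below the setpoint; the default (0.5 °C/s, τ = 120 s) holds 37 °C
from a 21 °C ambient within a fraction of a degree, consistent with the
±1 °C stability expected of an on/off controller. Reservoir heights convert
to pressure with 1 mmHg = 1.35951 cmH₂O (standard conditions, fixed so
tests are exact).

## Numerical and design choices

- Coordinates are 0-based, half-open, x along the vessel axis; scan lines
  sit at integer columns x_k = x0 + (k + 0.5)·w/n with halves rounded down,
  so all n lines are strictly inside the ROI. Tilt beyond a few degrees is
  the caller's responsibility; scan lines are columns, so a tilt θ inflates
  measured diameters by 1/cos θ (0.5 % at 5.7°).
- Even smoothing windows are rejected rather than silently incremented.
- Degenerate inputs never abort a session: a frame with no valid line
  reports absent means and zero counts; failed frames become absent rows.
- Determinism: a phantom spec + seed renders bit-identical stacks; sessions
  are pure functions of their inputs; the CLI writes a manifest sufficient
  to reproduce any deterministic run.
- A minimum-wall-thickness constraint on inner-edge search is a plausible
  future refinement for vessels with irregular lumen content; it is not
  implemented, and very low lumen contrast simply yields `inner_valid =
  FALSE` lines.

## Known limitations

Single straight vessel per scene; no curved-axis tracing, drift correction
or automatic axis detection; no model-based wall fitting; per-side wall
asymmetry is not reported (OD/ID are symmetric separations). The 2 Hz gate
is a faithful compatibility default, not a performance limit of the offline
pipeline.
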