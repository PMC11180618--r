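---
title: "Spatiotemporal mapping and waveform metrics for contracting tubular organs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal mapping and waveform metrics for contracting tubular organs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`myowave` quantifies travelling contraction waves in fluorescence
time-lapse recordings of a pinned tubular organ such as the mouse uterine
horn. This vignette is the package's account of the method: the model
behind each stage, the parameters that matter and why their defaults are
what they are, the numerical choices that make the pipeline reproducible,
what the synthetic simulator does and does not emulate, and the known
limitations.

## The measurement model

The organ appears as a bright horizontal tube on a dark background. Two
muscle systems move it: circular-muscle contractions narrow the tube
locally, and longitudinal contractions compress tissue along the axis
without changing the diameter. Both concentrate the fluorescent reporter
where tissue compresses, so local pixel intensity rises under either kind
of contraction, while the projected tube width responds only to the
circular kind. The pipeline therefore derives *two* spatiotemporal maps:

* **area** `A(x, t)` — the pixel distance between the detected upper and
  lower boundaries of column `x` in frame `t`, a unit-pixel-width proxy
  for the local cross-section;
* **mean intensity** `M(x, t)` — the mean of the *raw* (never smoothed)
  pixel values between those boundaries.

A wave travelling at speed `v` appears in either map as a diagonal ridge
of slope `v`; on an axis oriented oviduct → cervix, a positive slope is a
wave moving toward the cervix.

## Stage 1: boundary identification

Frames are Gaussian-smoothed with window 3 along time and window 5 along
both spatial axes. "Size" means window length; sigma follows the common
automatic rule `0.3 ((size - 1)/2 - 1) + 0.8`, so stating the sizes fully
determines the filters. This smoothing exists only to stabilise edge
detection; all intensity analyses use the raw stack, because smoothing
dilutes exactly the local intensity changes stage 2 measures.

Each smoothed frame yields a weighted Sobel edge index
`S_h + 2 S_v` at a 5×5 aperture (extended Sobel taps from the binomial
construction: smoothing `(1+x)^(n-1)`, derivative `(1+x)^(n-3)(x^2-1)`).
Boundaries are located per column from the cumulative profile of the
absolute edge index, in three steps:

1. *Noise floor.* The column's absolute edge index is clipped at 3× its
   median. Real edges occupy few rows, so the median is background
   dominated; clipping empties the background while leaving genuine edges
   intact, and is a no-op on noise-free input (median 0). Without this
   step, accumulated sensor noise along a tall column can cross the
   threshold far outside the organ.
2. *Crossing.* The running cumulative sum, normalised by the column's
   mean clipped |edge index|, is followed top-down and bottom-up; the
   first and last crossings of the threshold (default 2) bracket the
   organ. The normalisation makes detection invariant to a global
   intensity rescaling, which is why results tolerate exposure
   differences between recordings.
3. *Refinement.* A bare threshold crossing sits on the outer tail of the
   blurred edge response and would bias both boundaries outward by about
   two pixels (and the area map by twice that). Each crossing is
   therefore snapped to the sub-pixel peak of the edge response in a
   small window just inside it, with parabolic interpolation between the
   peak's neighbours — standard edge localisation, and the reason the
   noise-free tracing error is well under a pixel.

The raw per-column boundaries are then regularised by a cubic
interpolation spline with knots every 10 columns (parameter
`knot_spacing`). Isolated excursions narrower than the knot spacing —
e.g. a stain in the dish pulling the lower crossing toward it for a few
columns — fall between knots and are rebuilt from the clean neighbours.
Columns without a crossing (the thin, low-gradient organ ends) stay
invalid; interior invalid gaps up to one knot spacing are bridged by the
spline; only the widest valid run per frame (the organ body) is analysed.
If the spline makes the boundaries cross, both are clamped to their
midpoint ± 0.5 px so the area stays non-negative; frames with fewer than
four valid knots are flagged unusable rather than guessed.

## Stage 2: map enhancement

Raw maps carry the organ's static width/brightness profile on top of the
travelling waves. The enhancement pipeline is, in order:

1. subtract a centred moving average along space (window 51 columns) —
   removes the baseline profile and any slow axial gradient;
2. Sobel gradient magnitude (aperture 5) on the space × time matrix —
   marks change in any direction, so ridges appear regardless of travel
   direction;
3. centred moving average along time (window 5 frames) — suppresses
   residual frame noise.

Two ordering choices deserve a note. Detrending *before* the gradient is
deliberate: differentiating first would fold the derivative of any slow
axial gradient into every gradient magnitude, and the package's own
invariance requirement — adding a smooth spatial gradient of period much
longer than the detrend window must leave the enhanced map essentially
unchanged — cannot hold in that order. Second, all three filters are
zero-phase (centred), so ridge positions are never displaced in space or
time; moving averages are the simplest filters with that property, and
their windows are exposed in `enhance_params()` for users who need to
match other acquisitions. Masked cells are excluded from every window and
remain masked; the Sobel step sees constant-extrapolated fill values at
mask borders but its output is re-masked immediately.

Because the enhancement is a gradient *magnitude*, a wave band appears as
change ridges flanking the crest, symmetric about it; the band's centre
of mass sits on the crest, which is how the tests associate enhanced
ridges with simulated ground truth.

## Stage 3: waveform metrics

Wave marking is manual by design (automating ridge calling is out of
scope); an annotation records a ridge segment (two `(column, frame)`
endpoints along one crest), the band extent (two columns), and the frame
at which the next crest passes the ridge's start column. With the
calibration defaults `110.85 px = 1 mm` and 5 frames/s:

* velocity = |ridge slope|, µm/s; its sign on the oviduct-left axis gives
  the direction, with a floor (default 0.1 µm/s) below which a wave is
  called stationary;
* amplitude = band extent, µm. Amplitude is a *spatial* extent, not an
  intensity excursion: that is the only reading that carries the same
  units on area- and intensity-based maps;
* period = time to the successor crest, s — time between successive waves
  at a fixed position, which makes frequency = 1/period independent of
  velocity; waves without a successor in the window simply lack
  period-derived metrics, and summaries count per metric;
* wavelength = velocity / frequency, µm, exact by construction.

Segments split the spatial axis into oviductal, middle and cervical
thirds, half-open, with boundaries at `floor(n/3)` and `floor(2n/3)`; a
wave belongs to the third containing its ridge midpoint (a single
deterministic label even when a wave straddles a boundary). The sampling
protocol draws 3 waves per segment uniformly without replacement, seeded.

## Statistics

Group comparison is a two-tailed Mann–Whitney test after per-group ROUT
outlier removal; ROUT is applied per group because pooling would let a
genuine group difference masquerade as outliers.

The exact Mann–Whitney path enumerates the null U distribution with the
classical rank-sum dynamic program, used automatically when
`n_a · n_b ≤ 400` and there are no ties. Otherwise the normal
approximation applies tie, continuity and Edgeworth corrections; the
Edgeworth term uses the excess kurtosis of the untied U distribution,
`γ₂ = −1.2 (m² + n² + mn + m + n) / (mn(N+1))`, verified in the tests
against the enumerated distribution, and keeps the approximation within
0.01 of the exact p throughout the 8–20 sample range.

ROUT is reduced to one sample: the robust "model" is the median, the
robust scale is the RSDR (68.27th percentile of absolute residuals with
the `n/(n−1)` small-sample correction), residual t-scores get two-tailed
p-values at `n−1` degrees of freedom, and a Benjamini–Hochberg step at
rate Q (default 1%) selects outliers; removal iterates until stable.
Samples below n = 5 and zero-scale samples are never touched. Flags are
scale-invariant because residuals and RSDR scale together.

## The simulator, and what passing tests show

`simulate_video()` renders a horizontally centred tube with half-diameter
`r(x,t) = r0 (1 − a·w(x − s v t))`, where `w` is a raised-cosine bump
train of compact support `band_width` and spacing `wave_spacing` — smooth,
bounded, and analytically integrable, which is what makes the
fluorophore-conservation check exact. In circular mode the interior
intensity rises as `(r0/r)^γ` (γ = 1 conserves the per-column fluorophore
integral); longitudinal mode keeps `r = r0` and carries only a density
wave `(1 + a·w)^γ`. Ends taper smoothly to 15% diameter over 8% of the
width (thin, low-gradient, like real organ ends), optional stain-like
Gaussian blobs sit strictly outside the tube, Gaussian sensor noise is
added per frame, and output is quantised to 8 bits. All randomness flows
from one seed; identical parameters yield bit-identical stacks.

Simulator defaults are the study's acquisition conditions: 5 frames/s,
110.85 px/mm, 300 s recordings, and waves at the reported uterine scale
(12.8 µm/s speed, 800 µm spacing, 190 µm band width, 30% constriction).
Where a condition had no stated value (tube half-diameter 40 px in a
160 px frame, interior intensity 140/255, noise regimes 0 and 5 grey
levels, up to 3 stains), values were chosen once to resemble the
recordings the method targets and are not revisited.

What the simulator does *not* emulate: organ curvature and drift,
pin-site deformation, photobleaching, flat-field inhomogeneity, waves
that start, stop, collide or change speed, and intensity texture within
the tissue. Passing tests therefore demonstrate that the implementation
recovers known waves under the stated geometry and noise — they do not
certify accuracy on curved, drifting or optically uneven real recordings,
where boundary parameters may need retuning.

Ground-truth annotations (`truth_annotations()`) place ridge endpoints
exactly on crest trajectories but cap the ridge span at about one wave
spacing: a mark spanning a crest's entire traversal would put every ridge
midpoint near the organ centre and defeat per-segment sampling, and a
local mark is also how waves are annotated by hand.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based, row 0 at the top, column 0 at the left,
  all intervals half-open — one convention everywhere.
* Convolutions use explicit tap sums with replicate padding; moving
  averages use zero padding with per-cell counts so partial windows
  average only what they see and masked cells never fabricate values.
* Splines are `stats::splinefun(method = "fmm")`, which reproduces
  polynomials up to cubic exactly.
* Tables travel as UTF-8 CSV with `.` decimals plus a JSON sidecar
  (calibration, parameters, provenance); `read(write(x))` is exact, and a
  missing column fails with the column's name.
* Degenerate cases fail loudly and specifically: single-frame videos,
  crops too thin to hold two boundaries, ridge endpoints in the same
  frame, successor frames not after the ridge start, undersized segments
  (named), horns with fewer than three embryos.
* PNG round-trips snap values within 1e-9 of an integer, because 8-bit
  files store `k/255` which is not exactly representable in binary
  floating point.
* Embryo positions slightly above 1 (XY projection versus measured horn
  path) are assigned to the cervical third rather than rejected; negative
  positions count as oviductal.

## Problem sizes

The test suite validates modules on tubes of roughly 300–600 × 80–120 px
over 8–40 s, and the end-to-end checks use 1200 × 160 px over 300 frames
for boundary accuracy and full 300 s (1500-frame) recordings at
600 × 80 px for parameter recovery — sizes chosen so the whole suite runs
in minutes on a laptop while still exercising the acquisition scale in
space and duration.

## Known limitations

* Compressed video containers are not decoded; inputs are lossless
  PNG/TIFF frame sequences.
* One organ per video, horizontally oriented; overlapping horns and
  ovary/cervix pins are out of scope.
* The area map reads only the projected silhouette: a wave on the camera-
  facing surface that leaves the silhouette unchanged is visible only in
  the intensity map — this asymmetry is by design and is exactly what the
  area/intensity comparison is for.
* Wave marking is manual; the package computes metrics from marks, it
  does not find waves.
* Directionality is reported per wave (sign of the slope); the package
  deliberately offers no population-level directionality statistics.
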