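---
title: "Methods: coupled gravimetric and imaging sorption analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled gravimetric and imaging sorption analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hygrex)
```

## The measurement problem

Hygroscopic materials such as wood exchange water vapour with the air.
Two coupled observables describe the process: the moisture content
(dry-basis mass fraction, in percent) and the in-plane dimensions of the
specimen, which change in proportion to moisture content below fibre
saturation. The instrument this package analyzes holds flat specimens in
a climate chamber over a microbalance while a camera photographs them at
every weighing, so both streams refer to the same undisturbed specimen.
`hygrex` turns the two raw streams — a mass/climate log and a time-lapse
image sequence — into sorption isotherms, swelling statistics and
dynamics, and ships a virtual instrument that generates both streams with
known ground truth.

## Image evaluation

### Segmentation

Frames are converted channel-wise from sRGB to CIELAB under the D65 white
point with lightness on the standard [0, 100] scale. The defaults for the
background intervals are the calibrated constants of the reference
system, `L 1.821/17.536`, `a −2.656/7.803`, `b −11.501/3.916`; these only
make sense on the standard CIELAB scale, which is why the white point and
scaling are fixed and documented rather than configurable. The printed
pairs are read as per-channel `[lo, hi]` intervals describing the
*background*: a pixel is background exactly when all three channel values
fall inside their interval, and specimen otherwise. Thresholding the
background rather than the specimen makes the segmentation robust to the
colour and brightness variation of wood surfaces; the thresholds remain
configurable per experiment because they depend on the imaging setup.

### Mask cleanup

Foreground components are labelled with 8-connectivity and background
with 4-connectivity — the standard dual pair that avoids topological
paradoxes. Every foreground component with at most 7 000 px is deleted
(the bound is inclusive, reading "maximum size" literally); losing the
specimen entirely is an error rather than an empty result. Interior holes
— background regions not 4-connected to the image border, such as the
2 mm mounting hole (about 111 px across at 0.018 mm/px) — are filled;
notches open to the border are left alone. Artifact removal runs before
hole filling, so out-of-threshold specks sitting inside a hole do not
bridge it. The cleanup pass is idempotent.

### Rotation alignment

Specimens are mounted with the tangential direction roughly horizontal
but never perfectly straight. The residual tilt is estimated from the
*minimum-area bounding rectangle* of the foreground convex hull (rotating
calipers over the hull-edge angles, then a continuous local refinement of
the bounding-box area). We deliberately avoid the more common
inertia-tensor principal axes: the specimens are 20 × 20 mm squares, for
which the second-moment matrix is isotropic and its principal axes are
numerically meaningless, while the minimum-area rectangle stays
well-posed for squares and recovers rendered tilts of ±10° within the
0.2° tolerance the tests enforce. Corrections are limited to ±45° (larger offsets are mounting
errors, not tilt); ties at exactly 45° resolve toward the
smaller-magnitude rotation, and the degenerate square-at-45° case is
aligned to whichever diagonal orientation minimizes the bounding box.
The mask is resampled with bilinear interpolation and re-binarized at
0.5.

### Centre-band widths

Widths are the mean column (radial) or row (tangential) sums of the
binary mask over a band of `f` columns/rows centred on the foreground
centroid, with `f` odd so the half-width `h = (f − 1)/2` is integral
(even `f` is rejected, never silently adjusted). The centroid coordinate
is rounded half-up to an integer index; a centroid is stable under edge
noise, unlike the bounding-box midpoint. The default `f = 81` averages
about 1.5 mm across the specimen centre, suppressing single-column noise
while staying clear of the corners. On any axis-aligned solid rectangle
the estimators are exact, and they equal a naive double-loop sum by
construction — both properties are enforced in the tests. Pixel widths
convert to mm by the fixed optical scale; the nominal 0.018 mm/px is used
as canonical (the alternative value implied by quoting 81 columns as
1.473 mm, 0.01819 mm/px, differs by 1 % and is absorbed by the
configurable scale).

## Mass-side logic

Moisture content is dry-basis: `m = (m_u − m_0)/m_0 × 100`, with `m_0`
the mass at the equilibrated 0 % r.h. state (the final mass of the first
equilibrated 0 % step; when two 0 % steps equilibrate, the first is
used). Negative transients are possible near dryness and are warnings,
not errors.

A step is equilibrated when the OLS slope of the last five weighings
(15-min cycles), expressed in percent per 60-min window, is strictly
below 0.01 % in absolute value — the absolute value so the same criterion
serves absorption and desorption. The percent basis is the window-mean
mass by default (`basis = "first"` is available); the two differ by well
under the criterion itself at these mass-change rates. Restated per
minute and truncated to two significant digits the threshold is
0.00016 %/min (truncation, not rounding, of 0.0001667; the truncated
figure is the conventional citation form). Regression uses actual
timestamps, so irregular logs are handled; the 36/48 h minimum/maximum
step durations are instrument behaviour and therefore enforced by the
virtual instrument, not by the analyzer, which accepts any real log.

Logs are segmented by consecutive runs of the r.h. setpoint matched
against a contiguous slice of the 22-step schedule (a log may start
mid-schedule); any setpoint sequence that cannot be aligned is a hard
error that prints the divergence. EMC is the *last* mass of an
equilibrated step — the value closest to the asymptote, matching an
instrument that switches humidity the moment the criterion holds.

## Swelling statistics

Swelling is referenced to the dry dimension: `S = (w − w_dry)/w_dry ×
100`, with the dry dimensions interpolated at the end of the equilibrated
0 % step. Image times are mapped to moisture content by linear
interpolation of the mass stream (a no-op when frames coincide with
weighings, as the virtual instrument arranges); frames outside the mass
record range are dropped rather than extrapolated.

Differential swelling divides the maximum swelling of a direction by the
shrink-onset moisture content, `q = S_max / MC_onset`, reported to two
decimals with full precision retained internally. The onset is the
moisture content above which drying no longer shrinks the specimen
(fibre-saturation plateau); fixed defaults are 30 % MC for pine and 40 %
for beech, and an optional detect mode fits the continuous two-segment
model `S = a + q·min(MC, b)` over candidate breakpoints on the observed
MC grid, requiring at least six points and a decisive improvement (5 % in
SSE) over a single straight line before trusting a breakpoint. Maximum
swelling scans all frames regardless of equilibrium flags; no outlier
filter is applied, which a single bad frame can therefore dominate — the
per-frame failure flags from the measurement stage are the intended
guard.

Within one sorption step the moisture-content and swelling series are
min–max normalized (extrema exactly 0 and 1; constant series are an
error, not silently zero) and related by an OLS fit with free intercept —
free because a forced zero intercept would hide lags between the two
processes, which are exactly what the comparison is for. R² is computed
on the normalized series as plotted.

Time to approximate equilibrium rounds the MC series to three decimals
and takes the time of the first point whose rounded value equals its
successor's. Rounding is decimal half-away-from-zero with a one-ulp
guard, so values written as `.0005` round up despite binary floating
point. With exponential kinetics this statistic is monotone in the time
constant over the relevant range, which is what makes it usable as a
thickness-ordering diagnostic.

## The virtual instrument

The generator exists to make every pipeline stage testable against known
truth; its defaults are the study conditions, not tuning knobs.

* **Specimens**: 20 × 20 × 1.5 mm with a 2 mm central hole; dry masses
  306 mg (pine) and 394 mg (beech); true differential swelling 0.19/0.31
  (pine radial/tangential, onset 30 % MC) and 0.15/0.41 (beech, onset
  40 %).
* **Isotherm**: a GAB curve (monolayer 6.5 % MC, C = 8, K = 0.75) for
  desorption — a textbook type-II shape giving ~17 % EMC at 85 % r.h. —
  with absorption a fixed ratio 0.85 of desorption. The ratio form keeps
  desorption ≥ absorption everywhere and EMC(0) = 0 by construction.
  These are generator parameters chosen for realism, not claims about any
  measured curve.
* **Kinetics**: single-exponential approach to the step target with
  τ = 180 min at 1.5 mm thickness, scaled by thickness² (Fickian
  diffusion scaling; exponent configurable). 180 min makes every step
  equilibrate comfortably within the 36 h minimum cycle while leaving a
  long enough transient to exercise the criterion.
* **Noise**: Gaussian balance noise of 5 µg SD (the instrument's stated
  repeatability) and dimension noise of 0.3 px SD (sub-pixel edge
  jitter). Seeds are mandatory; runs are bit-identical for a fixed seed.
* **Cadence**: weighings and frames every 15 min; steps advance by the
  analyzer's own criterion after 36 h, or unconditionally at 48 h.
* **Rendering**: uniform background whose colour sits inside the
  threshold intervals, specimen far outside them, per-pixel colour noise
  of 0.003 SD — about the largest level that essentially never crosses
  the Lab intervals at the dark-background operating point — plus up to a
  few artifact discs of 50–3 000 px placed on the background, clear of
  the specimen edges (artifacts touching the specimen would merge with
  it, which is a segmentation hazard, not an artifact-removal test).

What the generator does *not* emulate: earlywood/latewood texture,
specimen warp and bending, non-exponential (multi-phase) kinetics,
scanning isotherms inside the hysteresis loop, and drift in illumination
or camera geometry. Tests passing on synthetic data therefore validate
the geometry, the criterion logic and the statistics — not the
segmentation thresholds for any particular real camera, which must be
calibrated per setup.

## Problem sizes and numerical choices

The test and acceptance runs use downscaled frames — 320 px at
0.09 mm/px, so a 20 mm specimen spans ~222 px and the default f = 81 band
still fits — which keeps a rendered round-trip at a fraction of a second
per frame while preserving every geometric property (the estimators are
resolution-exact on rectangles; recovery tolerances of 1–2 px refer to
the frame's own pixel size). Full 2 046 px frames at 0.018 mm/px are
supported and differ only in runtime. Virtual experiments run the full
22-step schedule (~3 200 weighings); parameter-recovery checks use the
generator's dimension series directly, with image round-trips validated
separately, so twenty replicate experiments stay within seconds.

Numerical conventions worth knowing: interval inclusion in thresholding
is closed on both ends; the artifact bound is inclusive; band centres
round half-up; rotation resampling re-binarizes at 0.5; the strict
less-than of the equilibrium criterion is preserved exactly (a slope
equal to the threshold is not equilibrium); and the breakpoint search in
onset detection is restricted to observed MC values, so its resolution is
the data's own grid spacing.

## Known limitations

Only the two in-plane directions are measured — a top-view camera cannot
see longitudinal (thickness) changes. Swelling maxima are unfiltered
order statistics and inherit single-frame outliers. Onset detection needs
data on both sides of the plateau (a run started below fibre saturation
must use fixed mode). The schedule matcher assumes setpoints are recorded
exactly; a chamber that logs drifting setpoints needs them quantized
upstream. The CLI wrapper is a thin script over the exported functions;
batch orchestration across many specimens is left to the caller.
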