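---
title: "Monitoring spring frost damage to winter wheat: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring spring frost damage to winter wheat: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatfrost)
library(dplyr)
```

## The problem

A late-spring cold snap that hits winter wheat between stem elongation and
booting can sterilize developing ears and cut yields without leaving the
kind of canopy damage that is easy to survey on the ground. Agricultural
departments publish a province-level affected-area statistic from field
surveys, but that single number carries no spatial information: it does not
say *which* fields were hit. Dense satellite vegetation-index time series
carry the spatial signal — canopy NDVI dips during and after the frost —
but thresholding a damage index directly is unreliable because mixed pixels
and natural variability blur the damaged/undamaged boundary.

`wheatfrost` combines the two: it computes a per-pixel cumulative damage
index from the NDVI time series, then uses the official statistic to decide
how far down the damage ranking the affected-area map should reach. The
output is a map whose total winter-wheat area matches the survey while its
spatial pattern comes from the satellite signal.

## The monitoring chain

### NDVI and smoothing

Per pixel and day, `ndvi()` computes `(nir - red) / (nir + red)` from
nadir-adjusted surface reflectance. Days with a zero band sum or negative
reflectance are masked rather than raised as errors: cloud contamination is
routine, not exceptional. `fill_gaps()` closes observation gaps by linear
interpolation (edge gaps are held at the nearest valid value; a pixel with
no valid day at all is unusable and errors), and `sg_smooth()` applies a
Savitzky–Golay filter with a 7-day window and a quadratic local polynomial.
The window length is the standard choice for daily NDVI de-noising; the
polynomial degree is our fixed default (degree 2 preserves the curvature of
a phenology curve while suppressing day-to-day noise) and both are
configurable. At the series edges the polynomial is fitted on the truncated
window that remains inside the series — no reflection or padding — so the
filter is a single well-defined linear operator; tests pin this behaviour
down by comparing against an independent per-window least-squares fit.

### The reference curve: shape-model fitting

What would a frost-hit pixel's NDVI have looked like without the frost? We
estimate it by geometrically rescaling the pixel's *multi-year average*
frost-free curve `g` (the shape model, `multi_year_average()`):

```
h(x) = sy * ( g( sx * (x + t0) ) + bias ) - bias
```

`sx` and `t0` absorb year-to-year phenological shifts (an early or late
spring), `sy` absorbs magnitude differences (stand density, management),
and `bias` is a fixed crop-specific constant (0.61 for winter wheat) that
centres the magnitude scaling: with it, `sy` pivots the curve about the
level `-bias` rather than about zero. The typeset form of this transform in
the shape-model literature is ambiguous about grouping; we adopt the
reading above, in which `bias` acts as a baseline-centering constant and a
transform with `sy = 1` is bias-independent (a property the tests assert).

`fit_smf()` minimizes the weighted RMSE between `h` and the SG-filtered
frost-year curve over the box `sx` ∈ [0.9, 1.1], `sy` ∈ [0.5, 1.85],
`t0` ∈ [−10, 10] days. The optimizer is deterministic by construction:

1. a coarse grid over `(sx, t0)` (steps 0.01 and 1 day). For fixed
   `(sx, t0)` the objective is linear in `sy`, so the profile-optimal `sy`
   is computed in closed form at every node and clamped to its bounds;
2. bounded local polish (`L-BFGS-B`) from the best node;
3. ties broken toward the identity `(1, 1, 0)` — in the priority order
   `sx`, `sy`, `t0` — and a final guard that the returned fit is never
   worse than no transformation at all.

No stochastic restarts, hence no seeds: the same inputs always give the
same fit. Weights default to uniform because the field's practice does not
fix them; they are injectable per day. The full pipeline sets the weights
of the provisional frost window (meteorological onset to the shape model's
peak) to zero before fitting, so the frost dip itself cannot drag the
fitted reference down toward the damaged curve — without this the
magnitude parameter systematically underestimates the reference exactly
where the damage index is computed. The template is interpolated linearly
at scaled time arguments and extended at its edge values beyond the
window.

### The damage index

`compute_sfdi()` accumulates the daily difference between the reference
curve and the affected curve over the frost window, inclusive at both ends:

```
SFDI = sum_{i = sf_begin}^{sf_end} [ NDVI_ref(i) - NDVI_frost(i) ]
```

The window start is the meteorological frost onset when a record exists;
otherwise `detect_frost_window()` finds the first sustained NDVI decline
before the reference peak (two consecutive daily drops of at least
0.005 NDVI each by default — the per-day floor is what keeps smoothing
ripple and noise from triggering a spurious onset near the peak, where the
clean slope approaches zero). The window end is the day the *reference*
curve peaks: beyond the peak the crop enters grain filling, leaf colour
turns, and the spectral signature of frost damage can no longer be
separated from normal senescence. Daily terms are summed as written —
days when the affected curve sits above the reference subtract — with a
clip-at-zero variant behind `clip_negative = TRUE`, since the literature
is silent on flooring. All day indices are offsets since the season start
(1 March = day 0; a 3 April onset is day 33).

### Area correction against the official statistic

Raw SFDI has no agreed damage threshold, and "SFDI > 0" would sweep in
every mixed pixel. `score_sfdi()` therefore bins the index: SFDI ≥ 16
scores 1 (worst), 15 ≤ SFDI < 16 scores 2, …, 1 ≤ SFDI < 2 scores 16;
below 1 a pixel is unscored and treated as unaffected. `sasc_select()`
then accumulates winter-wheat area — crop fraction × pixel area, in mu
(666.67 m²) — over whole score classes, worst class first, and stops at
the cutoff whose cumulative area is nearest the official statistic. Ties
go to the smaller, more conservative selection; if even all scored pixels
fall short of the target, everything scored is selected with a warning.
Class-granular selection mirrors how such corrections are done in
practice; `partial = TRUE` additionally refines the last class pixel by
pixel in decreasing-SFDI order. The stopping rule's optimality over all
whole-class cutoffs is verified in the tests by exhaustive enumeration,
and identical inputs give bit-identical selections.

### Validation

`accuracy_rate()` is the symmetric ratio of official to monitored area,
`100 * min/max`, in percent (the April 2018 Shandong event: 489,000 mu
surveyed vs 545,000 mu monitored gives 89.72%). `yield_reduction_table()`
compares frost-year county yields with the mean over caller-specified
normal years — the package deliberately does not try to auto-detect which
years were "normal" from the yields themselves. `classify_severity()`
applies the official bands: no damage at ≤ 0% reduction, mild below 10%,
medium from 10% to 30% inclusive, severe above. The official prose leaves
10–11% unassigned ("less than 10%" mild, "11–30%" medium); we close the
gap at 10 because the affected-area definition uses "reduced by more than
10%", and the thresholds are configurable. `sfdi_regression()` is plain
OLS of a per-unit covariate (minimum temperature, yield reduction) on mean
SFDI. The per-pixel severity map produced by `severity_from_sfdi()` is a
quantile mapping and is flagged as an exploratory extension, not an
official classification.

## What the synthetic scenes emulate

`simulate_frost_scene()` generates every input the pipeline needs, with
truth attached, so the whole chain is testable without any satellite
download:

* **Phenology** — a double-logistic curve (baseline 0.30, amplitude 0.50,
  green-up inflection day 12, senescence inflection day 78, rates
  0.15/day) sampled daily over a 92-day window anchored at 1 March. This
  peaks near day 45 (mid-April), the NDVI range a dense winter-wheat
  canopy shows on the North China Plain in spring.
* **The frost event** — a triangular ("vee") NDVI dip on a random subset
  of crop pixels: onset day 33 (3 April), closing 10 days later (the 3–13
  April impact of the motivating event), per-pixel depth uniform in
  0.25–0.55 NDVI. Depths in this range represent damage deep enough to
  clear the lowest score bin (SFDI ≥ 1) — the regime the score table
  addresses; shallower dips are by construction below the method's
  detection floor, which is a genuine limitation, not a test artifact.
  The dip integral gives the injected pixel an SFDI of roughly
  `depth × recovery_days / 2`.
* **Observation** — NDVI is inverted to a red/NIR pair through the fixed
  band model `nir = 0.25 (1 + ndvi)`, `red = 0.25 (1 − ndvi)` (so
  `ndvi()` recovers the target exactly), Gaussian noise (default sd 0.01)
  is added per day, and days are dropped at a configurable gap rate to
  emulate cloud masking.
* **History** — five frost-free seasons with small year effects
  (amplitude sd 0.03, common timing shift sd 2 days); their average is
  the shape model, so the fit stage faces a template that does not match
  the frost year exactly, as in reality.
* **Geometry** — 500 m square pixels (≈ 375 mu each) and a crop-fraction
  field uniform on 0.4–1 for wheat pixels, with 10% of pixels carrying no
  wheat.

All randomness flows from one integer seed; a regenerated scene is
byte-identical on disk.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spatially correlated noise and cloud runs,
mixed-pixel phenology (each synthetic pixel is pure wheat plus a
fraction), BRDF and atmospheric residuals, multiple or overlapping frost
events in one season, and real year-to-year phenology shifts larger than a
few days. On real scenes the separation between damaged and undamaged
pixels will be weaker than the near-perfect recovery seen on synthetic
ones.

## Numerical choices and degenerate inputs

* Observed NDVI outside [−1, 1] is clamped and flagged invalid;
  model-derived curves (a shape-model transform at large `sy`) may
  legitimately leave the physical range and are kept unclamped.
* A constant (zero-variance) fit target returns an identity-adjacent fit
  with a warning rather than an arbitrary optimum.
* Grid/optimizer resolution: the `(sx, t0)` grid steps (0.01, 1 day) are
  fine enough that, with the closed-form `sy` profile, the polish stage
  starts inside the basin of the global optimum for curves of this
  smoothness; a lattice-enumeration test bounds any remaining gap at
  1e−3 RMSE.
* `sasc_select()` always selects at least the worst score class, even
  when that overshoots the target (the first prefix is the first
  candidate cutoff).
* Pixel areas: projected rasters use `|width × height| / 666.67`;
  geographic rasters use a spherical cell-area formula at the cell's
  latitude (authalic radius), cross-checked against a geodesic polygon
  oracle in the tests.

## Problem sizes used by the test suite

The suite exercises the chain at sizes chosen to make every property
checkable in well under a minute each: 92-day single curves, 50-seed
parameter-recovery and selection-optimality simulations, and 24×24-pixel
end-to-end scenes (576 shape-model fits per run). These sizes are the
package's own testing choices; the code itself is size-agnostic, and the
shared-grid fitter (`(sx, t0)` nodes precomputed once per template) is
what keeps per-pixel fitting of larger scenes linear in pixel count.

## Known limitations

* One frost event per season; overlapping events merge into one window.
* Single-crop logic: the bias constant, score table and severity bands are
  winter-wheat values.
* The SFDI floor at score 16 (SFDI ≥ 1) means shallow damage is invisible
  to the correction stage by design.
* When no meteorological onset is available, decline detection on smoothed
  curves can place the onset a day early: the filter spreads the dip's
  leading edge. Tests assert ±1 day.
* The severity-by-quantile pixel map is exploratory; only the
  yield-reduction severity classes follow an official definition.
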