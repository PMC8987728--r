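---
title: "Arc-length corridors: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arc-length corridors: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridr)
library(dplyr)
library(ggplot2)
```

## The problem

Experimental biomechanics produces families of two-dimensional signals —
ligament force-displacement curves, head acceleration-time traces from
volunteer sled tests, hysteretic load-unload loops from thoracic pendulum
impacts — that must be summarized as a single *characteristic average*
with *response corridors* quantifying between-specimen variability.
Surrogates (crash-test dummies, computational human body models) are then
assessed against the average and corridors. Point-wise averaging over time
or over the x-axis fails for such data in two ways: signals that are
non-monotonic in one or both axes have no single-valued representation
y(x), and signals whose shared features (peaks, valleys) are misaligned
get those features smeared flat in the average.

`corridr` addresses both problems with a three-stage pipeline:
arc-length re-parameterization, optional signal registration, and
point-wise statistics with elliptical confidence regions.

## Stage 1: arc-length re-parameterization

Cumulative arc length along a curve is strictly increasing no matter how
the curve bends, so expressing both coordinates as functions of
*normalized* arc length ŝ ∈ [0, 1] turns every signal — hysteretic loops
included — into a pair of single-valued traces x(ŝ), y(ŝ) without any
manual segmentation.

Because the two axes usually carry incommensurate units (mm vs N), raw
arc length would be dominated by the larger-magnitude axis. Each axis is
therefore divided by the mean range of that axis over all signals (mean
of per-signal maxima minus mean of per-signal minima) before arc length
is accumulated. Using mean extrema, rather than per-signal extrema,
preserves the relative sizes of individual signals. The scaled
coordinates are used *only* for arc-length computation; all later stages
work on the original data. Segments are treated as linear, matching the
piecewise-linear interpolation used for resampling; a degenerate axis
(zero range) falls back to divisor 1 with a warning so constant channels
remain processable.

All signals are then resampled by linear interpolation onto a common
uniform grid of `n_resample` normalized-arc-length values (default 200,
a grid fine enough that corridor geometry is stable for the signal
densities used here while keeping registration cheap). Endpoints are
reproduced exactly. Input signals need not share sampling rates, point
counts, or endpoints.

## Stage 2: signal registration

Arc-length re-parameterization embeds an assumption: that shared
features sit at about the same ŝ in every signal. Phase jitter or
specimen-to-specimen timing variation violates it, and the point-wise
average then underestimates peak amplitudes. Registration gives each
signal *i* a warping function h_i(ŝ) — a monotone cubic Hermite
(Fritsch–Carlson) spline through `m` interior control points, anchored
at (0,0) and (1,1) — and re-evaluates the signal at the warped arc
lengths. Monotonicity guarantees warping only re-times a signal, never
reorders it.

The `n · m` control points (both coordinates free) are optimized jointly
to maximize

> (C_x + C_y) / 2 − penalty,

where C_x and C_y average the Pearson correlation over all off-diagonal
signal pairs on the common grid, for the x and y traces respectively.
The penalty is the squared deviation of the warps from the identity,
λ Σ_i Σ_j (h_i(ŝ_j) − ŝ_j)², summed over signals and grid points. Two
published anchors calibrate this aggregation: λ = 10⁻² should align
features well, and λ = 1 should suppress warping almost entirely. A
penalty *averaged* over signals and integrated over ŝ cannot reproduce
the second anchor for oscillatory data — both the correlation gain and
such a penalty scale quadratically with the misalignment, so their ratio
is independent of how much misalignment there is and λ = 1 would never
pin the warps. Summing over signals and grid points restores the
documented behaviour at the study scale (n ≈ 7 signals, 200 grid
points): with λ = 1 the optimized warps stay within 0.01 of the
identity, with λ = 10⁻² they move freely. The exported
`warp_penalty()` reports the interpretable per-signal mean integrated
squared deviation (trapezoid quadrature); the objective weights it by
`n * n_resample`.

Design choices where the formulation was open:

* **Score/penalty combination.** Subtraction of the aggregated penalty
  from the combined correlation, the simplest single-objective form
  consistent with "warping limited by a penalty".
* **Free control-point abscissae.** Both (s_k, h_k) coordinates of each
  interior control point are free; only the exterior anchors are fixed.
  Ordering constraints are enforced by construction: each coordinate set
  is parameterized as normalized cumulative sums of exponentiated free
  parameters, so any parameter vector yields a valid monotone warp and
  the zero vector is exactly the identity.
* **Optimizer.** Bounded quasi-Newton (`optim` L-BFGS-B, forward-difference
  gradients) from the identity start, bounds ±4 on the log-increment
  parameters, tolerance 10⁻⁶ on the objective, at most 500 iterations.
  The objective is smooth, and a derivative-free simplex search scales
  poorly in the 2(m+1)n free parameters (70 for m = 4, n = 7). If the
  optimizer fails to improve on the identity, identity warps are
  returned with a warning, so the reported objective never degrades.

Choosing `m`: registration is unnecessary for monotonic data (`m = 0`,
the default). For non-monotonic data a workable rule of thumb is one
control point per prominent inflection of the characteristic shape —
ignoring small-scale noise-driven inflections — e.g. 4 for a
three-cycle oscillatory trace, 2 for a load-plateau-unload loop. Both
`m` and λ should be reported alongside any published corridors.

## Stage 3: statistics, ellipses, envelope

At each grid point the (x, y) values across the n registered signals are
modelled as uncorrelated normal: sample means give the characteristic
average; sample standard deviations (n − 1 denominator) give the spread.
The level set of the uncorrelated bivariate normal at coverage
probability p is an axis-aligned ellipse centered at the means with
semi-axes √(χ²₂(p))·SD(x) and √(χ²₂(p))·SD(y), where the 2-dof
chi-squared quantile has the closed form χ²₂(p) = −2 ln(1 − p). The
default p = 0.394 makes χ²₂(p) ≈ 1 — the conventional ±1 SD corridor —
but any coverage can be requested.

The response corridor is the envelope of all these ellipses. It is
extracted numerically: the field F(x, y) = min over ellipses of the
normalized quadratic form is sampled on a regular grid over the ellipse
bounding box plus a 5% margin, and the F = 1 iso-contour is traced
(marching squares with linear interpolation of cell crossings, via
`grDevices::contourLines`). Numerical details that matter:

* **Adaptive grid.** `grid_resolution` (default 250 cells per axis) is a
  lower bound; the grid is refined per axis until the median ellipse
  semi-axis spans at least two cells (capped at 4000), since thin
  corridors otherwise fall between grid lines. Each ellipse updates only
  the cells of its own bounding box, so refinement stays cheap.
* **Densification.** The grid supplies a finite sample of a conceptually
  continuous family of ellipses. When the between-signal spread is small
  relative to the spacing of consecutive centers, the sampled union
  disconnects into beads; interpolated ellipses are inserted until each
  step is at most half a semi-axis (measured in each neighbor's own
  semi-axis units, which keeps the rule equivariant under axis
  rescaling). `extract_envelope()` itself is faithful to whatever
  ellipse set it is given; densification happens in `build_corridors()`.
* **Degeneracy.** A zero standard deviation yields a degenerate ellipse
  axis; such ellipses contribute nothing beyond their center to the
  field (no epsilon inflation). If *every* ellipse is degenerate
  (identical input signals) the corridor collapses onto the average,
  returned with a warning. If several closed contours remain (widely
  separated ellipse groups), the largest-area contour is kept with a
  warning.
* **Splitting.** The closed envelope is cut into the two conventional
  corridor polylines at the vertices nearest the average's endpoints,
  and the arcs are labelled by their signed side relative to the
  average's direction of travel (left = outer). All split geometry is
  computed in coordinates normalized by the envelope extent, so the
  result is invariant under rescaling either axis. Where an end ellipse
  is degenerate (all signals share an origin) the average endpoint can
  protrude from the envelope by about one resample step; the enclosure
  check tolerates up to twice the average's mean vertex step (at least
  1% of the extent) and otherwise refuses to split, with a warning.

## Synthetic families and what they do (not) show

`generate_monotonic()`, `generate_oscillatory()`, and
`generate_hysteretic()` emulate the three archetypes of biomechanical
signal shape with known ground truth, for recovery and calibration
tests. Their defaults are fixed study conditions:

* *Monotonic* (12 signals, mirroring a 12-specimen ligament study): a
  smoothstep base y = u²(3 − 2u) — toe, quasi-linear, concave-down
  regions — with ±15% uniform endpoint and stiffness jitter and additive
  y-noise (SD 0.01 on unit amplitude). Endpoints deliberately differ
  across signals.
* *Oscillatory* (7 signals, a typical volunteer cohort): damped sinusoid
  e^(−1.2 t) sin(6πt + φ) on t ∈ [0, 1] with per-signal phase
  φ ~ U(−0.6, 0.6) rad — about ±10% of one oscillation period, a
  moderate inter-subject timing variability that visibly smears the
  unregistered average — plus y-noise.
* *Hysteretic* (8 signals, a typical PMHS series): a parametric
  load-plateau-unload loop (exponential rise with an inflection into a
  gently sloped plateau; unload returning below the loading path to a
  residual displacement), ±10% amplitude jitter, y-noise.

All randomness flows from one seed through a fixed stream order, so a
spec plus seed reproduces identical output. What these families do *not*
emulate: measurement noise with frequency structure, drift, outlier
specimens, or the exact magnitudes of any published dataset — so passing
tests demonstrate the method's statistical and geometric properties, not
agreement with any particular experiment.

The coverage calibration used in the tests builds 50 signals as one base
curve plus independent bivariate Gaussian perturbation (SD 0.02 per
axis) at every sampled point, runs the default pipeline, and measures
the per-grid-point fraction of signal points inside that grid point's
own p = 0.394 ellipse, averaged over the grid. The observed coverage
(≈ 0.42) sits slightly above the nominal p because arc-length
resampling of x-perturbed signals induces a small correlation between
the x and y deviations at a grid point, and a correlated pair is covered
by the axis-aligned ellipse at a slightly higher rate; the uncorrelated
model is exactly the simplification the method accepts.

## A worked example

```{r example, fig.width = 7, fig.height = 4.5, eval = FALSE}
fam <- generate_oscillatory(seed = 101)
res <- build_corridors(fam$signals, m = 4, lambda = 1e-2)
glance(res)
autoplot(res)
```

`glance()` reports the registration objective before and after (the
combined correlation rises as features align), the chi-squared value in
use, and the envelope area; `tidy()` returns the average and both
corridor polylines in long format for custom plotting.

## Limitations

* Arc length is sensitive to high-frequency noise, which inflates a
  signal's path length and skews ŝ; noisy signals should be filtered
  before corridor generation.
* One signal much longer than the rest stretches the common ŝ scale;
  crop only when physically justified.
* The per-point statistical model is uncorrelated normal; rotated
  (correlated) ellipses are out of scope by design.
* `m` and λ remain user choices; the inflection-count rule and
  λ = 10⁻² are good starting points but a parametric sweep is advisable
  for sparsely sampled signals.
* Registration is a local optimization from the identity; severely
  misaligned signals (features shifted by more than roughly half a
  feature width) may need more control points or pre-alignment.
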