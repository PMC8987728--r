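# corridr

Characteristic averages and statistical response corridors for families
of two-dimensional experimental signals.

Biomechanical testing — ligament force-displacement characterization,
volunteer sled-test head kinematics, post-mortem thoracic impact
response — yields sets of signals y₁(x), …, yₙ(x) that must be reduced
to one *characteristic average* curve plus *response corridors*
quantifying the between-specimen spread, against which surrogates
(anthropometric test devices, computational human body models) are
assessed. Point-wise averaging fails when signals are non-monotonic or
hysteretic (no single-valued y(x)) and smears peaks when shared features
are misaligned across specimens. `corridr` implements the arc-length
corridor approach:

1. **Arc-length re-parameterization.** Each signal is scaled per axis by
   the mean range over signals, re-expressed as x(ŝ), y(ŝ) against
   normalized arc length ŝ ∈ [0, 1] (monotone for any curve shape, so
   hysteretic loops need no segmentation), and resampled onto a common
   uniform ŝ grid.
2. **Signal registration** (optional, `m > 0`). Each signal gets a
   monotone cubic Hermite warping function h_i(ŝ) through `m` interior
   control points, anchored at (0,0) and (1,1). All control points are
   optimized jointly to maximize the mean pairwise Pearson correlation
   across signals, (C_x + C_y)/2, minus a penalty λ Σ_{i,j}(h_i(ŝ_j) −
   ŝ_j)² that limits deviation from the identity: λ = 10⁻² aligns
   features freely, λ = 1 effectively disables warping.
3. **Statistics.** At each grid point the n values of x and y are
   summarized by sample means (the characteristic average) and standard
   deviations, giving an axis-aligned confidence ellipse with semi-axes
   √(χ²₂(p))·SD, where χ²₂(p) = −2 ln(1 − p). The corridor is the
   envelope of all ellipses, extracted as the iso-contour of the
   min-of-quadratic-forms field and split into inner/outer polylines.
   The default p = 0.394 reproduces the conventional ±1 SD corridor
   (χ²₂ ≈ 1).

Everything is data-frame in, tibble out: a signal set is a long data
frame with columns `signal`, `x`, `y`, and results come with `tidy()`,
`glance()`, and `autoplot()` methods.

## Worked example

Twelve synthetic concave force-displacement curves (toe / linear /
concave-down regions, variable endpoints — monotone data, so no
registration is needed):

```r
library(corridr)

fam <- generate_monotonic(seed = 1)   # 12 signals + ground-truth base
res <- build_corridors(fam$signals)   # m = 0, p = 0.394, N = 200
res
#> Corridor result
#>   12 signals, 200 grid points, m = 0, lambda = 0.01, p = 0.394
#>   registration objective: 0.998822 -> 0.998822
#>   envelope: 913 vertices, area 0.1363
glance(res)[, c("C_x", "C_y", "chi2_value", "envelope_area")]
#>     C_x    C_y chi2_value envelope_area
#>  0.9991 0.9986      1.002        0.1363
```

The combined correlation is already ≈ 0.999 before registration (as
expected for monotone signals), the chi-squared value ≈ 1 confirms the
±1 SD corridor, and the corridor area reflects the spread injected by
the generator's ±15% stiffness/endpoint jitter. `autoplot(res)` overlays
the input signals, the corridor band, and the average;
`write_corridor_result(res, "out/")` writes `average.csv`,
`inner_corridor.csv`, `outer_corridor.csv`, and a `run_metadata.txt`
recording `m`, `lambda`, `p`, and the seed so corridors are reportable
and reproducible.

For oscillatory data with misaligned peaks, registration matters:

```r
osc <- generate_oscillatory(seed = 101)         # 7 phase-jittered signals
res <- build_corridors(osc$signals, m = 4)      # 4 warp control points
```

On this fixture the combined correlation rises from ≈ 0.87 to ≈ 0.99 and
the average's main peak recovers to ≈ 98% of the mean individual peak
amplitude (≈ 77% without registration).

A thin command-line wrapper is installed at
`inst/scripts/corridr-cli.R`:

```sh
Rscript inst/scripts/corridr-cli.R fixture --family hysteretic --out-dir data
Rscript inst/scripts/corridr-cli.R corridors --input 'data/hyst_*.csv' \
    --out-dir out --m 2 --lambda 0.01
```

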