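---
title: "A repulsive-potential model of microtubule aster positioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A repulsive-potential model of microtubule aster positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 4)
library(asterdyn)
```

## The model

Microtubule asters in cytoplasmic explants of syncytial *Drosophila*
embryos move away from the droplet boundary and away from each other,
settling into regular arrangements: a single aster centers, a pair
partitions the available space, three asters form a near-equilateral
triangle and four a near-square. `asterdyn` implements the effective
agent model behind these observations and the analytics used to quantify
them.

Each aster is a point agent at the focus of a radial microtubule array
whose density falls off exponentially, `rho(r) = exp(-r / lambda)`. The
repulsion an aster exerts — on the boundary or on a neighbouring aster —
follows that density, but is *inhibited at short range*: microtubules
shorter than a slip length `x0` push inefficiently (they buckle or slip
rather than transmit force), captured by the factor
`r^2 / (x0^2 + r^2)`. The force magnitude at separation `r` is therefore

    f(r) = amplitude * r^2 / (x0^2 + r^2) * exp(-r / lambda)

with amplitude `f0 = 0.007` against the boundary and `f1 = 0.005`
between asters (the boundary repulsion is 40% stronger), decay lengths
`lambda = 15` um (boundary) and `lambda_aster = 12` um (pair), and slip
lengths `x0 = 15` um for both. Motion is overdamped: `v = gamma * F`
with mobility `gamma = 1`, integrated by the explicit Euler method at
`dt = 0.1` in arbitrary model time units (the source work never fixes a
mapping from model time to seconds, so neither do we). A noise force of
amplitude `delta_f = 5e-4` acts along a fresh random unit vector per
aster per step, exactly as stated in the source scheme (a
`noise_sqrt_dt` switch enables diffusive scaling instead). The domain is
a disk of radius `R = 40` um by default; boundary interaction uses a
mirror charge at the nearest boundary point.

```{r forces}
p <- aster_params()
d <- seq(0, 60, by = 0.5)
plot(d, force_magnitude("wall", d, p), type = "l",
     xlab = "separation (um)", ylab = "force (model units)")
lines(d, force_magnitude("pair", d, p), lty = 2)
legend("topright", c("aster-boundary", "aster-aster"), lty = 1:2)
```

### The wall force and the mirror image

The source description offers two devices for the boundary interaction:
an explicit force law evaluated at the perpendicular aster–wall
separation `b`, and a mirror charge reflected across the boundary (at
distance `2b`). These are not equivalent, and the package had to decide
which one the published simulations used. The deciding experiment is the
aster pair started 2 um apart at the center of a 40-um explant (the
stated two-aster initialization): with the wall force evaluated at `b`,
the inward centering force on each aster (~4.5e-4 at `b` = 39) crushes
the weak short-range pair repulsion (~7.4e-5 at `d` = 2) and the pair
collapses instead of separating. With the wall force evaluated at the
image distance `2b`, the inward force at the center is ~3.7e-5, the pair
separates, and the steady state lands near the observed equal partition
of space. The image reading also reproduces the published multi-aster
statistics. `wall_distance_mode = "image"` is therefore the default;
`"separation"` remains available for probing the alternative reading.

At the exact disk center the inward direction is undefined and the wall
force is taken to be zero (the continuity limit of the radial field). A
step that would carry an aster out of the disk is clamped 0.5 um inside
along the radial and counted.

The Results of the source work quote slip lengths of 18 um (boundary)
and 25 um (aster–aster) while the Methods use 15 um for both "for
simplicity"; we default to the Methods values and expose both fields
independently (`x0_wall`, `x0_aster`).

## Simulating configurations

```{r sim}
sim <- simulate_asters(data.frame(x = -39, y = 0), seed = 1)
glance(sim)
```

A single aster initialized 1 um from the boundary escapes — slowly at
first, because the slip factor suppresses force generation at short
boundary distances — and migrates toward the center. Multi-aster
ensembles are driven by `simulate_configurations()`, which seeds
initial positions uniformly in the concentric disk of radius `R - 5` um
(avoiding the clamp zone; a boundary-proximal `"ring"` mode is also
available) and pools convex-hull interior angles across runs:

```{r configs}
cfg <- simulate_configurations(3, n_runs = 5, seed = 1)
cfg$mode_deg
```

Three-aster runs concentrate at 60 degrees and four-aster runs at 90
(5-degree bins centered on multiples of 5, so a tight equilateral
cluster reports its mode at exactly 60 rather than splitting between
edge-aligned bins). Four-aster finals are classified `square`
(4-vertex hull, all angles within 15 degrees of 90, side ratio < 1.5),
`Y` (3-vertex hull with one interior aster) or `other`; the tolerance
definitions are our own, as no quantitative definition of a "regular
square" exists in the source.

**Integration budget.** Runs stop at a positional plateau (every aster
displaced less than 0.015 um over the trailing 10^4 steps — separating
slip-zone creep from equilibrium jitter) or at `max_steps = 1e6` steps
(t = 1e5), whichever comes first, and configurations are read at the
last time point. The budget matters scientifically: Y-shaped four-aster
configurations are long-lived saddle-region states that drain into
squares over a few multiples of this horizon. Classifying at t = 1e5
retains the Y minority alongside the square majority, which is the
regime the published counts describe; integrating an order of magnitude
longer converts essentially all runs to squares.

## The one-dimensional models

`simple_steady_states()` solves the analytic force-balance model on a
diameter, where each aster's potential follows its microtubule
distribution, `F(x) = F0 * exp(-x / lambda)`. One aster balances at the
center. For a pair, each aster pushes on the other "as it pushes on a
boundary": the midplane between equal asters acts as a mirror wall, so
the neighbour term is evaluated at the half-separation. The printed
equations of the source evaluate it at the full separation instead,
which would yield the equal partition `2R/3 * {1, 2}` — the
configuration the source explicitly presents as what this
identical-properties model does *not* predict. We follow the printed
solution and the surrounding narrative: the balance lands at
`x1 = R/2`, `x2 = 3R/2` (asters spaced half the diameter) for every
`(F0, lambda, R)`, and the discrepancy between that prediction and the
observed equal partition is precisely the evidence that aster–aster
repulsion is weaker than aster–boundary repulsion.

`simulate_1d_ensemble()` integrates the full slip-inhibited force law on
`[0, 2R]` by Euler–Maruyama: each aster feels its nearest endpoint (the
1D analogue of the single mirror charge; summing both endpoint forces
would let the far wall pin a boundary-proximal aster at the near wall,
because the slip factor crushes the near-wall force), plus pair
repulsion and per-step noise `delta_f * xi`, with reflecting endpoints.
Single asters start 1 um from the boundary, pairs 1 um either side of
the midpoint. The horizon is fixed (2.5e6 steps, t = 2.5e5) so all runs
share one grid; the travel-time analysis behind that choice shows an
aster reaches ~80% of the way to the center within the horizon for
explants up to R = 50 um but not for R = 80 um, which is exactly the
size scaling and saturation the ensemble reproduces:

```{r scaling, eval = FALSE}
position_vs_size_curve(c(20, 30, 40, 50, 80), n_runs = 300, seed = 1)
```

(300 runs per radius complete in a few minutes; reduce `n_runs` for a
quick look.)

## Track, granule and intensity analytics

`separation_series()` pairs two trajectories, computes 3D-aware
Euclidean separation, normalizes by the mean of the last 12 frames (the
source's frame-count convention for "final" values; its "3 s (= 12
frames)" at a 15-s frame interval is internally inconsistent, so the
frame count is adopted and exposed as `tail_frames`), and derives the
central-difference velocity (one-sided and flagged at the ends).
`steady_state_geometry()` reports boundary distances
`b_i = R - |p_i - center|` (projected), the inter-aster distance `d`,
and the maximum projected separation `M = 2R - b1 - b2`.

`align_and_test_perturbation()` time-aligns replicate series to a
perturbation, estimates initial-response slopes by least squares with
confidence intervals, and compares final separations between groups
with a two-sided rank-sum test on pooled tail frames at a significance
level of 0.05 fixed a priori. The source names a signed-rank test for
what are unpaired pools; the rank-sum variant is the statistically
coherent choice for that design, and a `paired` option restores the
signed-rank behaviour for genuinely paired replicates.

`compute_msd()` time-averages squared displacements per track,
ensemble-averages across tracks, and fits `a * t^c` on log–log axes from
the 2nd lag to one third of the shortest usable track (configurable);
the exponent `c` separates diffusive (~1) from directed (>1) motion.
`exclusion_zone_test()` compares nearest-granule distances from the
aster against four random in-explant positions per explant (re-drawn
when they land within a 2-um granule footprint — the footprint radius is
our parameter, the source states none), pooled across explants with a
two-sided Mann–Whitney test. `aster_frame_velocity_field()` expresses
granule motion in a frame moving with the aster and rotated so the
(5-frame-smoothed) aster velocity points along -y.

`radial_profile()` bins intensity by distance from the centrosome in
0.2-um bins (per-bin maximum by default — a radial maximum projection —
normalized to the global maximum; empty bins are missing, not zero), and
`fit_exponential_decay()` fits `A * exp(-r / lambda) + B` excluding the
first two bins (the centrosome), with the background bounded at zero
and initial guesses taken from the 1/e crossing.
`fit_separation_velocity_model()` fits the slip-inhibited velocity law
`v(d) = A * rho(d) * d^2 / (x0^2 + d^2)` either with the density fixed
from a prior fit (two-step) or jointly.

```{r decay}
prof <- gen_radial_profile(seed = 1)
glance(fit_exponential_decay(prof))
```

## Synthetic data: what it does and does not emulate

Every analysis input can be generated with embedded ground truth.
`gen_aster_tracks()` resamples simulator trajectories at a 15-unit
frame interval and adds Gaussian localization noise (default SD 0.2 um,
sub-pixel tracking accuracy at the magnifications involved).
`gen_radial_profile()` produces a centrosome peak (2 bins) on a
mono-exponential decay (default decay length 11.8 um) with background
0.05 and noise SD 0.03 — within the realistic 2–5% range for
line-averaged normalized profiles, and chosen once so that a single
profile constrains the decay length to about ±0.3 um, commensurate with
the published estimate's stated precision. `gen_separation_movie()`
renders line profiles between two simulated separating asters as
superposed exponentials, so the midline intensity obeys the closed form
`2 * exp(-d / (2 * lambda)) + B`.

`gen_granule_tracks()` is an explicit synthetic construction (the source
provides no generative model for granules): fractional Gaussian motion
with Hurst index `c/2` supplies an exact power-law MSD at any target
exponent, an advecting slip-exponential repulsion plus a hard exclusion
core around a moving aster produce the granule-free zone and
counter-streaming. Presets `paper_with_aster` and `paper_no_aster`
target exponents 1.3 and 1.5 respectively, the values fitted to the
one-aster and no-aster granule data in the source. Exponent-recovery
tests run on noise-free tracks: localization noise adds a constant MSD
floor that biases the short-lag slope downward by design, and that
corruption is a separate, documented effect rather than part of the
estimator contract.

Passing tests on these generators show the analytics are correct for
data with the assumed structure (exponential profiles, power-law MSDs,
Gaussian localization error, circular explants). They do not establish
robustness to segmentation artifacts, drift, uneven illumination, or
non-circular explant geometry — real-data features the generators do
not emulate.

## Numerical choices and limitations

* Root finding (`simple_steady_states`) is nested bisection to residual
  forces below 1e-12; nonlinear fits use Levenberg–Marquardt with
  bounded parameters, and non-identifiable fits (flat likelihood,
  background-only profiles) raise errors rather than returning numbers.
* All stochastic entry points take a `seed` and restore the caller's
  RNG state; identical seeds give bit-identical outputs, including
  through the compiled engines, which draw from R's generator.
* The problem sizes used by the test-suite calibrations are 500 null
  replicates for the two type-I checks, 100 synthetic profiles for the
  decay-length recovery, 100 noisy datasets for the slip-length
  recovery, and 300 runs per radius for the 1D size-scaling curve.
* Asters are point agents; there is no filament-level mechanics, no
  hydrodynamic coupling, and no 3D simulation (explants are treated as
  quasi-2D). Granule analytics are track-based, not flow
  reconstructions.
* The classification tolerances for "square" and the steady-state
  plateau thresholds are package choices, logged with each run, and
  results near those boundaries should be read accordingly.
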