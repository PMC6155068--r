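---
title: "Modelling planarian photo-response orientation: binocular inputs, threshold turning and wigwag noise"
author: "wigwag package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling planarian photo-response orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wigwag)
```

## The model and its assumptions

A gliding planarian senses light with two pigment-cup eyes, each rotated by an
obliqueness $\beta$ away from the anterior–posterior axis so that the two
monocular fields overlap on the anterior side in a binocular field
$bf = 2\beta$. The package models the input to each eye as the illuminated
fraction of a semicircular cup. With the light bearing $\theta$ measured from
the anterior axis (degrees, positive to the animal's right):

$$L(\theta) = \max\{0,\, -\sin(\theta - bf/2)\}, \qquad
  R(\theta) = \max\{0,\, \sin(\theta + bf/2)\},$$

both clamped to $[0, 1]$; the clamp is the total-function form of restricting
the bearing range so inputs never go negative. Three assumptions are baked in:

* **Parallel rays.** The physical source sits ~30 cm from a 4-cm arena, so ray
  divergence is below ~8°; the simulator therefore treats $\theta$ as a
  function of heading only, never of position, exactly as the closed-form
  input model requires.
* **180° monocular half-fields.** The sine model implies each eye sees a full
  half-plane. Real morphometric monocular fields are slightly narrower
  (~172.6°); that measured value enters only the morphometric helper
  `posterior_blind_field()` ($2(180 - \alpha + \beta)$) and never the
  simulator.
* **Memoryless decisions.** Each wigwag event is an independent
  sense-and-decide moment; there is no temporal integration of light between
  events, and no learning.

The decision rule is threshold-gated proportional turning. When
$|R - L| \le \tau$ the animal holds its course (plus wigwag noise); when
$|R - L| > \tau$ it turns *away from the brighter side* by
$\mathrm{gain}\cdot(|R - L| - \tau)$. The two above-threshold branches are
implemented symmetrically (the sign is taken from $R - L$), since left/right
behavioral symmetry is the premise of the whole geometry.

Between decisions the animal advances one unit step. The position recursion
advances with the heading *held over the elapsed interval*: at each event the
agent first steps along its current heading, then updates the heading, which
takes effect at the next event. This ordering follows the position update
literally and measurably widens the wigwag-free twin-tail separation (~55–57°
cohort average) relative to the turn-first ordering (~52°), because the
pre-turn segment drags the exit position toward the initial heading — the same
thing a video tracker measuring whole trajectories sees.

Closed forms implemented in `geometry`:

* front blind-like spot half-angle: $\arcsin(\tau) - bf/2$ when the threshold
  crossing falls in the monocular zone ($\arcsin\tau > bf$), else
  $\arcsin\!\big(\tau / (2\cos(bf/2))\big)$ from the binocular-zone identity
  $R - L = 2\cos(bf/2)\sin\theta$;
* response band upper edge: $180 - \arcsin(\tau) - bf/2$;
* maximum attainable difference: $1$ for $bf < 90°$, $\sin(bf)$ beyond. When
  $\tau$ exceeds it, there is no crossing and both functions signal an error.

Every closed form is tested against a 0.01°-grid brute-force scan of the
input difference over a grid of binocular fields and thresholds.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `bf_deg` | 40 (species option: 60) | degrees | binocular field |
| `tau` | 0.5 | input units (max 1) | response threshold |
| `gain` | 3 | dimensionless | proportional turn coefficient |
| `gain_units` | `"radians"` | — | scale of the turn term |
| `wigwag_angle_sd` | 18.7 | degrees | swing SD |
| `wigwag_log_mean` | −0.15 | log-s | interval log-mean |
| `wigwag_log_sd` | 0.44 | — | interval log-SD |
| `arena_radius` | 40 | unit steps / mm | assay arena |
| `max_events` | 400 | events | termination guard |

The turn term is read in radians by default: $3\,(|R-L| - \tau)$ radians gives
turns up to ~86°, commensurate with a wigwag head swing, which is the stated
intent of the coefficient; read in degrees the turns would top out at 1.5° and
the model could not clear its own response band inside the arena. The degree
reading remains available (`gain_units = "degrees"`) so the alternative is
testable rather than silently discarded.

$\tau$ is a free parameter rather than a constant because the two-source
assay discriminates between thresholds (0.5 versus 0.6) — `sim_config`
accepts any $\tau \in (0,1)$.

The interval distribution is parameterized by $(\mu, \sigma)$ on the natural
log scale; `lognormal_moments()` converts to natural-scale mean
$e^{\mu + \sigma^2/2} \approx 0.948$ s and variance. The literature quotes the
event rate variously as one per ~0.7–0.77 s while the fitted log-normal
implies a mean of 0.948 s and median 0.861 s; the package defaults follow the
fitted $(\mu, \sigma)$ and leave the mean interval an explicit argument of
`expected_turnaway_time()`, so either reading is reproducible.

## Wigwag: noise that rescues the blind spot

At $bf = 40°$, $\tau = 0.5$ the front blind-like spot spans ±15.4°, *less*
than one swing SD (18.7°), so a single swing carries the bearing outside the
blind spot with probability $2(1 - \Phi(15/18.7)) \approx 42\%$; with events
every ~0.7 s a head-on animal turns away in $0.7/0.42 \approx 1.7$ s. At
$bf = 0°$ or $80°$ the spot (±30° and ±19°) exceeds the swing SD and the
exceedance drops (11% and 31%), which is the analytic content of the claim
that a 40° binocular field is tuned to the animal's own motor noise.

**Why the binocular-field sweep runs without the wigwag term.** In the
simulated recursion the sub-threshold noise $\xi$ *accumulates* in the
heading, so an agent in the blind spot performs a random walk with step SD
18.7° and diffuses out of even a ±30° spot within a few events regardless of
`bf`; simulated mean escape then declines monotonically with `bf` and no
optimum appears. The optimum — higher mean escape at 40° than at 0° or 80°,
with larger cohort-to-cohort fluctuations outside 40° — emerges from the
wigwag-free base model, where front-blind starters walk straight into the
light (at `bf = 0°` one agent in six starts inside the spot and scores an
escape value near −1: that is the "lottery" behind the large SD). The package
therefore treats the sweep's study condition as the wigwag-free rule
(`sweep_binocular_field()` defaults to `wigwag_enabled = FALSE`), and treats
the wigwag rescue as the per-event exceedance calculus above rather than as
accumulated heading drift. Both noise settings remain available in
`sim_config` for any cohort.

## The simulator

One agent = one substream. The master seed plus an agent counter determine a
32-bit substream seed, so cohorts are reproducible and enlarging a cohort
never reshuffles earlier agents; sweeps give each binocular-field value a
fresh seed block. Agents start at the arena center with uniform random
headings and run until they cross the arena edge (radius 40 steps; one step
corresponds to roughly speed × mean interval ≈ 0.8–1 mm) or hit the
`max_events` guard, which flags rather than errors.

Perturbation models mirror the two classical eye manipulations:
anaesthetizing an eye scales its input by a gain in $[0,1]$; removing an
eyecup deletes the pigment shield, modelled as $|\sin(\cdot)|$ — the eye
responds from both sides. With two sources (the two-source assay, which
removes the posterior blind field and produces bow-tie escape plots), per-eye
inputs are summed across sources and then clamped to 1; summation is the
minimal linear combination rule, and the clamp point is recorded in the
config so the alternative (no clamp) is a one-line change.

## Analytics and numerical choices

* **Exit bearings** are measured from the final *position* relative to the
  start (light direction mapped to 0°, clockwise, away = 180°), matching what
  a tracking camera sees; headings are not used for this statistic.
* **Escape value** is net displacement projected on the light-propagation
  axis divided by total path length; for unit-step trajectories this equals
  the per-event displacement away from the light, and the same definition
  applies unchanged to mm-scale tracking tables.
* **Twin-tail grouping** splits at 180° with the boundary value assigned to
  the right group (a measure-zero choice); an empty group raises an error and
  callers fall back to circular-SD reporting.
* **Circular statistics**: $\bar R = 1$ is flagged as infinite precision,
  $\bar R = 0$ as precision 0; the guard thresholds are $10^{-12}$ from the
  exact values.
* **Per-cohort averaging** of orientation uses the circular mean (the
  arithmetic-versus-circular choice is not dictated by the statistic's
  definition; circular is the defensible one for angles and is stated here as
  an assumption).
* **Wigwag extraction** classifies heading increments above a deadband by
  sign; each sign reversal is a turning event, and only complete
  inter-reversal segments yield (angle, interval) pairs — so a constant or
  monotone heading ramp yields no events by construction. The deadband
  (default 1°) suppresses tracking jitter at the cost of censoring genuine
  sub-deadband swings: a fraction $\approx 2\varphi(0)\,\delta/\sigma$ (~4%
  at $\delta = 1°$, $\sigma = 18.7°$) of swings is dropped and their
  neighbours merge, inflating the fitted SD by several percent. On noise-free
  synthetic tracks the appropriate deadband is small (the tests use 0.1°,
  where the recovery bias is negligible); on real video data the deadband
  should sit at the tracker's jitter floor.
* **Turn-angle regression** is ordinary least squares of turn magnitude on
  light-angle magnitude (the trend is treated as linear), reported as $r^2$
  on all pairs and on the sub-130° subset.

## The synthetic tracking generator

`generate_tracking()` emulates a video-tracking export: 30 Hz frames, mm
coordinates, gliding at 1.0 mm/s, heading piecewise constant between wigwag
events, event times from the fitted log-normal clock and swing magnitudes
from $|\mathcal N(0, 18.7^2)|$ with *alternating* direction. Alternation
reflects the oscillatory character of head sway (out, then back) and keeps
the marginal swing distribution exactly $\mathcal N(0, 18.7^2)$, which the
test suite verifies by a Kolmogorov–Smirnov check on the generator's
ground-truth swings (attached to the table as an attribute) and by a full
generate → extract → fit round trip recovering the SD, the interval
$(\mu, \sigma)$ and the speed. An optional phototaxis mode runs the turning
rule on top of the sway, and `generate_turn_dataset()` produces the
scatter-plot analogue: model turns plus measurement noise inside the response
band, uniform turns outside it.

What the generator does **not** emulate — and therefore what passing tests do
not establish about real data: tracking jitter and pixel quantization, body
deformation (head versus centroid positions), wall-following after edge
contact, variable gliding speed, and any temporal integration of flashed
light. Event times are quantized to the frame grid on output, which biases
log-interval recovery by well under the test tolerances at 30 Hz.

## Problem sizes

The test suite and acceptance script use desk-scale sizes chosen to keep
Monte-Carlo error well inside the assertion bands: 10⁴ draws for parameter
recovery (3-SE bands), 10⁶ draws for the exceedance oracle, 40-agent cohorts
(the published cohort size) replicated 15–40 times for the twin-tail
separation (cohort-level SD ~6.4°, so the replicate average carries a
standard error near 1°), and 400-agent cohorts per binocular-field value for
the escape sweep with 80 replicate cohorts for the fluctuation comparison.

## Known limitations

* The escape-value optimum is demonstrated as an *ordering* across
  binocular fields, not as absolute published escape values, which were read
  from a figure.
* The per-event exceedance calculus and the accumulating simulation noise are
  two views of wigwag that do not coincide inside the blind spot (see above);
  the package makes the choice explicit instead of hiding it.
* Real-animal statistics (measured twin-tail angles, regression $r^2$,
  morphometric field angles) depend on laboratory data; the package
  demonstrates the corresponding computations on synthetic fixtures only.
* Wall interactions and flashing-light protocols are out of scope.
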