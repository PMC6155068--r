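# wigwag

Planarians glide away from light. They do it imperfectly and stereotypically:
escape trajectories split into two "twin tails" that straddle the straight-away
direction, and an animal lit exactly head-on cannot tell left from right until
a spontaneous sideways sway of its head — its *wigwag* self-motion — breaks the
symmetry. `wigwag` is an R package that models and analyses this behavior for
researchers in computational ethology and invertebrate sensory biology: it
implements the binocular input model, the threshold-gated turning rule, the
stochastic wigwag process, an arena simulator, and the trajectory statistics
used to quantify photo-response orientation.

## The model

Each pigment-cup eye is rotated by an obliqueness β away from the body axis,
so the two 180° monocular fields overlap anteriorly in a *binocular field*
bf = 2β. With the light bearing θ measured from the anterior axis (positive to
the animal's right) the eye inputs are clamped sines, with maximum input 1:

    L(θ) = max(0, −sin(θ − bf/2)),   R(θ) = max(0, sin(θ + bf/2))

A turn is triggered only when the subtractive signal |R − L| exceeds a response
threshold τ (default 0.5). The heading φ then changes by the proportional term
`gain · (|R − L| − τ)` (gain 3, read in radians) directed away from the
brighter side, plus a wigwag perturbation ξ ~ Normal(0, 18.7°²); between turns
the animal glides straight, one unit step per wigwag event, with inter-event
times log-normal (log-mean −0.15, log-SD 0.44 s). This geometry produces:

* a **front blind-like spot** — the anterior sector where |R − L| ≤ τ — of
  half-angle ≈ 15° at bf = 40°,
* a **response band** of bearings that trigger avoidance, ending at 130°,
* a **posterior blind field** behind the animal (morphometrically
  2(180 − α + β) for measured monocular field α),
* and the analytic rescue of head-on approaches: the probability that one
  wigwag swing exceeds the blind spot, 2(1 − Φ(z/σ)) ≈ 42%, so an animal
  facing the light escapes in about `interval / p` ≈ 1.6–1.7 s.

The statistics side provides the circular mean resultant length R̄ and the
precision index 1/√(−2 ln R̄), escape values (net displacement along the light
axis per unit path length), twin-tail separation (difference of left- and
right-group median exit bearings split at 180°), 90° rose binning, turn-angle
regression, wigwag event extraction from heading series, and maximum-likelihood
fits of the swing and interval distributions. A synthetic tracking-data
generator emulates video-tracking exports (mm, s, 30 Hz) so every analysis
routine is testable without laboratory data.

## Worked example

```r
library(wigwag)
geom <- eye_geometry(40)                       # D. japonica binocular field

abs(input_difference(130, geom))               # input difference at 130 deg
#> [1] 0.5
front_blind_half_angle(geom, tau = 0.5)        # front blind-like spot
#> [1] 15.42902
response_band(geom, tau = 0.5)
#>     lower     upper
#>  15.42902 130.00000

exceedance_probability(15, 18.7)               # swing beats the blind spot
#> [1] 0.4224725
expected_turnaway_time(0.4224725, 0.7)         # head-on escape time, seconds
#> [1] 1.65699

cfg <- sim_config(bf_deg = 40, wigwag_enabled = FALSE, n_agents = 40, seed = 1)
per <- summarize_cohort(run_cohort(cfg))
twin_tail_separation(per$exit_bearing)
#> Twin-tail separation 58.9 deg (left median 150.2, n = 16; right median 209.1, n = 24)
circular_summary(per$exit_bearing)
#> Circular summary (n = 40): mean 185.8 deg, R = 0.6812, precision index 1.141

sweep_binocular_field(c(0, 40, 80), n = 400,
                      config = sim_config(wigwag_enabled = FALSE, seed = 1))
#>   bf_deg   n mean_escape sd_escape
#> 1      0 400       0.598     0.738
#> 2     40 400       0.679     0.541
#> 3     80 400       0.510     0.551
```

Reading the output: at a 130° light bearing the two eyes differ by exactly the
response threshold, so 130° is the outer edge of the avoidance band; the inner
edge (±15.4°) is the front blind-like spot. Without wigwag noise a 40-agent
cohort splits into two escape tails ~59° apart. The sweep shows the escape
value peaking at a 40° binocular field: narrower fields leave a wide front
blind spot through which agents walk straight into the light (hence the large
SD at bf = 0), wider fields blur the left–right contrast and broaden the
posterior blind field.

The command-line wrapper exposes the same pipeline
(`simulate`, `sweep`, `analyze`, `fixtures`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "wigwag.R", package = "wigwag"))') \
    simulate --config inst/extdata/oa1l.yaml --out out/
```

## Package layout

* `R/geometry.R` — closed-form optics of the two-eye input model
* `R/behavior.R` — turning rule, wigwag distributions, exceedance calculus
* `R/simulator.R` — event-driven arena simulation, perturbations, sweeps
* `R/analytics.R` — circular and trajectory statistics, wigwag extraction, MLE
* `R/synthetic.R` — synthetic video-tracking and turn-dataset generators
* `R/io.R`, `R/cli.R`, `inst/cli/wigwag.R` — TSV/config I/O and commands
* `vignettes/phototaxis-model.Rmd` — the methods vignette
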