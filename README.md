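# shoalspect

Do fish in bigger shoals cooperate less? The volunteer's dilemma says they
should: when one volunteer's predator inspection informs the whole group,
the mixed evolutionarily stable strategy gives each individual a smaller
volunteering probability in larger groups — and even makes it less likely
that *anyone* inspects. `shoalspect` is an analysis pipeline for testing
that prediction in guppies confronted with a predator model in a
1.5 m × 1.5 m arena, built for tracking data (per-frame x, y positions per
fish) from trials of 5-, 10- and 20-fish groups.

The pipeline covers, end to end:

- **Trajectory quality control** — tracker-CSV ingest, exclusion of
  impossible tracks (speed > 50 cm/s or jumps > 50 cm between retained
  detections), and labelling of the two 7-minute analysis phases around
  the screen lift that reveals the predator model.
- **Behavioural scoring** — inspection events (maximal runs of visible
  frames within 30 cm of any part of the predator polygon), the five
  per-fish inspection metrics, refuge use from tracking visibility, and
  merged multi-fish "group inspections".
- **Cohesion** — per-second median Voronoi density (cells clipped to the
  arena) and chain-rule sub-group sizes (density clustering at 6 cm
  reachability, minPts 2), aggregated to a 14-minute series per trial.
- **Bayesian inference** — Poisson / Beta / Gamma GLMMs with trial random
  intercepts (Gibbs sampling via JAGS), Savage–Dickey Bayes factors with
  Jeffreys-style verbal strength, 89% highest density intervals and
  back-transformed marginal effects for every group-size contrast, an
  optional Gaussian-process smooth over minutes for the cohesion series,
  and a Poisson GLM of inspectors per inspection.
- **Game theory** — mixed-ESS solutions of the volunteer's dilemma and its
  shared-cost, group-size-dependent-cost and synergy variants, with
  analytic payoffs verified against exhaustive enumeration.
- **Ground-truthed synthetic data** — a trajectory generator emulating the
  study design whose scheduled inspections and refuge bouts are recovered
  *exactly* by the metric pipeline, and a GLMM generative twin used for
  simulation-based calibration.

At its core the baseline game solves, for group size *n*, cost *c* and
benefit *b* (0 < c < b), the indifference condition
`b − c = b·(1 − (1−p)^(n−1))`, giving `1 − p = (c/b)^(1/(n−1))` and
`P(good) = 1 − (1−p)^n`; the Savage–Dickey Bayes factor for a contrast β
is `prior(β = 0) / posterior(β = 0)`.

## Worked example

The theory the experiment tests, in four lines:

```r
library(shoalspect)
predict_group_size_curve("baseline", cost = 0.3, benefit = 1, n_range = c(5, 10, 20))
#>       n p_volunteer p_good
#> 1     5      0.2599  0.778
#> 2    10      0.1252  0.738
#> 3    20      0.0614  0.718
```

Per-individual volunteering falls four-fold from 5-fish to 20-fish groups,
and the chance anyone inspects falls from 0.78 to 0.72 — the "group size
paradox" the experiment probes. The synergy variant shows when it can
reverse: with accelerating returns to joint inspection
(`synergy_slope = 0.06, synergy_power = 2`, c/b = 0.9) the solved
volunteering probabilities are p(5) = 0.028 but p(20) = 1.000.

A full synthetic experiment through the measurement-and-inference pipeline
(1-minute phases to keep it quick; `trial_scenario()` defaults are the
15-trial study design):

```r
arena <- arena_config(phase_duration_s = 60)
sim  <- generate_trajectories(trial_scenario(arena = arena), seed = 11)
traj <- filter_tracks(sim$trajectories, arena)
traj <- label_phases(traj, setNames(sim$meta$screen_lift_frame, sim$meta$trial_id), arena)
behav <- behavior_table(traj, sim$meta, arena)
tapply(behav$n_inspections, behav$group_size, mean)
#>    5   10   20
#> 0.92 0.80 1.52

fits <- analyze_behavior(behav, mcmc = list(chains = 2, iter = 1500, seed = 2))
summarize_all_models(fits)   # one row per contrast, e.g.:
#> refuge  intermediate → large  during  BF 1e+06 (extreme, in favour)
#>         89% HDI [-0.214, -0.131]  marginal effect -0.173

gi <- group_inspections(detect_inspections(traj, arena))
fit_inspectors_glm(gi, sim$meta)[, c("level", "estimate", "mean_inspectors")]
#>   level        estimate mean_inspectors
#> 1 small           0.302            1.35
#> 2 intermediate    0.393            1.48
#> 3 large           1.62             5.07
```

Large synthetic groups inspect most, intermediate groups use refuges most,
and inspecting parties grow with group size — the qualitative pattern the
generator's defaults emulate. The Bayes factor line reads: extreme
evidence that large groups spent less time in refuges than intermediate
groups while the predator was visible (17 percentage points, 89% HDI 13–21).

## The analysis, step by step

Numbered drivers under `analysis/` run the whole study on synthetic data
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # 15 trials, 25 fps, two 7-min phases -> scratch/tracks
Rscript analysis/02_metrics.R       # behaviour, group inspections, cohesion series
Rscript analysis/03_inference.R     # six GLMMs, GP time-series models, inspectors GLM
Rscript analysis/04_vd_theory.R     # ESS curves for baseline + variants
Rscript analysis/05_calibration.R   # HDI coverage per family
```

The methods vignette
(`vignettes/predator-inspection-groupsize.Rmd`) documents the models,
priors, numerical choices and the generator's design, including what
passing on synthetic data does and does not show about real fish. To refit
the deposited tracking data of the original study, unpack it as
`meta.csv` + `tracks/<trial>.csv` and call `refit_deposited(dir)`.

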