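# camobreak

Disruptive colouration defeats visual search not only by creating false
edges, but by making different patches of a target group perceptually
with *different background objects*. The classic way to test this is a
two-alternative search task: human observers view a bi-coloured striped
display carrying illusory two-tone foreground squares (a colour-reversal
illusion) and must report whether a small, barely-visible circular
target is on the left or right half of the screen. The target sits
either on a homogeneous tone (`Dark`, `Light`) or on a tone boundary
with *identical local contrast* but different object structure:
within the background stripes (`Stripe`), inside a square (`Square`),
or on the border between a square and its background (`Border`).

`camobreak` implements the full life cycle of such an experiment as a
tested, reproducible pipeline:

* **Stimulus generation** — 1024 x 768 px displays with 8 stripes
  (boundaries jittered N(0, 16 px) around a 128 px grid, midline fixed),
  24 colour-reversed squares (4 per non-midline boundary), and a 16 px
  target exactly 10% lighter than its local background, placed under
  the five treatment rules (`build_scene()`, `render_scene()`,
  `write_scene()` for PNG/PGM + JSON ground truth).
* **Session design** — randomised within-subject 2 (square size) x 5
  (treatment) factorial: 4 blocks of 50 trials (5 replicates per cell
  per block), preceded by 10 flagged practice trials
  (`build_session()`).
* **Synthetic observer** — per-cell log-normal detection times with
  subject random intercepts, right-censoring at the 15 s time-out,
  rounding to 10 ms, and treatment-dependent wrong-side error
  probabilities on the logit scale (`simulate_experiment()`,
  `preset_effect_profiles()`).
* **Censored estimation** — per subject x treatment x size cell, the
  mean detection time is estimated by maximum likelihood under a
  right-censored log-normal model,
  mean = exp(mu + sigma^2 / 2)
  (`fit_censored_lognormal()`, `estimate_cells()`); treating time-outs
  as 15 s observations would bias the mean downwards.
* **Inference** — the cell means (normal error) and error counts
  (binomial, logit link) are modelled with square size, treatment and
  their interaction as fixed effects and a per-subject random
  intercept, fitted by ML with lme4. Terms are tested by the change in
  deviance against a chi-square; each treatment is compared with the
  a priori `Border` reference by unadjusted simple contrasts; all 10
  pairs get Tukey-type single-step adjusted comparisons (multcomp);
  the pairwise table is condensed into an ordering string such as
  `Border>(Square = Stripe)>(Dark = Light)`; and a classical
  repeated-measures ANOVA (arc-sine-square-root transformed
  proportions) cross-checks the conclusions (`analyse_trials()`,
  `run_experiment()`).

## Worked example

```r
library(camobreak)
run <- run_experiment("chromatic_like", n_subjects = 25, seed = 3)
print(run)
```

```
Camouflage search experiment run
  profile chromatic_like | 25 subjects x 200 main trials | seed 3
  5000 main trials, 0.24% censored (time-outs)

  Detection time (censored-corrected means):
    interaction  X2 =    1.00, df = 4, p = 0.9097
    treatment    X2 =  377.40, df = 4, p = 2.119e-80
    square_size  X2 =    0.54, df = 1, p = 0.4644
    ordering:  Border>(Square = Stripe)>(Dark = Light)

  Wrong-side errors (binomial, logit link):
    interaction  X2 =    0.90, df = 4, p = 0.9243
    treatment    X2 =  257.68, df = 4, p = 1.438e-54
    square_size  X2 =    6.24, df = 1, p = 0.01252
    ordering:  Border>(Stripe = Square)>(Dark = Light)
```

Each `X2` line is a likelihood-ratio (deviance) test between nested ML
fits; `df` is the fixed-parameter difference (4 for the five-level
treatment factor). The ordering strings group treatments whose
Tukey-adjusted pairwise differences are non-significant at alpha = 0.05
and sort groups by estimated mean: here targets on square-background
borders took longest to find and drew the most errors, boundary targets
within a single object were intermediate, and monotone targets were
easiest — the planted chromatic-like pattern, recovered end to end from
raw simulated trials. `summary(run)` adds the contrast tables and the
ANOVA cross-check; `plot(run)` draws cell means with standard errors.

Individual stages are exposed too:

```r
sc <- build_scene("Border", "large", seed = 7)   # one display
write_scene(sc, "scene.png")                      # raster + JSON truth
plan <- build_session("S01", master_seed = 11)    # 10 + 200 trials
cells <- estimate_cells(run$trials)               # censored-corrected means
```

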