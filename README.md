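# sentsync

Affective synchrony and sentiment trajectories in online health
communities.

## What it is for

Peer-to-peer health forums (chronic-pain communities especially) are places
where the emotional tone of what a user writes may entrain to the tone of
what they reply to, and where a user's overall tone may drift over months
of participation. `sentsync` measures both from interaction records — one
record per comment, pairing the comment text with the text of the parent it
replied to, with a timestamp and feedback score — and ships a synthetic
community generator with known coupling, phase lag, noise and trend so the
whole pipeline is testable without any platform data.

The core machinery:

* **Dual-lexicon sentiment scoring.** Each text is scored by a rule-based
  valence scorer (graded token valences, negation flip with damping,
  booster increments, `s / sqrt(s^2 + 15)` normalization to [-1, 1]) and a
  positive/negative word-ratio scorer; the analysis variable is the mean of
  the two z-scored outputs, standardized over the whole analyzed corpus.
* **Bivariate wavelet synchrony.** Series are percentile-transformed, then
  analyzed with a Morlet (&omega;<sub>0</sub> = 6) continuous wavelet
  transform. The cross-wavelet transform `W^XY = W^X conj(W^Y)` yields
  *common power* `|W^XY|` (matched intensity) and *relative phase*
  `arg W^XY` (0&deg; = in-phase, 180&deg; = antiphase); smoothing and
  normalizing gives *wavelet coherence* `R^2` in [0, 1], a correlation
  localized in time and frequency. Common power is tested pointwise against
  the product of the two theoretical AR(1) red-noise spectra (exact
  `z K_1(z)` tail; critical constant 3.999 at 5%), coherence against Monte
  Carlo critical values from simulated AR(1) pairs. Per-user statistics are
  the fractions of significant points inside the cone of influence —
  overall and within low (20–32 interactions), medium (10–20) and high
  (<10) frequency bands — plus the circular mean relative phase.
* **Shuffled baselines and group tests.** The identical pipeline runs on
  permuted data; paired t tests (with d<sub>av</sub> and d<sub>z</sub>
  effect sizes), repeated-measures band ANOVA, and Pearson-vs-wavelet
  correlation analyses summarize the cohort.
* **Growth-curve modelling.** Each user's sentiment is collapsed to 100
  proportional interaction windows and modelled with
  `sentiment ~ window * common_power * days_active + health_pct +
  word_count + (1 | user)`, all variables z-scored, reporting standardized
  betas, variance components, ICC and marginal/conditional R².

See the vignette (`vignettes/sentiment-synchrony.Rmd`) for the full
methodological account.

## Worked example

Simulate a small coupled community, push it through text generation,
ingestion, scoring, wavelet synchrony with shuffled baselines, and the
growth model:

```r
library(sentsync)
cfg <- pipeline_config(seed = 42, n_users = 8, nsim = 100)
cfg$sim <- sim_config(n_users = 8, n_interactions_range = c(150, 300),
                      seed = 42)
report <- run_pipeline(cfg)
print(report)
```

```
sentsync run report (config 1844467640)
  users analyzed: 8   interactions: 2119 (excluded: 86, retention 96.10%)
  scorer agreement: alpha = 0.93, r = 0.88
  common power:  real 0.1031 vs shuffled 0.0505  (t(7) = 7.37, p = 0.00015, d_av = 4.67)
  coherence:     real 0.1393 vs shuffled 0.0564  (t(7) = 4.99, p = 0.0016, d_av = 2.46)
  mean RP angle: -4.1 deg
  band ANOVA (common power): F(2, 14) = 5000.15, p = 1e-20
  growth model:
Mixed-effects growth-curve fit
  users: 8   observations: 800
                            term   beta ci_low ci_high       p
                     (Intercept)  0.017 -0.069   0.104 7.0e-01
                          window -0.183 -0.266  -0.100 1.8e-05
                    ...
  sigma2 = 0.984  tau00 = 0.000  ICC = 0.000
  marginal R2 = 0.027  conditional R2 = 0.027
```

Reading it: the community was generated with coupling 0.6 at a 24-
interaction oscillation and a slow negative trend. The real common-power
and coherence fractions sit well above their shuffled baselines (users
really are entrained to their peers); the mean relative phase near 0&deg;
says the coupling is in-phase; the band ANOVA reflects synchrony
concentrated in the low-frequency band where it was injected; and the
standardized window slope of the growth model is negative, recovering the
generated downward sentiment drift. The two scorers agree strongly
(alpha = 0.93, r = 0.88), which is what justifies averaging them into one
compound score.

Per-user metrics live in `report$metrics`; `interaction_surface(report$growth)`
evaluates the model-implied sentiment slope across the synchrony × tenure
moderator grid.

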