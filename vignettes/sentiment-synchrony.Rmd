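---
title: "Measuring affective synchrony and sentiment trajectories in online health communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring affective synchrony and sentiment trajectories in online health communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Members of peer-to-peer health forums react to one another. When a user
replies to a post, the emotional tone of their comment may drift toward the
tone of the material they are replying to — *affective synchrony* — and over
months of participation their overall tone may trend up or down. `sentsync`
quantifies both phenomena from interaction records: one record per comment,
pairing the comment text with the text of the parent it replied to, plus a
timestamp and a feedback score.

Two analysis questions structure the package. First, does a user's comment
sentiment co-fluctuate with the sentiment of the content they interact with,
beyond what chance alignment of two noisy series would produce? Second, how
does a user's sentiment evolve across their tenure, and is that trajectory
moderated by how synchronous they are with the community and how long they
stay?

## Pipeline overview

The stages, each an exported function group:

1. **Ingestion** (`read_interactions()`, `filter_comments()`,
   `select_eligible_users()`): JSON-Lines records are grouped per user and
   sorted chronologically. Deleted content (a removal flag or sentinel body
   such as `"[removed]"`), records with missing text, and comments under 3
   words are excluded, each with exactly one logged reason code. Word counts
   use whitespace tokenization after stripping URLs and non-ASCII symbols,
   because the short-comment rule exists precisely to drop bare links and
   emoji. Users need at least 100 retained interactions — the length below
   which the low-frequency part of the wavelet analysis becomes unreliable —
   counted *after* exclusions.

2. **Sentiment scoring** (`lexicon_score()`, `ratio_score()`,
   `compound_score()`): every comment and parent text is scored by two
   pluggable lexicon scorers. Scorer A applies graded token valences with
   contextual rules — a negator in the three preceding tokens flips the
   valence and damps it by 0.74; boosters add ±0.293 attenuated with
   distance — and compresses the sum to $[-1, 1]$ via $s/\sqrt{s^2+15}$.
   Scorer B is a positive/negative word-ratio on a −100..100 tone-like
   scale. The analysis variable is the *compound score*: the mean of the two
   z-scored outputs, standardized over all retained comments of all analyzed
   users (not per user), so that trajectories remain comparable across
   users. `scorer_agreement()` reports Cronbach's alpha of the two-item
   scale and the Pearson correlation, the usual justification for
   aggregating two scorers.

3. **Wavelet synchrony** (`morlet_cwt()`, `xwt()`, `wtc()`,
   `analyze_pair()`): each user's self series and peer series are first
   mapped to empirical percentiles (`percentile_transform()`, average ranks
   for ties), which tames sentiment spikes while preserving rank order.
   Both series are then transformed with a Morlet continuous wavelet
   ($\omega_0 = 6$) on a dyadic scale grid. The cross-wavelet transform
   $W^{XY} = W^X \overline{W^Y}$ gives *common power* $|W^{XY}|$ (matched
   intensity) and *relative phase* $\arg W^{XY}$ (lead–lag structure); the
   smoothed, normalized version gives *wavelet coherence*
   $R^2 \in [0,1]$, a correlation localized in time and frequency.
   Significance of common power is tested pointwise against the product of
   the two theoretical AR(1) red-noise spectra; the exact null tail of the
   normalized statistic is $z K_1(z)$, giving the familiar 3.999 critical
   constant at the 5% level. Coherence significance uses Monte Carlo
   critical values from simulated independent AR(1) pairs (2000
   initializations in production runs). Per-user summaries count the
   fraction of significant points among points inside the cone of
   influence, overall and within three period bands: low (20–32
   interactions, closed), medium (10–20, right-open), high (<10).

4. **Shuffled baseline and group tests** (`shuffled_baseline()`,
   `paired_synchrony_test()`, `band_anova()`, `correlate_metrics()`): the
   identical pipeline is rerun on permuted data, and per-user real vs
   shuffled fractions are compared by a paired two-tailed t test with both
   Cohen's d conventions ($d_{av}$, using the average of the two SDs, and
   $d_z$, using the SD of the differences — reported side by side because
   the two conventions are both common and not interchangeable). Band
   differences use a one-way repeated-measures ANOVA with the conventional
   $(k-1, (k-1)(n-1))$ degrees of freedom, followed by pairwise paired t
   tests; construct validity is probed by correlating the wavelet metrics
   with per-user Pearson correlations of the raw paired series.

5. **Trajectory modelling** (`window_transform()`, `fit_growth_model()`):
   each user's compound-sentiment series is collapsed to 100 proportional
   interaction windows (window 1 = first 1% of their activity), and windowed
   sentiment is modelled with a mixed-effects growth curve: window index as
   the fixed growth term, per-user random intercepts, and common power,
   days active, mean word count and mean health-word percentage as
   covariates, with the window × common-power × days-active moderation
   structure. All continuous variables are z-scored across the analysis
   table so coefficients are standardized betas. The fit reports variance
   components, the intraclass correlation $\tau_{00}/(\tau_{00}+\sigma^2)$,
   and marginal/conditional $R^2$ under the standard variance-partition
   definition for random-intercept models.

## The synthetic community generator

No public corpus of this kind can be redistributed — interaction records
from health forums are withheld for privacy — so the package ships a
generator (`simulate_community()`, `simulate_pair()`, `simulate_text()`)
whose parameters are the ground truth every test recovers.

Each user's *peer* stream is an AR(1) background plus a unit sinusoid at the
configured oscillation period. The *self* stream mixes a phase-shifted copy
of that oscillation (weight = `coupling`) with an independent AR(1)
background, a linear tenure trend, and white observation noise. Design
choices worth stating:

* **One exogenous peer stream per user.** Real peers are many distinct
  authors, but the analysis treats "peer sentiment" as a single interleaved
  series, so a single generating process is the faithful emulation.
* **Phase lag applies only to the oscillatory component**, not the AR(1)
  noise, so the relative-phase ground truth at the oscillation period is
  exactly the configured lag and recovery can be asserted quantitatively.
* **Per-user seeds** derive deterministically from the master seed and user
  index (`derive_seed()`), so a community is reproducible user by user.
* **Defaults.** 199 users; series lengths uniform on 100–600 (bracketing a
  few hundred interactions per user while keeping desk-scale runtime);
  coupling 0.6; phase lag 0 (in-phase coupling, the empirically typical
  regime for supportive interactions); oscillation period 24 interactions,
  placing the injected synchrony inside the low-frequency analysis band;
  AR(1) coefficient 0.3 and innovation SD 1 (mildly persistent,
  unit-scale noise); trend −0.002 sentiment units per 1% of activity (a
  slow negative drift, small relative to noise); tenure uniform on 10–400
  days. Empirical spectra of real sentiment series are not well
  characterized in the literature, so the oscillation period is chosen to
  populate the analysis bands rather than to match any platform's data.
* **Text generation.** `simulate_text()` draws tokens from the bundled
  valence lexicon so the expected lexicon score is monotone in the target
  valence; latent sentiment maps to text valence through
  $\tanh(x/1.5)$. The corpus writer interleaves a small fraction of
  removed and under-length records so the ingestion filters are exercised,
  and its bookkeeping is the oracle for conservation tests.

What the generator does *not* emulate: reply-tree topology, multiple
distinct peer authors, nonstationary activity bursts, vocabulary drift, or
any platform-specific artifact. Green tests therefore demonstrate that the
estimators recover known structure of this generating family — not that any
particular real community carries that structure.

## Numerical choices

* **Wavelet grid**: $s_0 = 2\,dt$, $dj = 1/12$, largest period $\ge n/2$;
  $dt$ is one interaction (event index), not clock time, because the
  analysis frequencies are defined in interaction counts.
* **FFT padding**: series are zero-padded to the next power of two at least
  twice the length, so the implied convolution is linear; the
  FFT path agrees with direct time-domain convolution to $10^{-8}$
  relative error on test fixtures.
* **Cone of influence**: e-folding time $\sqrt 2\,s$; all summary fractions
  count only points whose period is below the local cone.
* **Coherence smoothing**: Gaussian in time with width equal to the scale,
  boxcar across scales with the standard 0.6-octave decorrelation width for
  Morlet wavelets; both passes renormalize by the smoothed window mass so a
  constant field passes through unchanged and self-coherence is exactly 1.
* **Percentile ties** use average ranks — deterministic and invariant under
  permutation of equal values.
* **AR(1) estimation** is the lag-1 autocorrelation clipped to ±0.99, so
  strongly trending series degrade gracefully instead of producing an
  infinite red-noise spectrum.
* **Windowing remainders**: when a series length is not divisible by 100,
  the earliest windows take the extra observations — deterministic,
  order-preserving, and exactly mean-conserving under segment-size weights.
* **Shuffling strategy**: the default permutes only the self series,
  which destroys alignment while preserving both marginal distributions;
  permuting both is available as an option (`strategy = "both"`).
* **Tenure regressor**: "days active" is computed both as span (last minus
  first day) and as count of distinct active days; span is the default
  regressor, distinct-day counts are carried alongside.
* **Eligibility threshold and minimum series length** are separate
  parameters that default to the same value (100), since both derive from
  the same wavelet-reliability argument but need not be coupled.

## Problem sizes

The shipped test-suite and the reproduction script run at desk scale by
design: Monte Carlo coherence nulls use 200 initializations (2000 is the
production default, available via `pipeline_config(paper_scale = TRUE)`),
null-calibration and operating-characteristic checks use 200 simulated
seeds or cohorts at series lengths 128–512, and growth-model recovery uses
200 replicate fits at 199 users × 100 windows. The end-to-end
reproduction script analyzes a 20-user simulated community through the
full text pipeline.

## Known limitations

* The bundled lexicons are compact general-purpose lists; they demonstrate
  the scoring machinery and suffice for synthetic text, but production
  analyses of real corpora should plug in a full-coverage lexicon via
  `read_lexicon()`. Scorer B deliberately does not claim equivalence to
  any proprietary dictionary's summary variables.
* Significance of wavelet points is pointwise; no area-wise (cluster)
  correction is applied, so the per-user *fractions* of significant points
  should be compared between conditions (real vs shuffled) rather than
  interpreted as calibrated error rates for individual regions.
* The growth model fits random intercepts only — no random slopes,
  autocorrelated residuals, or nonlinear growth terms.
* Repeated-measures ANOVA reports conventional error degrees of freedom;
  sphericity is not corrected.
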