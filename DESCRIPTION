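Package: sentsync
Title: Affective Synchrony and Sentiment Trajectories in Online Health
    Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies affective synchrony between social-media users and
    the peers they interact with in online health communities, and models
    long-run trajectories of comment sentiment.  Provides lexicon-based
    sentiment scoring with two pluggable valence scorers combined into a
    standardized compound score; from-scratch Morlet continuous-wavelet
    machinery (cross-wavelet transform, wavelet coherence, AR(1) red-noise
    and Monte Carlo significance, cone of influence); per-user synchrony
    statistics (common-power and coherence fractions, circular relative
    phase) tested against shuffled baselines; frequency-band comparisons;
    and mixed-effects growth-curve models of proportionally windowed
    sentiment.  A synthetic community generator with known coupling, phase
    lag, noise and trend makes every stage testable without platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
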