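Package: cogmark
Title: Behavioural Markers of Rational Thinking from Multimodal Movement Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives behavioural markers of rational-thinking propensity from
    multimodal (eye, hand, head) movement recordings collected during an
    ambiguous odd-one-out task. Implements the full analysis pipeline:
    confidence/range gaze filtering, head-angle re-ranging, resampling and
    alignment of the three modalities; total-velocity distributions on shared
    Freedman-Diaconis bins; saccade detection by velocity, peak-acceleration
    and path-distance thresholds; 8x8 cross-channel coordination (Pearson
    correlation) matrices; earth mover's distances between velocity CDFs and
    affine-invariant Riemannian distances between coordination matrices;
    classical multidimensional scaling of the resulting distance matrices;
    and constrained stepwise selection with Tukey-bisquare robust regression
    against a scalar trait score. A synthetic-cohort generator with planted
    trait-behaviour effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
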