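---
title: "Movement-based markers of rational thinking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-based markers of rational thinking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmark)
```

# The analysis in one paragraph

`cogmark` asks whether a scalar trait score (a rational-thinking
questionnaire total on a 0–100 scale) is associated with how people move
while solving an ambiguous two-round odd-one-out task. Three modalities —
gaze (x, y plus tracker confidence), hand (x, y, z) and head rotation
(rx, ry, rz in degrees) — are cleaned, resampled and aligned; each
recording is then summarised two ways: by the distribution of its total
speed and by its 8×8 cross-channel correlation ("coordination") matrix.
Distances between recordings (earth mover's distance between speed CDFs;
affine-invariant Riemannian distance between correlation matrices) are
embedded with classical MDS, and a constrained stepwise search asks
whether a single embedding coordinate predicts the trait. Direct
per-participant features (mean speeds, saccade rate, decision-change
ratio, decision times, between-round coordination stability) are tested
the same way with bisquare robust regression.

# Preprocessing model and assumptions

- **Gaze filtering.** Samples are kept iff confidence ≥ 0.6 *and* both
  coordinates lie in the normalized world frame [0, 1]. The boundary is
  kept (removal is strictly below threshold). Removed samples become gaps;
  nothing is imputed before the resampling policy sees the gap.
- **Head re-ranging.** Device angles arrive on [0, 360); they are mapped
  to [−180, 180) by subtracting 360 from values ≥ 180, i.e. 359° → −1°
  and 180° → −180° (half-open convention; only the range, not the
  boundary, is dictated by the device geometry).
- **Hand trimming.** The first and last 2 s are discarded: hand trackers
  are unreliable while hands enter/leave the sensing volume.
- **Resampling.** Linear interpolation onto uniform grids — 60 Hz for
  gaze, 10 Hz for hand and head. Grid points inside a raw gap longer than
  `max_gap = 0.5` s are flagged invalid rather than trusted. Angles are
  unwrapped onto the real line (shortest-arc steps), interpolated, and
  re-wrapped, so interpolation never sweeps through the ±180° seam. Linear
  interpolation is the simplest scheme that preserves the low-frequency
  content this analysis uses; a band-limited-signal property test checks
  that resampling changes mean speed by < 5 %.
- **Shared correlation grid.** The 8-channel series for correlation
  analysis is co-resampled at 10 Hz, the coarsest analysis rate: taking
  gaze down to 10 Hz avoids manufacturing hand/head samples that were
  never measured. The joint validity mask is the AND of the per-modality
  masks.
- **Exclusions.** A participant enters a modality's analyses only with
  ≥ 60 s of valid samples in that modality (counted as valid samples ÷
  rate), and enters at all only with a questionnaire completion time
  ≥ 62 min. Retention is bookkept per modality *and* jointly, because
  missing intervals need not align across modalities.

# Kinematic features

Speeds use central finite differences (one-sided at the ends); head
angular speed differences are taken on the circle. A speed sample
adjacent to any invalid input sample is invalid. Histogram bin widths
follow Freedman–Diaconis, `h = 2·IQR·n^(−1/3)`, on the speeds pooled over
*all* recordings of a modality, so every recording of a modality shares
identical edges — a prerequisite for comparing distributions. Quartiles
use the midpoint (Hazen) convention, `quantile(type = 5)`, which makes
the widths bit-reproducible and matches the convention of the numerical
environment standard in this field. Zero-IQR input falls back to a
Scott-like width `3.49·sd·n^(−1/3)` and records the fallback.

**Saccade detection.** Candidate events are maximal runs of speed above a
velocity threshold (runs separated by a single sample merge); a candidate
is kept iff its peak acceleration (first difference of speed) exceeds
90 a.u./s² and its path distance exceeds 0.005 a.u. The velocity
threshold itself is **a reconstruction**: no authoritative value is
available, so it is exposed as required configuration with default
1.5 a.u./s, chosen so that simulated fixational drift (≈ 0.05 a.u./s) is
far below threshold while single-frame saccadic jumps (≥ 3 a.u./s at
60 Hz for an 0.1 a.u. jump) are far above. Note that with the default
thresholds at 60 Hz the velocity gate implies a displacement ≥ 0.05 a.u.,
so the distance gate binds only under looser velocity settings; tests
exercise it explicitly with a lowered velocity threshold.

# Distances

**EMD.** For 1-D distributions the minimal-transport cost equals
`∫ |CDF1 − CDF2| dz`. Histogram CDFs are piecewise linear between bin
edges; `emd()` evaluates both CDFs on the union of the edge sets and
integrates the absolute difference exactly, resolving sign changes inside
a segment analytically rather than by quadrature. `emd_samples()` applies
the same closed form to step CDFs of weighted samples, where the integral
reduces to `Σ |ΔCDF|·gap` and is exactly the optimal transport cost; the
test suite verifies this against an independently coded monotone-coupling
transport oracle at 1e-10.

**Riemannian distance.** `RD(C1, C2) = sqrt(Σ log² λ_n)` with `λ_n` the
eigenvalues of `C1⁻¹C2` — the standard affine-invariant metric on SPD
matrices. The square root is taken (a squared variant sits behind
`squared = TRUE`), consistent with the metric's use in the SPD-geometry
literature. Correlation matrices are shrunk toward the identity,
`(1 − ε)C + εI` with ε = 1e-6, which guarantees positive definiteness at
a perturbation far below estimation noise; ε is configurable and recorded
on the object.

# Embedding and association

Classical (Torgerson) MDS: double-centre `−D²/2`, eigendecompose, keep
up to 10 dimensions with positive eigenvalues. EMD and RD matrices need
not be Euclidean-embeddable; negative-eigenvalue mass is truncated and
reported. Coordinate signs are fixed by requiring the largest-magnitude
loading of each dimension to be positive, making embeddings deterministic
across runs and platforms.

**Stepwise selection** adds the best absent coordinate when its partial
F-test p ≤ 0.05, removes the worst present one when p ≥ 0.10, never
removes the constant, and stops at a fixed point. Two readings of
"selects coordinate k" exist: *k entered the final stepwise model*, and
the stricter *k is the only surviving coordinate*. The procedure reports
both (`in_model` and `selected`); the strict single-survivor rule is the
acceptance gate for reported models, because with ten screened
coordinates a second spurious term enters a noise-free model with
probability ≈ 1 − 0.95⁹ ≈ 0.37, so recovery statements about a planted
coordinate are meaningful only under the "entered the model" reading.

**Robust regression.** `MASS::rlm` with Tukey bisquare, tuning constant
4.685 (the conventional 95 %-efficiency value). R² is computed from the
final robust weights (`1 − SSE_w/SST_w` with the weighted mean). The
p-value against the constant model uses the squared Wald statistic of the
slope over its robust standard error, referred to F(1, n−2): a
Monte-Carlo check showed that an F test built from weighted residual sums
of squares is anticonservative (≈ 9–13 % at nominal 5 %), because the
weights are chosen from the same data, while the Wald form calibrates to
5.1 % at n = 32. Pearson ρ is reported on raw pairs, robust R² alongside.

**Rank-sum.** Decision-time comparisons delegate to
`stats::wilcox.test`: exact enumeration for small tie-free samples, and
the tie-corrected normal approximation otherwise. This differs
cosmetically from a fixed n ≤ 20 exactness cut-off but agrees exactly on
small samples (the enumeration example in the tests reproduces p = 0.1)
and is the behaviour R users expect.

No multiple-testing correction is applied across the nine direct
features; the run manifest says so explicitly and consumers see raw
p-values.

# The synthetic cohort generator

The generator is the package's study-conditions document: its defaults
*are* the simulated experiment.

- **Latent drive.** A single renewal process of "target switches"
  (interval 0.4 s + Exp(1.1 s), i.e. ≈ 0.67 switches/s) with independent
  uniform coordinates drives all modalities: gaze fixates the target and
  jumps near-instantaneously; hand follows a mixed target through two
  cascaded 0.22 s low-pass stages (smooth reach-like segments); head
  angles follow a heavier 0.7 s low-pass with amplitudes of ±25°/15°/8°
  (turn/nod/tilt) reported on the 0–360° convention. A per-participant
  coupling κ mixes the shared target with modality-own switching
  processes; κ controls the off-diagonal mass of the downstream
  coordination matrix (κ = 0 yields mean |off-diagonal| ≈ 0.10 at 120 s,
  driven by the effective degrees of freedom of smooth series).
- **Gaze imperfections.** Confidence is drawn in [0.75, 1] at baseline;
  low-confidence gap events (2/min, mean 0.8 s) drop confidence below
  0.6, half of them also pushing coordinates out of frame; 2 % of
  isolated samples are additionally degraded. Hand tracking drops out
  1/min for 0.4 s (timestamp gaps). All rates are configurable; setting
  them to zero yields an all-valid record.
- **Trial logs.** Round 1 has 12 trials, round 2 has 13; each trial
  offers a change opportunity independently with probability 1/2;
  decision changes are Bernoulli with the participant's per-round
  probability. Decision times are log-normal (positive, right-skewed)
  with medians 6.8 s / 8.2 s for rounds 1/2 and person-level lognormal
  variation (sdlog 0.2 between persons, 0.35 between trials).
- **Trait effects.** Trait scores are Normal(50, 15) clipped to [0, 100].
  Each effect slope shifts the log of a participant parameter per trait
  z-score (logit scale for the change probability), with lognormal
  individual noise (sd 0.25). Between-round coordination stability is
  planted as a trait-scaled magnitude of the coupling change with random
  direction, pointed away from the nearer coupling bound so that the
  planted magnitude is never truncated.
- **Effect magnitudes.** Defaults are |slope| = 0.6 (1.0 on the change
  logit), which produce end-to-end trait–feature correlations around
  |ρ| ≈ 0.6–0.9 at n = 32 — deliberately clear planted effects, chosen so
  that sign-recovery tests have decisive power at cohort sizes of a few
  dozen. Observed effects in real cohorts of this kind are weaker
  (|ρ| ≈ 0.35–0.55), so passing recovery tests demonstrates that the
  pipeline detects effects of the planted size, not that it would detect
  arbitrarily small real ones.
- **Seeding.** One master integer seed; every cohort draw, participant
  substream, recording and log derives its own 31-bit substream seed by a
  fixed modular-arithmetic hash of (seed, stage label, indices), so any
  piece can be regenerated independently and results are bit-identical
  across runs.

**What the generator does not emulate:** saccadic main-sequence dynamics
(amplitude–velocity relation), smooth pursuit, stimulus-layout-specific
gaze (trials are exchangeable within a round), eye-tracker calibration
drift, and any rendering of actual task content. Tests passing on this
generator therefore validate the *pipeline's* statistics (calibration,
recovery, metric properties), not ecological realism of the simulated
movement.

# Problem sizes and runtime choices

The shipped tests use cohorts of n = 32 (20 planted replicates, 60 null
replicates at the same size), 120 s recordings per round, 100-replicate
stepwise-recovery batches and 400-replicate null-selection batches; the
acceptance script runs one n = 32 cohort plus the numerical self-checks.
These sizes give each statistical assertion decisive power (binomial
bands are computed, not guessed) while keeping a full run on one CPU in
the minutes range.

# Known limitations

- The robust R² definition (weighted SSE ratio) is one of several in use;
  values are comparable within this package, not across software.
- The stepwise procedure's null selection rate over ten screened
  coordinates is ≈ 0.4 (measured in the tests); the single-survivor
  acceptance rule mitigates but does not remove selection effects, and no
  cross-validation is attempted.
- EMD between *histogram* representations inherits binning error; the
  self-check in the acceptance script quantifies it (relative error
  ≈ 0.4 % at 5 000 samples) but it is not zero.
- With heavy missingness the 10 Hz joint grid can fall below 60 s of
  valid samples even when each modality individually passes, so the
  correlation-matrix analyses can have smaller n than the per-modality
  ones — mirrored in the exclusion report.
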