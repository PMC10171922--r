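# cogmark

Behavioural markers of rational-thinking propensity from multimodal
movement recordings.

## What this is for

When people solve an ambiguous odd-one-out task in augmented reality, their
eye, hand and head movements carry information beyond their explicit
choices. `cogmark` implements an analysis pipeline that turns raw
multimodal recordings — gaze position with tracker confidence, 3-D hand
position, head rotation angles — plus per-trial decision logs into
candidate behavioural markers of a scalar rational-thinking trait score
(0–100), and quantifies the trait–behaviour associations. Because raw
human recordings of this kind are rarely shareable, the package ships a
first-class synthetic-cohort generator with planted, signed
trait–behaviour effects, so every stage of the pipeline is testable end to
end and its power and calibration can be measured by parameter recovery.

## The method

For each participant and task round the pipeline computes two
representations of movement:

1. **Total-velocity distributions.** Speeds
   `v_tot = sqrt(v_x^2 + v_y^2 + v_z^2)` (2-D form for gaze; angular
   differences on the circle for head rotation) are histogrammed on bin
   edges shared across all recordings of a modality, chosen by the
   Freedman–Diaconis rule `h = 2·IQR·n^(-1/3)` on the pooled speeds.
   Distributions are compared with the 1-D earth mover's distance via its
   closed form, `EMD = ∫ |CDF1(z) − CDF2(z)| dz`.
2. **Coordination matrices.** The 8×8 Pearson correlation matrix across
   the aligned channels (hand x, y, z; gaze x, y; head rx, ry, rz),
   compared with the affine-invariant Riemannian metric
   `RD(C1, C2) = sqrt(Σ log² λ_n)`, where `λ_n` are the eigenvalues of
   `C1⁻¹C2`.

Each pairwise distance matrix is embedded by classical (Torgerson) MDS,
and a constrained stepwise regression (add at p ≤ 0.05, remove at
p ≥ 0.10, first 10 coordinates, accepted only when exactly one coordinate
survives) searches for a single MDS coordinate associated with the trait
score. Reported effect sizes use Tukey-bisquare robust regression
(tuning constant 4.685): robust R² and the p-value of the F statistic
against the constant model. Direct associations (mean speeds, saccade
rate, decision-change ratio, decision times, between-round RD) are
reported alongside as Pearson ρ with robust R²/p. Decision-time
differences between rounds use the Wilcoxon–Mann–Whitney rank-sum test.

Saccades are detected from 60 Hz gaze by a velocity threshold
(configurable; default 1.5 a.u./s) with peak-acceleration (> 90 a.u./s²)
and path-distance (> 0.005 a.u.) gates.

## Worked example

```r
library(cogmark)
cfg <- run_config(spec = cohort_spec(n_participants = 16, seed = 42))
res <- run_pipeline(cfg)
subset(res$direct_associations, round == 2 | is.na(round))
```

```
            feature  n    rho r_squared p_value round
      ratio_changed 16 -0.777    0.6436 4.8e-04     2
    mean_time_first 16 -0.078    0.0047 8.2e-01     2
   mean_time_second 16 -0.101    0.0112 7.2e-01     2
         total_time 16 -0.064    0.0032 8.5e-01     2
 mean_head_velocity 16 -0.925    0.8645 6.5e-07     2
 mean_hand_velocity 16 -0.903    0.8271 3.6e-06     2
 mean_gaze_velocity 16  0.930    0.8745 4.3e-07     2
       saccade_rate 16  0.851    0.7393 4.2e-05     2
  rd_between_rounds 16 -0.689    0.5137 4.0e-03    NA
```

The default `cohort_spec()` plants signed trait effects — slower hand and
head movement, faster gaze with more saccades, fewer decision changes and
more stable between-round coordination at higher trait scores — and the
table shows the pipeline recovering every planted sign with small
p-values, while the unplanted decision-time features stay null. The
`res$mds_associations` table gives the stepwise/MDS route (selected
coordinate, robust R², p per representation and round), and
`res$round_time_comparison` the rank-sum comparison of first-decision
times between rounds:

```r
str(res$round_time_comparison)
#> $ median_round1: num 7
#> $ median_round2: num 8.05
#> $ p_value      : num 0.0036
```

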