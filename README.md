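# attendr

Attention recognition from facial-landmark geometry, for researchers
studying visual attention in children with autism spectrum disorder (ASD)
and typically developing (TD) comparison groups.

During a continuous performance task (CPT) — press a clicker when the
target letter appears in a virtual classroom — a face tracker emits 34
facial landmarks per video frame as (x, y) coordinates in millimetres.
attendr turns those streams into attention/inattention labels and
classifiers:

1. **Annotation.** Each 1400 ms letter slot is labeled from behaviour and
   response correctness: attention iff the child was looking at the screen
   *and* responded correctly; frames inherit their slot's label.
2. **Geometric features.** Every valid frame becomes the vector of all
   pairwise landmark distances
   `d(a,b) = sqrt((x_b − x_a)² + (y_b − y_a)²)` — 561 features — then
   z-scored with training-set moments, `Z = (x − m)/s`.
3. **Distance-threshold selection.** For each pair,
   `gf = mean_inattention(d) − mean_attention(d)`; pairs are ranked by `gf`
   descending and the top k (default 20) kept. When the head turns away,
   distances from the camera-near jaw to midface features grow by tens of
   millimetres — those pairs carry the signal.
4. **Classifiers.** An RBF-kernel SVM (defaults C = 11, γ = 0.1, with a
   seeded cross-validated grid search over C ∈ 1..26,
   γ ∈ {0.001, 0.01, 0.1, 1, 10}), and a small CNN over 32×32 binary
   landmark rasters (conv 32 → pool → conv 64 → pool → dense 62 → dense 1;
   161,789 parameters), implemented in-package and verified against
   numerical gradients.
5. **Evaluation.** Participant-specific (repeated 80/20 frame splits),
   leave-one-participant-out (LOPO), and bidirectional within/cross-group
   protocols, with accuracy, rank-based AUC, F1 and confusion matrices.
6. **Synthetic cohorts.** A landmark-stream simulator (3D head template,
   state-dependent yaw, orthographic projection, slot-level Markov chain,
   matching CPT event logs) with analytic ground truth, so every stage is
   testable without human video.

## Worked example

```r
library(attendr)

cfg     <- synthetic_config(n_per_group = 2, frames_per_participant = 660, seed = 42)
cohort  <- generate_cohort(cfg)          # 4 participants, ASD + TD
samples <- cohort_samples(cohort)        # slot labels propagated to frames
features <- cohort_features(cohort)      # 561 distance features per frame

table(features$label)
#>   attention inattention
#>        2102         481

threshold_table(features) |> head(3)
#>   feature description                         inattention_mean_mm attention_mean_mm gf_mm
#> 1 f_4_12  left top jaw - nose tip                            102.              67.2  35.1
#> 2 f_3_12  left jaw angle - nose tip                           85.1             55.6  29.5
#> 3 f_4_14  left top jaw - nose bottom boundary                 98.0             70.8  27.1

fit_attention_model(features, model = "svm", k = 20)
#> <attention_model: RBF-SVM> 20 selected features, C = 11, gamma = 0.1
#>   trained on 2583 rows (train ACC 1.000)

leave_one_participant_out(features, seed = 1)$summary
#>     acc   auc    f1     n
#> 1     1     1     1     4
```

The threshold table reads: averaged over inattention frames the left-top-jaw
to nose-tip distance is ~35 mm longer than over attention frames — the head
turned sideways rotates that depth into the image plane — so that pair ranks
first for the classifier. With only mild simulated heterogeneity
(participant offsets of 1.5 mm, shared gaze direction), a model trained on
three participants transfers perfectly to the fourth; raise
`participant_offset_sd` and lower `yaw_side_prob` and LOPO accuracy falls
while participant-specific accuracy stays near ceiling.

`landmark_mae(samples[samples$participant_id == "A01", ])` gives the
tracking-distortion check (mean absolute change of the jaw-to-jaw distance
across consecutive attention frames): `0.86` mm here, i.e. sub-millimetre
jitter.

A command-line front end over the same functions lives at
`inst/scripts/attention-tool.R` (`simulate`, `train`, `evaluate`
subcommands).

## Package layout

- `R/schema.R`, `R/session.R` — 34-landmark schema, pair indexing, CSV I/O
- `R/annotation.R` — slot construction and labeling rules
- `R/features.R` — distances, standardization, distortion MAE
- `R/selection.R` — class means, thresholds, top-k selection
- `R/svm.R`, `R/cnn.R`, `R/raster.R`, `R/model.R` — classifiers
- `R/evaluate.R` — metrics and the three evaluation regimes
- `R/synthetic.R` — cohort simulator and analytic ground truth
- `vignettes/attendr-methods.Rmd` — the full methods account
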