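---
title: "Methods: geometric attention recognition from facial landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric attention recognition from facial landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(attendr)
```

## The problem

Children with autism spectrum disorder (ASD) are easily drawn away from a
learning task, and assessing their attention usually means a person watching
video afterwards. attendr implements an automated alternative: recognising
attention versus inattention from the stream of 34 facial landmarks that
consumer face-tracking SDKs emit per video frame, collected while a child
performs a continuous performance task (CPT) — press a clicker when the
target letter X appears on a virtual classroom board. The package covers the
full pipeline: slot-level labeling from response correctness, pairwise
distance features, a distance-threshold feature selection, an RBF-SVM and a
small CNN classifier, and three evaluation protocols that probe how far such
models generalise across children. A synthetic landmark simulator with full
ground truth makes every stage testable without human video data.

## Data model and annotation

A *session* is one participant's recording: frames at 16 Hz, each carrying a
frame index, timestamp, validity flag and 34 coordinate pairs in millimetres.
Frames whose tracking confidence was too low arrive with missing
coordinates; they are marked invalid and excluded from every downstream
computation — no imputation, mirroring how tracking SDKs simply drop
low-confidence frames.

Letter presentations last 1400 ms. Each presentation defines a *slot*; the
slot's frames are those with timestamps in `[onset, onset + 1400)`,
truncated to `floor(1400 * 16 / 1000) = 22` frames so adjacent slots never
share a frame (1400 ms is not a whole number of 62.5 ms frame periods; we
floor rather than alternate 22/23-frame slots, and spans are half-open on
the right). A slot is labeled **attention** exactly when the participant was
looking at the screen *and* responded correctly (clicked on the target, or
withheld on a non-target); looking away or responding incorrectly gives
**inattention**. The full 8-row truth table is documented in
`?label_slot`. Correct rejections count as attention — inattention is tied
to incorrect responses or averted gaze, not to the absence of a click.
Frames inherit their slot's label; invalid frames and frames outside all
slots are labeled `invalid`, so attention + inattention + invalid always
equals the frame count.

## Geometric features

Each valid frame is reduced to the Euclidean distances between all pairs of
landmarks,

$$d(a, b) = \sqrt{(x_b - x_a)^2 + (y_b - y_a)^2},$$

giving `choose(34, 2) = 561` features per frame, indexed canonically by the
lexicographic rank of the pair. (Some sources describe this pool as 560
features; 561 is combinatorially forced, and `pair_table(drop_pair =)`
exists for strict replication against a 560-feature convention.) Distances
are translation-invariant, so the features carry head pose and facial
configuration but not face position in the image.

Features are z-scored, $Z = (x - m)/s$, with $m$ and $s$ estimated on
training rows only and reused verbatim on test rows. We use the population
standard deviation (divide by $n$); the choice is configurable and
immaterial at the frame counts involved, but it is stated because the
convention is often left implicit. Features constant on the training data
are dropped (the transform is undefined at $s = 0$) and recorded on the
returned object.

As a tracking-quality check, `landmark_mae()` reports the mean absolute
change of one sentinel distance — right top jaw to left top jaw, the pair
most sensitive to pose distortion — across consecutive valid frames of the
same class. Pairing is broken by invalid frames and label changes. A static
recording gives exactly 0; on the default simulator settings values land
around a millimetre, reflecting the configured coordinate noise.

## Distance-threshold feature selection

For each pair, the *distance threshold* is the difference of class means:

$$gf = \bar d_{\text{inattention}} - \bar d_{\text{attention}}.$$

The table is sorted by $gf$ descending and the top $k$ pairs (explored in
multiples of 10; $k = 20$ is the default operating point) feed the SVM. Two
readings of the per-class mean exist: mean landmark *coordinates* per class,
or mean per-frame *distances*. The pipeline uses mean distances — that is
the quantity the thresholds must be comparable to — while
`class_mean_face()` provides the mean-coordinate "mean-intensity face" for
visualisation. By default frames are pooled across training participants;
selection always runs inside the training fold of whatever evaluation
regime is active, so no test information reaches it. Ties (exactly equal
$gf$) break towards the smaller feature id, which makes selection
deterministic and the 10/20/30 menus nested. An absolute-value ranking mode
(`abs_mode = TRUE`) is available; the default is signed, since reference
threshold tables report uniformly positive values.

## Classifiers

**RBF-SVM.** A Gaussian radial-basis-function SVM on the selected,
standardized features, with `C = 11` and `gamma = 0.1` as defaults — the
values a 10-fold cross-validated grid search over integer `C` in 1..26 and
`gamma` in {0.001, 0.01, 0.1, 1, 10} selects on CPT-style data.
`grid_search()` reruns that search: folds are seeded and stratified by
class (a participant-blocked variant can be had by splitting manually), the
objective is mean CV accuracy, and ties break towards smaller `C`, then
smaller `gamma`. No class weighting is applied; imbalance is addressed at
the metric level (AUC, F1). Decision values are reoriented after fitting so
that a larger score always means attention, independent of libsvm's
class-order quirk.

**CNN.** Valid frames are rendered as 32×32 binary images (white landmark
dots on black) and classified by a fixed small network: two valid 3×3
convolutions of 32 and 64 maps, each followed by 2×2 max-pooling, then
dense layers of 62 and 1 units with ReLU hidden activations, a sigmoid
output and 20% dropout before the output stage — 161,789 trainable
parameters. The network is implemented in the package itself with exact
im2col convolutions and verified against numerical gradients; evaluation
mode is deterministic and batch-invariant.

Rasterization choices that matter: by default the normalization box is the
frame's own landmark bounding box with a 1-pixel margin, which makes the
image invariant to translation and uniform scale — the CNN then sees facial
*configuration* only. A shared global box (`bounds =`) preserves absolute
pose across frames and changes what the network can learn; this is a real
modeling decision, not a detail, and both modes are exposed. Dot size is
one pixel; coincident landmarks share a pixel.

Training specifics were chosen once and documented rather than tuned:
adaptive-moment optimizer, learning rate 1e-3, batch 32, 30 epochs, binary
cross-entropy, 10% stratified validation split, He initialisation, inverted
dropout. All are configurable through `cnn_config()`; the seed fixes
initialisation, shuffling and dropout, so training is reproducible
bit-for-bit on a given platform.

## Evaluation protocols

`metric_suite()` reports accuracy, rank-based AUC (Mann–Whitney with ties
counted one half — equal to the $O(n^2)$ pairwise comparison, which the
tests verify directly) and F1. The F1 positive class is attention, the
majority class in CPT data; this is configurable, and stated because a bare
F1 value is ambiguous otherwise. Confusion matrices are laid out truth ×
prediction with attention first.

Three regimes, all refitting selection and standardization inside each
training fold:

* **Participant-specific** — repeated stratified 80/20 frame splits within
  each participant (10 repetitions by default), averaged over repetitions
  and then participants. Participants lacking a class are excluded with a
  warning.
* **Leave-one-participant-out (LOPO)** — one fold per participant, trained
  on everyone else. When a held-out participant lacks one class, ACC/F1 are
  kept and AUC is flagged `NA` and excluded from the AUC average.
* **Within/cross-group** — each group's *participants* are split 80/20
  (participant-level, so nobody straddles train and test), a model per
  group is trained, and all four train×test cells are scored; repeated 50
  times by default with means and SDs per cell.

## The synthetic generator

The simulator emulates the statistical structure the method assumes — not
faces. A 3D template (34 points, child-scaled: ~130 mm wide, ~100 mm of
jaw-to-nose depth) is perturbed per participant (`participant_offset_sd`,
default 1.5 mm), rotated per frame and projected orthographically.
Attention frames face the screen (yaw ~ N(0°, 3°)); inattention frames look
toward a screen corner (yaw magnitude ~ N(25°, 5°), direction fixed per
participant, with all participants sharing the corner by default —
`yaw_side_prob` lowers that). Pitch jitter (2°), coordinate noise (0.5 mm)
and a 2% invalid-frame rate complete the rendering. A two-state Markov
chain switches the latent state per slot (stay-attention 0.9,
return-to-attention 0.6), giving a stationary inattention share of
0.1/0.7 ≈ 14% — the kind of imbalance CPT data shows. Event logs are
generated *from* the latent state so that the annotation rules reproduce it
exactly; the generator and the annotation module therefore test each other.

The depth of the template is what plants the recoverable signal: under yaw,
orthographic projection rotates the hidden jaw-to-midface depth into the
image plane, so distances from the camera-near jaw to midface and far-side
features *grow* by tens of millimetres while the mirrored pairs on the
turned-away side *shrink* comparably. `planted_discriminative_pairs()`
computes these shifts in closed form from the template and the two mean
poses. Because growth and shrinkage are mirror images, a magnitude ranking
of planted shifts and a signed ranking of empirical thresholds can never
coincide for a symmetric face; recovery is therefore assessed
mode-consistently — signed empirical ranking against signed analytic
ranking, and magnitude against magnitude (via `select_top_k`'s absolute
mode). Both recover at least 15 of the planted top-20 pairs on the default
cohort, and typically 18–20.

Raising `participant_offset_sd` (and mixing yaw sides) is the
heterogeneity knob: participant-specific accuracy stays near ceiling while
LOPO accuracy falls, monotonically widening the specific-vs-generalized gap
— the qualitative signature of heterogeneous attentional behaviour that
motivates participant-specific modeling in ASD cohorts.

What the simulator does **not** model: facial expression and action-unit
dynamics, blinks and occlusions, perspective effects, tracking drift, or
any appearance information. Passing tests on synthetic cohorts show the
pipeline recovers planted geometry and ordering properties under the
method's own assumptions; they do not certify performance on real
children's video.

## Numerical choices and degenerate inputs

* Slots floor to 22 frames at defaults; events outside the session window
  raise a coverage error; overlapping assigned spans are rejected.
* Population SD in standardization; constant training features dropped with
  a warning; applying parameters to mismatched columns is a schema error.
* Selection and grid-search ties break deterministically (smaller id /
  smaller `C` / smaller `gamma`).
* Single-class inputs raise class-coverage errors at fit time; single-class
  *test* truth yields `NA` AUC with a warning rather than an error.
* Rasterization clips to the 32×32 grid and rejects degenerate
  (zero-width) bounds and missing coordinates.
* CNN sigmoid outputs are clamped to [1e-12, 1−1e-12] inside the loss;
  scores compare batch-vs-single within 1e-6.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to exercise
every claim on a single CPU in minutes: the default synthetic cohort
(8 + 8 participants, ~3,000 frames each, ~47,000 usable frames) for
threshold recovery; a 6-participant heterogeneous cohort (660 frames each)
for the specific-vs-LOPO gap and group transfer; a 2-participant cohort for
the CNN regime and 300/100 planted half-plane rasters for CNN learnability;
SVM kernel problems are capped at 5,000 training rows by stratified
subsampling where the pooled cohort would exceed that.

## Known limitations

The 560-vs-561 pair-count discrepancy in some references is resolved in
favour of the combinatorial count. Landmark index/name conventions differ
across sources; the schema fixes one printed index→name map and treats
textual pair descriptions as annotations only. The CNN trains on CPU-scale
problems only — no GPU path, augmentation or architecture search — and the
simulator's orthographic camera slightly understates the asymmetry a
perspective camera would give between the approaching and receding sides of
the face.
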