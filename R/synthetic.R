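#' Canonical 3D face template
#'
#' A 34-landmark frontal face in millimetres, anthropometrically plausible for
#' a school-age child: ~130 mm wide at the upper jaw, ~95 mm brow-to-chin,
#' with ~100 mm of depth between the jaw line (posterior) and the nose tip
#' (anterior). The x axis points to the subject's left, y up, z toward the
#' camera; the eye line sits near y = 0. Cross-face pair distances fall in the
#' tens-to-130 mm range typical of mm-calibrated landmark trackers.
#'
#' Depth matters: under head yaw, orthographic projection rotates the hidden
#' z-extent of jaw-to-midface pairs into the image plane, which is what makes
#' those pair distances grow when the head turns — the signal the
#' distance-threshold selection hunts for.
#'
#' @return A 34x3 matrix (columns `x`, `y`, `z`), rows in schema order.
#' @export
face_template_3d <- function() {
  m <- rbind(
    c(-65,  -5, -60), c(-52, -45, -45), c(  0, -75, -10), c( 52, -45, -45),
    c( 65,  -5, -60), c(-45,  15, -10), c(-30,  20,  -2), c(-14,  17,   0),
    c( 14,  17,   0), c( 30,  20,  -2), c( 45,  15, -10), c(  0,   8,   5),
    c(  0, -22,  40), c(-16, -28,  15), c(  0, -32,  22), c( 16, -28,  15),
    c(-42,   0, -15), c(-16,   0,  -5), c( 16,   0,  -5), c( 42,   0, -15),
    c(-26, -48,   5), c(-10, -44,  15), c(  0, -43,  18), c( 10, -44,  15),
    c( 26, -48,   5), c( 14, -52,  10), c(  0, -55,  14), c(-14, -52,  10),
    c(  0, -58,  12), c(  0, -50,  14), c(-28,   5, -10), c(-28,  -5, -10),
    c( 28,   5, -10), c( 28,  -5, -10)
  )
  dimnames(m) <- list(.landmark_names, c("x", "y", "z"))
  m
}

# yaw: rotation about the vertical axis; positive yaw swings the subject's
# left jaw toward the camera. pitch: rotation about the horizontal axis.
rotate_project <- function(template, yaw_deg, pitch_deg) {
  ty <- yaw_deg * pi / 180
  tp <- pitch_deg * pi / 180
  x <- template[, 1L]; y <- template[, 2L]; z <- template[, 3L]
  xr <- outer(cos(ty), x) - outer(sin(ty), z)
  zr <- outer(sin(ty), x) + outer(cos(ty), z)
  yr <- outer(cos(tp), y) - sin(tp) * zr
  list(x = xr, y = yr)
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the simulator emulates: per-participant
#' landmark streams at 16 Hz segmented into 1400 ms CPT letter slots, where a
#' two-state (attention/inattention) Markov chain switches per slot. Attention
#' frames face the screen (yaw ~ N(0, 3) degrees); inattention frames look
#' sideways toward a screen corner (yaw ~ N(25, 5) degrees, direction fixed
#' per participant). Frames are rendered by rotating a per-participant
#' perturbation of the 3D template and projecting orthographically, with
#' per-frame pitch jitter, coordinate noise, and a small rate of invalid
#' (tracking-lost) frames. Matching CPT event logs are emitted whose
#' (target, click, looking) combinations reproduce each slot's latent state
#' under the annotation rules.
#'
#' @param n_per_group Participants per group (default 8).
#' @param frames_per_participant Approximate frames per recording (default
#'   3000, about 190 s at 16 Hz; recordings are a whole number of slots).
#' @param frame_rate_hz Capture rate (16).
#' @param slot_duration_ms Letter duration (1400).
#' @param template 34x3 template matrix (see [face_template_3d()]).
#' @param attention_yaw_mean,attention_yaw_sd Per-frame yaw distribution
#'   (degrees) in attention slots (0, 3).
#' @param inattention_yaw_mean,inattention_yaw_sd Per-frame yaw magnitude
#'   distribution in inattention slots (25, 5); the sign is fixed per
#'   participant.
#' @param yaw_side_prob Probability that a participant's inattention side is
#'   positive (toward their left). Default 1: all participants share the
#'   screen corner; lower it to plant heterogeneous sides.
#' @param pitch_sd Per-frame pitch jitter sd (degrees, 2).
#' @param participant_offset_sd Per-participant 3D shape perturbation sd (mm,
#'   1.5) — the heterogeneity knob.
#' @param coordinate_noise_sd Per-frame, per-coordinate tracking noise sd
#'   (mm, 0.5).
#' @param invalid_rate Fraction of frames with lost tracking (0.02).
#' @param p_attention_stay Markov probability of staying in attention from
#'   one slot to the next (0.9).
#' @param p_inattention_to_attention Markov probability of returning to
#'   attention (0.6). The defaults give a stationary inattention share of
#'   0.1 / 0.7, about 14% — the minority-class imbalance typical of CPT data.
#' @param seed Cohort seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 8, frames_per_participant = 3000,
                             frame_rate_hz = 16, slot_duration_ms = 1400,
                             template = face_template_3d(),
                             attention_yaw_mean = 0, attention_yaw_sd = 3,
                             inattention_yaw_mean = 25,
                             inattention_yaw_sd = 5, yaw_side_prob = 1,
                             pitch_sd = 2, participant_offset_sd = 1.5,
                             coordinate_noise_sd = 0.5, invalid_rate = 0.02,
                             p_attention_stay = 0.9,
                             p_inattention_to_attention = 0.6, seed = 1) {
  stopifnot(
    n_per_group >= 1, frames_per_participant >= 22, frame_rate_hz > 0,
    slot_duration_ms > 0, is.matrix(template),
    nrow(template) == n_landmarks(), ncol(template) == 3,
    attention_yaw_sd >= 0, inattention_yaw_sd >= 0, pitch_sd >= 0,
    participant_offset_sd >= 0, coordinate_noise_sd >= 0,
    invalid_rate >= 0, invalid_rate < 1,
    yaw_side_prob >= 0, yaw_side_prob <= 1,
    p_attention_stay >= 0, p_attention_stay <= 1,
    p_inattention_to_attention >= 0, p_inattention_to_attention <= 1
  )
  structure(as.list(environment()), class = "synthetic_config")
}

#' Stationary label distribution of the slot Markov chain
#' @param config A [synthetic_config()].
#' @return Named numeric: long-run probability of `attention` and
#'   `inattention` slots.
#' @export
markov_stationary <- function(config) {
  p_ai <- 1 - config$p_attention_stay
  p_ia <- config$p_inattention_to_attention
  pi_in <- if (p_ai + p_ia == 0) 0.5 else p_ai / (p_ai + p_ia)
  c(attention = 1 - pi_in, inattention = pi_in)
}

#' Analytically planted discriminative pairs
#'
#' For the two mean poses (attention: frontal; inattention: mean yaw toward
#' the positive side), computes each pair's projected distance and the shift
#' between poses, directly from the noise-free template. The table is the
#' ground truth that parameter-recovery tests compare the empirical
#' distance-threshold ranking against: `shift_mm` is the signed analytic
#' counterpart of `gf` (inattention minus attention), `abs_shift_mm` its
#' magnitude. Sorted by `abs_shift_mm` descending (ties by `feature_id`).
#'
#' @param config A [synthetic_config()].
#' @return A tibble: `feature_id`, `i`, `j`, `feature`, `d_attention_mm`,
#'   `d_inattention_mm`, `shift_mm`, `abs_shift_mm`.
#' @export
planted_discriminative_pairs <- function(config) {
  pose <- function(yaw) {
    pr <- rotate_project(config$template, yaw, 0)
    as.vector(stats::dist(cbind(pr$x[1L, ], pr$y[1L, ])))
  }
  d_att <- pose(config$attention_yaw_mean)
  d_in <- pose(config$inattention_yaw_mean)
  out <- pair_table()[c("feature_id", "i", "j", "feature")]
  out$d_attention_mm <- d_att
  out$d_inattention_mm <- d_in
  out$shift_mm <- d_in - d_att
  out$abs_shift_mm <- abs(out$shift_mm)
  out[order(-out$abs_shift_mm, out$feature_id), ]
}

# event combinations consistent with each latent state under label_slot()
.attention_combos <- rbind(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, TRUE))
.inattention_combos <- rbind(
  c(TRUE, FALSE, TRUE),   # missed target while looking
  c(FALSE, TRUE, TRUE),   # false click while looking
  c(TRUE, FALSE, FALSE),  # looked away, missed target
  c(FALSE, FALSE, FALSE)  # looked away during non-target
)

#' Generate one synthetic participant
#'
#' Samples a slot-level attention state chain, renders the landmark stream by
#' rotating the participant's perturbed template (state-dependent yaw, pitch
#' jitter, orthographic projection, coordinate noise, invalid frames), and
#' emits a CPT event log whose response pattern reproduces the latent states
#' under [label_slot()].
#'
#' @param config A [synthetic_config()].
#' @param participant_id Identifier for the session.
#' @param group `"ASD"` or `"TD"`.
#' @param severity Severity recorded in the session metadata.
#' @param seed Participant seed.
#' @return A list with `session` (a `landmark_session`), `events` (tibble) and
#'   `truth` (list: per-frame `labels` tibble, `yaw_side`,
#'   `inattention_yaw_mean`, per-slot `states`).
#' @export
generate_participant <- function(config, participant_id = "S01",
                                 group = "ASD", severity = "none", seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  fps <- floor(config$slot_duration_ms * config$frame_rate_hz / 1000)
  n_slots <- max(1L, round(config$frames_per_participant / fps))
  n <- n_slots * fps

  # per-participant shape and pose parameters
  template_p <- config$template +
    matrix(rnorm(length(config$template), sd = config$participant_offset_sd),
           nrow(config$template), 3L)
  side <- if (runif(1) < config$yaw_side_prob) 1 else -1

  # slot-level two-state Markov chain, started from its stationary law
  st <- markov_stationary(config)
  states <- character(n_slots)
  states[1L] <- sample(names(st), 1L, prob = st)
  if (n_slots > 1) {
    for (s in 2:n_slots) {
      p_att <- if (states[s - 1L] == "attention") config$p_attention_stay
      else config$p_inattention_to_attention
      states[s] <- if (runif(1) < p_att) "attention" else "inattention"
    }
  }

  # events consistent with the latent state
  onsets <- (seq_len(n_slots) - 1L) * fps * 1000 / config$frame_rate_hz
  combo <- matrix(NA, n_slots, 3L)
  for (s in seq_len(n_slots)) {
    pool <- if (states[s] == "attention") .attention_combos else .inattention_combos
    combo[s, ] <- pool[sample(nrow(pool), 1L), ]
  }
  distractors <- setdiff(LETTERS, "X")
  events <- stimulus_events(tibble::tibble(
    onset_ms = onsets,
    duration_ms = config$slot_duration_ms,
    letter = ifelse(combo[, 1L], "X", sample(distractors, n_slots, replace = TRUE)),
    is_target = combo[, 1L],
    clicked = combo[, 2L],
    looking_at_screen = combo[, 3L]
  ))

  # render frames: state-dependent yaw, pitch jitter, project, add noise
  frame_state <- rep(states, each = fps)
  yaw <- ifelse(
    frame_state == "attention",
    rnorm(n, config$attention_yaw_mean, config$attention_yaw_sd),
    side * rnorm(n, config$inattention_yaw_mean, config$inattention_yaw_sd)
  )
  pitch <- rnorm(n, 0, config$pitch_sd)
  pr <- rotate_project(template_p, yaw, pitch)
  xs <- pr$x + matrix(rnorm(n * n_landmarks(), sd = config$coordinate_noise_sd),
                      n, n_landmarks())
  ys <- pr$y + matrix(rnorm(n * n_landmarks(), sd = config$coordinate_noise_sd),
                      n, n_landmarks())
  valid <- runif(n) >= config$invalid_rate
  xs[!valid, ] <- NA_real_
  ys[!valid, ] <- NA_real_

  idx <- seq_len(n_landmarks()) - 1L
  frames <- tibble::tibble(
    frame = seq_len(n) - 1L,
    timestamp_ms = (seq_len(n) - 1L) * 1000 / config$frame_rate_hz,
    valid = valid
  )
  coords <- matrix(0, n, 2L * n_landmarks())
  coords[, seq(1L, ncol(coords), by = 2L)] <- xs
  coords[, seq(2L, ncol(coords), by = 2L)] <- ys
  colnames(coords) <- coord_columns()
  frames <- dplyr::bind_cols(frames, tibble::as_tibble(coords))

  session <- landmark_session(frames, participant_id = participant_id,
                              group = group, severity = severity,
                              frame_rate_hz = config$frame_rate_hz)
  truth <- list(
    labels = tibble::tibble(frame = frames$frame,
                            true_label = ifelse(valid, frame_state, "invalid")),
    states = states,
    yaw_side = side,
    inattention_yaw_mean = side * config$inattention_yaw_mean
  )
  list(session = session, events = events, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Generates `n_per_group` participants for each of the ASD and TD groups,
#' with per-participant seeds derived deterministically from the cohort seed,
#' so the same configuration always reproduces the same cohort.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` of participant bundles (see
#'   [generate_participant()]), with the config in attribute `"config"`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_total <- 2L * config$n_per_group
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  bundles <- vector("list", n_total)
  k <- 0L
  for (g in c("ASD", "TD")) {
    for (p in seq_len(config$n_per_group)) {
      k <- k + 1L
      pid <- sprintf("%s%02d", if (g == "ASD") "A" else "T", p)
      sev <- if (g == "ASD") c("mild", "moderate")[1L + (p %% 2L)] else "none"
      bundles[[k]] <- generate_participant(config, participant_id = pid,
                                           group = g, severity = sev,
                                           seed = seeds[k])
    }
  }
  names(bundles) <- vapply(bundles, function(b) b$session$participant_id, "")
  structure(bundles, config = config, class = "synthetic_cohort")
}

#' Labeled frame samples for a cohort
#'
#' Runs the annotation pipeline (slot segmentation from the event logs, label
#' propagation) on every participant and binds the labeled frames, with a
#' `group` column.
#'
#' @param cohort A `synthetic_cohort` (or list of participant bundles).
#' @return Labeled frames tibble across participants.
#' @export
cohort_samples <- function(cohort) {
  purrr::map_dfr(cohort, function(b) {
    lab <- annotate_session(b$session, b$events)
    lab$group <- b$session$group
    lab
  })
}

#' Distance-feature samples for a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @param ... Passed to [distance_features()].
#' @return Feature tibble across participants (invalid frames dropped).
#' @export
cohort_features <- function(cohort, ...) {
  samples <- cohort_samples(cohort)
  feats <- distance_features(samples, ...)
  feats$group <- samples$group[match(
    paste(feats$participant_id, feats$frame),
    paste(samples$participant_id, samples$frame)
  )]
  feats
}
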