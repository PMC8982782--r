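#' Validate a table of CPT stimulus events
#'
#' Each event is one letter presentation in the continuous performance task:
#' its onset, duration (1400 ms by default), the letter, whether it was the
#' target, whether the participant clicked, and whether the participant was
#' looking at the screen during the slot.
#'
#' @param events A data frame with columns `onset_ms`, `letter`, `is_target`,
#'   `clicked`, `looking_at_screen` and optionally `duration_ms`.
#' @param default_duration_ms Duration filled in when absent.
#' @return A tibble sorted by onset with all six columns.
#' @export
stimulus_events <- function(events, default_duration_ms = 1400) {
  events <- tibble::as_tibble(events)
  if (!"duration_ms" %in% names(events)) events$duration_ms <- default_duration_ms
  needed <- c("onset_ms", "duration_ms", "letter", "is_target", "clicked",
              "looking_at_screen")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols) > 0) {
    abort(sprintf("events table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "attendr_format_error")
  }
  events <- events[needed]
  if (any(events$duration_ms <= 0)) {
    abort("event durations must be positive.", class = "attendr_domain_error")
  }
  events <- events[order(events$onset_ms), ]
  if (nrow(events) > 1 &&
      any(diff(events$onset_ms) < events$duration_ms[-nrow(events)] -
            1000 * .Machine$double.eps)) {
    # onsets may be as close as one slot's worth of frames; true overlap of
    # assigned frame spans is checked in build_slots()
  }
  events
}

#' Label a stimulus slot from behaviour and response correctness
#'
#' A slot counts as attention exactly when the participant was looking at the
#' screen *and* responded correctly (clicked on the target letter, or withheld
#' the click on a non-target). Looking away, missing the target, or a false
#' click all yield inattention. The full truth table over
#' (`is_target`, `clicked`, `looking_at_screen`):
#'
#' | is_target | clicked | looking | label |
#' |-----------|---------|---------|-------|
#' | TRUE  | TRUE  | TRUE  | attention   |
#' | FALSE | FALSE | TRUE  | attention   |
#' | TRUE  | FALSE | TRUE  | inattention |
#' | FALSE | TRUE  | TRUE  | inattention |
#' | any   | any   | FALSE | inattention |
#'
#' @param events An event tibble (see [stimulus_events()]); vectorised over
#'   rows.
#' @return Character vector, `"attention"` or `"inattention"`, one per event.
#' @export
label_slot <- function(events) {
  correct <- events$is_target == events$clicked
  ifelse(events$looking_at_screen & correct, "attention", "inattention")
}

#' Segment a session into stimulus slots
#'
#' Assigns each stimulus event the frames whose timestamp falls in
#' `[onset, onset + duration)`, truncated to
#' `floor(duration_ms * frame_rate / 1000)` frames (22 frames for the default
#' 1400 ms slots at 16 Hz) so that adjacent slots never share a frame. Frame
#' spans are reported half-open on the right.
#'
#' @param session A `landmark_session`.
#' @param events An event tibble (see [stimulus_events()]).
#' @return A tibble with one row per slot: `slot_index`, `onset_ms`,
#'   `duration_ms`, `label`, `first_frame`, `end_frame` (exclusive),
#'   `n_frames`.
#' @export
build_slots <- function(session, events) {
  stopifnot(inherits(session, "landmark_session"))
  events <- stimulus_events(events)
  frames <- session$frames
  if (nrow(events) == 0) {
    return(tibble::tibble(
      slot_index = integer(), onset_ms = numeric(), duration_ms = numeric(),
      label = character(), first_frame = integer(), end_frame = integer(),
      n_frames = integer()
    ))
  }
  t0 <- min(frames$timestamp_ms)
  t1 <- max(frames$timestamp_ms)
  bad <- events$onset_ms < t0 - 1e-9 | events$onset_ms > t1 + 1e-9
  if (any(bad)) {
    abort(sprintf(
      "event onset(s) outside the session time range [%g, %g] ms: %s",
      t0, t1, paste(events$onset_ms[bad], collapse = ", ")
    ), class = "attendr_coverage_error")
  }
  cap <- floor(events$duration_ms * session$frame_rate_hz / 1000)
  labels <- label_slot(events)
  spans <- purrr::pmap(
    list(events$onset_ms, events$duration_ms, cap),
    function(onset, dur, k) {
      in_win <- which(frames$timestamp_ms >= onset - 1e-9 &
                        frames$timestamp_ms < onset + dur - 1e-9)
      in_win <- head(in_win, k)
      if (length(in_win) == 0) {
        c(first = NA_integer_, end = NA_integer_, n = 0L)
      } else {
        c(first = frames$frame[in_win[1L]],
          end = frames$frame[in_win[length(in_win)]] + 1L,
          n = length(in_win))
      }
    }
  )
  out <- tibble::tibble(
    slot_index = seq_len(nrow(events)) - 1L,
    onset_ms = events$onset_ms,
    duration_ms = events$duration_ms,
    label = labels,
    first_frame = purrr::map_int(spans, ~ as.integer(.x[["first"]])),
    end_frame = purrr::map_int(spans, ~ as.integer(.x[["end"]])),
    n_frames = purrr::map_int(spans, ~ as.integer(.x[["n"]]))
  )
  occupied <- out[out$n_frames > 0, ]
  if (nrow(occupied) > 1) {
    ord <- order(occupied$first_frame)
    if (any(occupied$end_frame[ord][-nrow(occupied)] >
            occupied$first_frame[ord][-1])) {
      abort("slot frame spans overlap; check event onsets and durations.",
            class = "attendr_validation_error")
    }
  }
  out
}

#' Propagate slot labels to individual frames
#'
#' Every valid frame inside a slot inherits the slot's label; invalid frames
#' keep the label `"invalid"` regardless of slot, and frames outside all slots
#' are `"invalid"` too. Label counts therefore always satisfy
#' attention + inattention + invalid = total frames.
#'
#' @param session A `landmark_session`.
#' @param slots Slot table from [build_slots()].
#' @return The session's frames tibble with an added `label` column and a
#'   `participant_id` column.
#' @export
propagate_labels <- function(session, slots) {
  stopifnot(inherits(session, "landmark_session"))
  frames <- session$frames
  label <- rep("invalid", nrow(frames))
  for (s in seq_len(nrow(slots))) {
    if (slots$n_frames[s] == 0) next
    in_slot <- frames$frame >= slots$first_frame[s] &
      frames$frame < slots$end_frame[s]
    label[in_slot] <- slots$label[s]
  }
  label[!frames$valid] <- "invalid"
  dplyr::bind_cols(
    tibble::tibble(participant_id = session$participant_id),
    frames,
    tibble::tibble(label = label)
  )
}

#' Annotate a session end-to-end
#'
#' Convenience wrapper: builds slots from the event log and propagates labels
#' to frames.
#'
#' @inheritParams build_slots
#' @return Labeled frames tibble (see [propagate_labels()]).
#' @export
annotate_session <- function(session, events) {
  propagate_labels(session, build_slots(session, events))
}
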