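#' Construct a landmark session
#'
#' A session is one participant's recording: a frames table (frame index,
#' timestamp, validity flag and 34 landmark coordinate pairs in millimetres)
#' plus participant-level metadata. Frames whose coordinates are missing carry
#' `valid = FALSE` and are excluded from all feature computation.
#'
#' @param frames A data frame with columns `frame`, `timestamp_ms`, `valid`
#'   and `x_0, y_0, ..., x_33, y_33`. Frame indices must be strictly
#'   increasing; rows with any missing coordinate are forced to
#'   `valid = FALSE`.
#' @param participant_id Participant identifier.
#' @param group Cohort label, `"ASD"` or `"TD"`.
#' @param severity `"mild"`, `"moderate"` or `"none"`.
#' @param task_level CPT distraction level: `"baseline"`, `"easy"`,
#'   `"medium"` or `"hard"`.
#' @param frame_rate_hz Capture rate in frames per second (default 16).
#' @return An object of class `landmark_session`.
#' @export
landmark_session <- function(frames, participant_id = "P1",
                             group = c("ASD", "TD"),
                             severity = c("none", "mild", "moderate"),
                             task_level = c("baseline", "easy", "medium", "hard"),
                             frame_rate_hz = 16) {
  group <- match.arg(group)
  severity <- match.arg(severity)
  task_level <- match.arg(task_level)
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    abort("`frame_rate_hz` must be a positive number.", class = "attendr_domain_error")
  }
  frames <- tibble::as_tibble(frames)
  needed <- c("frame", "timestamp_ms", "valid", coord_columns())
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("frames table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      class = "attendr_format_error"
    )
  }
  frames <- frames[needed]
  frames$frame <- as.integer(frames$frame)
  if (nrow(frames) > 1 && any(diff(frames$frame) <= 0)) {
    abort("frame indices must be strictly increasing.",
          class = "attendr_validation_error")
  }
  cc <- coord_columns()
  any_na <- rowSums(is.na(as.matrix(frames[cc]))) > 0
  frames$valid <- as.logical(frames$valid) & !any_na
  structure(
    list(frames = frames, participant_id = participant_id, group = group,
         severity = severity, task_level = task_level,
         frame_rate_hz = frame_rate_hz),
    class = "landmark_session"
  )
}

#' @export
print.landmark_session <- function(x, ...) {
  cat(sprintf(
    "<landmark_session> %s (%s, %s, task %s)\n  %d frames at %g Hz, %d invalid\n",
    x$participant_id, x$group, x$severity, x$task_level,
    nrow(x$frames), x$frame_rate_hz, sum(!x$frames$valid)
  ))
  invisible(x)
}

# n x 34 coordinate matrices for the session's frames (valid or not)
session_coord_matrices <- function(frames) {
  idx <- seq_len(n_landmarks()) - 1L
  list(
    x = as.matrix(frames[paste0("x_", idx)]),
    y = as.matrix(frames[paste0("y_", idx)])
  )
}

#' Read a landmark session from CSV
#'
#' Reads a landmark-stream CSV with header
#' `frame,timestamp_ms,valid,x_0,y_0,...,x_33,y_33`. Rows with any missing
#' coordinate are marked invalid; the number of loaded and invalid frames is
#' reported as a message.
#'
#' @param path Path to the CSV file.
#' @inheritParams landmark_session
#' @param quiet Suppress the frame-count message.
#' @return A `landmark_session`.
#' @seealso [write_session()]
#' @export
read_session <- function(path, participant_id = "P1", group = "ASD",
                         severity = "none", task_level = "baseline",
                         frame_rate_hz = 16, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "attendr_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("frame", "timestamp_ms", "valid", coord_columns())
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("malformed header: missing column(s) %s",
              paste(missing_cols, collapse = ", ")),
      class = "attendr_format_error"
    )
  }
  session <- landmark_session(raw, participant_id = participant_id,
                              group = group, severity = severity,
                              task_level = task_level,
                              frame_rate_hz = frame_rate_hz)
  if (!quiet) {
    message(sprintf("Loaded %d frames (%d invalid) from %s",
                    nrow(session$frames), sum(!session$frames$valid), path))
  }
  session
}

#' Write a landmark session to CSV
#'
#' Writes the session's frames with fixed 6-decimal coordinate rendering so
#' that [read_session()] round-trips coordinates exactly at the 1e-6 mm level.
#'
#' @param session A `landmark_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "landmark_session"))
  frames <- session$frames
  out <- frames
  for (col in c("timestamp_ms", coord_columns())) {
    v <- sprintf("%.6f", out[[col]])
    v[is.na(out[[col]])] <- ""
    out[[col]] <- v
  }
  out$valid <- ifelse(frames$valid, "TRUE", "FALSE")
  ok <- tryCatch({
    readr::write_csv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort(sprintf("Cannot write to %s", path), class = "attendr_io_error")
  invisible(path)
}

#' Read and write CPT stimulus event logs
#'
#' Event logs hold one row per letter presentation:
#' `onset_ms,letter,is_target,clicked,looking_at_screen` with an optional
#' `duration_ms` column (default 1400 ms per presentation).
#'
#' @param path CSV path.
#' @param default_duration_ms Duration used when the file has no
#'   `duration_ms` column.
#' @return A tibble of events sorted by onset.
#' @export
read_events <- function(path, default_duration_ms = 1400) {
  if (!file.exists(path)) {
    abort(sprintf("No such file: %s", path), class = "attendr_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("onset_ms", "letter", "is_target", "clicked", "looking_at_screen")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("malformed event header: missing column(s) %s",
              paste(missing_cols, collapse = ", ")),
      class = "attendr_format_error"
    )
  }
  if (!"duration_ms" %in% names(raw)) raw$duration_ms <- default_duration_ms
  stimulus_events(raw)
}

#' @rdname read_events
#' @param events An event tibble as returned by [stimulus_events()].
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}
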