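#' Euclidean distance between two 2D points
#'
#' @param p,q Numeric length-2 vectors (x, y) in millimetres, or two-column
#'   matrices of points (vectorised row-wise).
#' @return Distance(s) in millimetres.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  if (ncol(p) != 2 || ncol(q) != 2) {
    abort("points must have two coordinates (x, y).", class = "attendr_domain_error")
  }
  if (anyNA(p) || anyNA(q) || any(!is.finite(p)) || any(!is.finite(q))) {
    abort("coordinates must be finite.", class = "attendr_domain_error")
  }
  unname(sqrt((q[, 1] - p[, 1])^2 + (q[, 2] - p[, 2])^2))
}

#' All pairwise landmark distances for one frame
#'
#' Computes the 561 inter-landmark Euclidean distances of a single frame, in
#' canonical `feature_id` order (see [pair_table()]).
#'
#' @param x,y Numeric length-34 coordinate vectors (mm).
#' @return Numeric length-561 vector of distances, named by feature column.
#' @export
frame_distance_vector <- function(x, y) {
  stopifnot(length(x) == n_landmarks(), length(y) == n_landmarks())
  d <- as.vector(stats::dist(cbind(x, y)))
  names(d) <- pair_table()$feature
  d
}

#' Pairwise-distance feature table for labeled frames
#'
#' Transforms labeled landmark frames into one row per usable frame with all
#' 561 pairwise distances as columns `f_<i>_<j>`. Invalid frames, and (when a
#' `label` column is present) frames labeled `"invalid"`, are skipped; the
#' number skipped is reported as a message.
#'
#' @param frames A labeled frames tibble (e.g. from [annotate_session()] or
#'   [cohort_samples()]), or a `landmark_session` (all valid frames used,
#'   unlabeled).
#' @param drop_pair Optional length-2 integer vector: one landmark pair to
#'   exclude from the feature pool.
#' @param quiet Suppress the skipped-frame message.
#' @return A tibble with columns `participant_id`, `frame`, `label` (if
#'   available) and the distance features.
#' @export
distance_features <- function(frames, drop_pair = NULL, quiet = TRUE) {
  if (inherits(frames, "landmark_session")) {
    pid <- frames$participant_id
    frames <- frames$frames
    frames$participant_id <- pid
  }
  frames <- tibble::as_tibble(frames)
  keep <- frames$valid
  if ("label" %in% names(frames)) keep <- keep & frames$label != "invalid"
  n_skip <- sum(!keep)
  if (!quiet && n_skip > 0) {
    message(sprintf("Skipping %d invalid/unlabeled frame(s).", n_skip))
  }
  frames <- frames[keep, ]
  pt <- pair_table(drop_pair = drop_pair)
  mats <- session_coord_matrices(frames)
  feat <- matrix(0, nrow(frames), nrow(pt),
                 dimnames = list(NULL, pt$feature))
  for (k in seq_len(nrow(pt))) {
    i <- pt$i[k] + 1L
    j <- pt$j[k] + 1L
    feat[, k] <- sqrt((mats$x[, i] - mats$x[, j])^2 +
                        (mats$y[, i] - mats$y[, j])^2)
  }
  meta <- tibble::tibble(
    participant_id = if ("participant_id" %in% names(frames))
      frames$participant_id else NA_character_,
    frame = frames$frame
  )
  if ("label" %in% names(frames)) meta$label <- frames$label
  dplyr::bind_cols(meta, tibble::as_tibble(feat))
}

#' Fit feature standardization on training data
#'
#' Computes the per-feature mean `m` and standard deviation `s` of the
#' training rows, for the z-score transform `Z = (x - m) / s`. Features that
#' are constant on the training data (`s = 0`) are dropped and recorded, since
#' the transform is undefined there.
#'
#' @param train Feature tibble (from [distance_features()]), or any data frame
#'   with `f_*` columns.
#' @param sd_type `"population"` (divide by n; the default) or `"sample"`
#'   (divide by n - 1).
#' @param features Optional character vector restricting which feature columns
#'   to standardize (defaults to all `f_*` columns).
#' @return An object of class `standardization_params`: a tibble with columns
#'   `feature`, `m`, `s` (dropped features excluded), with the dropped feature
#'   names in attribute `"dropped"`.
#' @export
standardize_fit <- function(train, sd_type = c("population", "sample"),
                            features = NULL) {
  sd_type <- match.arg(sd_type)
  features <- features %||% feature_columns(train)
  if (nrow(train) < 2) {
    abort("need at least 2 rows to fit standardization.",
          class = "attendr_insufficient_data_error")
  }
  x <- as.matrix(train[features])
  m <- colMeans(x)
  n <- nrow(x)
  s <- sqrt(colSums(sweep(x, 2L, m)^2) / if (sd_type == "population") n else n - 1L)
  dropped <- features[s == 0]
  if (length(dropped) > 0) {
    warn(sprintf("Dropping %d constant feature(s): %s", length(dropped),
                 paste(head(dropped, 5L), collapse = ", ")))
  }
  keep <- s > 0
  structure(
    tibble::tibble(feature = features[keep], m = unname(m[keep]),
                   s = unname(s[keep])),
    dropped = dropped, sd_type = sd_type,
    class = c("standardization_params", "tbl_df", "tbl", "data.frame")
  )
}

#' Apply fitted standardization parameters
#'
#' Applies the training-data z-score transform to new rows; test rows always
#' reuse the training `m` and `s` (no refitting). Dropped features are removed.
#'
#' @param params A `standardization_params` object from [standardize_fit()].
#' @param data Feature tibble containing at least the retained features.
#' @return `data` with standardized feature columns (dropped features removed,
#'   non-feature columns untouched).
#' @export
standardize_apply <- function(params, data) {
  stopifnot(inherits(params, "standardization_params"))
  missing_cols <- setdiff(params$feature, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("data lacks feature column(s): %s",
                  paste(head(missing_cols, 5L), collapse = ", ")),
          class = "attendr_schema_error")
  }
  out <- data
  dropped <- attr(params, "dropped")
  out <- out[setdiff(names(out), dropped)]
  x <- as.matrix(out[params$feature])
  z <- sweep(sweep(x, 2L, params$m), 2L, params$s, "/")
  out[params$feature] <- tibble::as_tibble(z)
  out
}

#' Invert a standardization (for checking round-trips)
#' @inheritParams standardize_apply
#' @return `data` with features mapped back to the original scale.
#' @export
standardize_invert <- function(params, data) {
  stopifnot(inherits(params, "standardization_params"))
  out <- data
  x <- as.matrix(out[params$feature])
  out[params$feature] <- tibble::as_tibble(
    sweep(sweep(x, 2L, params$s, "*"), 2L, params$m, "+")
  )
  out
}

#' Landmark distortion check (MAE over consecutive frames)
#'
#' Quality-control statistic for landmark tracking: the mean absolute change
#' of one sentinel inter-landmark distance across consecutive valid frames
#' carrying the same class label. The default pair (0, 4) spans right top jaw
#' to left top jaw, the pair most sensitive to head-pose distortion. Gaps from
#' invalid or differently-labeled frames break the consecutive pairing. A
#' static (noise-free, fixed-pose) recording yields exactly 0.
#'
#' @param frames Labeled frames tibble (from [annotate_session()]).
#' @param pair Length-2 integer vector of landmark indices.
#' @param label_filter Class whose frames are compared (default
#'   `"attention"`).
#' @return MAE in millimetres (single number).
#' @export
landmark_mae <- function(frames, pair = c(0L, 4L), label_filter = "attention") {
  if (inherits(frames, "landmark_session")) {
    abort("landmark_mae() needs labeled frames; call annotate_session() first.",
          class = "attendr_domain_error")
  }
  i <- vec_as_landmark(pair[1L], "pair[1]")
  j <- vec_as_landmark(pair[2L], "pair[2]")
  use <- frames$valid & frames$label == label_filter
  sub <- frames[use, ]
  if (nrow(sub) < 2) {
    abort("need at least 2 valid frames with the requested label.",
          class = "attendr_insufficient_data_error")
  }
  d <- sqrt((sub[[paste0("x_", i)]] - sub[[paste0("x_", j)]])^2 +
              (sub[[paste0("y_", i)]] - sub[[paste0("y_", j)]])^2)
  consecutive <- diff(sub$frame) == 1L
  if (!any(consecutive)) {
    abort("no consecutive same-label valid frame pairs available.",
          class = "attendr_insufficient_data_error")
  }
  mean(abs(diff(d))[consecutive])
}
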