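#' Per-class mean landmark coordinates
#'
#' Averages each landmark coordinate over a class's valid frames — the
#' "mean-intensity face" that visualises the attention pose (facing the
#' screen) against the inattention pose (looking sideways).
#'
#' @param frames Labeled frames tibble (see [annotate_session()]).
#' @param label Class to average, `"attention"` or `"inattention"`.
#' @return A tibble with columns `index`, `name`, `x`, `y` (mm) and attribute
#'   `"n_frames"`.
#' @export
class_mean_face <- function(frames, label = c("attention", "inattention")) {
  label <- match.arg(label)
  sub <- frames[frames$valid & frames$label == label, ]
  if (nrow(sub) == 0) {
    abort(sprintf("no valid frames with label '%s'.", label),
          class = "attendr_insufficient_data_error")
  }
  mats <- session_coord_matrices(sub)
  out <- landmark_schema()
  out$x <- unname(colMeans(mats$x))
  out$y <- unname(colMeans(mats$y))
  out$label <- label
  attr(out, "n_frames") <- nrow(sub)
  out
}

#' Per-class mean pairwise distances
#'
#' Arithmetic mean of every pairwise-distance feature over a class's rows —
#' the per-class summaries that the distance-threshold selection compares.
#'
#' @param features Feature tibble with a `label` column (from
#'   [distance_features()]).
#' @param label Class to average.
#' @return A tibble with columns `feature` and `mean_mm`.
#' @export
class_mean_distances <- function(features, label = c("attention", "inattention")) {
  label <- match.arg(label)
  cols <- feature_columns(features)
  sub <- features[features$label == label, ]
  if (nrow(sub) == 0) {
    abort(sprintf("no rows with label '%s'.", label),
          class = "attendr_insufficient_data_error")
  }
  tibble::tibble(feature = cols,
                 mean_mm = unname(colMeans(as.matrix(sub[cols]))))
}

#' Distance thresholds from per-class mean distances
#'
#' For every landmark pair, the distance threshold is
#' `gf = inattention mean - attention mean` (mm): how much further apart the
#' pair sits, on average, when the head is turned away. The returned table is
#' sorted by `gf` descending (ties broken by smaller `feature_id`), the order
#' in which features are then selected.
#'
#' @param attention_means,inattention_means Tibbles with columns `feature` and
#'   `mean_mm` (from [class_mean_distances()]), covering the same features.
#' @return A `threshold_table`: tibble with columns `feature_id`, `i`, `j`,
#'   `feature`, `description`, `inattention_mean_mm`, `attention_mean_mm`,
#'   `gf_mm`.
#' @export
distance_thresholds <- function(attention_means, inattention_means) {
  if (!setequal(attention_means$feature, inattention_means$feature)) {
    abort("attention and inattention mean tables cover different features.",
          class = "attendr_schema_error")
  }
  merged <- dplyr::inner_join(
    dplyr::rename(attention_means, attention_mean_mm = "mean_mm"),
    dplyr::rename(inattention_means, inattention_mean_mm = "mean_mm"),
    by = "feature"
  )
  pt <- pair_table()
  out <- dplyr::inner_join(pt, merged, by = "feature")
  out$gf_mm <- out$inattention_mean_mm - out$attention_mean_mm
  out <- out[order(-out$gf_mm, out$feature_id),
             c("feature_id", "i", "j", "feature", "description",
               "inattention_mean_mm", "attention_mean_mm", "gf_mm")]
  structure(out, class = c("threshold_table", class(tibble::tibble())))
}

#' Full threshold-selection pipeline on a feature table
#'
#' Computes both class mean-distance vectors from a labeled feature table and
#' their per-pair differences. In every evaluation regime this is run on
#' training rows only, so no test information leaks into feature selection.
#'
#' @inheritParams class_mean_distances
#' @return A `threshold_table` (see [distance_thresholds()]).
#' @export
threshold_table <- function(features) {
  distance_thresholds(
    class_mean_distances(features, "attention"),
    class_mean_distances(features, "inattention")
  )
}

#' Select the top-k features by distance threshold
#'
#' Returns the `k` landmark pairs with the largest threshold `gf` (selection
#' is typically explored in multiples of 10; 20 features is the default
#' operating point). Ties are broken by smaller `feature_id`, making the
#' selection deterministic and the k / k+10 menus nested.
#'
#' @param table A `threshold_table`.
#' @param k Number of features to keep, in `1..nrow(table)` (default 20).
#' @param abs_mode Rank by `|gf|` instead of signed `gf`. Off by default
#'   (all reference thresholds are positive); useful when shifts of both signs
#'   are informative.
#' @return The selected rows of `table`, in selection order.
#' @export
select_top_k <- function(table, k = 20, abs_mode = FALSE) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > nrow(table) ||
      k != floor(k)) {
    abort(sprintf("`k` must be an integer in 1..%d.", nrow(table)),
          class = "attendr_domain_error")
  }
  key <- if (abs_mode) abs(table$gf_mm) else table$gf_mm
  ord <- order(-key, table$feature_id)
  table[ord[seq_len(k)], ]
}

#' Write a threshold table to CSV
#'
#' Mirrors the reference layout: pair, description, per-class means and the
#' distance threshold, sorted descending.
#'
#' @param table A `threshold_table`.
#' @param path Output CSV path.
#' @export
write_threshold_table <- function(table, path) {
  out <- tibble::tibble(
    pair = paste0("D: ", table$i, "-", table$j),
    description = table$description,
    inattention_mean_mm = table$inattention_mean_mm,
    attention_mean_mm = table$attention_mean_mm,
    gf_mm = table$gf_mm
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
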