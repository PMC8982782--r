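#' Plot a threshold table
#'
#' Bar chart of the top-k distance thresholds (`gf`, mm), the view used to
#' pick the feature menu.
#'
#' @param object A `threshold_table`.
#' @param k Number of leading features to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_table <- function(object, k = 20, ...) {
  top <- select_top_k(object, k = min(k, nrow(object)))
  top$pair <- factor(paste0(top$i, "-", top$j),
                     levels = rev(paste0(top$i, "-", top$j)))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$gf_mm, y = .data$pair)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "distance threshold gf (mm)", y = "landmark pair",
                  title = sprintf("Top %d distance thresholds", nrow(top))) +
    ggplot2::theme_minimal()
}

#' Plot per-class mean faces
#'
#' Overlays the attention and inattention mean-intensity faces (per-class
#' mean landmark positions): the attention face looks at the screen, the
#' inattention face is compressed sideways by the mean yaw.
#'
#' @param ... One or more tibbles from [class_mean_face()].
#' @return A ggplot object.
#' @export
plot_mean_faces <- function(...) {
  faces <- dplyr::bind_rows(...)
  ggplot2::ggplot(faces, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL,
                  title = "Mean-intensity faces by class") +
    ggplot2::theme_minimal()
}

#' Plot a landmark raster image
#'
#' @param img 0/1 matrix from [rasterize_frame()].
#' @return A ggplot object (white dots on black, as fed to the CNN).
#' @export
plot_raster <- function(img) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(t(img))[(df$row - 1) * ncol(img) + df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$value))) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "white")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot evaluation results
#'
#' For cross-group evaluations: AUC and F1 distributions over iterations per
#' train/test cell. For the other regimes: per-participant metric
#' distributions.
#'
#' @param object An `attention_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attention_eval <- function(object, ...) {
  if (object$regime == "cross_group") {
    df <- tidyr::pivot_longer(
      object$per_iteration[c("train_group", "test_group", "auc", "f1")],
      c("auc", "f1"), names_to = "metric", values_to = "value"
    )
    df$cell <- paste0("train ", df$train_group, " / test ", df$test_group)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$value)) +
      ggplot2::geom_boxplot(fill = "grey85") +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = NULL, y = NULL,
                    title = "Within- and cross-group evaluation") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  } else {
    df <- tidyr::pivot_longer(
      object$per_participant[c("participant_id", "acc", "auc", "f1")],
      c("acc", "auc", "f1"), names_to = "metric", values_to = "value"
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
      ggplot2::geom_boxplot(fill = "grey85") +
      ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
      ggplot2::labs(x = NULL, y = NULL, title = object$regime) +
      ggplot2::theme_minimal()
  }
}
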