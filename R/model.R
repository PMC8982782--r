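#' Fit an attention classifier (SVM or CNN pipeline)
#'
#' One entry point for both classifier families, fitting every stage on the
#' training rows only:
#'
#' * `model = "svm"`: distance-threshold feature selection (top-`k` pairs by
#'   `gf`), z-score standardization, then an RBF-kernel SVM.
#' * `model = "cnn"`: per-frame 32x32 landmark rasterization, then the small
#'   convolutional network.
#'
#' @param train For the SVM, a feature tibble (from [distance_features()])
#'   with a `label` column; for the CNN, a labeled frames tibble (from
#'   [annotate_session()] / [cohort_samples()]). A labeled frames tibble also
#'   works for the SVM (features are computed internally).
#' @param model `"svm"` or `"cnn"`.
#' @param k Number of selected distance features (SVM; default 20).
#' @param C,gamma SVM hyperparameters (defaults 11, 0.1).
#' @param abs_mode Rank features by `|gf|` instead of signed `gf` (SVM).
#' @param cnn A [cnn_config()] (CNN path).
#' @param seed Seed recorded in the model; for the CNN it overrides the
#'   config seed.
#' @return An `attention_model` object with a [predict()] method returning
#'   `.pred_label` and `.score` per row.
#' @export
fit_attention_model <- function(train, model = c("svm", "cnn"), k = 20,
                                C = 11, gamma = 0.1, abs_mode = FALSE,
                                cnn = cnn_config(), seed = NULL) {
  model <- match.arg(model)
  if (model == "svm") {
    if (length(feature_columns(train)) == 0) train <- distance_features(train)
    thr <- threshold_table(train)
    sel <- select_top_k(thr, k = k, abs_mode = abs_mode)
    keep <- c(intersect(c("participant_id", "frame", "label"), names(train)),
              sel$feature)
    train_sel <- train[keep]
    params <- standardize_fit(train_sel)
    train_std <- standardize_apply(params, train_sel)
    fit <- train_svm(train_std, C = C, gamma = gamma)
    pred_train <- predict(fit, train_std)
    structure(
      list(kind = "svm", fit = fit, standardization = params,
           selected = sel, k = k, C = C, gamma = gamma, seed = seed,
           n_train = nrow(train_std),
           train_accuracy = mean(pred_train$.pred_label == train_std$label)),
      class = "attention_model"
    )
  } else {
    if (!is.null(seed)) cnn$seed <- seed
    ras <- rasterize_frames(train)
    fit <- train_cnn(ras$images, ras$meta$label, config = cnn)
    pred_train <- predict(fit, ras$images)
    structure(
      list(kind = "cnn", fit = fit, config = cnn, seed = cnn$seed,
           n_train = dim(ras$images)[3L],
           train_accuracy = mean(pred_train$.pred_label == ras$meta$label)),
      class = "attention_model"
    )
  }
}

#' @export
print.attention_model <- function(x, ...) {
  if (x$kind == "svm") {
    cat(sprintf(
      "<attention_model: RBF-SVM> %d selected features, C = %g, gamma = %g\n  trained on %d rows (train ACC %.3f)\n",
      x$k, x$C, x$gamma, x$n_train, x$train_accuracy))
  } else {
    cat(sprintf(
      "<attention_model: CNN> %d parameters, %d epochs\n  trained on %d images (train ACC %.3f)\n",
      cnn_n_parameters(x$fit), x$config$epochs, x$n_train, x$train_accuracy))
  }
  invisible(x)
}

#' Predict attention labels and scores
#'
#' @param object An `attention_model` from [fit_attention_model()].
#' @param newdata For an SVM model, a feature tibble (or labeled frames
#'   tibble) with the selected feature columns; for a CNN model, a labeled
#'   frames tibble.
#' @param ... Unused.
#' @return Tibble with `.pred_label` and `.score`, one row per input row.
#' @export
predict.attention_model <- function(object, newdata, ...) {
  if (object$kind == "svm") {
    if (length(feature_columns(newdata)) == 0) {
      newdata <- distance_features(newdata)
    }
    std <- standardize_apply(object$standardization, newdata)
    predict(object$fit, std)
  } else {
    ras <- rasterize_frames(newdata)
    predict(object$fit, ras$images)
  }
}

#' @export
tidy.attention_model <- function(x, ...) {
  if (x$kind == "svm") {
    tibble::as_tibble(x$selected)
  } else {
    tibble::tibble(
      layer = c("conv1", "conv2", "dense1", "dense2"),
      parameters = c(
        length(x$fit$params$W1) + length(x$fit$params$b1),
        length(x$fit$params$W2) + length(x$fit$params$b2),
        length(x$fit$params$W3) + length(x$fit$params$b3),
        length(x$fit$params$W4) + length(x$fit$params$b4)
      )
    )
  }
}

#' @export
glance.attention_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_train = x$n_train,
    train_accuracy = x$train_accuracy,
    k = if (x$kind == "svm") x$k else NA_integer_,
    C = if (x$kind == "svm") x$C else NA_real_,
    gamma = if (x$kind == "svm") x$gamma else NA_real_,
    epochs = if (x$kind == "cnn") x$config$epochs else NA_integer_,
    n_parameters = if (x$kind == "cnn") cnn_n_parameters(x$fit) else NA_integer_
  )
}
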