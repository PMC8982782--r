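#' RBF-SVM configuration
#'
#' Default hyperparameters for the attention SVM: `C = 11`, `gamma = 0.1`,
#' selected by cross-validated grid search over integer `C` in 1..26 and
#' `gamma` in {0.001, 0.01, 0.1, 1, 10}.
#'
#' @param C Soft-margin penalty (positive).
#' @param gamma RBF kernel width (positive).
#' @param C_grid,gamma_grid Grids searched by [grid_search()].
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(C = 11, gamma = 0.1, C_grid = 1:26,
                       gamma_grid = c(0.001, 0.01, 0.1, 1, 10),
                       cv_folds = 10) {
  stopifnot(C > 0, gamma > 0, length(C_grid) >= 1, length(gamma_grid) >= 1,
            all(C_grid > 0), all(gamma_grid > 0), cv_folds >= 2)
  structure(list(C = C, gamma = gamma, C_grid = C_grid,
                 gamma_grid = gamma_grid, cv_folds = cv_folds),
            class = "svm_config")
}

# seeded stratified fold assignment: within each class, shuffle then deal
# round-robin so every fold holds both classes whenever counts allow
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid search for SVM hyperparameters
#'
#' Exhaustive search over `C_grid x gamma_grid`, scoring each cell by mean
#' cross-validated accuracy with seeded, class-stratified folds. Ties are
#' broken towards smaller `C`, then smaller `gamma`, so the search is
#' deterministic given the seed.
#'
#' @param train Standardized feature tibble with a `label` column holding both
#'   classes.
#' @param config An [svm_config()].
#' @param seed Integer seed for the fold assignment.
#' @return A list with `C`, `gamma` and the full `grid` tibble
#'   (`C`, `gamma`, `cv_accuracy`).
#' @export
grid_search <- function(train, config = svm_config(), seed = 1) {
  labels <- train$label
  if (length(unique(labels)) < 2) {
    abort("training data must contain both classes.",
          class = "attendr_class_coverage_error")
  }
  if (min(table(labels)) < config$cv_folds) {
    abort(sprintf("need at least %d rows per class for %d-fold CV.",
                  config$cv_folds, config$cv_folds),
          class = "attendr_insufficient_data_error")
  }
  cols <- feature_columns(train)
  x <- as.matrix(train[cols])
  y <- factor(labels, levels = c("inattention", "attention"))
  fold <- stratified_folds(labels, config$cv_folds, seed = seed)
  grid <- tidyr::expand_grid(C = config$C_grid, gamma = config$gamma_grid)
  grid$cv_accuracy <- purrr::map2_dbl(grid$C, grid$gamma, function(C, g) {
    correct <- 0L
    for (f in seq_len(config$cv_folds)) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = C, gamma = g, scale = FALSE)
      correct <- correct +
        sum(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  })
  best <- grid[order(-grid$cv_accuracy, grid$C, grid$gamma), ][1L, ]
  list(C = best$C, gamma = best$gamma, grid = grid)
}

#' Train the RBF-SVM attention classifier
#'
#' Fits a Gaussian radial-basis-function SVM on standardized features. The
#' model keeps continuous decision scores oriented so that larger scores mean
#' attention, which drives AUC computation downstream.
#'
#' @param train Standardized feature tibble with a `label` column.
#' @param C,gamma Hyperparameters (defaults 11 and 0.1).
#' @return An object of class `attention_svm`.
#' @export
train_svm <- function(train, C = 11, gamma = 0.1) {
  labels <- train$label
  if (length(unique(labels)) < 2) {
    abort("training data must contain both classes.",
          class = "attendr_class_coverage_error")
  }
  cols <- feature_columns(train)
  x <- as.matrix(train[cols])
  y <- factor(labels, levels = c("inattention", "attention"))
  fit <- e1071::svm(x, y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1L]
  # libsvm's decision-value sign depends on which class it saw first; store an
  # orientation so that higher score always means attention
  sign_flip <- if (mean(dv[y == "attention"]) >= mean(dv[y == "inattention"])) 1 else -1
  structure(
    list(fit = fit, features = cols, C = C, gamma = gamma,
         sign_flip = sign_flip),
    class = "attention_svm"
  )
}

#' Predict with a trained attention SVM
#'
#' @param object An `attention_svm`.
#' @param newdata Standardized feature tibble with the model's feature
#'   columns.
#' @param ... Unused.
#' @return A tibble with `.pred_label` and continuous `.score` (higher =
#'   attention), one row per input row.
#' @export
predict.attention_svm <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    abort(sprintf("newdata lacks feature column(s): %s",
                  paste(head(missing_cols, 5L), collapse = ", ")),
          class = "attendr_schema_error")
  }
  x <- as.matrix(newdata[object$features])
  pr <- predict(object$fit, x, decision.values = TRUE)
  tibble::tibble(
    .pred_label = unname(as.character(pr)),
    .score = object$sign_flip * unname(attr(pr, "decision.values")[, 1L])
  )
}
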