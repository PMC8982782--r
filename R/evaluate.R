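#' Rank-based AUC
#'
#' Probability that a randomly drawn attention score exceeds a randomly drawn
#' inattention score, ties counting one half (the Mann-Whitney statistic).
#'
#' @param truth Character vector of true labels.
#' @param scores Continuous scores, higher = attention.
#' @param positive Positive class (default `"attention"`).
#' @return AUC in [0, 1]; `NA` with a warning if `truth` has one class.
#' @export
auc_rank <- function(truth, scores, positive = "attention") {
  pos <- truth == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined: truth contains a single class.")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for one train/test configuration
#'
#' Computes accuracy, rank-based AUC and F1 (attention as the positive class
#' by default, the majority class in CPT data) together with the 2x2 confusion
#' matrix, laid out with truth in rows (attention first) and prediction in
#' columns.
#'
#' @param truth,pred Character label vectors of equal length.
#' @param scores Optional continuous scores for AUC (higher = positive).
#' @param positive Positive class for F1 (default `"attention"`).
#' @return One-row tibble: `acc`, `auc`, `f1`, `tp`, `fn`, `fp`, `tn`,
#'   `n_test`. `tp` counts true-positive (attention) frames; `fn` attention
#'   frames predicted inattention; `fp` inattention frames predicted
#'   attention; `tn` the rest.
#' @examples
#' truth <- rep(c("attention", "inattention"), c(200, 30))
#' pred <- truth
#' pred[1:4] <- "inattention"   # 4 missed attention frames
#' pred[201:206] <- "attention" # 6 missed inattention frames
#' metric_suite(truth, pred)$acc # 220/230
#' @export
metric_suite <- function(truth, pred, scores = NULL, positive = "attention") {
  stopifnot(length(truth) == length(pred))
  negative <- setdiff(c("attention", "inattention"), positive)
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  n <- length(truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  auc <- if (!is.null(scores)) auc_rank(truth, scores, positive) else NA_real_
  tibble::tibble(acc = (tp + tn) / n, auc = auc, f1 = f1,
                 tp = tp, fn = fn, fp = fp, tn = tn, n_test = n)
}

#' Confusion matrix from a metric row
#' @param metrics One-row tibble from [metric_suite()].
#' @return 2x2 integer matrix, truth in rows (attention, inattention).
#' @export
confusion_matrix <- function(metrics) {
  matrix(c(metrics$tp, metrics$fp, metrics$fn, metrics$tn), 2L, 2L,
         dimnames = list(truth = c("attention", "inattention"),
                         predicted = c("attention", "inattention")))
}

# split rows 80/20 stratified by label; returns logical train mask
stratified_split_mask <- function(labels, train_fraction = 0.8) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
    train[idx[seq_len(n_tr)]] <- TRUE
  }
  train
}

fit_and_score <- function(train, test, model, ...) {
  m <- fit_attention_model(train, model = model, ...)
  pred <- predict(m, test)
  metric_suite(test$label, pred$.pred_label, pred$.score)
}

#' Participant-specific evaluation
#'
#' Trains and tests within each participant separately: repeated stratified
#' 80/20 frame splits per participant (default 10 repetitions), feature
#' selection and standardization refit on each training split, metrics
#' averaged over repetitions and then over participants. Participants lacking
#' one of the two classes are excluded with a warning.
#'
#' @param samples Labeled samples tibble covering several participants: for
#'   `model = "svm"` a feature tibble ([distance_features()]), for
#'   `model = "cnn"` a labeled frames tibble.
#' @param model `"svm"` or `"cnn"`.
#' @param reps Number of repeated splits per participant (default 10).
#' @param train_fraction Fraction of frames trained on (default 0.8).
#' @param seed Integer seed controlling all splits.
#' @param ... Passed to [fit_attention_model()] (e.g. `k`, `C`, `gamma`).
#' @return A list of class `attention_eval`: `per_split` (one row per
#'   participant x repetition), `per_participant` (means over repetitions),
#'   `summary` (means over participants), `regime`.
#' @export
participant_specific_eval <- function(samples, model = "svm", reps = 10,
                                      train_fraction = 0.8, seed = 1, ...) {
  set.seed(seed)
  per_split <- list()
  for (pid in unique(samples$participant_id)) {
    rows <- samples[samples$participant_id == pid, ]
    if (length(unique(rows$label)) < 2) {
      warn(sprintf("participant %s lacks a class; excluded.", pid))
      next
    }
    for (r in seq_len(reps)) {
      tr <- stratified_split_mask(rows$label, train_fraction)
      res <- fit_and_score(rows[tr, ], rows[!tr, ], model, ...)
      res$participant_id <- pid
      res$rep <- r
      per_split[[length(per_split) + 1L]] <- res
    }
  }
  per_split <- dplyr::bind_rows(per_split)
  per_participant <- dplyr::summarise(
    dplyr::group_by(per_split, .data$participant_id),
    dplyr::across(c("acc", "auc", "f1"), ~ mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  structure(
    list(per_split = per_split, per_participant = per_participant,
         summary = summarise_eval(per_participant),
         regime = "participant_specific"),
    class = "attention_eval"
  )
}

#' Leave-one-participant-out (generalized) evaluation
#'
#' For each participant, trains on all other participants and tests on the
#' held-out one — one fold per participant, with feature selection and
#' standardization refit inside each training fold so no information from the
#' test participant leaks in. Folds whose test participant lacks a class keep
#' ACC/F1 but have AUC flagged `NA` and excluded from the AUC average.
#'
#' @inheritParams participant_specific_eval
#' @return An `attention_eval` list: `per_participant` (one row per held-out
#'   participant), `summary`, `regime`.
#' @export
leave_one_participant_out <- function(samples, model = "svm", seed = 1, ...) {
  participants <- unique(samples$participant_id)
  if (length(participants) < 2) {
    abort("need at least 2 participants for leave-one-participant-out.",
          class = "attendr_configuration_error")
  }
  set.seed(seed)
  per_participant <- purrr::map_dfr(participants, function(pid) {
    test <- samples[samples$participant_id == pid, ]
    train <- samples[samples$participant_id != pid, ]
    res <- fit_and_score(train, test, model, ...)
    res$participant_id <- pid
    res
  })
  structure(
    list(per_participant = per_participant,
         summary = summarise_eval(per_participant),
         regime = "leave_one_participant_out"),
    class = "attention_eval"
  )
}

#' Bidirectional within- and cross-group evaluation
#'
#' Repeatedly splits each group's participants 80/20 (participant-level, so no
#' participant straddles train and test), trains on one group's training
#' participants and tests on each group's held-out participants: four cells
#' (train A / test A, train A / test B, train B / test A, train B / test B)
#' per iteration, 50 iterations by default.
#'
#' @param samples_a,samples_b Labeled samples tibbles for the two groups.
#' @param group_names Length-2 character names for the groups.
#' @param iterations Number of repeated participant-level splits (default 50).
#' @inheritParams participant_specific_eval
#' @return An `attention_eval` list: `per_iteration` (cell x iteration rows)
#'   and `summary` (mean and sd of ACC/AUC/F1 per cell), `regime`.
#' @export
cross_group_eval <- function(samples_a, samples_b,
                             group_names = c("A", "B"), iterations = 50,
                             model = "svm", train_fraction = 0.8, seed = 1,
                             ...) {
  set.seed(seed)
  groups <- list(samples_a, samples_b)
  names(groups) <- group_names
  pids <- lapply(groups, function(g) unique(g$participant_id))
  if (any(vapply(pids, length, integer(1)) < 2)) {
    abort("each group needs at least 2 participants for an 80/20 participant split.",
          class = "attendr_configuration_error")
  }
  per_iteration <- list()
  for (it in seq_len(iterations)) {
    split <- lapply(pids, function(p) {
      p <- sample(p)
      n_tr <- max(1L, min(length(p) - 1L, round(train_fraction * length(p))))
      list(train = p[seq_len(n_tr)], test = p[-seq_len(n_tr)])
    })
    models <- lapply(group_names, function(g) {
      tr <- groups[[g]][groups[[g]]$participant_id %in% split[[g]]$train, ]
      fit_attention_model(tr, model = model, ...)
    })
    names(models) <- group_names
    for (g_train in group_names) {
      for (g_test in group_names) {
        te <- groups[[g_test]][
          groups[[g_test]]$participant_id %in% split[[g_test]]$test, ]
        pred <- predict(models[[g_train]], te)
        res <- metric_suite(te$label, pred$.pred_label, pred$.score)
        res$train_group <- g_train
        res$test_group <- g_test
        res$iteration <- it
        per_iteration[[length(per_iteration) + 1L]] <- res
      }
    }
  }
  per_iteration <- dplyr::bind_rows(per_iteration)
  summary <- dplyr::summarise(
    dplyr::group_by(per_iteration, .data$train_group, .data$test_group),
    dplyr::across(c("acc", "auc", "f1"),
                  list(mean = ~ mean(.x, na.rm = TRUE),
                       sd = ~ sd(.x, na.rm = TRUE))),
    .groups = "drop"
  )
  structure(
    list(per_iteration = per_iteration, summary = summary,
         regime = "cross_group"),
    class = "attention_eval"
  )
}

#' Average evaluation metrics over rows
#'
#' The summary step used for every regime: plain arithmetic means of ACC, AUC
#' and F1 over the supplied rows (e.g. over participants), with `NA` AUCs
#' (single-class test sets) excluded from the AUC average.
#'
#' @param results Tibble with columns `acc`, `auc`, `f1`.
#' @return One-row tibble of means (plus `n`, the number of rows averaged).
#' @export
summarise_eval <- function(results) {
  tibble::tibble(
    acc = mean(results$acc, na.rm = TRUE),
    auc = mean(results$auc, na.rm = TRUE),
    f1 = mean(results$f1, na.rm = TRUE),
    n = nrow(results)
  )
}

#' @export
print.attention_eval <- function(x, ...) {
  cat(sprintf("<attention_eval: %s>\n", x$regime))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.attention_eval <- function(x, ...) {
  x$per_iteration %||% x$per_participant
}

#' @export
glance.attention_eval <- function(x, ...) {
  if (x$regime == "cross_group") x$summary else
    dplyr::mutate(x$summary, regime = x$regime)
}
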