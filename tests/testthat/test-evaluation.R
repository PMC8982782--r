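test_that("metric_suite computes ACC, F1 and the confusion matrix correctly", {
  truth <- rep(c("attention", "inattention"), c(200, 30))
  pred <- truth
  pred[1:4] <- "inattention"
  pred[201:206] <- "attention"
  m <- metric_suite(truth, pred)
  expect_equal(m$acc, 220 / 230)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(196, 4, 6, 24))
  cm <- confusion_matrix(m)
  expect_equal(unname(rowSums(cm)), c(200, 30))  # conservation by truth class
  expect_equal(sum(cm), m$n_test)
  prec <- 196 / 202; rec <- 196 / 200
  expect_equal(m$f1, 2 * prec * rec / (prec + rec))
  # perfect prediction
  p <- metric_suite(truth, truth, scores = as.numeric(truth == "attention"))
  expect_equal(c(p$acc, p$auc, p$f1), c(1, 1, 1))
  # constant scores give AUC 0.5 (all ties)
  expect_equal(metric_suite(truth, pred, scores = rep(1, 230))$auc, 0.5)
})

test_that("rank-based AUC equals the O(n^2) pairwise oracle, ties counted half", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    truth <- sample(c("attention", "inattention"), n, TRUE)
    if (length(unique(truth)) < 2) next
    scores <- sample(round(rnorm(n), 1))  # rounded to force ties
    pos <- scores[truth == "attention"]
    neg <- scores[truth == "inattention"]
    oracle <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc_rank(truth, scores), oracle, tolerance = 1e-12)
  }
  expect_warning(a <- auc_rank(rep("attention", 5), 1:5), "single class")
  expect_true(is.na(a))
})

test_that("participant-specific evaluation averages over splits and participants", {
  cfg <- het_config(21, n_per_group = 2, frames = 440, offset_sd = 4)
  feats <- cohort_features(generate_cohort(cfg))
  res <- suppressWarnings(
    participant_specific_eval(feats, reps = 2, seed = 3, k = 10)
  )
  # planted signal: high within-participant accuracy
  expect_gt(res$summary$acc, 0.85)
  # averaging math equals a hand-computed mean of the stored tables
  agg <- tapply(res$per_split$acc, res$per_split$participant_id, mean)
  expect_equal(sort(res$per_participant$acc),
               sort(as.vector(agg)), tolerance = 1e-12)
  expect_equal(res$summary$acc, mean(res$per_participant$acc))
  # shuffled labels destroy the signal
  shuf <- feats
  set.seed(4)
  shuf$label <- sample(shuf$label)
  null_res <- suppressWarnings(
    participant_specific_eval(shuf, reps = 2, seed = 3, k = 10)
  )
  expect_lt(abs(null_res$summary$auc - 0.5), 0.15)
})

test_that("LOPO has one fold per participant and never leaks participants", {
  cfg <- het_config(22, n_per_group = 2, frames = 440, offset_sd = 4)
  feats <- cohort_features(generate_cohort(cfg))
  res <- suppressWarnings(leave_one_participant_out(feats, seed = 5, k = 10))
  expect_equal(sort(res$per_participant$participant_id),
               sort(unique(feats$participant_id)))
  # each fold's test size equals that participant's row count (no straddling)
  counts <- table(feats$participant_id)
  expect_equal(res$per_participant$n_test,
               unname(as.integer(counts[res$per_participant$participant_id])))
  expect_error(leave_one_participant_out(feats[feats$participant_id == "A01", ]),
               class = "attendr_configuration_error")
})

test_that("cross-group cells are honored and orthogonal groups fail to transfer", {
  # two groups with opposite planted shift directions on disjoint features
  fa <- planted_features(25, n_features = 6, shift = 4, shifted = 1:2,
                         seed = 6, participant_id = "A1")
  fa2 <- planted_features(25, n_features = 6, shift = 4, shifted = 1:2,
                          seed = 7, participant_id = "A2")
  fb <- planted_features(25, n_features = 6, shift = 4, shifted = 3:4,
                         seed = 8, participant_id = "B1")
  fb2 <- planted_features(25, n_features = 6, shift = 4, shifted = 3:4,
                          seed = 9, participant_id = "B2")
  res <- cross_group_eval(dplyr::bind_rows(fa, fa2), dplyr::bind_rows(fb, fb2),
                          group_names = c("A", "B"), iterations = 4,
                          seed = 10, k = 4)
  expect_equal(nrow(res$per_iteration), 4 * 4)  # iterations honored exactly
  s <- res$summary
  within <- s$auc_mean[s$train_group == s$test_group]
  cross <- s$auc_mean[s$train_group != s$test_group]
  expect_gt(min(within), max(cross))
  expect_error(cross_group_eval(fa, dplyr::bind_rows(fb, fb2),
                                iterations = 1),
               class = "attendr_configuration_error")
})

test_that("tidiers expose per-unit results and summaries", {
  f <- planted_features(20, n_features = 5, shift = 4, seed = 11)
  m <- fit_attention_model(f, k = 3)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(nrow(tidy(m)), 3)
  g <- glance(m)
  expect_equal(g$kind, "svm")
  expect_equal(g$n_train, nrow(f))
})
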