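test_that("a one-cell grid is returned as-is and the search matches its oracle", {
  f <- planted_features(n_per_class = 25, n_features = 4, shift = 4, seed = 1)
  cfg1 <- svm_config(C_grid = 3, gamma_grid = 0.5, cv_folds = 5)
  got <- grid_search(f, cfg1, seed = 9)
  expect_equal(got$C, 3)
  expect_equal(got$gamma, 0.5)

  # exhaustive oracle: re-evaluate every grid cell with the same fold plan
  cfg <- svm_config(C_grid = c(1, 10), gamma_grid = c(0.01, 1), cv_folds = 4)
  got <- grid_search(f, cfg, seed = 9)
  fold <- attendr:::stratified_folds(f$label, 4, seed = 9)
  cols <- attendr:::feature_columns(f)
  x <- as.matrix(f[cols])
  y <- factor(f$label, levels = c("inattention", "attention"))
  oracle <- expand.grid(C = cfg$C_grid, gamma = cfg$gamma_grid)
  oracle$acc <- mapply(function(C, g) {
    correct <- 0
    for (k in 1:4) {
      fit <- e1071::svm(x[fold != k, ], y[fold != k], kernel = "radial",
                        cost = C, gamma = g, scale = FALSE)
      correct <- correct + sum(predict(fit, x[fold == k, ]) == y[fold == k])
    }
    correct / length(y)
  }, oracle$C, oracle$gamma)
  merged <- merge(got$grid, oracle, by = c("C", "gamma"))
  expect_equal(merged$cv_accuracy, merged$acc, tolerance = 1e-12)
  best <- oracle[order(-oracle$acc, oracle$C, oracle$gamma), ][1, ]
  expect_equal(got$C, best$C)
  expect_equal(got$gamma, best$gamma)
})

test_that("grid search demands both classes and enough rows per fold", {
  f <- planted_features(n_per_class = 25, seed = 2)
  single <- f[f$label == "attention", ]
  expect_error(grid_search(single, svm_config(cv_folds = 5)),
               class = "attendr_class_coverage_error")
  expect_error(grid_search(f[1:30, ], svm_config(cv_folds = 26)),
               class = "attendr_insufficient_data_error")
})

test_that("the RBF SVM separates planted blobs and fails on contradictions", {
  f <- planted_features(n_per_class = 30, n_features = 3, shift = 8, seed = 3)
  p <- standardize_fit(f)
  z <- standardize_apply(p, f)
  m <- train_svm(z)
  pred <- predict(m, z)
  expect_equal(mean(pred$.pred_label == z$label), 1)
  expect_error(train_svm(z[z$label == "attention", ]),
               class = "attendr_class_coverage_error")
  # duplicated contradictory points cannot exceed 50% on those points
  contra <- tibble::tibble(
    label = rep(c("attention", "inattention"), each = 20),
    f_0_1 = rep(c(0, 1), 20), f_0_2 = rep(c(0, 1), 20)
  )
  mc <- train_svm(contra, C = 1, gamma = 0.5)
  predc <- predict(mc, contra)
  expect_lte(mean(predc$.pred_label == contra$label), 0.5)
})

test_that("the RBF kernel beats a linear kernel on an XOR pattern", {
  set.seed(4)
  n <- 40
  x1 <- sample(c(0, 1), n, TRUE); x2 <- sample(c(0, 1), n, TRUE)
  f <- tibble::tibble(
    label = ifelse(xor(x1, x2), "attention", "inattention"),
    f_0_1 = x1 + rnorm(n, 0, 0.05), f_0_2 = x2 + rnorm(n, 0, 0.05)
  )
  rbf <- train_svm(f, C = 10, gamma = 1)
  acc_rbf <- mean(predict(rbf, f)$.pred_label == f$label)
  y <- factor(f$label, levels = c("inattention", "attention"))
  lin <- e1071::svm(as.matrix(f[c("f_0_1", "f_0_2")]), y, kernel = "linear",
                    cost = 10, scale = FALSE)
  acc_lin <- mean(predict(lin, as.matrix(f[c("f_0_1", "f_0_2")])) == y)
  expect_gt(acc_rbf, acc_lin)
})

test_that("predictions are row-wise, deterministic, and AUC-consistent", {
  f <- planted_features(n_per_class = 25, n_features = 4, shift = 2, seed = 5)
  p <- standardize_fit(f)
  z <- standardize_apply(p, f)
  m <- train_svm(z)
  pred1 <- predict(m, z)
  # permuted rows give permuted outputs
  perm <- sample(nrow(z))
  pred2 <- predict(m, z[perm, ])
  expect_equal(pred2$.score, pred1$.score[perm])
  # determinism under refit with identical data
  m2 <- train_svm(z)
  expect_equal(predict(m2, z)$.score, pred1$.score)
  # the stored scores drive AUC identical to the O(n^2) pairwise oracle
  pos <- pred1$.score[z$label == "attention"]
  neg <- pred1$.score[z$label == "inattention"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc_rank(z$label, pred1$.score), mean(cmp), tolerance = 1e-12)
  expect_error(predict(m, z[setdiff(names(z), "f_0_1")]),
               class = "attendr_schema_error")
})

test_that("held-out AUC does not improve as label noise increases", {
  noise_auc <- function(rate, seed) {
    f <- planted_features(n_per_class = 40, n_features = 3, shift = 2.5,
                          seed = seed)
    set.seed(seed + 1000)
    flip <- runif(nrow(f)) < rate
    f$noisy <- ifelse(flip, ifelse(f$label == "attention", "inattention",
                                   "attention"), f$label)
    tr <- attendr:::stratified_split_mask(f$noisy, 0.75)
    train <- f[tr, ]; test <- f[!tr, ]
    p <- standardize_fit(train)
    m <- train_svm(dplyr::mutate(standardize_apply(p, train),
                                 label = .data$noisy))
    sc <- predict(m, standardize_apply(p, test))$.score
    auc_rank(test$label, sc)  # scored against clean truth
  }
  set.seed(6)
  levels <- c(0, 0.2, 0.4)
  mean_auc <- vapply(levels, function(r) {
    mean(vapply(1:10, function(s) noise_auc(r, 100 * s), numeric(1)))
  }, numeric(1))
  # monotone hardness within sampling error
  expect_gte(mean_auc[1], mean_auc[2] - 0.03)
  expect_gte(mean_auc[2], mean_auc[3] - 0.03)
})
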