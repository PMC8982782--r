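test_that("class mean faces average coordinates over the class's valid frames", {
  frames <- random_frames(4, seed = 1)
  frames$label <- c("attention", "attention", "inattention", "invalid")
  frames$x_0 <- c(10, 20, 30, 40)
  one <- class_mean_face(frames[c(1, 3), ], "attention")
  expect_equal(one$x[1], 10)  # single frame: that frame's coordinates
  mf <- class_mean_face(frames, "attention")
  expect_equal(mf$x[1], 15)
  expect_equal(attr(mf, "n_frames"), 2)
  # brute-force per-coordinate oracle over all landmarks
  sub <- frames[frames$label == "attention", ]
  expect_equal(mf$x, unname(colMeans(sub[paste0("x_", 0:33)])))
  expect_equal(mf$y, unname(colMeans(sub[paste0("y_", 0:33)])))
  expect_error(class_mean_face(frames, "inattention")$x, NA)
  frames$label <- "attention"
  frames$valid <- FALSE
  expect_error(class_mean_face(frames, "attention"),
               class = "attendr_insufficient_data_error")
})

test_that("class mean distances match a brute-force mean oracle", {
  f <- planted_features(n_per_class = 10, n_features = 5, seed = 2)
  m <- class_mean_distances(f, "attention")
  sub <- f[f$label == "attention", ]
  expect_equal(m$mean_mm, unname(colMeans(sub[m$feature])))
  # identical rows give back that row; {100, 120} averages to 110
  g <- tibble::tibble(label = c("attention", "attention"),
                      f_0_1 = c(100, 120), f_0_2 = c(7, 7))
  mm <- class_mean_distances(g, "attention")
  expect_equal(mm$mean_mm[mm$feature == "f_0_1"], 110)
  expect_equal(mm$mean_mm[mm$feature == "f_0_2"], 7)
  expect_error(class_mean_distances(g, "inattention"),
               class = "attendr_insufficient_data_error")
})

test_that("distance thresholds reproduce printed per-pair differences", {
  att <- tibble::tibble(feature = c("f_3_15", "f_4_6"), mean_mm = c(146.9, 125.72))
  inatt <- tibble::tibble(feature = c("f_3_15", "f_4_6"), mean_mm = c(171.45, 149.17))
  tt <- distance_thresholds(att, inatt)
  expect_equal(tt$gf_mm[tt$feature == "f_3_15"], 24.55)
  expect_equal(tt$gf_mm[tt$feature == "f_4_6"], 23.45)
  # sorted descending
  expect_identical(tt$feature[1], "f_3_15")
  # identical class means give all-zero thresholds
  z <- distance_thresholds(att, att)
  expect_equal(z$gf_mm, c(0, 0))
  expect_error(distance_thresholds(att, inatt[1, ]),
               class = "attendr_schema_error")
})

test_that("thresholds are antisymmetric under class swap", {
  f <- planted_features(n_per_class = 15, n_features = 8, seed = 3)
  tt <- threshold_table(f)
  swapped <- f
  swapped$label <- ifelse(f$label == "attention", "inattention", "attention")
  tt2 <- threshold_table(swapped)
  merged <- dplyr::inner_join(tt[c("feature", "gf_mm")],
                              tt2[c("feature", "gf_mm")], by = "feature")
  expect_equal(merged$gf_mm.x, -merged$gf_mm.y, tolerance = 1e-12)
})

test_that("select_top_k is deterministic, nested, and matches a sort oracle", {
  set.seed(4)
  f <- planted_features(n_per_class = 20, n_features = 60,
                        shifted = 1:30, shift = 0, seed = 4)
  tt <- threshold_table(f)
  expect_equal(nrow(select_top_k(tt, nrow(tt))), nrow(tt))
  # k = 1 picks the max-gf pair
  expect_equal(select_top_k(tt, 1)$gf_mm, max(tt$gf_mm))
  # nesting: top-10 is a prefix of top-20
  expect_identical(select_top_k(tt, 10)$feature_id,
                   select_top_k(tt, 20)$feature_id[1:10])
  # brute-force oracle including the tie rule (smaller feature_id first)
  k <- 10
  ord <- order(-tt$gf_mm, tt$feature_id)
  expect_identical(select_top_k(tt, k)$feature_id, tt$feature_id[ord[1:k]])
  expect_error(select_top_k(tt, 0), class = "attendr_domain_error")
  expect_error(select_top_k(tt, nrow(tt) + 1), class = "attendr_domain_error")
})

test_that("exact ties break towards the smaller feature_id", {
  att <- tibble::tibble(feature = c("f_0_1", "f_0_2", "f_0_3"),
                        mean_mm = c(10, 10, 10))
  inatt <- tibble::tibble(feature = c("f_0_1", "f_0_2", "f_0_3"),
                          mean_mm = c(12, 12, 13))
  tt <- distance_thresholds(att, inatt)
  sel <- select_top_k(tt, 2)
  expect_identical(sel$feature, c("f_0_3", "f_0_1"))
})

test_that("threshold tables export in the reference CSV layout", {
  withr::with_tempfile("f", fileext = ".csv", {
    feats <- planted_features(n_per_class = 8, n_features = 4, seed = 5)
    write_threshold_table(threshold_table(feats), f)
    out <- readr::read_csv(f, show_col_types = FALSE)
    expect_identical(names(out), c("pair", "description",
                                   "inattention_mean_mm",
                                   "attention_mean_mm", "gf_mm"))
    expect_false(is.unsorted(rev(out$gf_mm)))
  })
})
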