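test_that("rasterization maps landmarks to the documented pixels", {
  # 34 distinct pixel positions -> 34 set pixels
  px <- c(0:31, 0, 1)
  py <- c(0:31, 1, 0)
  b <- list(xmin = 0, xmax = 340, ymin = 0, ymax = 340)
  x <- (px + 0.5) * 340 / 32
  y <- (py + 0.5) * 340 / 32
  img <- rasterize_frame(x, y, bounds = b)
  expect_equal(sum(img), 34)
  # all landmarks coincident -> exactly one set pixel
  img1 <- rasterize_frame(rep(5, 34), rep(5, 34),
                          bounds = list(xmin = 0, xmax = 10, ymin = 0, ymax = 10))
  expect_equal(sum(img1), 1)
  # random frames: pixel set equals the direct per-landmark mapping
  set.seed(1)
  for (rep in 1:5) {
    x <- runif(34, -70, 70); y <- runif(34, -90, 40)
    b <- list(xmin = -80, xmax = 80, ymin = -100, ymax = 50)
    img <- rasterize_frame(x, y, bounds = b)
    px <- pmin(pmax(floor((x - b$xmin) / (b$xmax - b$xmin) * 32), 0), 31)
    py <- pmin(pmax(floor((y - b$ymin) / (b$ymax - b$ymin) * 32), 0), 31)
    oracle <- matrix(0L, 32, 32)
    oracle[cbind(py + 1, px + 1)] <- 1L
    expect_identical(img, oracle)
  }
  expect_error(rasterize_frame(x, y, bounds = list(xmin = 1, xmax = 1,
                                                   ymin = 0, ymax = 1)),
               class = "attendr_domain_error")
  expect_error(rasterize_frame(c(NA, x[-1]), y), class = "attendr_domain_error")
})

test_that("per-frame bounds make rasters invariant to translation and scale", {
  set.seed(2)
  x <- runif(34, -60, 60); y <- runif(34, -80, 30)
  img <- rasterize_frame(x, y)
  img_ts <- rasterize_frame(3 * x + 500, 3 * y - 200)
  expect_identical(img, img_ts)
})

test_that("the network has the hand-computed parameter count", {
  # conv1: 32 maps x (3x3x1 + 1) = 320
  # conv2: 64 maps x (3x3x32 + 1) = 18496
  # dense1: 62 x (6*6*64 + 1) = 142910 ; dense2: 1 x (62 + 1) = 63
  expect_equal(cnn_n_parameters(cnn_config()), 320 + 18496 + 142910 + 63)
  dm <- attendr:::cnn_dims(cnn_config())
  expect_equal(c(dm$h1, dm$h1p, dm$h2, dm$h2p, dm$flat),
               c(30, 15, 13, 6, 2304))
})

test_that("training reduces loss and learns a planted half-plane signal", {
  hp <- halfplane_images(60, seed = 3)
  tr <- c(1:45, 61:105)
  te <- setdiff(1:120, tr)
  fit <- train_cnn(hp$images[, , tr], hp$labels[tr],
                   cnn_config(epochs = 6, seed = 4))
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  pred <- predict(fit, hp$images[, , te])
  expect_gte(mean(pred$.pred_label == hp$labels[te]), 0.9)
  expect_true(all(pred$.score >= 0 & pred$.score <= 1))
  expect_error(train_cnn(hp$images[, , 1:10], rep("attention", 10)),
               class = "attendr_class_coverage_error")
})

test_that("evaluation-mode scoring is deterministic and batch-invariant", {
  hp <- halfplane_images(20, seed = 5)
  fit <- train_cnn(hp$images, hp$labels, cnn_config(epochs = 2, seed = 6))
  batch <- predict(fit, hp$images)$.score
  single <- vapply(seq_len(40), function(r) {
    predict(fit, hp$images[, , r, drop = FALSE])$.score
  }, numeric(1))
  expect_equal(batch, single, tolerance = 1e-6)
  # identical images get identical scores
  twice <- array(hp$images[, , c(1, 1)], dim = c(32, 32, 2))
  sc <- predict(fit, twice)$.score
  expect_equal(sc[1], sc[2])
  expect_error(predict(fit, array(0, dim = c(16, 16, 2))),
               class = "attendr_schema_error")
  # refitting with the same seed reproduces scores exactly
  fit2 <- train_cnn(hp$images, hp$labels, cnn_config(epochs = 2, seed = 6))
  expect_equal(predict(fit2, hp$images)$.score, batch)
})

test_that("convolution backpropagation matches numerical gradients", {
  # small random net, finite-difference check on a few weights of each layer
  cfg <- cnn_config(conv1_maps = 2, conv2_maps = 3, dense_units = 4,
                    dropout_rate = 0, epochs = 1, seed = 7)
  set.seed(7)
  state <- list(dm = attendr:::cnn_dims(cfg),
                idx1 = attendr:::im2col_index(32L, 32L, 1L, 3L))
  state$idx2 <- attendr:::im2col_index(state$dm$h1p, state$dm$h1p, 2L, 3L)
  params <- attendr:::init_cnn_params(cfg)
  x <- array(round(runif(32 * 32 * 2)), dim = c(32, 32, 1, 2))
  y <- c(1, 0)
  loss_fn <- function(p) {
    fw <- attendr:::cnn_forward(p, x, cfg, state, training = FALSE)
    pr <- pmin(pmax(fw$score, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  fw <- attendr:::cnn_forward(params, x, cfg, state, training = FALSE)
  grads <- attendr:::cnn_backward(params, fw, y, cfg, state)
  eps <- 1e-5
  for (nm in c("W1", "b2", "W3", "W4", "b4")) {
    k <- sample(length(params[[nm]]), 1)
    pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
    pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
    numeric_grad <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    expect_equal(grads[[nm]][k], numeric_grad, tolerance = 1e-4)
  }
})
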