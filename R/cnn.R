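#' Convolutional network configuration
#'
#' Fixed small topology for 32x32 binary landmark rasters: two valid 3x3
#' convolutions of 32 and 64 feature maps, each followed by 2x2 max-pooling,
#' then fully connected layers of 62 and 1 units with a 20% dropout before the
#' output stage. Hidden activations are rectifiers; the output is a sigmoid
#' score in [0, 1] (attention = 1). Training uses the adaptive-moment
#' optimizer on binary cross-entropy.
#'
#' @param conv1_maps,conv2_maps Feature maps per convolution (32, 64).
#' @param kernel Convolution kernel side (3).
#' @param pool Max-pool side (2).
#' @param dense_units Width of the hidden dense layer (62).
#' @param dropout_rate Dropout probability in [0, 1) (0.2).
#' @param epochs,batch_size,learning_rate Training schedule (30, 32, 1e-3).
#' @param validation_fraction Fraction of training rows held out to monitor
#'   accuracy during training.
#' @param seed Integer seed fixing initialization, shuffling and dropout.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(conv1_maps = 32, conv2_maps = 64, kernel = 3, pool = 2,
                       dense_units = 62, dropout_rate = 0.2, epochs = 30,
                       batch_size = 32, learning_rate = 1e-3,
                       validation_fraction = 0.1, seed = 1) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, kernel >= 1, pool >= 1)
  structure(
    list(conv1_maps = conv1_maps, conv2_maps = conv2_maps, kernel = kernel,
         pool = pool, dense_units = dense_units, dropout_rate = dropout_rate,
         epochs = epochs, batch_size = batch_size,
         learning_rate = learning_rate,
         validation_fraction = validation_fraction, seed = seed),
    class = "cnn_config"
  )
}

# ---- internal tensor ops (column-major arrays, batch last) -----------------

# flat-index map for im2col: rows = kernel positions x input channels,
# cols = output positions, entries index into an (H, W, C) array
im2col_index <- function(H, W, C, k) {
  Ho <- H - k + 1L
  Wo <- W - k + 1L
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, k * k * C, Ho * Wo)
  r <- 0L
  for (c in seq_len(C)) {
    for (dw in 0:(k - 1L)) {
      for (dh in 0:(k - 1L)) {
        r <- r + 1L
        idx[r, ] <- (ho + dh) + (wo + dw - 1L) * H + (c - 1L) * H * W
      }
    }
  }
  idx
}

# x: (H, W, C, B) -> cols (k*k*C, P*B), columns ordered position-fastest
im2col <- function(x, idx) {
  d <- dim(x)
  B <- d[4L]
  HWC <- prod(d[1:3])
  P <- ncol(idx)
  xf <- as.vector(x)
  cols <- matrix(0, nrow(idx), P * B)
  for (b in seq_len(B)) {
    cols[, (b - 1L) * P + seq_len(P)] <- xf[idx + (b - 1L) * HWC]
  }
  cols
}

# scatter-add gradient of im2col back to the input tensor
col2im <- function(dcols, idx, dims) {
  B <- dims[4L]
  HWC <- prod(dims[1:3])
  P <- ncol(idx)
  dx <- numeric(HWC * B)
  offs <- rep((seq_len(B) - 1L) * HWC, each = P)
  for (r in seq_len(nrow(idx))) {
    tgt <- rep(idx[r, ], B) + offs
    dx[tgt] <- dx[tgt] + dcols[r, ]
  }
  array(dx, dim = dims)
}

conv_forward <- function(x, W, b, idx) {
  cols <- im2col(x, idx)
  out <- W %*% cols + b           # (F, P*B)
  list(out = out, cols = cols)
}

# reshape conv output (F, P*B) into an (Ho, Wo, F, B) activation tensor
conv_to_tensor <- function(out, Ho, Wo, B) {
  Fm <- nrow(out)
  a <- array(t(out), dim = c(Ho, Wo, B, Fm))  # rows are p-fastest within b
  aperm(a, c(1L, 2L, 4L, 3L))
}

tensor_to_conv <- function(a) {
  d <- dim(a)  # (Ho, Wo, F, B)
  t(matrix(aperm(a, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L]))
}

maxpool_forward <- function(x, pool = 2L) {
  d <- dim(x)
  Ho <- d[1L] %/% pool
  Wo <- d[2L] %/% pool
  i1 <- seq(1L, Ho * pool, by = pool)
  j1 <- seq(1L, Wo * pool, by = pool)
  s <- vector("list", pool * pool)
  n <- 0L
  for (dj in 0:(pool - 1L)) {
    for (di in 0:(pool - 1L)) {
      n <- n + 1L
      s[[n]] <- x[i1 + di, j1 + dj, , , drop = FALSE]
    }
  }
  out <- s[[1L]]
  for (n in 2:length(s)) out <- pmax(out, s[[n]])
  list(out = out, slices = s, in_dim = d, i1 = i1, j1 = j1)
}

maxpool_backward <- function(pf, dout, pool = 2L) {
  dx <- array(0, dim = pf$in_dim)
  taken <- array(FALSE, dim = dim(dout))
  n <- 0L
  for (dj in 0:(pool - 1L)) {
    for (di in 0:(pool - 1L)) {
      n <- n + 1L
      mask <- (pf$slices[[n]] == pf$out) & !taken
      taken <- taken | mask
      dx[pf$i1 + di, pf$j1 + dj, , ] <-
        dx[pf$i1 + di, pf$j1 + dj, , ] + mask * dout
    }
  }
  dx
}

cnn_dims <- function(config, size = 32L) {
  k <- config$kernel
  p <- config$pool
  h1 <- size - k + 1L          # after conv1
  h1p <- h1 %/% p              # after pool1
  h2 <- h1p - k + 1L           # after conv2
  h2p <- h2 %/% p              # after pool2
  list(h1 = h1, h1p = h1p, h2 = h2, h2p = h2p,
       flat = h2p * h2p * config$conv2_maps)
}

init_cnn_params <- function(config, size = 32L) {
  k <- config$kernel
  dm <- cnn_dims(config, size)
  he <- function(nr, nc, fan_in) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  list(
    W1 = he(config$conv1_maps, k * k, k * k),
    b1 = numeric(config$conv1_maps),
    W2 = he(config$conv2_maps, k * k * config$conv1_maps,
            k * k * config$conv1_maps),
    b2 = numeric(config$conv2_maps),
    W3 = he(config$dense_units, dm$flat, dm$flat),
    b3 = numeric(config$dense_units),
    W4 = matrix(rnorm(config$dense_units, sd = sqrt(1 / config$dense_units)),
                1L, config$dense_units),
    b4 = 0
  )
}

cnn_forward <- function(params, x, config, state, training = FALSE,
                        dropout_mask = NULL) {
  B <- dim(x)[4L]
  dm <- state$dm
  c1 <- conv_forward(x, params$W1, params$b1, state$idx1)
  a1 <- conv_to_tensor(c1$out, dm$h1, dm$h1, B)
  r1 <- pmax(a1, 0)
  p1 <- maxpool_forward(r1, config$pool)
  c2 <- conv_forward(p1$out, params$W2, params$b2, state$idx2)
  a2 <- conv_to_tensor(c2$out, dm$h2, dm$h2, B)
  r2 <- pmax(a2, 0)
  p2 <- maxpool_forward(r2, config$pool)
  flat <- matrix(p2$out, dm$flat, B)
  z3 <- params$W3 %*% flat + params$b3
  a3 <- pmax(z3, 0)
  if (training && config$dropout_rate > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(
        (runif(length(a3)) >= config$dropout_rate) / (1 - config$dropout_rate),
        nrow(a3), ncol(a3)
      )
    }
    a3d <- a3 * dropout_mask
  } else {
    a3d <- a3
  }
  z4 <- params$W4 %*% a3d + params$b4
  score <- 1 / (1 + exp(-as.vector(z4)))
  list(score = score, x = x, c1 = c1, a1 = a1, r1 = r1, p1 = p1,
       c2 = c2, a2 = a2, r2 = r2, p2 = p2, flat = flat, z3 = z3, a3 = a3,
       a3d = a3d, dropout_mask = dropout_mask)
}

cnn_backward <- function(params, fw, y, config, state) {
  B <- length(y)
  dm <- state$dm
  dz4 <- matrix((fw$score - y) / B, 1L, B)
  gW4 <- dz4 %*% t(fw$a3d)
  gb4 <- sum(dz4)
  da3 <- t(params$W4) %*% dz4
  if (!is.null(fw$dropout_mask)) da3 <- da3 * fw$dropout_mask
  dz3 <- da3 * (fw$z3 > 0)
  gW3 <- dz3 %*% t(fw$flat)
  gb3 <- rowSums(dz3)
  dflat <- t(params$W3) %*% dz3
  dp2 <- array(dflat, dim = dim(fw$p2$out))
  dr2 <- maxpool_backward(fw$p2, dp2, config$pool)
  da2 <- dr2 * (fw$a2 > 0)
  dc2 <- tensor_to_conv(da2)
  gW2 <- dc2 %*% t(fw$c2$cols)
  gb2 <- rowSums(dc2)
  dcols2 <- t(params$W2) %*% dc2
  dp1 <- col2im(dcols2, state$idx2, dim(fw$p1$out))
  dr1 <- maxpool_backward(fw$p1, dp1, config$pool)
  da1 <- dr1 * (fw$a1 > 0)
  dc1 <- tensor_to_conv(da1)
  gW1 <- dc1 %*% t(fw$c1$cols)
  gb1 <- rowSums(dc1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4)
}

adam_step <- function(params, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / (1 - beta1^t)
    vhat <- opt$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Number of trainable parameters of the network
#'
#' Closed-form count from the topology: each convolution contributes
#' `maps * (kernel^2 * in_channels + 1)` weights, each dense layer
#' `out * (in + 1)`.
#'
#' @param x A `cnn_config` or a trained `attention_cnn`.
#' @return Integer parameter count.
#' @export
cnn_n_parameters <- function(x) {
  if (inherits(x, "attention_cnn")) x <- x$config
  stopifnot(inherits(x, "cnn_config"))
  sum(vapply(init_cnn_params(x), length, integer(1)))
}

#' Train the convolutional attention classifier
#'
#' Trains the fixed-topology network of [cnn_config()] on binary landmark
#' raster images with the adaptive-moment optimizer and binary cross-entropy
#' loss. A stratified validation split monitors held-out accuracy per epoch.
#' Training is deterministic given the config seed.
#'
#' @param images Array `32 x 32 x n` of 0/1 rasters (see
#'   [rasterize_frames()]).
#' @param labels Character vector (`"attention"`/`"inattention"`) or 0/1
#'   numeric (attention = 1), length n.
#' @param config A [cnn_config()].
#' @return An object of class `attention_cnn` with the fitted weights, config
#'   and per-epoch `history`.
#' @export
train_cnn <- function(images, labels, config = cnn_config()) {
  y <- cnn_encode_labels(labels)
  if (length(unique(y)) < 2) {
    abort("training data must contain both classes.",
          class = "attendr_class_coverage_error")
  }
  n <- dim(images)[3L]
  stopifnot(length(y) == n)
  set.seed(config$seed)
  state <- list(
    dm = cnn_dims(config),
    idx1 = im2col_index(32L, 32L, 1L, config$kernel),
    idx2 = NULL
  )
  state$idx2 <- im2col_index(state$dm$h1p, state$dm$h1p, config$conv1_maps,
                             config$kernel)
  params <- init_cnn_params(config)
  opt <- list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val >= 2) {
    # stratified: take proportional heads per class from a shuffled order
    idx <- integer(0)
    for (cl in unique(y)) {
      cl_idx <- sample(which(y == cl))
      idx <- c(idx, head(cl_idx, max(1L, round(config$validation_fraction *
                                                 length(cl_idx)))))
    }
    idx
  } else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  history <- tibble::tibble(epoch = integer(), loss = numeric(),
                            val_accuracy = numeric())
  t_step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batch_losses <- numeric(0)
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      xb <- array(images[, , bidx, drop = FALSE],
                  dim = c(32L, 32L, 1L, length(bidx)))
      fw <- cnn_forward(params, xb, config, state, training = TRUE)
      p <- pmin(pmax(fw$score, 1e-12), 1 - 1e-12)
      batch_losses <- c(batch_losses,
                        -mean(y[bidx] * log(p) + (1 - y[bidx]) * log(1 - p)))
      grads <- cnn_backward(params, fw, y[bidx], config, state)
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, opt, config$learning_rate, t_step)
      params <- upd$params
      opt <- upd$opt
    }
    val_acc <- if (length(val_idx) > 0) {
      sc <- cnn_scores(params, images[, , val_idx, drop = FALSE], config, state)
      mean((sc >= 0.5) == (y[val_idx] == 1))
    } else NA_real_
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, loss = mean(batch_losses), val_accuracy = val_acc
    ))
  }
  structure(
    list(params = params, config = config, state = state, history = history,
         n_train = length(tr_idx)),
    class = "attention_cnn"
  )
}

cnn_encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    as.numeric(labels)
  } else {
    stopifnot(all(labels %in% c("attention", "inattention")))
    as.numeric(labels == "attention")
  }
}

cnn_scores <- function(params, images, config, state, chunk = 256L) {
  if (length(dim(images)) == 2L) images <- array(images, dim = c(dim(images), 1L))
  n <- dim(images)[3L]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    xb <- array(images[, , idx, drop = FALSE], dim = c(32L, 32L, 1L, length(idx)))
    out[idx] <- cnn_forward(params, xb, config, state, training = FALSE)$score
  }
  out
}

#' Predict with a trained convolutional classifier
#'
#' Evaluation-mode forward pass (dropout off): deterministic, and identical
#' whether images are scored in batches or one at a time.
#'
#' @param object An `attention_cnn`.
#' @param images Array `32 x 32 x n` (or a single 32x32 matrix).
#' @param ... Unused.
#' @return A tibble with `.pred_label` (score >= 0.5 means attention) and
#'   `.score` in [0, 1].
#' @export
predict.attention_cnn <- function(object, images, ...) {
  dims <- dim(images)
  if (dims[1L] != 32L || dims[2L] != 32L) {
    abort("images must be 32 x 32 rasters.", class = "attendr_schema_error")
  }
  sc <- cnn_scores(object$params, images, object$config, object$state)
  tibble::tibble(
    .pred_label = ifelse(sc >= 0.5, "attention", "inattention"),
    .score = sc
  )
}
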