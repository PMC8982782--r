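# Shared fixtures: all built programmatically at test time.

# a frames tibble with random coordinates (valid unless stated)
random_frames <- function(n = 5, seed = 1) {
  set.seed(seed)
  coords <- matrix(runif(n * 68, -80, 80), n, 68)
  colnames(coords) <- attendr:::coord_columns()
  dplyr::bind_cols(
    tibble::tibble(frame = seq_len(n) - 1L,
                   timestamp_ms = (seq_len(n) - 1L) * 62.5,
                   valid = TRUE),
    tibble::as_tibble(coords)
  )
}

random_session <- function(n = 5, seed = 1, ...) {
  landmark_session(random_frames(n, seed), ...)
}

# a labeled feature tibble with a planted mean shift on `shifted` features
planted_features <- function(n_per_class = 30, n_features = 10, shift = 3,
                             shifted = 1:2, sd = 1, seed = 1,
                             participant_id = "P1") {
  set.seed(seed)
  n <- 2 * n_per_class
  label <- rep(c("attention", "inattention"), each = n_per_class)
  pt <- pair_table()
  cols <- pt$feature[seq_len(n_features)]
  x <- matrix(rnorm(n * n_features, mean = 100, sd = sd), n, n_features,
              dimnames = list(NULL, cols))
  x[label == "inattention", shifted] <- x[label == "inattention", shifted] + shift
  dplyr::bind_cols(
    tibble::tibble(participant_id = participant_id,
                   frame = seq_len(n) - 1L, label = label),
    tibble::as_tibble(x)
  )
}

# binary rasters with dots confined to the left or right image half
halfplane_images <- function(n_per_class, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  arr <- array(0L, dim = c(32, 32, n))
  side <- rep(c("L", "R"), each = n_per_class)
  for (r in seq_len(n)) {
    px <- sample(if (side[r] == "L") 0:15 else 16:31, 34, replace = TRUE)
    py <- sample(0:31, 34, replace = TRUE)
    m <- matrix(0L, 32, 32)
    m[cbind(py + 1L, px + 1L)] <- 1L
    arr[, , r] <- m
  }
  list(images = arr,
       labels = rep(c("attention", "inattention"), each = n_per_class))
}

# small heterogeneous synthetic cohort used by evaluation-regime tests
het_config <- function(seed, n_per_group = 3, frames = 660,
                       offset_sd = 10) {
  synthetic_config(
    n_per_group = n_per_group, frames_per_participant = frames,
    participant_offset_sd = offset_sd, yaw_side_prob = 0.5,
    p_attention_stay = 0.85, seed = seed
  )
}

ref_path <- function(file) system.file("extdata", file, package = "attendr")
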