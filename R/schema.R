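# 34-point face schema used by consumer landmark SDKs. The index -> name map is
# fixed; note 12 (nose tip) and 29 (top lower lip) sit out of visual sequence.
.landmark_names <- c(
  "right top jaw",            # 0
  "right jaw angle",          # 1
  "gnathion",                 # 2
  "left jaw angle",           # 3
  "left top jaw",             # 4
  "outer right brow",         # 5
  "right brow corner",        # 6
  "inner right brow corner",  # 7
  "inner left brow corner",   # 8
  "left brow center",         # 9
  "outer left brow corner",   # 10
  "nose root",                # 11
  "nose tip",                 # 12
  "nose lower right boundary",# 13
  "nose bottom boundary",     # 14
  "nose lower left boundary", # 15
  "outer right eye",          # 16
  "inner right eye",          # 17
  "inner left eye",           # 18
  "outer left eye",           # 19
  "right lip corner",         # 20
  "right apex upper lip",     # 21
  "upper lip center",         # 22
  "left apex upper lip",      # 23
  "left lip corner",          # 24
  "left edge lower lip",      # 25
  "lower lip center",         # 26
  "right edge lower lip",     # 27
  "bottom lower lip",         # 28
  "top lower lip",            # 29
  "upper corner right eye",   # 30
  "lower corner right eye",   # 31
  "upper corner left eye",    # 32
  "lower corner left eye"     # 33
)

#' Number of landmarks and landmark pairs
#'
#' The face schema has 34 named landmarks, giving `choose(34, 2) = 561`
#' unordered landmark pairs. All pairwise distances are used as the feature
#' pool; [pair_table()] enumerates them in canonical order.
#'
#' @return `n_landmarks()` returns 34; `n_pairs()` returns 561.
#' @export
n_landmarks <- function() length(.landmark_names)

#' @rdname n_landmarks
#' @export
n_pairs <- function() choose(n_landmarks(), 2L)

#' The 34-landmark face schema
#'
#' Returns the ordered landmark schema: index 0 is the right top jaw, index 33
#' the lower corner of the left eye. "Left"/"right" refer to the subject's own
#' left and right.
#'
#' @return A tibble with columns `index` (integer, 0-33) and `name`.
#' @examples
#' landmark_schema()
#' @export
landmark_schema <- function() {
  tibble::tibble(index = seq_along(.landmark_names) - 1L, name = .landmark_names)
}

#' Canonical feature id of a landmark pair
#'
#' Every unordered pair of distinct landmark indices maps to a canonical
#' `feature_id`: the rank (0-based) of the pair in lexicographic order over all
#' `(i, j)` with `i < j`. The map is order-insensitive and bijective over the
#' 561 pairs.
#'
#' @param i,j Integer landmark indices in 0-33, `i != j`. Vectorised.
#' @return Integer vector of feature ids in `0:560`.
#' @examples
#' pair_index(0, 1)   # 0
#' pair_index(33, 32) # 560
#' @export
pair_index <- function(i, j) {
  n <- n_landmarks()
  i <- vec_as_landmark(i, "i")
  j <- vec_as_landmark(j, "j")
  if (any(i == j)) {
    abort("`i` and `j` must name two distinct landmarks.", class = "attendr_domain_error")
  }
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  as.integer(lo * n - lo * (lo + 1L) / 2L + (hi - lo - 1L))
}

vec_as_landmark <- function(x, arg) {
  if (length(x) == 0 || anyNA(x) || any(x != floor(x)) || any(x < 0) ||
      any(x > n_landmarks() - 1L)) {
    abort(
      sprintf("`%s` must contain integer landmark indices in 0..%d.", arg, n_landmarks() - 1L),
      class = "attendr_domain_error"
    )
  }
  as.integer(x)
}

#' Enumerate all landmark pairs
#'
#' Lists every unordered landmark pair in canonical `feature_id` order together
#' with the feature column name used throughout the package (`f_<i>_<j>`) and a
#' human-readable description built from the schema names.
#'
#' @param drop_pair Optional length-2 integer vector naming one pair to drop
#'   (for strict replication against sources that use a 560-pair pool).
#' @return A tibble with columns `feature_id`, `i`, `j`, `feature`,
#'   `description`.
#' @export
pair_table <- function(drop_pair = NULL) {
  n <- n_landmarks()
  idx <- utils::combn(seq_len(n) - 1L, 2L)
  out <- tibble::tibble(
    feature_id = seq_len(ncol(idx)) - 1L,
    i = idx[1L, ],
    j = idx[2L, ],
    feature = paste0("f_", idx[1L, ], "_", idx[2L, ]),
    description = paste0(.landmark_names[idx[1L, ] + 1L], " - ",
                         .landmark_names[idx[2L, ] + 1L])
  )
  if (!is.null(drop_pair)) {
    stopifnot(length(drop_pair) == 2L)
    out <- out[out$feature_id != pair_index(drop_pair[1L], drop_pair[2L]), ]
  }
  out
}

#' Feature column name for a landmark pair
#' @param i,j Landmark indices (vectorised); order-insensitive.
#' @return Character vector like `"f_3_15"`.
#' @export
pair_feature_name <- function(i, j) {
  paste0("f_", pmin(i, j), "_", pmax(i, j))
}

# columns of a data frame that hold pairwise-distance features
feature_columns <- function(x) grep("^f_[0-9]+_[0-9]+$", names(x), value = TRUE)

coord_columns <- function() {
  idx <- seq_len(n_landmarks()) - 1L
  as.vector(rbind(paste0("x_", idx), paste0("y_", idx)))
}
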