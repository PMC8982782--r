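#' Normalization bounds for rasterizing a frame
#'
#' Default bounds are the frame's own landmark bounding box expanded so that
#' landmarks keep a margin of whole pixels from the raster edge. Per-frame
#' bounds discard absolute pose/scale (each face fills the raster); passing a
#' shared box to [rasterize_frame()] instead preserves pose across frames.
#'
#' @param x,y Length-34 landmark coordinates (mm).
#' @param margin_px Margin in pixels (default 1).
#' @param size Raster side length in pixels (default 32).
#' @return A list with `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
frame_bounds <- function(x, y, margin_px = 1, size = 32) {
  expand <- function(lo, hi) {
    w <- hi - lo
    if (w <= 0) w <- 1
    pad <- margin_px * w / (size - 2 * margin_px)
    c(lo - pad, lo - pad + w * size / (size - 2 * margin_px))
  }
  bx <- expand(min(x), max(x))
  by <- expand(min(y), max(y))
  list(xmin = bx[1], xmax = bx[2], ymin = by[1], ymax = by[2])
}

#' Rasterize one landmark frame to a binary image
#'
#' Maps each landmark to the pixel
#' `(floor((x - xmin) / w * size), floor((y - ymin) / h * size))`, clipped to
#' the raster, and sets it to 1 on a 0 background (a white-dots-on-black
#' image). Coincident landmarks share a pixel, so an image holds between 1 and
#' 34 set pixels.
#'
#' @param x,y Length-34 landmark coordinates (mm).
#' @param bounds Normalization box (see [frame_bounds()]); defaults to the
#'   frame's own box.
#' @param size Raster side length (default 32).
#' @return A `size x size` integer matrix of 0/1 (rows indexed by y).
#' @export
rasterize_frame <- function(x, y, bounds = NULL, size = 32) {
  if (anyNA(x) || anyNA(y)) {
    abort("cannot rasterize a frame with missing coordinates.",
          class = "attendr_domain_error")
  }
  bounds <- bounds %||% frame_bounds(x, y, size = size)
  w <- bounds$xmax - bounds$xmin
  h <- bounds$ymax - bounds$ymin
  if (w <= 0 || h <= 0) {
    abort("bounds must have positive width and height.",
          class = "attendr_domain_error")
  }
  px <- pmin(pmax(floor((x - bounds$xmin) / w * size), 0), size - 1)
  py <- pmin(pmax(floor((y - bounds$ymin) / h * size), 0), size - 1)
  img <- matrix(0L, size, size)
  img[cbind(py + 1L, px + 1L)] <- 1L
  img
}

#' Rasterize a table of frames
#'
#' Converts labeled landmark frames into the 32x32 binary images consumed by
#' the convolutional classifier. Invalid frames (and `"invalid"` labels) are
#' skipped.
#'
#' @param frames Labeled frames tibble (see [annotate_session()]).
#' @param bounds `NULL` for per-frame bounding boxes (default), or a shared
#'   bounds list applied to every frame.
#' @param size Raster side length.
#' @return A list with `images` (array `size x size x n`) and `meta` (tibble
#'   with `participant_id`, `frame`, and `label` if present).
#' @export
rasterize_frames <- function(frames, bounds = NULL, size = 32) {
  keep <- if ("valid" %in% names(frames)) frames$valid else rep(TRUE, nrow(frames))
  if ("label" %in% names(frames)) keep <- keep & frames$label != "invalid"
  frames <- frames[keep, ]
  mats <- session_coord_matrices(frames)
  n <- nrow(frames)
  images <- array(0L, dim = c(size, size, n))
  for (r in seq_len(n)) {
    images[, , r] <- rasterize_frame(mats$x[r, ], mats$y[r, ],
                                     bounds = bounds, size = size)
  }
  meta <- tibble::tibble(
    participant_id = if ("participant_id" %in% names(frames))
      frames$participant_id else NA_character_,
    frame = frames$frame
  )
  if ("label" %in% names(frames)) meta$label <- frames$label
  list(images = images, meta = meta)
}

#' Write a raster image as a PNG for inspection
#'
#' @param img A 0/1 raster matrix from [rasterize_frame()].
#' @param path Output path.
#' @export
write_raster_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write PNG images.")
  }
  png::writePNG(img, path)
  invisible(path)
}
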