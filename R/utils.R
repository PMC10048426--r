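# Input checks shared across modules. Images are integer-valued arrays in
# [0, 255]: scenes are h x w x 3, grayscale and label rasters are h x w
# matrices, masks are logical matrices.

abort_grainscan <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "grainscan_error"), ...)
}

assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort_grainscan(
      sprintf("`%s` must be an h x w x 3 array", arg),
      "grainscan_invalid_input"
    )
  }
  if (any(image < 0 | image > 255, na.rm = TRUE)) {
    abort_grainscan(
      sprintf("`%s` must hold 8-bit values in [0, 255]", arg),
      "grainscan_invalid_input"
    )
  }
  invisible(image)
}

assert_gray_image <- function(gray, arg = "gray") {
  if (!is.matrix(gray) || length(gray) == 0L) {
    abort_grainscan(
      sprintf("`%s` must be a non-empty matrix", arg),
      "grainscan_invalid_input"
    )
  }
  if (any(gray < 0 | gray > 255, na.rm = TRUE)) {
    abort_grainscan(
      sprintf("`%s` must hold 8-bit values in [0, 255]", arg),
      "grainscan_invalid_input"
    )
  }
  invisible(gray)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_grainscan(
      sprintf("`%s` must be a logical matrix", arg),
      "grainscan_invalid_input"
    )
  }
  invisible(mask)
}

# Shift a matrix by (dr, dc), padding the vacated band with `fill`.
shift_matrix <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Chebyshev (box) dilation by radius r: TRUE wherever any pixel within the
# (2r+1)^2 neighbourhood is TRUE.
dilate_box <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    out <- out | shift_matrix(mask, dr, dc, FALSE)
  }
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 8-bit PNG I/O for scenes (values 0..255).
write_scene_png <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

read_scene_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

# Label rasters: 8-bit grey PNG when max label fits a byte, otherwise the
# label id is packed into the red/green channels (id = 256 * R + G).
write_label_png <- function(labels, path) {
  stopifnot(is.matrix(labels))
  mx <- max(labels)
  if (mx <= 255L) {
    png::writePNG(labels / 255, path)
  } else {
    hi <- labels %/% 256L
    lo <- labels %% 256L
    arr <- array(0, c(dim(labels), 3L))
    arr[, , 1] <- hi / 255
    arr[, , 2] <- lo / 255
    png::writePNG(arr, path)
  }
  invisible(path)
}

read_label_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) {
    lab <- round(x * 255)
  } else {
    lab <- round(x[, , 1] * 255) * 256L + round(x[, , 2] * 255)
  }
  storage.mode(lab) <- "integer"
  lab
}
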