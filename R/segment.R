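# Segmentation chain: median denoise -> grayscale -> Otsu threshold ->
# erosion markers -> marker-based watershed -> region extraction.

#' 5 x 5 median filter
#'
#' Applies a 5 x 5 median filter independently to each channel, the standard
#' cure for salt-and-pepper noise. Borders use reflect (symmetric) padding.
#'
#' @param image h x w x 3 array or h x w matrix with 8-bit values.
#' @return Filtered image, same shape.
#' @export
median_filter_5x5 <- function(image) {
  if (is.matrix(image)) {
    assert_gray_image(image)
    if (min(dim(image)) < 5L) {
      abort_grainscan("image must be at least 5 x 5", "grainscan_invalid_input")
    }
    return(median5_channel(image))
  }
  assert_rgb_image(image)
  if (min(dim(image)[1:2]) < 5L) {
    abort_grainscan("image must be at least 5 x 5", "grainscan_invalid_input")
  }
  out <- image
  for (ch in 1:3) out[, , ch] <- median5_channel(image[, , ch])
  out
}

#' RGB to 8-bit grayscale
#'
#' Luma conversion `round(0.299 R + 0.587 G + 0.114 B)`.
#'
#' @param image h x w x 3 array, 8-bit values.
#' @return Integer-valued h x w matrix in `[0, 255]`.
#' @export
to_grayscale <- function(image) {
  assert_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  g <- round(0.299 * matrix(image[, , 1], h, w) +
               0.587 * matrix(image[, , 2], h, w) +
               0.114 * matrix(image[, , 3], h, w))
  clamp(g, 0, 255)
}

#' Normalised intensity histogram
#'
#' `p(k) = count(k) / total` over the 256 intensity levels.
#'
#' @param gray 8-bit grayscale matrix.
#' @return An `intensity_histogram`: numeric length 256 (index k+1 holds
#'   p(k)), summing to 1.
#' @export
intensity_histogram <- function(gray) {
  assert_gray_image(gray)
  counts <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  structure(counts / length(gray), class = "intensity_histogram")
}

#' Otsu's threshold from a histogram
#'
#' For every candidate threshold t the histogram is split into a lower class
#' (k < t) and an upper class (k >= t); their probabilities U0, U1, means
#' m0, m1 and the between-class variance
#' `Vb2(t) = U0(t) U1(t) (m0(t) - m1(t))^2` are computed, and the smallest t
#' attaining the maximum variance is returned. The full per-threshold trace
#' is retained for inspection.
#'
#' @param hist An [intensity_histogram()] (any non-negative length-256 vector
#'   summing to 1 is accepted).
#' @return An `otsu_trace` list: `trace` tibble (t, U0, U1, m0, m1, Vb2),
#'   `thresh`, `Vb2_max`.
#' @export
otsu_threshold <- function(hist) {
  p <- as.numeric(hist)
  if (length(p) != 256L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort_grainscan("hist must be a length-256 probability vector",
                    "grainscan_invalid_input")
  }
  if (sum(p > 0) < 2L) {
    abort_grainscan("histogram has fewer than two occupied intensities",
                    "grainscan_degenerate_histogram")
  }
  k <- 0:255
  t_cand <- 0:255
  U0 <- c(0, cumsum(p)[1:255])          # mass of k < t
  U1 <- 1 - U0
  cmk <- c(0, cumsum(k * p)[1:255])     # first moment of k < t
  mu_tot <- sum(k * p)
  m0 <- ifelse(U0 > 0, cmk / U0, NA_real_)
  m1 <- ifelse(U1 > 0, (mu_tot - cmk) / U1, NA_real_)
  Vb2 <- ifelse(U0 > 0 & U1 > 0, U0 * U1 * (m0 - m1)^2, 0)
  best <- which.max(Vb2)               # first maximiser
  structure(
    list(
      trace = tibble(t = t_cand, U0 = U0, U1 = U1, m0 = m0, m1 = m1, Vb2 = Vb2),
      thresh = t_cand[best],
      Vb2_max = Vb2[best]
    ),
    class = "otsu_trace"
  )
}

#' @export
print.otsu_trace <- function(x, ...) {
  cat(sprintf("Otsu threshold: %d (between-class variance %.4f)\n",
              x$thresh, x$Vb2_max))
  invisible(x)
}

#' Plot the Otsu between-class variance trace
#'
#' @param object An `otsu_trace`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.otsu_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$t, y = .data$Vb2)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$thresh, linetype = 2) +
    ggplot2::labs(x = "threshold t", y = "between-class variance")
}

#' Binarise a grayscale image
#'
#' Foreground is `gray >= thresh`: grains are brighter than the dark
#' background, and Otsu's upper class is the `k >= t` class.
#'
#' @param gray 8-bit grayscale matrix.
#' @param thresh Threshold intensity in `[0, 255]`, or an `otsu_trace`.
#' @return Logical mask, TRUE = foreground.
#' @export
binarize <- function(gray, thresh) {
  assert_gray_image(gray)
  if (inherits(thresh, "otsu_trace")) thresh <- thresh$thresh
  if (thresh < 0 || thresh > 255) {
    abort_grainscan("thresh must lie in [0, 255]", "grainscan_invalid_input")
  }
  gray >= thresh
}

#' Binary erosion with a 3 x 3 structuring element
#'
#' A pixel survives iff all nine pixels of its 3 x 3 neighbourhood are
#' foreground; outside the image counts as background, so the result is
#' always a subset of the input.
#'
#' @param mask Logical matrix.
#' @param iterations Number of erosion passes (default 1).
#' @return Eroded logical matrix.
#' @export
erode_3x3 <- function(mask, iterations = 1L) {
  assert_mask(mask)
  out <- mask
  for (it in seq_len(iterations)) {
    acc <- out
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      acc <- acc & shift_matrix(out, dr, dc, FALSE)
    }
    out <- acc
  }
  out
}

#' Label 8-connected components
#'
#' Connected-component analysis of a binary mask with 8-connectivity;
#' components are numbered 1..n in raster-scan (row-major, reading) order of
#' their first pixel.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_markers <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  # bwlabel is 4-connected: union labels that touch diagonally
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    sh <- shift_matrix(lab, off[1], off[2], 0L)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) {
      prs <- unique(cbind(lab[sel], sh[sel]))
      for (r in seq_len(nrow(prs))) {
        ra <- find(prs[r, 1]); rb <- find(prs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab2 <- matrix(0L, nrow(mask), ncol(mask))
  lab2[lab > 0L] <- roots[lab[lab > 0L]]
  # renumber in raster-scan (row-major) order of first occurrence
  idx <- which(lab2 > 0L)
  scan_key <- (row(lab2)[idx] - 1L) * ncol(lab2) + col(lab2)[idx]
  first_seen <- tapply(scan_key, lab2[idx], min)
  remap <- integer(n)
  remap[as.integer(names(first_seen))] <- rank(first_seen, ties.method = "first")
  lab2[idx] <- remap[lab2[idx]]
  lab2
}

#' Marker-based watershed segmentation
#'
#' Grows each marker through the foreground mask over an inverted-grayscale
#' terrain (grains as basins), assigning every reachable foreground pixel to
#' exactly one marker. Backed by `EBImage::propagate`, the standard
#' marker-based region-growing segmenter.
#'
#' @param gray 8-bit grayscale matrix.
#' @param markers Integer label matrix (the eroded-component labels).
#' @param fg Logical foreground mask from [binarize()].
#' @return Integer label matrix; 0 = background, k >= 1 = grain labels.
#' @export
watershed_segment <- function(gray, markers, fg) {
  assert_gray_image(gray)
  assert_mask(fg)
  if (!any(markers > 0L)) {
    abort_grainscan("no markers to grow", "grainscan_no_marker")
  }
  if (any(markers > 0L & !fg)) {
    abort_grainscan("markers must lie inside the foreground mask",
                    "grainscan_invalid_input")
  }
  terrain <- (255 - gray) / 255
  out <- EBImage::propagate(terrain, seeds = markers, mask = fg)
  matrix(as.integer(out), nrow(gray), ncol(gray))
}

#' A segmented grain region
#'
#' @param label Integer region id.
#' @param mask_crop Logical crop of the grain mask.
#' @param rgb_crop RGB crop (same height/width), 8-bit values.
#' @param bbox `c(row0, col0, row1, col1)`, 0-based half-open.
#' @param contour Optional ordered boundary coordinates (computed lazily by
#'   [trace_contour()] when omitted).
#' @return A `grain_region` list with `area_px` filled in.
#' @export
grain_region <- function(label, mask_crop, rgb_crop, bbox, contour = NULL) {
  assert_mask(mask_crop, "mask_crop")
  structure(
    list(label = as.integer(label), bbox = as.integer(bbox),
         mask_crop = mask_crop, rgb_crop = rgb_crop,
         contour = contour, area_px = sum(mask_crop)),
    class = "grain_region"
  )
}

#' Extract per-grain regions from a label map
#'
#' Crops each label to its tight bounding box and drops regions the
#' merged-grain filter flags: the watershed cannot split genuinely touching
#' grains, so blobs larger than `merge_factor` times the scene's median
#' region area are rejected (and reported), as are specks below `min_area`.
#'
#' @param labels Integer label matrix.
#' @param image Source RGB scene (same height/width).
#' @param merge_factor Area multiple of the median region area above which a
#'   region is suspected of being merged grains (default 1.8).
#' @param min_area Minimum area in pixels for a region to be kept.
#' @param min_solidity Convexity confirmation for the merged-grain filter: a
#'   large region is only rejected when its solidity also falls below this
#'   value (touching grains form a concave waist; a legitimately large single
#'   grain stays near-convex). Set to 1 to reject on area alone.
#' @return List: `regions` (list of [grain_region()]), `rejects` (tibble:
#'   label, area_px, reason).
#' @export
extract_regions <- function(labels, image, merge_factor = 1.8, min_area = 25,
                            min_solidity = 0.95) {
  assert_rgb_image(image)
  if (!all(dim(labels) == dim(image)[1:2])) {
    abort_grainscan("labels and image sizes differ", "grainscan_invalid_input")
  }
  ids <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (length(ids) == 0L) {
    return(list(regions = list(),
                rejects = tibble(label = integer(), area_px = integer(),
                                 reason = character())))
  }
  areas <- vapply(ids, function(i) sum(labels == i), integer(1))
  med <- median(areas)
  regions <- list()
  rej <- list()
  for (j in seq_along(ids)) {
    i <- ids[j]
    if (areas[j] < min_area) {
      rej[[length(rej) + 1L]] <- tibble(label = i, area_px = areas[j],
                                        reason = "too_small")
      next
    }
    sel <- labels == i
    rr <- range(which(rowSums(sel) > 0))
    cc <- range(which(colSums(sel) > 0))
    mask <- sel[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    contour <- trace_contour(mask)
    if (areas[j] > merge_factor * med) {
      hull_idx <- grDevices::chull(contour[, 2], contour[, 1])
      hull_xy <- cbind(contour[hull_idx, 2], contour[hull_idx, 1])
      solidity <- areas[j] /
        convex_raster_area(hull_xy, nrow(mask), ncol(mask))
      if (solidity < min_solidity) {
        rej[[length(rej) + 1L]] <- tibble(label = i, area_px = areas[j],
                                          reason = "merged")
        next
      }
    }
    regions[[length(regions) + 1L]] <- grain_region(
      label = i, mask_crop = mask,
      rgb_crop = image[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE],
      bbox = c(rr[1] - 1L, cc[1] - 1L, rr[2], cc[2]),
      contour = contour
    )
  }
  rejects <- if (length(rej)) dplyr::bind_rows(rej) else
    tibble(label = integer(), area_px = integer(), reason = character())
  list(regions = regions, rejects = rejects)
}

#' Run the full segmentation chain on a scene image
#'
#' Median filter, grayscale, Otsu threshold, erosion markers, connected
#' components, marker-based watershed, region extraction.
#'
#' @param image h x w x 3 scene array, 8-bit values.
#' @param erosion_iterations Erosion passes for marker generation.
#' @param merge_factor,min_area Passed to [extract_regions()].
#' @return List: `regions`, `rejects`, `labels` (final label map), `otsu`
#'   (the threshold trace), `mask` (Otsu foreground).
#' @export
segment_scene <- function(image, erosion_iterations = 1L,
                          merge_factor = 1.8, min_area = 25) {
  assert_rgb_image(image)
  filtered <- median_filter_5x5(image)
  gray <- to_grayscale(filtered)
  ot <- otsu_threshold(intensity_histogram(gray))
  fg <- binarize(gray, ot)
  eroded <- erode_3x3(fg, iterations = erosion_iterations)
  markers <- label_markers(eroded)
  if (!any(markers > 0L)) {
    return(list(regions = list(),
                rejects = tibble(label = integer(), area_px = integer(),
                                 reason = character()),
                labels = matrix(0L, nrow(gray), ncol(gray)),
                otsu = ot, mask = fg))
  }
  labels <- watershed_segment(gray, markers, fg)
  ex <- extract_regions(labels, filtered, merge_factor = merge_factor,
                        min_area = min_area)
  c(ex, list(labels = labels, otsu = ot, mask = fg))
}
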