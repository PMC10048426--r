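# Per-grain feature blocks: geometry/morphology (18), colour histograms
# (48 bins x 6 channels = 288) and GLCM texture statistics (6 x 4 angles = 24).

#' Trace the closed boundary of a single-component mask
#'
#' Moore-neighbour tracing with Jacob's stopping criterion; returns the
#' ordered 8-connected boundary pixel sequence of the (single) foreground
#' component.
#'
#' @param mask Logical matrix with exactly one 8-connected component.
#' @return Integer matrix with columns `r`, `c` (1-based crop coordinates).
#' @export
trace_contour <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) {
    abort_grainscan("mask is empty", "grainscan_invalid_region")
  }
  lab <- label_markers(mask)
  if (max(lab) != 1L) {
    abort_grainscan("mask must hold exactly one connected component",
                    "grainscan_invalid_region")
  }
  nr <- nrow(mask); nc <- ncol(mask)
  tmask <- t(mask)
  first <- which(tmask)[1]  # raster (row-major) order
  r0 <- (first - 1L) %/% nc + 1L
  c0 <- (first - 1L) %% nc + 1L
  if (sum(mask) == 1L) return(cbind(r = r0, c = c0))

  # clockwise 8-neighbour ring starting north
  dirs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  fg <- function(p) p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc &&
    mask[p[1], p[2]]
  start <- c(r0, c0)
  cur <- start
  b <- 7L  # backtrack direction: west of the start is background by scan order
  pts <- list(start)
  first_next <- NULL
  limit <- 4L * sum(mask) + 8L
  repeat {
    nxt <- NULL
    dprev <- b
    for (s in 1:8) {
      d <- ((b - 1L + s) %% 8L) + 1L
      cand <- cur + dirs[d, ]
      if (fg(cand)) { nxt <- cand; break }
      dprev <- d
    }
    if (is.null(nxt)) break  # isolated pixel (guarded earlier)
    if (all(cur == start)) {
      if (is.null(first_next)) first_next <- nxt
      else if (all(nxt == first_next)) break  # Jacob's stopping criterion
    }
    # new backtrack: the last background neighbour checked, seen from nxt
    bpix <- cur + dirs[dprev, ]
    delta <- bpix - nxt
    b <- which(dirs[, 1] == delta[1] & dirs[, 2] == delta[2])
    cur <- nxt
    pts[[length(pts) + 1L]] <- cur
    if (length(pts) > limit) {
      abort_grainscan("contour tracing failed to close",
                      "grainscan_invalid_region")
    }
  }
  out <- do.call(rbind, pts)
  # the walk re-appends the start on closing; drop the trailing duplicate
  if (nrow(out) > 1L && all(out[nrow(out), ] == out[1, ])) {
    out <- out[-nrow(out), , drop = FALSE]
  }
  colnames(out) <- c("r", "c")
  out
}

# Perimeter estimate from the closed contour chain code.
# Corner-corrected weights (Vossepoel-Smeulders): axial 0.980, diagonal
# 1.406, minus 0.091 per direction change; low bias across orientations.
# The chain runs through boundary-pixel centres, i.e. half a pixel inside
# the true region outline; offsetting a closed convex curve outward by half
# a pixel lengthens it by 2 * pi * 0.5, hence the + pi term.
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n == 1L) return(4)  # single pixel: unit square boundary
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  dr <- nxt[, 1] - contour[, 1]
  dc <- nxt[, 2] - contour[, 2]
  keep <- !(dr == 0 & dc == 0)
  dr <- dr[keep]; dc <- dc[keep]
  diag_step <- dr != 0 & dc != 0
  dir_code <- paste(sign(dr), sign(dc))
  corners <- sum(dir_code != c(dir_code[length(dir_code)],
                               dir_code[-length(dir_code)]))
  0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * corners + pi
}

# Pixel-centre count inside (or on) a convex polygon, by row scanning.
convex_raster_area <- function(hull_xy, nr, nc) {
  hx <- hull_xy[, 1]; hy <- hull_xy[, 2]
  m <- length(hx)
  if (m == 1L) return(1L)
  if (m == 2L) {
    # degenerate hull: count centres on the segment
    return(sum(vapply(seq_len(nr), function(r) {
      dx <- hx[2] - hx[1]; dy <- hy[2] - hy[1]
      cnt <- 0L
      for (cc in seq_len(nc)) {
        cross <- dx * (r - hy[1]) - dy * (cc - hx[1])
        if (abs(cross) < 1e-9 &&
            cc >= min(hx) - 1e-9 && cc <= max(hx) + 1e-9 &&
            r >= min(hy) - 1e-9 && r <= max(hy) + 1e-9) cnt <- cnt + 1L
      }
      cnt
    }, integer(1))))
  }
  x2 <- c(hx[-1], hx[1]); y2 <- c(hy[-1], hy[1])
  total <- 0L
  for (r in seq_len(nr)) {
    xs <- numeric(0)
    for (e in seq_len(m)) {
      ylo <- min(hy[e], y2[e]); yhi <- max(hy[e], y2[e])
      if (r < ylo - 1e-9 || r > yhi + 1e-9) next
      if (abs(hy[e] - y2[e]) < 1e-12) {
        xs <- c(xs, hx[e], x2[e])
      } else {
        t <- (r - hy[e]) / (y2[e] - hy[e])
        xs <- c(xs, hx[e] + t * (x2[e] - hx[e]))
      }
    }
    if (length(xs) == 0) next
    lo <- ceiling(min(xs) - 1e-9); hi <- floor(max(xs) + 1e-9)
    if (hi >= lo) total <- total + (min(hi, nc) - max(lo, 1L) + 1L)
  }
  total
}

geometry_feature_names <- function() {
  c("area", "perimeter", "equivalent_diameter", "length", "width",
    "aspect_ratio", "convex_area", "solidity", "extent", "bbox_w", "bbox_h",
    "roundness", "compactness", "shape_factor", "eccentricity", "orientation",
    "hull_perimeter", "perimeter_ratio")
}

#' Geometry and morphology features of a grain region
#'
#' Computes the 18-value geometry block. Length and width are the major and
#' minor axes of the moment-matched ellipse (the ellipse with the same
#' second-order central moments as the pixel set), `equivalent_diameter`
#' is `sqrt(4 A / pi)`, `roundness = 4 pi A / P^2`, `compactness = P^2 / A`,
#' `shape_factor = A / (L l)`, `solidity = A / convex_area`, and
#' `extent = A / (bbox_w bbox_h)`.
#'
#' @param region A [grain_region()].
#' @return Named numeric vector of the 18 geometry features.
#' @export
geometry_features <- function(region) {
  stopifnot(inherits(region, "grain_region"))
  mask <- region$mask_crop
  A <- sum(mask)
  if (A == 0L) abort_grainscan("empty region", "grainscan_invalid_region")
  contour <- region$contour %||% trace_contour(mask)
  P <- chain_perimeter(contour)

  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l2 <= 1e-9) {
    abort_grainscan("degenerate (line-like) region", "grainscan_degenerate_shape")
  }
  L <- 4 * sqrt(l1)
  l <- 4 * sqrt(l2)
  orientation <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  eccentricity <- sqrt(1 - l2 / l1)

  hull_idx <- grDevices::chull(contour[, 2], contour[, 1])  # (x, y)
  hull_xy <- cbind(contour[hull_idx, 2], contour[hull_idx, 1])
  convex_area <- convex_raster_area(hull_xy, nrow(mask), ncol(mask))
  hx2 <- rbind(hull_xy[-1, , drop = FALSE], hull_xy[1, , drop = FALSE])
  hull_perimeter <- sum(sqrt(rowSums((hx2 - hull_xy)^2)))
  if (hull_perimeter <= 0) hull_perimeter <- P

  bbox_h <- nrow(mask); bbox_w <- ncol(mask)
  out <- c(
    area = A,
    perimeter = P,
    equivalent_diameter = sqrt(4 * A / pi),
    length = L,
    width = l,
    aspect_ratio = L / l,
    convex_area = convex_area,
    solidity = A / convex_area,
    extent = A / (bbox_w * bbox_h),
    bbox_w = bbox_w,
    bbox_h = bbox_h,
    roundness = 4 * pi * A / P^2,
    compactness = P^2 / A,
    shape_factor = A / (L * l),
    eccentricity = eccentricity,
    orientation = orientation,
    hull_perimeter = hull_perimeter,
    perimeter_ratio = P / hull_perimeter
  )
  out[geometry_feature_names()]
}

#' RGB to HSV conversion
#'
#' `V = max(R, G, B)`; `S = (M - m) / M` for `M > 0`, else 0; hue by the
#' standard sector formula with `+360` wrap for negatives. Vectorised.
#'
#' @param r,g,b Numeric vectors in `[0, 255]`.
#' @param scale255 If TRUE, hue and saturation are rescaled to `[0, 255]`
#'   (hue via `H / 360 * 255`) for uniform histogram binning; value is
#'   already on the 8-bit scale.
#' @return Matrix with columns `h`, `s`, `v`. Unscaled: `h` in `[0, 360)`,
#'   `s` in `[0, 1]`, `v` in `[0, 255]`.
#' @export
rgb_to_hsv_grain <- function(r, g, b, scale255 = FALSE) {
  M <- pmax(r, g, b)
  m <- pmin(r, g, b)
  d <- M - m
  s <- ifelse(M > 0, d / M, 0)
  h <- numeric(length(r))
  nz <- d > 0
  hr <- nz & M == r
  hg <- nz & M == g & !hr
  hb <- nz & M == b & !hr & !hg
  h[hr] <- 60 * ((g[hr] - b[hr]) / d[hr])
  h[hg] <- 60 * (2 + (b[hg] - r[hg]) / d[hg])
  h[hb] <- 60 * (4 + (r[hb] - g[hb]) / d[hb])
  h[h < 0] <- h[h < 0] + 360
  if (scale255) {
    cbind(h = h / 360 * 255, s = s * 255, v = M)
  } else {
    cbind(h = h, s = s, v = M)
  }
}

#' Colour-histogram block of a grain region
#'
#' 48-bin histograms (bin index `floor(value * bins / 256)`) of the six
#' channels R, G, B, H, S, V over the grain's pixels. By default only pixels
#' inside the grain mask are counted; `mode = "bbox"` counts every pixel of
#' the bounding box.
#'
#' @param region A [grain_region()].
#' @param bins Bins per channel (default 48).
#' @param mode `"mask"` (default) or `"bbox"`.
#' @return Named numeric vector of `6 * bins` counts, channel-major in the
#'   order R, G, B, H, S, V.
#' @export
channel_histograms <- function(region, bins = 48L, mode = c("mask", "bbox")) {
  stopifnot(inherits(region, "grain_region"))
  mode <- match.arg(mode)
  sel <- if (mode == "mask") region$mask_crop else
    matrix(TRUE, nrow(region$mask_crop), ncol(region$mask_crop))
  if (!any(sel)) abort_grainscan("empty region", "grainscan_invalid_region")
  r <- region$rgb_crop[, , 1][sel]
  g <- region$rgb_crop[, , 2][sel]
  b <- region$rgb_crop[, , 3][sel]
  hsv <- rgb_to_hsv_grain(r, g, b, scale255 = TRUE)
  chans <- list(R = r, G = g, B = b, H = hsv[, "h"], S = hsv[, "s"],
                V = hsv[, "v"])
  out <- unlist(lapply(names(chans), function(nm) {
    bin <- pmin(floor(chans[[nm]] * bins / 256), bins - 1L)
    cnt <- tabulate(bin + 1L, nbins = bins)
    setNames(cnt, sprintf("%s_bin%02d", nm, seq_len(bins)))
  }))
  out
}

glcm_offsets <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

#' Grey-level co-occurrence matrix
#'
#' Counts ordered intensity pairs `(i, j)` at the unit offset of the given
#' angle (0, 45, 90 or 135 degrees; offsets `(0,1)`, `(-1,1)`, `(-1,0)`,
#' `(-1,-1)` in row/column order). Both the pixel and its neighbour must lie
#' inside the mask. The matrix is 256 x 256, not symmetrised.
#'
#' @param gray_crop 8-bit grayscale matrix.
#' @param mask_crop Logical matrix, or NULL for the full crop.
#' @param angle One of 0, 45, 90, 135.
#' @return List: `G` (counts), `p` (normalised), `angle`, `offset`,
#'   `n_pairs`.
#' @export
glcm <- function(gray_crop, mask_crop = NULL, angle = 0) {
  assert_gray_image(gray_crop, "gray_crop")
  offs <- glcm_offsets()
  key <- as.character(angle)
  if (!key %in% names(offs)) {
    abort_grainscan("angle must be one of 0, 45, 90, 135",
                    "grainscan_invalid_input")
  }
  d <- offs[[key]]
  h <- nrow(gray_crop); w <- ncol(gray_crop)
  if (is.null(mask_crop)) mask_crop <- matrix(TRUE, h, w)
  rs <- seq_len(h); cs <- seq_len(w)
  rok <- rs + d[1] >= 1L & rs + d[1] <= h
  cok <- cs + d[2] >= 1L & cs + d[2] <= w
  src <- as.matrix(expand.grid(r = rs[rok], c = cs[cok]))
  if (nrow(src) == 0) {
    abort_grainscan("no valid pixel pairs for this offset",
                    "grainscan_empty_pairs")
  }
  dst <- cbind(src[, 1] + d[1], src[, 2] + d[2])
  ok <- mask_crop[src] & mask_crop[dst]
  if (!any(ok)) {
    abort_grainscan("no valid pixel pairs inside the mask",
                    "grainscan_empty_pairs")
  }
  i <- as.integer(gray_crop[src[ok, , drop = FALSE]])
  j <- as.integer(gray_crop[dst[ok, , drop = FALSE]])
  cnt <- tabulate(i * 256L + j + 1L, nbins = 256L * 256L)
  G <- matrix(cnt, 256L, 256L, byrow = TRUE)  # G[i + 1, j + 1]
  list(G = G, p = G / sum(G), angle = angle, offset = d, n_pairs = sum(G))
}

#' Haralick statistics of a normalised GLCM
#'
#' Contrast `sum (i-j)^2 p`, dissimilarity `sum |i-j| p`, homogeneity
#' `sum p / (1 + |i-j|)`, angular second moment `sum p^2`, energy
#' `sqrt(ASM)`, and correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` with moments taken from
#' the marginals of `p`; correlation is defined as 1 when either marginal
#' standard deviation vanishes (constant image).
#'
#' @param p Normalised GLCM (non-negative, sums to 1).
#' @return Named numeric: `CON`, `DIS`, `HO`, `ASM`, `EN`, `CORR`.
#' @export
glcm_stats <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p) || any(p < 0)) {
    abort_grainscan("p must be a square non-negative matrix",
                    "grainscan_invalid_distribution")
  }
  if (abs(sum(p) - 1) > 1e-6) {
    abort_grainscan("p must sum to 1", "grainscan_invalid_distribution")
  }
  n <- nrow(p)
  lev <- 0:(n - 1L)
  I <- matrix(lev, n, n)        # row index i
  J <- t(I)                     # column index j
  D <- I - J
  CON <- sum(D^2 * p)
  DIS <- sum(abs(D) * p)
  HO <- sum(p / (1 + abs(D)))
  ASM <- sum(p^2)
  EN <- sqrt(ASM)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj_)
  s_i <- sqrt(sum((lev - mu_i)^2 * pi_))
  s_j <- sqrt(sum((lev - mu_j)^2 * pj_))
  CORR <- if (s_i * s_j == 0) 1 else
    sum((I - mu_i) * (J - mu_j) * p) / (s_i * s_j)
  c(CON = CON, DIS = DIS, HO = HO, ASM = ASM, EN = EN, CORR = CORR)
}

#' Texture block of a grain region
#'
#' The six Haralick statistics of the masked 256-level GLCM at each of the
#' four standard angles, 24 values total.
#'
#' @param region A [grain_region()].
#' @param angles Angles in degrees.
#' @return Named numeric vector (`CON_0`, `DIS_0`, ..., `CORR_135`).
#' @export
texture_features <- function(region, angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(region, "grain_region"))
  gray <- to_grayscale(region$rgb_crop)
  out <- unlist(lapply(angles, function(a) {
    g <- glcm(gray, region$mask_crop, angle = a)
    st <- glcm_stats(g$p)
    setNames(st, paste0(names(st), "_", a))
  }))
  out
}

#' Feature registry
#'
#' Fixes the names, order and configuration of the feature vector so that
#' column meaning is reproducible: 18 geometry features, `6 * bins` colour
#' histogram counts, and `6 * length(angles)` texture statistics.
#'
#' @param bins Histogram bins per channel (default 48).
#' @param angles GLCM angles in degrees.
#' @param hist_mode `"mask"` or `"bbox"`, see [channel_histograms()].
#' @return A `feature_registry` list with `names`, per-block names and the
#'   configuration.
#' @export
feature_registry <- function(bins = 48L, angles = c(0, 45, 90, 135),
                             hist_mode = "mask") {
  geom <- geometry_feature_names()
  color <- as.vector(vapply(c("R", "G", "B", "H", "S", "V"), function(ch)
    sprintf("%s_bin%02d", ch, seq_len(bins)), character(bins)))
  texture <- as.vector(vapply(angles, function(a)
    paste0(c("CON", "DIS", "HO", "ASM", "EN", "CORR"), "_", a),
    character(6)))
  structure(
    list(names = c(geom, color, texture), geometry = geom, color = color,
         texture = texture, bins = as.integer(bins), angles = angles,
         hist_mode = hist_mode),
    class = "feature_registry"
  )
}

#' Write a feature registry to JSON
#' @param registry A [feature_registry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(unclass(registry), path, auto_unbox = TRUE)
  invisible(path)
}

#' Full feature vector of a grain region
#'
#' Concatenates the geometry, colour and texture blocks in registry order
#' (330 values under the default registry).
#'
#' @param region A [grain_region()].
#' @param registry A [feature_registry()].
#' @return Named numeric vector, `length(registry$names)`, all finite.
#' @export
feature_vector <- function(region, registry = feature_registry()) {
  fv <- c(
    geometry_features(region),
    channel_histograms(region, bins = registry$bins, mode = registry$hist_mode),
    texture_features(region, angles = registry$angles)
  )
  fv <- fv[registry$names]
  if (any(!is.finite(fv))) {
    abort_grainscan(
      sprintf("non-finite features for grain %d: %s", region$label,
              paste(names(fv)[!is.finite(fv)], collapse = ", ")),
      "grainscan_feature_error"
    )
  }
  fv
}

#' Build a labelled feature table from regions
#'
#' @param regions List of [grain_region()] objects.
#' @param labels Optional character vector of variety labels (one per
#'   region).
#' @param scene Optional scene identifier recorded per row.
#' @param registry A [feature_registry()].
#' @return Tibble: `scene`, `grain_id`, `variety` (NA when unlabelled), then
#'   one column per registry feature.
#' @export
build_feature_table <- function(regions, labels = NULL, scene = NA_character_,
                                registry = feature_registry()) {
  if (!is.null(labels) && length(labels) != length(regions)) {
    abort_grainscan("labels must match regions in length",
                    "grainscan_invalid_input")
  }
  rows <- lapply(seq_along(regions), function(i) {
    fv <- feature_vector(regions[[i]], registry = registry)
    dplyr::bind_cols(
      tibble(scene = scene, grain_id = regions[[i]]$label,
             variety = if (is.null(labels)) NA_character_ else labels[i]),
      as_tibble(as.list(fv))
    )
  })
  if (length(rows) == 0) {
    return(dplyr::bind_cols(
      tibble(scene = character(), grain_id = integer(), variety = character()),
      as_tibble(setNames(rep(list(numeric()), length(registry$names)),
                         registry$names))
    ))
  }
  dplyr::bind_rows(rows)
}

# Columns of a feature table that are provenance, not features.
meta_cols <- function() c("scene", "grain_id", "variety")

feature_cols <- function(table) setdiff(names(table), meta_cols())
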