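#' Variety profile for the synthetic grain generator
#'
#' A profile describes one grain variety as distributions over grain length,
#' width and body colour, plus the probability that a grain carries a bright
#' chalky patch. Lengths and widths are in pixels at the rendered scale;
#' colours are 8-bit RGB. The bundled default profiles are synthetic
#' stand-ins with long-grain vs short-grain structure, not measured rice
#' biometry.
#'
#' @param name Variety code (e.g. `"BM"`).
#' @param length_mean,length_sd Grain length distribution, pixels.
#' @param width_mean,width_sd Grain width distribution, pixels.
#' @param color_mean Length-3 RGB triple in `[0, 255]`.
#' @param color_sd Per-channel colour spread (one number).
#' @param chalkiness_prob Probability a grain shows a chalky patch.
#' @return A `variety_profile` list.
#' @export
variety_profile <- function(name, length_mean, length_sd, width_mean, width_sd,
                            color_mean, color_sd = 6, chalkiness_prob = 0.05) {
  if (length_sd < 0 || width_sd < 0 || length_mean <= 0 || width_mean <= 0) {
    abort_grainscan("profile means must be > 0 and sds >= 0",
                    "grainscan_invalid_parameter")
  }
  if (length_mean <= width_mean) {
    abort_grainscan("length_mean must exceed width_mean",
                    "grainscan_invalid_parameter")
  }
  if (length(color_mean) != 3L || any(color_mean < 0 | color_mean > 255)) {
    abort_grainscan("color_mean must be an RGB triple in [0, 255]",
                    "grainscan_invalid_parameter")
  }
  if (chalkiness_prob < 0 || chalkiness_prob > 1) {
    abort_grainscan("chalkiness_prob must lie in [0, 1]",
                    "grainscan_invalid_parameter")
  }
  structure(
    list(name = name, length_mean = length_mean, length_sd = length_sd,
         width_mean = width_mean, width_sd = width_sd,
         color_mean = as.numeric(color_mean), color_sd = color_sd,
         chalkiness_prob = chalkiness_prob),
    class = "variety_profile"
  )
}

#' Default synthetic variety profiles
#'
#' Eight profiles named after common Indian market varieties (three long-grain
#' basmati types, a broken basmati, three short kolam types and Sona Masuri).
#' The length/width/colour numbers are synthetic: chosen once so that classes
#' are separable mainly by grain geometry with mild colour differences, which
#' is what the downstream classifier bench is exercised on.
#'
#' @return Named list of [variety_profile()] objects.
#' @export
default_varieties <- function() {
  p <- list(
    variety_profile("BM",  60, 2.5, 13, 1.0, c(235, 232, 225), 6, 0.05),
    variety_profile("KB",  52, 2.2, 13, 1.0, c(228, 222, 210), 6, 0.05),
    variety_profile("TB",  46, 2.0, 14, 1.0, c(225, 218, 200), 6, 0.10),
    variety_profile("TKB", 34, 2.0, 13, 1.0, c(232, 228, 218), 6, 0.05),
    variety_profile("EK",  30, 1.5, 15, 1.2, c(230, 226, 215), 6, 0.08),
    variety_profile("HK",  27, 1.4, 16, 1.2, c(226, 220, 205), 6, 0.08),
    variety_profile("WK",  25, 1.3, 17, 1.3, c(222, 215, 198), 6, 0.10),
    variety_profile("SM",  22, 1.2, 14, 1.1, c(236, 233, 228), 6, 0.05)
  )
  setNames(p, vapply(p, `[[`, "", "name"))
}

#' Scene specification for the synthetic renderer
#'
#' @param grains List of `list(profile = , count = )` pairs, or a single
#'   profile with `count`.
#' @param width,height Canvas size in pixels (default matches a 5 MP sensor,
#'   2592 x 1944).
#' @param background_color RGB triple; default is a dark blue that gives
#'   strong grayscale contrast against pale grains.
#' @param noise_density Fraction of pixels hit by salt-and-pepper noise,
#'   in `[0, 0.5)`.
#' @param min_gap Minimum Chebyshev gap in pixels between any two grain
#'   masks; 0 permits touching grains.
#' @param seed Integer seed; the whole render is a deterministic function of
#'   the spec including this seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(grains, width = 2592, height = 1944,
                       background_color = c(20, 30, 90),
                       noise_density = 0, min_gap = 4, seed = 1L) {
  if (inherits(grains, "variety_profile")) {
    grains <- list(list(profile = grains, count = 1L))
  }
  counts <- vapply(grains, function(g) g$count, numeric(1))
  if (any(counts < 0)) {
    abort_grainscan("grain counts must be >= 0", "grainscan_invalid_parameter")
  }
  if (noise_density < 0 || noise_density >= 0.5) {
    abort_grainscan("noise_density must lie in [0, 0.5)",
                    "grainscan_invalid_parameter")
  }
  if (min_gap < 0) {
    abort_grainscan("min_gap must be >= 0", "grainscan_invalid_parameter")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         grains = grains, background_color = as.numeric(background_color),
         noise_density = noise_density, min_gap = as.integer(min_gap),
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Render one grain sprite
#'
#' A grain is modelled as a rotated filled ellipse whose radius is modulated
#' by a low-amplitude radial sinusoid (boundary jitter), optionally with a
#' brighter chalky patch. Draws length/width/colour from the profile using
#' the current RNG state.
#'
#' @param profile A [variety_profile()].
#' @param angle Rotation in radians; `NULL` draws uniformly from `[0, pi)`.
#' @param jitter_amp Maximum relative amplitude of the boundary sinusoid;
#'   0 yields an exact discrete ellipse.
#' @return List with `mask` (logical crop), `rgb` (crop array, background 0),
#'   `length`, `width` (sampled dimensions, pixels), `variety`.
#' @export
make_grain_sprite <- function(profile, angle = NULL, jitter_amp = 0.03) {
  if (!inherits(profile, "variety_profile")) {
    abort_grainscan("`profile` must be a variety_profile",
                    "grainscan_invalid_parameter")
  }
  len <- rnorm(1, profile$length_mean, profile$length_sd)
  wid <- rnorm(1, profile$width_mean, profile$width_sd)
  len <- max(len, 4)
  wid <- clamp(wid, 3, 0.9 * len)
  if (is.null(angle)) angle <- runif(1, 0, pi)
  amp <- if (jitter_amp > 0) runif(1, 0, jitter_amp) else 0
  freq <- sample(2:3, 1)
  phase <- runif(1, 0, 2 * pi)

  a <- len / 2
  b <- wid / 2
  ext <- a * (1 + amp) + 1
  w <- max(2L, ceiling(2 * ext))
  h <- w
  # pixel centres relative to the crop centre
  cx <- seq_len(w) - (w + 1) / 2
  cy <- seq_len(h) - (h + 1) / 2
  dx <- matrix(rep(cx, each = h), h, w)   # column offset
  dy <- matrix(rep(cy, w), h, w)          # row offset
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  if (amp > 0) {
    phi <- atan2(v / b, u / a)
    lim <- 1 + amp * sin(freq * phi + phase)
  } else {
    lim <- 1
  }
  mask <- rho <= lim

  # trim to tight bbox
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  mask <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]

  npix <- sum(mask)
  rgb <- array(0, c(dim(mask), 3L))
  for (ch in 1:3) {
    vals <- profile$color_mean[ch] + rnorm(npix, 0, profile$color_sd)
    plane <- matrix(0, nrow(mask), ncol(mask))
    plane[mask] <- clamp(vals, 0, 255)
    rgb[, , ch] <- plane
  }
  if (runif(1) < profile$chalkiness_prob && npix > 12) {
    # chalky patch: brighten an off-centre elliptical sub-region toward white
    idx <- which(mask, arr.ind = TRUE)
    ctr <- idx[sample.int(nrow(idx), 1), ]
    pr <- max(2, 0.25 * min(dim(mask)))
    d2 <- (row(mask) - ctr[1])^2 + (col(mask) - ctr[2])^2
    patch <- mask & d2 <= pr^2
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[patch] <- plane[patch] + 0.5 * (255 - plane[patch])
      rgb[, , ch] <- plane
    }
  }
  list(mask = mask, rgb = rgb, length = len, width = wid,
       variety = profile$name)
}

#' Render a synthetic grain scene with ground truth
#'
#' Places the requested grains by rejection sampling so that no two grain
#' masks come within `min_gap` pixels (Chebyshev distance) of each other,
#' composites them over the background, then applies salt-and-pepper noise
#' as the final step. The whole render is deterministic given the spec.
#'
#' @param spec A [scene_spec()].
#' @param max_attempts Placement attempts per grain before failing.
#' @return List with `image` (h x w x 3 array, 0-255) and `truth`, a list of
#'   `label_raster` (integer matrix, 0 = background), `grains` (tibble:
#'   grain_id, variety, length_px, width_px).
#' @export
render_scene <- function(spec, max_attempts = 400L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  image <- array(rep(spec$background_color, each = h * w), c(h, w, 3L))
  labels <- matrix(0L, h, w)
  forbidden <- matrix(FALSE, h, w)

  rows <- list()
  gid <- 0L
  for (entry in spec$grains) {
    cnt <- entry$count
    if (cnt <= 0) next
    for (i in seq_len(cnt)) {
      sp <- make_grain_sprite(entry$profile)
      mh <- nrow(sp$mask); mw <- ncol(sp$mask)
      if (mh > h || mw > w) {
        abort_grainscan("grain sprite larger than canvas",
                        "grainscan_placement_error", placed = gid)
      }
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        r0 <- sample.int(h - mh + 1L, 1L)
        c0 <- sample.int(w - mw + 1L, 1L)
        sub <- forbidden[r0:(r0 + mh - 1L), c0:(c0 + mw - 1L)]
        if (!any(sub & sp$mask)) {
          gid <- gid + 1L
          ridx <- r0:(r0 + mh - 1L); cidx <- c0:(c0 + mw - 1L)
          lab_sub <- labels[ridx, cidx]
          lab_sub[sp$mask] <- gid
          labels[ridx, cidx] <- lab_sub
          for (ch in 1:3) {
            plane <- image[ridx, cidx, ch]
            plane[sp$mask] <- sp$rgb[, , ch][sp$mask]
            image[ridx, cidx, ch] <- plane
          }
          # grow the keep-out zone: this mask dilated by min_gap, padded so
          # the dilation reaches beyond the sprite crop
          g <- spec$min_gap
          pad <- matrix(FALSE, mh + 2L * g, mw + 2L * g)
          pad[(g + 1L):(g + mh), (g + 1L):(g + mw)] <- sp$mask
          dil <- dilate_box(pad, g)
          pr <- max(1L, r0 - g):min(h, r0 + mh - 1L + g)
          pc <- max(1L, c0 - g):min(w, c0 + mw - 1L + g)
          forbidden[pr, pc] <- forbidden[pr, pc] |
            dil[pr - (r0 - g) + 1L, pc - (c0 - g) + 1L]
          rows[[gid]] <- tibble(
            grain_id = gid, variety = sp$variety,
            length_px = sp$length, width_px = sp$width
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort_grainscan(
          sprintf("could not place grain %d of %d after %d attempts",
                  i, cnt, max_attempts),
          "grainscan_placement_error", placed = gid
        )
      }
    }
  }

  if (spec$noise_density > 0) {
    hit <- runif(h * w) < spec$noise_density
    salt <- runif(h * w) < 0.5
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[hit & salt] <- 255
      plane[hit & !salt] <- 0
      image[, , ch] <- plane
    }
  }

  truth_tbl <- if (gid > 0L) dplyr::bind_rows(rows) else
    tibble(grain_id = integer(), variety = character(),
           length_px = numeric(), width_px = numeric())
  list(
    image = round(image),
    truth = list(label_raster = labels, grains = truth_tbl)
  )
}

#' Write a labelled synthetic dataset to disk
#'
#' Renders each spec, writes the scene PNG and the ground-truth label raster
#' PNG, and a CSV manifest with header
#' `scene,grain_id,variety,length_px,width_px`. Seeds are recorded in a
#' sidecar `manifest.json`.
#'
#' @param specs List of [scene_spec()] objects.
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite existing files.
#' @return The manifest tibble, invisibly written to `manifest.csv`.
#' @export
make_labeled_dataset <- function(specs, out_dir, force = FALSE) {
  if (inherits(specs, "scene_spec")) specs <- list(specs)
  if (dir.exists(out_dir) && !force &&
      file.exists(file.path(out_dir, "manifest.csv"))) {
    abort_grainscan(sprintf("%s already holds a dataset; use force = TRUE",
                            out_dir), "grainscan_io_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(specs)) {
    sc <- render_scene(specs[[i]])
    scene_name <- sprintf("scene_%03d.png", i)
    write_scene_png(sc$image, file.path(out_dir, scene_name))
    write_label_png(sc$truth$label_raster,
                    file.path(out_dir, sprintf("scene_%03d_labels.png", i)))
    g <- sc$truth$grains
    if (nrow(g) > 0) rows[[i]] <- dplyr::mutate(g, scene = scene_name,
                                                .before = 1)
  }
  manifest <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(scene = character(), grain_id = integer(), variety = character(),
           length_px = numeric(), width_px = numeric())
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(
    list(seeds = vapply(specs, `[[`, integer(1), "seed"),
         n_scenes = length(specs)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE
  )
  manifest
}

#' Simulate a labelled per-grain feature table
#'
#' Renders individual grain sprites (no scene compositing) for each variety,
#' runs the feature extractor on each, and returns the labelled feature
#' table. This is the fast path for exercising the classifier bench.
#'
#' @param n_per_class Grains per variety.
#' @param varieties Named list of profiles, default [default_varieties()].
#' @param seed Integer seed.
#' @param registry Feature registry, see [feature_registry()].
#' @return Tibble: `grain_id`, `variety`, then one column per feature.
#' @export
simulate_grain_table <- function(n_per_class = 30, varieties = default_varieties(),
                                 seed = 1L, registry = feature_registry()) {
  set.seed(seed)
  rows <- list()
  gid <- 0L
  for (pf in varieties) {
    for (i in seq_len(n_per_class)) {
      gid <- gid + 1L
      sp <- make_grain_sprite(pf)
      reg <- grain_region_from_sprite(sp, label = gid)
      fv <- feature_vector(reg, registry = registry)
      rows[[gid]] <- dplyr::bind_cols(
        tibble(grain_id = gid, variety = pf$name),
        as_tibble(as.list(fv))
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Wrap a sprite as a grain_region (used by the sprite-level fast path).
grain_region_from_sprite <- function(sprite, label = 1L) {
  grain_region(
    label = label, mask_crop = sprite$mask, rgb_crop = sprite$rgb,
    bbox = c(0L, 0L, nrow(sprite$mask), ncol(sprite$mask))
  )
}
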