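# Feature blocks: contour, geometry, colour histograms, GLCM texture.

test_that("contour tracing closes around the mask boundary", {
  # single pixel
  m1 <- matrix(FALSE, 3, 3); m1[2, 2] <- TRUE
  expect_equal(nrow(trace_contour(m1)), 1)

  # filled square: 36 distinct boundary pixels
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  ct <- trace_contour(sq)
  expect_equal(nrow(unique(as.data.frame(ct))), 36)
  boundary <- sq & !oracle_erode3(sq)
  expect_setequal(paste(ct[, 1], ct[, 2]),
                  paste(which(boundary, arr.ind = TRUE)[, 1],
                        which(boundary, arr.ind = TRUE)[, 2]))

  # random blobs: contour pixels + interior fill reproduce the mask.
  # The fill floods the complement 4-connectedly from the border (a
  # 4-connected flood cannot slip through an 8-connected closed contour).
  set.seed(21)
  vs <- default_varieties()
  for (i in 1:5) {
    sp <- make_grain_sprite(vs[[sample(names(vs), 1)]])
    m <- sp$mask
    ct <- trace_contour(m)
    cmask <- matrix(FALSE, nrow(m), ncol(m))
    cmask[ct] <- TRUE
    outside <- !cmask & (row(m) == 1 | row(m) == nrow(m) |
                           col(m) == 1 | col(m) == ncol(m))
    repeat {
      grown <- outside
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        grown <- grown | grainscan:::shift_matrix(outside, d[1], d[2], FALSE)
      }
      grown <- grown & !cmask
      if (identical(grown, outside)) break
      outside <- grown
    }
    enclosed <- !outside
    expect_identical(enclosed, m)
  }

  expect_error(trace_contour(matrix(FALSE, 3, 3)),
               class = "grainscan_invalid_region")
  two <- matrix(FALSE, 5, 5); two[1, 1] <- TRUE; two[5, 5] <- TRUE
  expect_error(trace_contour(two), class = "grainscan_invalid_region")
})

test_that("geometry features are exact on analytic shapes", {
  # discrete disk of radius 20
  disk <- flat_region(disk_mask(20), c(200, 200, 200))
  g <- geometry_features(disk)
  expect_lt(abs(g[["area"]] - pi * 400) / (pi * 400), 0.02)
  expect_lt(abs(g[["roundness"]] - 1), 0.05)
  expect_lt(abs(g[["aspect_ratio"]] - 1), 0.05)
  expect_lt(abs(g[["equivalent_diameter"]] - 40), 1)
  expect_gt(g[["solidity"]], 0.97)
  expect_lte(g[["solidity"]], 1)

  # solidity strictly decreases after carving a notch
  notched <- disk_mask(20)
  ctr <- (nrow(notched) + 1) / 2
  notched[(ctr - 2):(ctr + 2), 1:ctr] <- FALSE
  notched_region <- flat_region(oracle_label8(notched) == 1L, c(200, 200, 200))
  g2 <- geometry_features(notched_region)
  expect_lt(g2[["solidity"]], g[["solidity"]] - 0.02)

  # noise-free 60 x 24 ellipse sprite
  er <- ellipse_region(60, 24, angle = 0)
  ge <- geometry_features(er)
  expect_lt(abs(ge[["length"]] - 60) / 60, 0.05)
  expect_lt(abs(ge[["width"]] - 24) / 24, 0.05)
  expect_lt(abs(ge[["aspect_ratio"]] - 2.5), 0.13)
  expect_equal(ge[["bbox_w"]], 60)
  expect_equal(ge[["bbox_h"]], 24)
  expect_lt(abs(ge[["eccentricity"]] - sqrt(1 - (12 / 30)^2)), 0.02)

  # a line-like region is degenerate
  line <- matrix(FALSE, 5, 30); line[3, 3:28] <- TRUE
  expect_error(geometry_features(flat_region(line, c(1, 1, 1))),
               class = "grainscan_degenerate_shape")
})

test_that("dimensionless geometry features are scale invariant", {
  small <- geometry_features(ellipse_region(30, 12, angle = 0.4))
  big <- geometry_features(ellipse_region(60, 24, angle = 0.4))
  for (f in c("aspect_ratio", "roundness", "solidity", "extent")) {
    expect_lt(abs(small[[f]] - big[[f]]) / big[[f]], 0.03)
  }
})

test_that("HSV conversion matches the reference implementation", {
  expect_equal(unname(rgb_to_hsv_grain(0, 0, 0)[1, ]), c(0, 0, 0))
  pure_red <- rgb_to_hsv_grain(255, 0, 0)
  expect_equal(unname(pure_red[1, ]), c(0, 1, 255))

  set.seed(12)
  r <- sample(0:255, 1000, replace = TRUE)
  g <- sample(0:255, 1000, replace = TRUE)
  b <- sample(0:255, 1000, replace = TRUE)
  ours <- rgb_to_hsv_grain(r, g, b)
  ref <- t(grDevices::rgb2hsv(r, g, b, maxColorValue = 255))
  dh <- abs(ours[, "h"] - ref[, 1] * 360)
  dh <- pmin(dh, 360 - dh)  # hue wraps
  expect_lt(max(dh), 1e-9)
  expect_lt(max(abs(ours[, "s"] - ref[, 2])), 1e-9)
  expect_lt(max(abs(ours[, "v"] - ref[, 3] * 255)), 1e-9)
})

test_that("channel histograms bin masked pixels and conserve counts", {
  sq <- matrix(FALSE, 8, 8); sq[2:7, 2:7] <- TRUE
  grey <- flat_region(sq, c(128, 128, 128))
  h <- channel_histograms(grey)
  n <- sum(sq)
  # value 128 lands in 0-based bin floor(128 * 48 / 256) = 24
  expect_equal(unname(h[["R_bin25"]]), n)
  expect_equal(unname(h[["G_bin25"]]), n)
  expect_equal(unname(h[["B_bin25"]]), n)
  expect_equal(unname(h[["S_bin01"]]), n)  # grey has zero saturation
  for (ch in c("R", "G", "B", "H", "S", "V")) {
    expect_equal(sum(h[grepl(paste0("^", ch, "_"), names(h))]), n)
  }

  # random crop vs per-pixel tally oracle on the R channel
  set.seed(31)
  m <- matrix(runif(64) < 0.7, 8, 8)
  rgb <- array(sample(0:255, 64 * 3, replace = TRUE), c(8, 8, 3))
  reg <- grain_region(1L, m, rgb, c(0L, 0L, 8L, 8L))
  h2 <- channel_histograms(reg)
  vals <- rgb[, , 1][m]
  for (bin in 1:48) {
    expect_equal(unname(h2[[sprintf("R_bin%02d", bin)]]),
                 sum(floor(vals * 48 / 256) == bin - 1))
  }

  # bbox mode counts every pixel in the crop
  h3 <- channel_histograms(reg, mode = "bbox")
  expect_equal(sum(h3[grepl("^R_", names(h3))]), 64)
})

test_that("GLCM matches hand counts and the double-loop oracle", {
  row3 <- matrix(c(5, 5, 9), 1, 3)
  g <- glcm(row3, angle = 0)
  expect_equal(g$G[6, 6], 1)   # (5, 5)
  expect_equal(g$G[6, 10], 1)  # (5, 9)
  expect_equal(sum(g$G), 2)

  # constant crop: all pairs on the diagonal
  const <- matrix(7, 4, 5)
  g2 <- glcm(const, angle = 90)
  expect_equal(g2$G[8, 8], g2$n_pairs)
  expect_equal(g2$n_pairs, 3 * 5)

  set.seed(44)
  gray <- matrix(sample(0:255, 12 * 12, replace = TRUE), 12, 12)
  mask <- matrix(runif(144) < 0.8, 12, 12)
  offs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))
  for (a in names(offs)) {
    g3 <- glcm(gray, mask, angle = as.numeric(a))
    expect_identical(g3$G, oracle_glcm(gray, mask, offs[[a]]))
    expect_equal(sum(g3$p), 1)
  }

  expect_error(glcm(matrix(5, 1, 1), angle = 0),
               class = "grainscan_empty_pairs")
  expect_error(glcm(gray, mask, angle = 30), class = "grainscan_invalid_input")
})

test_that("Haralick statistics match hand values and the brute-force oracle", {
  # all mass on one diagonal cell: the constant-image limit
  p1 <- matrix(0, 16, 16); p1[4, 4] <- 1
  s1 <- glcm_stats(p1)
  expect_equal(unname(s1), c(0, 0, 1, 1, 1, 1))

  # two-cell hand computation
  p2 <- matrix(0, 8, 8); p2[1, 1] <- 0.5; p2[1, 2] <- 0.5
  s2 <- glcm_stats(p2)
  expect_equal(s2[["CON"]], 0.5)
  expect_equal(s2[["DIS"]], 0.5)
  expect_equal(s2[["HO"]], 0.75)
  expect_equal(s2[["ASM"]], 0.5)
  expect_equal(s2[["EN"]], sqrt(0.5))

  set.seed(55)
  for (i in 1:5) {
    p <- matrix(runif(64), 8, 8); p <- p / sum(p)
    expect_equal(glcm_stats(p), oracle_glcm_stats(p), tolerance = 1e-10)
  }

  expect_error(glcm_stats(matrix(1, 4, 4)),
               class = "grainscan_invalid_distribution")
})

test_that("texture statistics at 0 degrees equal 90 degrees on the transpose", {
  set.seed(66)
  gray <- matrix(sample(0:255, 120, replace = TRUE), 10, 12)
  mask <- matrix(runif(120) < 0.85, 10, 12)
  s0 <- glcm_stats(glcm(gray, mask, 0)$p)
  s90t <- glcm_stats(glcm(t(gray), t(mask), 90)$p)
  expect_equal(s0, s90t, tolerance = 1e-12)
})

test_that("feature vectors have registry length, order and determinism", {
  reg <- ellipse_region(44, 16, angle = 0.7, seed = 4)
  fv <- feature_vector(reg)
  expect_length(fv, 330)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_registry()$names)
  expect_identical(fv, feature_vector(reg))

  # a reduced registry shrinks the colour block accordingly
  small <- feature_registry(bins = 16)
  expect_length(feature_vector(reg, registry = small), 18 + 96 + 24)
})

test_that("aspect ratio separates long-grain from short-grain populations", {
  vs <- default_varieties()
  ar <- function(pf) {
    sp <- make_grain_sprite(pf)
    reg <- grain_region(1L, sp$mask, sp$rgb,
                        c(0L, 0L, nrow(sp$mask), ncol(sp$mask)))
    geometry_features(reg)[["aspect_ratio"]]
  }
  set.seed(10)
  a_long <- replicate(100, ar(vs$BM))
  a_short <- replicate(100, ar(vs$WK))
  expect_gt(oracle_auc(a_long, a_short), 0.95)
})

test_that("feature tables assemble, label and round-trip through CSV", {
  regions <- lapply(1:6, function(i)
    ellipse_region(30 + 2 * i, 14, angle = 0.2 * i, label = i, seed = i))
  tab <- build_feature_table(regions, labels = rep(c("A", "B"), 3),
                             scene = "s1")
  expect_equal(nrow(tab), 6)
  expect_equal(ncol(tab), 3 + 330)
  expect_equal(tab$variety, rep(c("A", "B"), 3))

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)

  expect_error(build_feature_table(regions, labels = c("A", "B")),
               class = "grainscan_invalid_input")
})
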