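# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles are deliberately literal (loops, no shared code with
# the implementation under test).

# 5x5 median with symmetric reflect padding, one channel.
oracle_median5 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n - i + 1, i)
  }
  out <- m
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- numeric(25)
    k <- 0
    for (dr in -2:2) for (dc in -2:2) {
      k <- k + 1
      vals[k] <- m[refl(r + dr, nr), refl(c + dc, nc)]
    }
    out[r, c] <- median(vals)
  }
  out
}

# Exhaustive Otsu search: loop over all 256 candidate thresholds, literal
# class sums, strict > update (first maximiser kept).
oracle_otsu <- function(p) {
  best_t <- NA_integer_; best_v <- -1
  for (t in 0:255) {
    U0 <- if (t == 0) 0 else sum(p[1:t])
    U1 <- 1 - U0
    if (U0 <= 0 || U1 <= 0) {
      v <- 0
    } else {
      m0 <- sum((0:(t - 1)) * p[1:t]) / U0
      m1 <- sum((t:255) * p[(t + 1):256]) / U1
      v <- U0 * U1 * (m0 - m1)^2
    }
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  list(thresh = best_t, Vb2_max = best_v)
}

# 3x3 erosion by literal neighbourhood AND (border = background).
oracle_erode3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) ok <- FALSE
    }
    out[r, c] <- ok
  }
  out
}

# 8-connected flood-fill labelling, components numbered in raster-scan
# (row-major) order of first pixel.
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      stack <- list(c(r, c))
      lab[r, c] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            stack[[length(stack) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# GLCM by literal double loop.
oracle_glcm <- function(gray, mask, d) {
  G <- matrix(0L, 256, 256)
  nr <- nrow(gray); nc <- ncol(gray)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + d[1]; c2 <- c + d[2]
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
        mask[r, c] && mask[r2, c2]) {
      i <- gray[r, c] + 1L; j <- gray[r2, c2] + 1L
      G[i, j] <- G[i, j] + 1L
    }
  }
  G
}

# The six Haralick statistics by literal double loops.
oracle_glcm_stats <- function(p) {
  n <- nrow(p)
  CON <- DIS <- HO <- ASM <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- (i - 1) - (j - 1)
    CON <- CON + d^2 * p[i, j]
    DIS <- DIS + abs(d) * p[i, j]
    HO <- HO + p[i, j] / (1 + abs(d))
    ASM <- ASM + p[i, j]^2
  }
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum((seq_len(n) - 1) * pi_); mu_j <- sum((seq_len(n) - 1) * pj_)
  s_i <- sqrt(sum(((seq_len(n) - 1) - mu_i)^2 * pi_))
  s_j <- sqrt(sum(((seq_len(n) - 1) - mu_j)^2 * pj_))
  CORR <- 0
  if (s_i * s_j == 0) {
    CORR <- 1
  } else {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      CORR <- CORR + ((i - 1) - mu_i) * ((j - 1) - mu_j) * p[i, j]
    }
    CORR <- CORR / (s_i * s_j)
  }
  c(CON = CON, DIS = DIS, HO = HO, ASM = ASM, EN = sqrt(ASM), CORR = CORR)
}

# Pairwise Mann-Whitney AUC (ties count one half).
oracle_auc <- function(scores_pos, scores_neg) {
  tot <- 0
  for (sp in scores_pos) for (sn in scores_neg) {
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  }
  tot / (length(scores_pos) * length(scores_neg))
}

# Fixture builders -----------------------------------------------------------

disk_mask <- function(radius, pad = 2L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  outer(seq_len(n), seq_len(n), function(r, c)
    (r - ctr)^2 + (c - ctr)^2 <= radius^2)
}

# Region with a flat grey body on a mask (default: full rectangle).
flat_region <- function(mask, rgb_value = c(128, 128, 128), label = 1L) {
  rgb <- array(0, c(dim(mask), 3L))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(mask), ncol(mask))
    plane[mask] <- rgb_value[ch]
    rgb[, , ch] <- plane
  }
  grain_region(label = label, mask_crop = mask, rgb_crop = rgb,
               bbox = c(0L, 0L, nrow(mask), ncol(mask)))
}

# Deterministic noise-free elliptical region of given axes.
ellipse_region <- function(len, wid, angle = 0, color = c(220, 215, 200),
                           label = 1L, seed = 1L) {
  set.seed(seed)
  pf <- variety_profile("FX", len, 0, wid, 0, color, color_sd = 0,
                        chalkiness_prob = 0)
  sp <- make_grain_sprite(pf, angle = angle, jitter_amp = 0)
  grain_region(label = label, mask_crop = sp$mask, rgb_crop = sp$rgb,
               bbox = c(0L, 0L, nrow(sp$mask), ncol(sp$mask)))
}

# A small labelled feature table with two well-separated 2-D classes
# (for classifier bench tests that do not need image features).
toy_two_class_table <- function(n_per_class = 20, gap = 6, seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    grain_id = seq_len(2 * n_per_class),
    variety = rep(c("A", "B"), each = n_per_class),
    f1 = c(rnorm(n_per_class, 0), rnorm(n_per_class, gap)),
    f2 = c(rnorm(n_per_class, 0), rnorm(n_per_class, gap))
  )
}
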