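# shared fixtures: small phantoms, analytic shapes, brute-force texture oracles

fast_kite_spec <- function(..., mm_per_px = 0.25, seed = 7L) {
  phantom_spec(body_length_mm = 100, body_max_width_mm = 20,
               width_position_rel = 0.3, body_profile = "kite",
               mm_per_px = mm_per_px, awn_count = 0L, seed = seed, ...)
}

scale_only_cal <- function(mm_per_px) {
  calibrate(NULL, NULL, mm_per_px = mm_per_px)
}

disk_mask <- function(r = 200, pad = 25) {
  n <- 2 * (r + pad)
  ctr <- n / 2
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  m <- matrix(0L, n, n)
  m[(g$x - ctr)^2 + (g$y - ctr)^2 <= r^2] <- 2L
  m
}

# flat-colour image from a mask and per-class RGB
paint_mask <- function(mask, colors = list(`0` = c(40, 70, 160),
                                           `2` = c(181, 160, 108),
                                           `3` = c(148, 131, 89))) {
  img <- array(0, c(dim(mask), 3))
  for (cls in names(colors)) {
    sel <- mask == as.integer(cls)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- colors[[cls]][ch]
      img[, , ch] <- plane
    }
  }
  img
}

checkerboard_image <- function(n = 16) {
  chk <- outer(seq_len(n), seq_len(n), function(a, b) (a + b) %% 2)
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- chk * 255
  img
}

# brute-force GLCM feature oracle: explicit loops over all pixel pairs
brute_glcm <- function(q, directions, g, symmetric = TRUE, d = 1L) {
  offs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))
  counts <- matrix(0, g, g)
  for (dir in directions) {
    o <- offs[[dir]] * d
    for (r in seq_len(nrow(q))) {
      for (c in seq_len(ncol(q))) {
        r2 <- r + o[1]; c2 <- c + o[2]
        if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
        if (is.na(q[r, c]) || is.na(q[r2, c2])) next
        counts[q[r, c] + 1L, q[r2, c2] + 1L] <-
          counts[q[r, c] + 1L, q[r2, c2] + 1L] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  p <- counts / sum(counts)
  i <- matrix(0:(g - 1), g, g); j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  nz <- p > 0
  c(contrast = sum(p * (i - j)^2),
    dissimilarity = sum(p * abs(i - j)),
    homogeneity = sum(p / (1 + (i - j)^2)),
    ASM = sum(p^2),
    energy = sqrt(sum(p^2)),
    correlation = if (sd_i > 0 && sd_j > 0)
      sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j) else 0,
    entropy = -sum(p[nz] * log(p[nz])),
    maximum_probability = max(p),
    cluster_shade = sum((i + j - mu_i - mu_j)^3 * p),
    cluster_prominence = sum((i + j - mu_i - mu_j)^4 * p))
}

# brute-force run enumerator: walk every line pixel by pixel
brute_glrm <- function(q, directions) {
  offs <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
               `135` = c(-1L, -1L))
  lev <- integer(0); len <- integer(0)
  h <- nrow(q); w <- ncol(q)
  for (dir in directions) {
    o <- offs[[dir]]
    # line starts: cells whose predecessor along -o is outside the grid
    for (r0 in seq_len(h)) {
      for (c0 in seq_len(w)) {
        pr <- r0 - o[1]; pc <- c0 - o[2]
        if (pr >= 1 && pr <= h && pc >= 1 && pc <= w) next
        r <- r0; c <- c0
        cur <- NA_integer_; n <- 0L
        while (r >= 1 && r <= h && c >= 1 && c <= w) {
          v <- q[r, c]
          if (is.na(v)) {
            if (n > 0) { lev <- c(lev, cur); len <- c(len, n) }
            cur <- NA_integer_; n <- 0L
          } else if (!is.na(cur) && v == cur) {
            n <- n + 1L
          } else {
            if (n > 0) { lev <- c(lev, cur); len <- c(len, n) }
            cur <- v; n <- 1L
          }
          r <- r + o[1]; c <- c + o[2]
        }
        if (n > 0) { lev <- c(lev, cur); len <- c(len, n) }
      }
    }
  }
  n_r <- length(len)
  n_px <- sum(!is.na(q))
  c(SRE = sum(1 / len^2) / n_r,
    LRE = sum(as.numeric(len)^2) / n_r,
    GLN = sum(tapply(rep(1, n_r), lev, sum)^2) / n_r,
    RLN = sum(tapply(rep(1, n_r), len, sum)^2) / n_r,
    RP = n_r / (n_px * length(directions)),
    LGRE = sum(1 / (lev + 1)^2) / n_r)
}

# feature records for a cohort, straight from the (exact) truth masks
cohort_view_records <- function(cohort, cal, view = "frontal") {
  lapply(seq_along(cohort$phantoms), function(i) {
    ph <- cohort$phantoms[[i]]
    view_record_from_mask(i, view, ph$image, ph$truth_mask, cal)
  })
}

cohort_certificates <- function(cohort, cal, view = "frontal") {
  lapply(cohort_view_records(cohort, cal, view),
         function(r) assemble_certificate(list(r)))
}

# cohort defaults for the statistics suites: natural biological + imaging
# variation at a coarse scale that keeps per-image cost low
stats_base_spec <- function(seed = 1L) {
  phantom_spec(body_length_mm = 90, body_max_width_mm = 16,
               width_position_rel = 0.35, mm_per_px = 0.6,
               awn_count = 10L, awn_length_mm = 25, awn_width_px = 1L,
               noise_sd = 3, seed = seed)
}

stats_jitter <- function() {
  list(body_length_mm = 0.04, body_max_width_mm = 0.05,
       width_position_rel = 0.04, awn_length_mm = 0.08,
       body_rgb = 0.03)
}

# datastore fixture: 6 plants x 1 spike x 4 views, with image files on disk
write_fixture_batch <- function(dir) {
  img_dir <- file.path(dir, "img")
  dir.create(img_dir, showWarnings = FALSE)
  rows <- expand.grid(accession_number = sprintf("k-%d", 19301:19306),
                      spike_number = 1L,
                      view = c("frontal", "back", "side1", "side2"),
                      stringsAsFactors = FALSE)
  rows$collection <- "Siberian Wheat Collection"
  rows$origin_country <- rep(c("Russia", "Russia", "Russia", "Kazakhstan",
                               "Kazakhstan", "Ethiopia"), 4)
  rows$variety_name <- rep(c("A", "A", "B", "B", "B", "C"), 4)
  rows$year_of_cultivation <- 2019L
  rows$plot_note <- "field 3"  # unknown column -> Plant annex
  rows$image_file <- sprintf("%s_v%s.ppm", rows$accession_number, rows$view)
  tiny <- array(128, c(2, 2, 3))
  for (f in unique(rows$image_file)) write_pnm(tiny, file.path(img_dir, f))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(rows, manifest, row.names = FALSE)
  list(manifest = manifest, img_dir = img_dir, rows = rows)
}
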