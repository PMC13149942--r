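#' Grey-level texture features of the spike body
#'
#' Texture is quantified over the body region of the image with two classic
#' matrix statistics: ten features of the grey-level co-occurrence matrix
#' (GLCM, Haralick-style) and six of the grey-level run-length matrix (GLRM,
#' Galloway-style). Luminance is the standard-definition Y component
#' (0.299 R + 0.587 G + 0.114 B), quantized uniformly over the region's
#' min-max range, so the features are invariant to adding a constant to all
#' luminances. Pixel pairs and runs are restricted to the region: a pair with
#' one pixel outside is dropped and a run is truncated at the region boundary.
#'
#' @name texture
NULL

GLCM_FEATURE_NAMES <- c("contrast", "dissimilarity", "homogeneity", "ASM",
                        "energy", "correlation", "entropy",
                        "maximum_probability", "cluster_shade",
                        "cluster_prominence")
GLRM_FEATURE_NAMES <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE")

# direction name -> (dr, dc) unit offset
TEXTURE_DIRECTIONS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                           `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Texture configuration
#'
#' @param gray_levels number of quantization levels (>= 2; default 32
#'   balances matrix sparsity against sensitivity at typical body sizes of
#'   ~1e4 px).
#' @param glcm_distance_px co-occurrence offset distance (>= 1).
#' @param directions subset of `c("0", "45", "90", "135")` (degrees).
#' @param symmetric accumulate each pair in both orders.
#' @return object of class `texture_config`.
#' @export
texture_config <- function(gray_levels = 32L, glcm_distance_px = 1L,
                           directions = c("0", "45", "90", "135"),
                           symmetric = TRUE) {
  ss_assert(is_scalar_num(gray_levels) && gray_levels >= 2,
            "gray_levels must be >= 2")
  ss_assert(is_scalar_num(glcm_distance_px) && glcm_distance_px >= 1,
            "glcm_distance_px must be >= 1")
  directions <- match.arg(directions, names(TEXTURE_DIRECTIONS),
                          several.ok = TRUE)
  structure(list(gray_levels = as.integer(gray_levels),
                 glcm_distance_px = as.integer(glcm_distance_px),
                 directions = directions, symmetric = isTRUE(symmetric)),
            class = "texture_config")
}

# quantized luminance matrix: integer levels 0..G-1 inside the region, NA out
quantize_region <- function(image, mask, cfg, min_region_px = 64L) {
  validate_image(image)
  validate_mask(mask, image)
  body <- region_mask(mask, "body")
  ss_assert(sum(body) >= min_region_px,
            sprintf("body region smaller than %d px", min_region_px),
            "spikescan_size_error")
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  # work on integer milli-luminance so that adding a constant to all pixels
  # shifts every value exactly and leaves the quantization bit-identical
  yi <- round(y * 1000)
  lo <- min(yi[body]); hi <- max(yi[body])
  g <- cfg$gray_levels
  q <- matrix(NA_integer_, nrow(mask), ncol(mask))
  constant <- hi == lo
  if (constant) {
    q[body] <- 0L
  } else {
    q[body] <- as.integer(floor((yi[body] - lo) * g / (hi - lo + 1)))
  }
  attr(q, "constant") <- constant
  q
}

glcm_matrix <- function(q, cfg) {
  g <- cfg$gray_levels
  d <- cfg$glcm_distance_px
  counts <- matrix(0, g, g)
  h <- nrow(q); w <- ncol(q)
  for (dir in cfg$directions) {
    o <- TEXTURE_DIRECTIONS[[dir]] * d
    r1 <- max(1, 1 - o[1]):min(h, h - o[1])
    c1 <- max(1, 1 - o[2]):min(w, w - o[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + o[1], c1 + o[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate(a[ok] * g + b[ok] + 1L, nbins = g * g)
    counts <- counts + matrix(tab, g, g, byrow = TRUE)
  }
  if (cfg$symmetric) counts <- counts + t(counts)
  ss_assert(sum(counts) > 0, "no valid pixel pairs in region",
            "spikescan_size_error")
  counts / sum(counts)
}

#' GLCM texture features
#'
#' Pairs are pooled over the configured directions, symmetrized and
#' normalized to a probability matrix `p(i, j)`; features use the standard
#' formulas (entropy with natural log and `0 log 0 = 0`; correlation defined
#' as 0 for a constant region, with the `constant` attribute set).
#'
#' @param image RGB array.
#' @param mask label mask (features are computed over the body class).
#' @param cfg a [texture_config()].
#' @return named numeric vector of the 10 features in `GLCM_FEATURE_NAMES`.
#' @export
glcm_features <- function(image, mask, cfg = texture_config()) {
  q <- quantize_region(image, mask, cfg)
  p <- glcm_matrix(q, cfg)
  g <- cfg$gray_levels
  i <- matrix(0:(g - 1), g, g)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i > 1e-12 && sd_j > 1e-12) {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  } else 0
  nz <- p > 0
  out <- c(
    contrast = sum(p * (i - j)^2),
    dissimilarity = sum(p * abs(i - j)),
    homogeneity = sum(p / (1 + (i - j)^2)),
    ASM = sum(p^2),
    energy = sqrt(sum(p^2)),
    correlation = corr,
    entropy = -sum(p[nz] * log(p[nz])),
    maximum_probability = max(p),
    cluster_shade = sum((i + j - mu_i - mu_j)^3 * p),
    cluster_prominence = sum((i + j - mu_i - mu_j)^4 * p)
  )
  attr(out, "constant") <- attr(q, "constant")
  out
}

# run-length extraction: list of run (level, length) for one direction
runs_in_direction <- function(q, dir) {
  o <- TEXTURE_DIRECTIONS[[dir]]
  h <- nrow(q); w <- ncol(q)
  seqs <- switch(dir,
    `0` = lapply(seq_len(h), function(r) q[r, ]),
    `90` = lapply(seq_len(w), function(c) q[, c]),
    `45` = { # anti-diagonals: constant row + col
      s <- row(q) + col(q)
      lapply(split(q[order(s, -row(q))], sort(as.vector(s))), identity)
    },
    `135` = { # main diagonals: constant col - row
      s <- col(q) - row(q)
      lapply(split(q[order(s, row(q))], sort(as.vector(s))), identity)
    })
  lev <- integer(0); len <- integer(0)
  for (v in seqs) {
    r <- rle(as.vector(v))
    keep <- !is.na(r$values)
    lev <- c(lev, r$values[keep])
    len <- c(len, r$lengths[keep])
  }
  list(level = lev, length = len)
}

#' GLRM texture features
#'
#' Runs of equal quantized level are extracted along the configured
#' directions inside the region (truncated at region boundaries) and pooled.
#' Features: short-run emphasis (SRE), long-run emphasis (LRE), grey-level
#' non-uniformity (GLN), run-length non-uniformity (RLN), run percentage
#' (RP, runs per region pixel and direction) and low grey-level run emphasis
#' (LGRE, with levels counted from 1 to avoid division by zero).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of the 6 features in `GLRM_FEATURE_NAMES`.
#' @export
glrm_features <- function(image, mask, cfg = texture_config()) {
  q <- quantize_region(image, mask, cfg)
  lev <- integer(0); len <- integer(0)
  for (dir in cfg$directions) {
    rr <- runs_in_direction(q, dir)
    lev <- c(lev, rr$level)
    len <- c(len, rr$length)
  }
  n_r <- length(len)
  n_px <- sum(!is.na(q))
  gln <- sum(tapply(rep(1, n_r), lev, sum)^2) / n_r
  rln <- sum(tapply(rep(1, n_r), len, sum)^2) / n_r
  out <- c(
    SRE = sum(1 / len^2) / n_r,
    LRE = sum(as.numeric(len)^2) / n_r,
    GLN = gln,
    RLN = rln,
    RP = n_r / (n_px * length(cfg$directions)),
    LGRE = sum(1 / (lev + 1)^2) / n_r
  )
  attr(out, "constant") <- attr(q, "constant")
  out
}

#' All 16 texture features
#'
#' @inheritParams glcm_features
#' @return named numeric vector: 10 `glcm_*` followed by 6 `glrm_*` features.
#' @export
texture_features <- function(image, mask, cfg = texture_config()) {
  gl <- glcm_features(image, mask, cfg)
  gr <- glrm_features(image, mask, cfg)
  stats::setNames(c(gl, gr),
                  c(paste0("glcm_", GLCM_FEATURE_NAMES),
                    paste0("glrm_", GLRM_FEATURE_NAMES)))
}
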