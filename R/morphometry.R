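#' Morphometric features of the spike silhouette
#'
#' Nineteen morphological quantities are computed from a label mask: eight
#' contour-level descriptors (axis length `c_L`, perimeter `c_P`, area `c_S`,
#' circularity `c_Ci`, roundness `c_Ro`, solidity/integrity `c_So`, rugosity
#' `c_Ru`, and awn area `c_Sa`) and the eleven parameters of a quadrangle
#' (kite) model of the body symmetrized about the spike's main axis.
#'
#' Definitions follow the standard ImageJ-style conventions:
#' circularity `4*pi*A/P^2`, roundness `4*A/(pi*L^2)` with `L` the axis
#' length, solidity `A/A_hull`, rugosity `P/P_hull`; all equal 1 for a disk
#' (rugosity >= 1 in general). Areas and perimeters are measured on the pixel
#' raster and converted to millimetres through the calibration.
#'
#' The symmetrized quadrangle is a kite with two vertices on the axis (base
#' and tip, `q_L` apart) and two lateral vertices at axis fraction `q_pW`,
#' each `q_W/2` off the axis. Three degrees of freedom `(q_L, q_W, q_pW)` are
#' measured; the remaining eight parameters (edge lengths `q_a`, `q_b`,
#' vertex angles `q_alpha`, `q_beta`, `q_gamma`, area `q_A`, perimeter `q_P`,
#' aspect ratio `q_r`) are derived analytically, so the kite identities
#' `q_P = 2(q_a + q_b)`, `q_A = q_L*q_W/2` and
#' `q_alpha + q_beta + 2*q_gamma = 360` hold to machine precision.
#'
#' @name morphometry
NULL

region_mask <- function(mask, class) mask == MASK_CLASSES[[class]]

#' Estimate the spike axis
#'
#' The axis is the first principal direction of the body pixel coordinates
#' through their centroid; base and tip are the extreme projections of body
#' pixels onto it. The base is taken at the lower image end (the imaging
#' protocol holds the spike vertically, base down); set `base_down = FALSE`
#' to flip.
#'
#' @param mask label mask.
#' @param base_down orient the base towards the bottom of the image.
#' @return object of class `axis_frame`: `base_px`, `tip_px` (x = column,
#'   y = row), `unit_axis`, `length_px`.
#' @export
estimate_axis <- function(mask, base_down = TRUE) {
  body <- region_mask(mask, "body")
  ss_assert(any(body), "body class is empty", "spikescan_geometry_error")
  w <- which(body, arr.ind = TRUE)
  xy <- cbind(x = w[, 2], y = w[, 1])
  if (nrow(xy) < 3 || all(apply(xy, 2, stats::var) < 1e-12)) {
    ss_stop("degenerate body: not enough spatial variance for an axis",
            "spikescan_geometry_error")
  }
  pc <- stats::prcomp(xy, center = TRUE, scale. = FALSE)
  u <- pc$rotation[, 1]
  u <- u / sqrt(sum(u^2))
  # base = lower end in image coordinates (larger y)
  if (base_down && u[2] > 0) u <- -u      # make u point upwards (y decreasing)
  if (!base_down && u[2] < 0) u <- -u
  ctr <- colMeans(xy)
  proj <- (xy[, 1] - ctr[1]) * u[1] + (xy[, 2] - ctr[2]) * u[2]
  base <- ctr + min(proj) * u
  tip <- ctr + max(proj) * u
  len <- max(proj) - min(proj)
  ss_assert(len > 0, "zero-length axis", "spikescan_geometry_error")
  structure(list(base_px = c(x = unname(base[1]), y = unname(base[2])),
                 tip_px = c(x = unname(tip[1]), y = unname(tip[2])),
                 unit_axis = c(x = unname(u[1]), y = unname(u[2])),
                 length_px = len),
            class = "axis_frame")
}

#' Outline descriptors of the spike body (plus awn area)
#'
#' @param mask label mask.
#' @param cal a `calibration` (only `mm_per_px` is used here).
#' @param axis optional precomputed [estimate_axis()] frame.
#' @return named numeric vector with elements `c_L`, `c_P`, `c_S`, `c_Ci`,
#'   `c_Ro`, `c_So`, `c_Ru`, `c_Sa` (mm / mm^2 / dimensionless).
#' @export
outline_features <- function(mask, cal, axis = NULL) {
  ss_assert(inherits(cal, "calibration"), "cal must be a calibration",
            "spikescan_contract_error")
  body <- region_mask(mask, "body")
  ss_assert(any(body), "body class is empty", "spikescan_geometry_error")
  if (is.null(axis)) axis <- estimate_axis(mask)
  mmpp <- cal$mm_per_px

  area_px <- sum(body)
  bnd <- trace_boundary(body)
  per_px <- boundary_perimeter(bnd)
  len_px <- axis$length_px + 1  # + 1 px for the pixel footprint at both ends

  hull_idx <- grDevices::chull(bnd[, 1], bnd[, 2])
  hull <- bnd[hull_idx, , drop = FALSE]
  hull_per_px <- polygon_perimeter(hull)
  # chull runs through boundary pixel centres; pixels extend 0.5 px beyond,
  # so add half a boundary layer to keep solidity of convex shapes <= 1
  hull_area_px <- polygon_area(hull) + hull_per_px / 2

  c_S <- area_px * mmpp^2
  c_P <- per_px * mmpp
  c_L <- len_px * mmpp
  c(c_L = c_L,
    c_P = c_P,
    c_S = c_S,
    c_Ci = 4 * pi * c_S / c_P^2,
    c_Ro = 4 * c_S / (pi * c_L^2),
    c_So = min(area_px / hull_area_px, 1),
    c_Ru = per_px / hull_per_px,
    c_Sa = sum(region_mask(mask, "awn")) * mmpp^2)
}

#' Half-width profile of the body along the axis
#'
#' For `n_bins` equal slices of relative axis position `t` in [0, 1], the
#' maximal perpendicular distance of body pixels on each side of the axis.
#' Empty slices get zero half-widths.
#'
#' @param mask label mask.
#' @param axis an [estimate_axis()] frame.
#' @param cal a `calibration`.
#' @param n_bins number of slices (>= 8).
#' @return data.frame with columns `t` (bin centre), `left_mm`, `right_mm`.
#' @export
width_profile <- function(mask, axis, cal, n_bins = 64L) {
  ss_assert(is_scalar_num(n_bins) && n_bins >= 8,
            "n_bins must be at least 8")
  body <- region_mask(mask, "body")
  ss_assert(any(body), "body class is empty", "spikescan_geometry_error")
  w <- which(body, arr.ind = TRUE)
  x <- w[, 2]; y <- w[, 1]
  u <- axis$unit_axis
  nv <- c(-u[2], u[1])
  t <- ((x - axis$base_px[1]) * u[1] + (y - axis$base_px[2]) * u[2]) /
    axis$length_px
  d <- (x - axis$base_px[1]) * nv[1] + (y - axis$base_px[2]) * nv[2]
  bin <- clamp(floor(t * n_bins) + 1L, 1L, n_bins)
  left <- right <- numeric(n_bins)
  pos <- d >= 0
  agg_l <- tapply(d[!pos], bin[!pos], function(z) max(-z))
  agg_r <- tapply(d[pos], bin[pos], max)
  # + 0.5 px: pixel centres sit half a pixel inside the digitized outline
  left[as.integer(names(agg_l))] <- agg_l + 0.5
  right[as.integer(names(agg_r))] <- agg_r + 0.5
  mmpp <- cal$mm_per_px
  data.frame(t = (seq_len(n_bins) - 0.5) / n_bins,
             left_mm = left * mmpp, right_mm = right * mmpp)
}

# the 8 analytic kite parameters from the 3 measured ones
kite_parameters <- function(q_L, q_W, q_pW) {
  q_a <- sqrt((q_pW * q_L)^2 + (q_W / 2)^2)
  q_b <- sqrt(((1 - q_pW) * q_L)^2 + (q_W / 2)^2)
  q_alpha <- 2 * atan2(q_W / 2, q_pW * q_L) * 180 / pi
  q_beta <- 2 * atan2(q_W / 2, (1 - q_pW) * q_L) * 180 / pi
  q_gamma <- (360 - q_alpha - q_beta) / 2
  c(q_L = q_L, q_W = q_W, q_pW = q_pW, q_a = q_a, q_b = q_b,
    q_alpha = q_alpha, q_beta = q_beta, q_gamma = q_gamma,
    q_A = q_L * q_W / 2, q_P = 2 * (q_a + q_b), q_r = q_W / q_L)
}

#' Fit the symmetrized quadrangle (kite) model
#'
#' The symmetrized width `w(t) = left(t) + right(t)` is taken from the binned
#' width profile; `q_pW` is the profile argmax (parabolic refinement over the
#' three bins around it), `q_W = w(q_pW)`, `q_L` the axis extent. The other 8
#' parameters are derived analytically.
#'
#' @inheritParams width_profile
#' @return named numeric vector of the 11 `q_*` parameters; attribute
#'   `clamped` flags a profile whose maximum sat on an end bin.
#' @export
fit_quadrangle <- function(mask, axis = NULL, cal, n_bins = 64L) {
  if (is.null(axis)) axis <- estimate_axis(mask)
  prof <- width_profile(mask, axis, cal, n_bins)
  wsum <- prof$left_mm + prof$right_mm
  i <- which.max(wsum)
  clamped <- FALSE
  if (i == 1L || i == length(wsum)) {
    clamped <- TRUE
    t_star <- clamp(prof$t[i], 0.02, 0.98)
    w_star <- wsum[i]
  } else {
    # parabolic interpolation through the three bins around the maximum
    y0 <- wsum[i - 1]; y1 <- wsum[i]; y2 <- wsum[i + 1]
    denom <- y0 - 2 * y1 + y2
    delta <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
    delta <- clamp(delta, -0.5, 0.5)
    t_star <- prof$t[i] + delta / length(wsum)
    w_star <- y1 - 0.25 * (y0 - y2) * delta
  }
  q_L <- (axis$length_px + 1) * cal$mm_per_px
  out <- kite_parameters(q_L, w_star, t_star)
  attr(out, "clamped") <- clamped
  out
}

#' All 19 morphological features of one view
#'
#' Convenience wrapper: axis, the 8 outline quantities and the 11 quadrangle
#' parameters in one named vector.
#'
#' @inheritParams outline_features
#' @param n_bins width-profile bins for the quadrangle fit.
#' @return named numeric vector of length 19 (8 `c_*` + 11 `q_*`).
#' @export
morphometric_features <- function(mask, cal, n_bins = 64L) {
  axis <- estimate_axis(mask)
  c(outline_features(mask, cal, axis),
    fit_quadrangle(mask, axis, cal, n_bins))
}
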