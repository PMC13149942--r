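#' Synthetic spike phantoms
#'
#' A phantom emulates the single-spike imaging protocol: a spike held
#' vertically (on a clip) against a saturated blue paper backdrop, optionally
#' with a reference colour chart in frame for scale and colour calibration.
#' The generator renders a lanceolate spike body, thin awn strokes and chart
#' patches, and returns the exact per-pixel ground-truth labelling alongside
#' the image, so every downstream stage of the pipeline can be validated
#' without real photographs.
#'
#' Geometry is stated in millimetres and converted through `mm_per_px`; the
#' rendered canvas is sized automatically. Rendering is a pure function of
#' `(spec, seed)`: the same spec always yields a bit-identical image and mask.
#' Noise is applied after labelling, so the truth mask is always noise-free.
#'
#' @name phantom
NULL

#' Reference colour-chart specification
#'
#' Defaults to a 4 x 6 grid with the widely published sRGB values of the
#' classic 24-patch ColorChecker target.
#'
#' @param reference_rgb numeric matrix, one row per patch (row-major grid
#'   order), columns R, G, B in 0-255.
#' @param rows,cols grid shape; `rows * cols` must equal `nrow(reference_rgb)`.
#' @param patch_size_mm physical side length of one (square) patch.
#' @param position_px optional `c(row, col)` of the grid's top-left pixel on
#'   the canvas; chosen automatically when `NULL`.
#' @return object of class `chart_spec`.
#' @export
chart_spec <- function(reference_rgb = colorchecker_classic_rgb(),
                       rows = 4L, cols = 6L,
                       patch_size_mm = 10, position_px = NULL) {
  ss_assert(is.matrix(reference_rgb) && ncol(reference_rgb) == 3L,
            "reference_rgb must be an n x 3 matrix")
  ss_assert(rows * cols == nrow(reference_rgb),
            "rows * cols must equal the number of reference patches")
  ss_assert(is_scalar_num(patch_size_mm) && patch_size_mm > 0,
            "patch_size_mm must be a positive number")
  structure(list(reference_rgb = reference_rgb, rows = as.integer(rows),
                 cols = as.integer(cols), patch_size_mm = patch_size_mm,
                 position_px = position_px),
            class = "chart_spec")
}

#' Published sRGB coordinates of the classic 24-patch ColorChecker
#' @return 24 x 3 integer matrix (row-major grid order).
#' @export
colorchecker_classic_rgb <- function() {
  matrix(c(115, 82, 68,   194, 150, 130,  98, 122, 157,   87, 108, 67,
           133, 128, 177, 103, 189, 170,  214, 126, 44,   80, 91, 166,
           193, 90, 99,   94, 60, 108,    157, 188, 64,   224, 163, 46,
           56, 61, 150,   70, 148, 73,    175, 54, 60,    231, 199, 31,
           187, 86, 149,  8, 133, 161,    243, 243, 242,  200, 200, 200,
           160, 160, 160, 122, 122, 121,  85, 85, 85,     52, 52, 52),
         ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("R", "G", "B")))
}

#' Phantom specification
#'
#' @param body_length_mm spike body length along its axis (base to tip).
#' @param body_max_width_mm maximal body width; must be smaller than the
#'   length (spikes are elongated).
#' @param width_position_rel relative axis position of the widest point,
#'   strictly inside (0, 1).
#' @param body_profile `"kite"` (body is the filled quadrangle itself) or
#'   `"smooth_lanceolate"` (smooth width profile
#'   `w(t) = W sin(pi t^gamma)` with the maximum at `width_position_rel`).
#' @param body_rgb,awn_rgb,background_rgb 8-bit RGB triples. `awn_rgb = NULL`
#'   derives the awn colour from the body colour (awns share the spike's
#'   pigmentation, slightly darkened).
#' @param awn_count number of awn strokes (0 for awnless spikes).
#' @param awn_length_mm stroke length.
#' @param awn_width_px stroke thickness in pixels (1-3 in practice).
#' @param chart optional [chart_spec()].
#' @param mm_per_px image scale.
#' @param rotation_deg in-plane tilt of the spike axis from vertical.
#' @param noise_sd per-channel Gaussian noise sd (8-bit scale), clipped.
#' @param seed RNG seed making the rendering reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_length_mm = 90, body_max_width_mm = 16,
                         width_position_rel = 0.35,
                         body_profile = c("smooth_lanceolate", "kite"),
                         body_rgb = c(181, 160, 108),
                         awn_count = 12L, awn_length_mm = 30,
                         awn_width_px = 2L, awn_rgb = NULL,
                         background_rgb = c(40, 70, 160),
                         chart = NULL, mm_per_px = 0.2,
                         rotation_deg = 0, noise_sd = 0, seed = 1L) {
  body_profile <- match.arg(body_profile)
  ss_assert(is_scalar_num(body_length_mm) && body_length_mm > 0,
            "body_length_mm must be positive")
  ss_assert(is_scalar_num(body_max_width_mm) && body_max_width_mm > 0,
            "body_max_width_mm must be positive")
  ss_assert(body_max_width_mm < body_length_mm,
            "body_max_width_mm must be smaller than body_length_mm")
  ss_assert(is_scalar_num(width_position_rel) &&
              width_position_rel > 0 && width_position_rel < 1,
            "width_position_rel must lie strictly inside (0, 1)")
  ss_assert(is_scalar_num(awn_count) && awn_count >= 0,
            "awn_count must be non-negative")
  ss_assert(is_scalar_num(awn_length_mm) && awn_length_mm >= 0,
            "awn_length_mm must be non-negative")
  ss_assert(is_scalar_num(awn_width_px) && awn_width_px >= 1,
            "awn_width_px must be a positive integer")
  ss_assert(is_scalar_num(mm_per_px) && mm_per_px > 0,
            "mm_per_px must be positive")
  ss_assert(is_scalar_num(noise_sd) && noise_sd >= 0,
            "noise_sd must be non-negative")
  body_rgb <- rgb_triple(body_rgb, "body_rgb")
  background_rgb <- rgb_triple(background_rgb, "background_rgb")
  awn_rgb <- if (is.null(awn_rgb)) {
    round(0.82 * body_rgb)
  } else {
    rgb_triple(awn_rgb, "awn_rgb")
  }
  if (!is.null(chart)) {
    ss_assert(inherits(chart, "chart_spec"), "chart must be a chart_spec")
    same <- apply(chart$reference_rgb, 1L,
                  function(p) all(abs(p - background_rgb) < 1))
    ss_assert(!any(same), "chart patch colours must differ from the background")
  }
  structure(list(body_length_mm = body_length_mm,
                 body_max_width_mm = body_max_width_mm,
                 width_position_rel = width_position_rel,
                 body_profile = body_profile,
                 body_rgb = body_rgb, awn_count = as.integer(round(awn_count)),
                 awn_length_mm = awn_length_mm,
                 awn_width_px = as.integer(round(awn_width_px)),
                 awn_rgb = awn_rgb, background_rgb = background_rgb,
                 chart = chart, mm_per_px = mm_per_px,
                 rotation_deg = rotation_deg, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# half-width (px) of the body at relative axis position t
body_halfwidth_px <- function(spec, t) {
  wp <- spec$width_position_rel
  hw <- spec$body_max_width_mm / spec$mm_per_px / 2
  out <- numeric(length(t))
  inside <- t >= 0 & t <= 1
  ti <- t[inside]
  if (spec$body_profile == "kite") {
    out[inside] <- hw * ifelse(ti <= wp, ti / wp, (1 - ti) / (1 - wp))
  } else {
    gamma <- log(0.5) / log(wp)
    out[inside] <- hw * sin(pi * ti^gamma)
  }
  out
}

# analytic body area in mm^2 for a spec
phantom_body_area_mm2 <- function(spec) {
  L <- spec$body_length_mm; W <- spec$body_max_width_mm
  if (spec$body_profile == "kite") {
    L * W / 2
  } else {
    gamma <- log(0.5) / log(spec$width_position_rel)
    L * W * stats::integrate(function(u) sin(pi * u^gamma), 0, 1,
                             rel.tol = 1e-10)$value
  }
}

#' Render a phantom
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: list with `image` (H x W x 3 array,
#'   0-255), `truth_mask` (integer matrix with the 4 class codes), `spec`, and
#'   `truth` (analytic ground truth: areas in mm^2, base/tip pixel
#'   coordinates, axis angle, pixel counts per class).
#' @export
generate_phantom <- function(spec) {
  ss_assert(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  mmpp <- spec$mm_per_px
  L_px <- spec$body_length_mm / mmpp
  hw_px <- spec$body_max_width_mm / mmpp / 2
  awn_px <- spec$awn_length_mm / mmpp
  theta <- spec$rotation_deg * pi / 180
  # axis unit vector in (x right, y down) coordinates, base -> tip (upwards)
  u <- c(sin(theta), -cos(theta))
  n <- c(-u[2], u[1]) # perpendicular

  # bounding extents of body + awns around the base point, before rotation
  lat <- hw_px + (if (spec$awn_count > 0) 0.85 * awn_px else 0) + 4
  top <- L_px + (if (spec$awn_count > 0) awn_px else 0) + 4
  corners <- rbind(c(-lat, 0), c(lat, 0), c(-lat, -top), c(lat, -top))
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rc <- corners %*% t(rot)
  margin <- 8
  spike_w <- diff(range(rc[, 1])) + 2 * margin
  spike_h <- diff(range(rc[, 2])) + 2 * margin

  chart_w <- 0; chart_h <- 0
  chart <- spec$chart
  if (!is.null(chart)) {
    side_px <- chart$patch_size_mm / mmpp
    pitch <- round(side_px * 1.25)
    chart_w <- chart$cols * pitch + margin
    chart_h <- chart$rows * pitch + margin
  }
  H <- ceiling(max(spike_h, chart_h + 2 * margin))
  W <- ceiling(spike_w + chart_w + margin)
  if (max(H, W) > 6000) {
    ss_stop("canvas would exceed 6000 px; decrease sizes or coarsen mm_per_px",
            "spikescan_sizing_error")
  }
  base <- c(chart_w + margin - min(rc[, 1]), H - margin) # (x, y)
  tip <- base + L_px * u

  # pixel coordinate grids (x = col, y = row)
  px <- matrix(rep(seq_len(W), each = H), H, W)
  py <- matrix(rep(seq_len(H), W), H, W)
  vx <- px - base[1]; vy <- py - base[2]
  t_axis <- (vx * u[1] + vy * u[2]) / L_px
  d_perp <- vx * n[1] + vy * n[2]

  mask <- matrix(MASK_CLASSES[["background"]], H, W)
  # half-pixel floor on the band: keeps the sub-pixel slivers at the sharp
  # base/tip rasterized, so the rendered body spans the full stated length
  body <- t_axis >= 0 & t_axis <= 1 &
    abs(d_perp) <= pmax(body_halfwidth_px(spec, pmin(pmax(t_axis, 0), 1)), 0.5)
  mask[body] <- MASK_CLASSES[["body"]]

  withr::with_seed(spec$seed, {
    # awns: thin strokes leaving the upper body boundary
    if (spec$awn_count > 0 && awn_px > 0.5) {
      t_att <- seq(0.55, 0.98, length.out = spec$awn_count)
      side <- rep_len(c(1, -1), spec$awn_count)
      tilt <- stats::runif(spec$awn_count, 5, 30) * pi / 180 # outward tilt
      wobble <- stats::runif(spec$awn_count, -5, 5) * pi / 180
      half <- (spec$awn_width_px - 1) / 2
      off <- expand.grid(dr = -ceiling(half):ceiling(half),
                         dc = -ceiling(half):ceiling(half))
      for (k in seq_len(spec$awn_count)) {
        hw_t <- body_halfwidth_px(spec, t_att[k])
        start <- base + t_att[k] * L_px * u + side[k] * hw_t * n
        ang <- tilt[k] + wobble[k]
        dirv <- cos(ang) * u + sin(ang) * n * side[k]
        s <- seq(0, awn_px, by = 0.35)
        ptx <- start[1] + s * dirv[1]
        pty <- start[2] + s * dirv[2]
        rr <- round(pty); cc <- round(ptx)
        for (o in seq_len(nrow(off))) {
          r2 <- rr + off$dr[o]; c2 <- cc + off$dc[o]
          keep <- (off$dr[o]^2 + off$dc[o]^2) <= max(half, 0.5)^2 + 1e-9
          if (!keep) next
          ok <- r2 >= 1 & r2 <= H & c2 >= 1 & c2 <= W
          ii <- cbind(r2[ok], c2[ok])
          cls <- mask[ii]
          ii <- ii[cls == MASK_CLASSES[["background"]], , drop = FALSE]
          mask[ii] <- MASK_CLASSES[["awn"]]
        }
      }
    }

    # chart patches
    chart_boxes <- NULL
    if (!is.null(chart)) {
      side_px <- round(chart$patch_size_mm / mmpp)
      pitch <- round(side_px * 1.25)
      pos <- chart$position_px
      if (is.null(pos)) pos <- c(margin, margin) # (row, col) top-left
      boxes <- vector("list", chart$rows * chart$cols)
      for (i in seq_len(chart$rows)) {
        for (j in seq_len(chart$cols)) {
          k <- (i - 1L) * chart$cols + j
          r0 <- pos[1] + (i - 1L) * pitch
          c0 <- pos[2] + (j - 1L) * pitch
          rs <- r0:(r0 + side_px - 1L); cs <- c0:(c0 + side_px - 1L)
          ss_assert(max(rs) <= H && max(cs) <= W,
                    "chart does not fit on the canvas", "spikescan_sizing_error")
          mask[rs, cs] <- MASK_CLASSES[["chart"]]
          boxes[[k]] <- c(r0 = r0, c0 = c0, side = side_px)
        }
      }
      chart_boxes <- do.call(rbind, boxes)
    }

    # paint the image from the final mask
    image <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- matrix(spec$background_rgb[ch], H, W)
      plane[mask == MASK_CLASSES[["body"]]] <- spec$body_rgb[ch]
      plane[mask == MASK_CLASSES[["awn"]]] <- spec$awn_rgb[ch]
      image[, , ch] <- plane
    }
    if (!is.null(chart)) {
      side_px <- chart_boxes[1, "side"]
      for (k in seq_len(nrow(chart_boxes))) {
        rs <- chart_boxes[k, "r0"]:(chart_boxes[k, "r0"] + side_px - 1L)
        cs <- chart_boxes[k, "c0"]:(chart_boxes[k, "c0"] + side_px - 1L)
        for (ch in 1:3) image[rs, cs, ch] <- chart$reference_rgb[k, ch]
      }
    }
    if (spec$noise_sd > 0) {
      image <- image + stats::rnorm(length(image), 0, spec$noise_sd)
      image <- clamp(round(image), 0, 255)
    }
  })

  storage.mode(mask) <- "integer"
  truth <- list(
    body_area_mm2 = phantom_body_area_mm2(spec),
    awn_area_mm2 = spec$awn_count * spec$awn_length_mm *
      (spec$awn_width_px * mmpp),
    base_px = c(x = base[1], y = base[2]),
    tip_px = c(x = tip[1], y = tip[2]),
    axis_angle_deg = spec$rotation_deg,
    class_px = c(background = sum(mask == 0L), chart = sum(mask == 1L),
                 body = sum(mask == 2L), awn = sum(mask == 3L)),
    chart_boxes = if (!is.null(chart)) chart_boxes else NULL
  )
  structure(list(image = image, truth_mask = mask, spec = spec, truth = truth),
            class = "phantom")
}

#' Generate a cohort of phantoms around a base specification
#'
#' Numeric fields named in `jitter` are perturbed multiplicatively with
#' Gaussian relative noise (`value * (1 + N(0, sd))`); RGB fields are jittered
#' per channel and clipped to 0-255. Each phantom receives its own seed drawn
#' from `seed`, so the cohort is reproducible as a whole.
#'
#' @param n number of phantoms (>= 1).
#' @param base_spec a [phantom_spec()].
#' @param jitter named list of non-negative relative standard deviations, e.g.
#'   `list(body_length_mm = 0.05, body_rgb = 0.03)`.
#' @param seed cohort seed.
#' @return object of class `phantom_cohort`: list with `phantoms` and the
#'   drawn `specs` (the per-phantom ground truth).
#' @export
generate_cohort <- function(n, base_spec, jitter = list(), seed = 1L) {
  ss_assert(is_scalar_num(n) && n >= 1, "n must be a positive integer")
  ss_assert(inherits(base_spec, "phantom_spec"), "base_spec must be a phantom_spec")
  ss_assert(is.list(jitter), "jitter must be a named list")
  if (length(jitter)) {
    ss_assert(all(names(jitter) %in% names(base_spec)),
              "jitter names must be phantom_spec fields")
    ss_assert(all(unlist(jitter) >= 0), "jitter sds must be non-negative")
  }
  n <- as.integer(n)
  specs <- withr::with_seed(as.integer(seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      s <- unclass(base_spec)
      for (f in names(jitter)) {
        sd <- jitter[[f]]
        if (sd == 0) next
        v <- s[[f]]
        if (f %in% c("body_rgb", "awn_rgb", "background_rgb")) {
          v <- clamp(round(v * (1 + stats::rnorm(3, 0, sd))), 0, 255)
        } else {
          v <- v * (1 + stats::rnorm(1, 0, sd))
        }
        s[[f]] <- v
      }
      # re-validate through the constructor, clamping the fragile fields
      s$width_position_rel <- clamp(s$width_position_rel, 0.05, 0.95)
      s$body_max_width_mm <- min(s$body_max_width_mm, 0.9 * s$body_length_mm)
      s$awn_count <- max(0L, as.integer(round(s$awn_count)))
      s$seed <- seeds[i]
      do.call(phantom_spec, s)
    })
  })
  structure(list(phantoms = lapply(specs, generate_phantom), specs = specs),
            class = "phantom_cohort")
}

#' Write a phantom to disk
#'
#' Image as binary PPM, truth mask as PGM of class codes, spec as JSON sidecar.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @param stem file stem, default `"phantom"`.
#' @return invisibly, the three paths written.
#' @export
write_phantom <- function(phantom, dir, stem = "phantom") {
  ss_assert(inherits(phantom, "phantom"), "phantom must be a phantom object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(stem, ".ppm"))
  p_mask <- file.path(dir, paste0(stem, "_mask.pgm"))
  p_spec <- file.path(dir, paste0(stem, "_spec.json"))
  write_pnm(phantom$image, p_img)
  write_mask(phantom$truth_mask, p_mask)
  spec <- unclass(phantom$spec)
  if (!is.null(spec$chart)) spec$chart <- unclass(spec$chart)
  jsonlite::write_json(spec, p_spec, auto_unbox = TRUE, digits = NA)
  invisible(c(image = p_img, mask = p_mask, spec = p_spec))
}
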