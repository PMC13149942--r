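#' Classical segmentation of spike photographs
#'
#' Splits an image taken against a uniform blue backdrop into the four scene
#' classes (background, colour chart, spike body, awns) and derives scale and
#' colour calibration from the chart. The approach is deliberately classical:
#' background removal by a hue window around the modal backdrop hue, chart
#' detection as a cluster of small rectangular patches, and separation of the
#' thick spike body from thin awns by morphological opening — awns are roughly
#' an order of magnitude thinner than the body, so they are exactly the
#' foreground the opening erases. Masks produced by any external segmenter can
#' be loaded instead via [load_mask()].
#'
#' @name segmentation
NULL

#' Segmentation configuration
#'
#' @param background_hue_window full width, in degrees, of the hue window
#'   around the modal background hue that is classified as backdrop.
#' @param min_body_component_px smallest connected component accepted as a
#'   spike body.
#' @param body_opening_radius_px disk radius of the morphological opening that
#'   separates the body from thin structures. The default of 5 px suits
#'   ~0.2 mm/px imagery where awns are 1-3 px thick.
#' @param awn_max_thickness_px maximal local thickness, in px, for residue to
#'   be labelled awn.
#' @param min_awn_component_px smallest residue component accepted as awn;
#'   filters the one-pixel fringe the opening shaves off the body outline.
#' @param mm_per_px fallback scale used by [calibrate()] when no chart is
#'   available.
#' @param min_background_saturation pixels less saturated than this are never
#'   counted as backdrop (protects grey/white chart patches).
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(background_hue_window = 40,
                                min_body_component_px = 64L,
                                body_opening_radius_px = 5L,
                                awn_max_thickness_px = 4L,
                                min_awn_component_px = 25L,
                                mm_per_px = NULL,
                                min_background_saturation = 0.15) {
  ss_assert(background_hue_window > 0 && min_body_component_px > 0 &&
              body_opening_radius_px > 0 && awn_max_thickness_px > 0,
            "all segmentation_config sizes must be positive")
  structure(list(background_hue_window = background_hue_window,
                 min_body_component_px = as.integer(min_body_component_px),
                 body_opening_radius_px = as.integer(body_opening_radius_px),
                 awn_max_thickness_px = as.integer(awn_max_thickness_px),
                 min_awn_component_px = as.integer(min_awn_component_px),
                 mm_per_px = mm_per_px,
                 min_background_saturation = min_background_saturation),
            class = "segmentation_config")
}

image_hsv <- function(image) {
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(as.vector(image[, , 1]), as.vector(image[, , 2]),
                            as.vector(image[, , 3]), maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# rectangularity + aspect screen for chart patch candidates
component_stats <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  out <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    rr <- range(w[, 1]); cc <- range(w[, 2])
    bh <- diff(rr) + 1L; bw <- diff(cc) + 1L
    c(id = id, area = nrow(w), bh = bh, bw = bw,
      fill = nrow(w) / (bh * bw),
      cy = mean(w[, 1]), cx = mean(w[, 2]))
  })
  do.call(rbind, out)
}

#' Segment a spike photograph
#'
#' @param image RGB array (0-255).
#' @param config a [segmentation_config()].
#' @return integer label mask (0 background, 1 chart, 2 body, 3 awn).
#' @export
segment_image <- function(image, config = segmentation_config()) {
  validate_image(image)
  hsv <- image_hsv(image)
  sat_ok <- hsv$s >= config$min_background_saturation
  # modal hue of the saturated pixels = backdrop hue (backdrop dominates)
  hh <- round(hsv$h[sat_ok])
  if (!length(hh)) ss_stop("no saturated pixels; not a backdrop scene",
                           "spikescan_empty_scene_error")
  h0 <- as.numeric(names(which.max(table(hh))))
  background <- sat_ok & hue_dist(hsv$h, h0) <= config$background_hue_window / 2
  fg <- !background
  if (!any(fg)) ss_stop("no foreground found", "spikescan_empty_scene_error")

  h <- nrow(fg); w <- ncol(fg)
  borders <- c(any(fg[1, ]), any(fg[h, ]), any(fg[, 1]), any(fg[, w]))
  if (sum(borders) >= 3) {
    warning("foreground touches three or more image borders; check framing",
            call. = FALSE)
  }

  mask <- matrix(MASK_CLASSES[["background"]], h, w)
  lab <- label_components(fg)
  stats <- component_stats(lab)

  # chart: cluster of >= 6 small rectangular components
  is_patch <- stats[, "fill"] >= 0.85 &
    stats[, "bh"] / stats[, "bw"] >= 0.5 & stats[, "bh"] / stats[, "bw"] <= 2 &
    stats[, "area"] >= 16 & stats[, "area"] <= 0.02 * h * w
  # the body is large and elongated; never a patch
  is_patch[which.max(stats[, "area"])] <- FALSE
  if (sum(is_patch) >= 6) {
    chart_ids <- stats[is_patch, "id"]
    mask[lab %in% chart_ids] <- MASK_CLASSES[["chart"]]
  }

  nonbg <- fg & mask != MASK_CLASSES[["chart"]]
  if (!any(nonbg)) ss_stop("no spike foreground found",
                           "spikescan_empty_scene_error")
  opened <- binary_open(nonbg, config$body_opening_radius_px)
  body <- largest_component(opened)$mask
  if (sum(body) < config$min_body_component_px) {
    ss_stop("no body component above min_body_component_px",
            "spikescan_empty_scene_error")
  }
  mask[body] <- MASK_CLASSES[["body"]]

  # residue: thin structures attached to (or near) the body -> awns
  residue <- nonbg & !body
  if (any(residue)) {
    near_body <- binary_dilate(body, 2L * config$body_opening_radius_px)
    fringe <- binary_dilate(body, 3L) # opening shaves a 1-2 px halo off the
    # body outline; true awns protrude well beyond it
    rlab <- label_components(residue)
    rstats <- component_stats(rlab)
    thin_r <- ceiling((config$awn_max_thickness_px + 1) / 2)
    thick <- binary_erode(residue, thin_r) # survives => too thick for an awn
    touching <- binary_dilate(body, 1L)
    for (k in seq_len(nrow(rstats))) {
      comp <- rlab == rstats[k, "id"]
      # awns are elongated thin structures reaching beyond the body fringe;
      # compact wedges/fringe shaved off the body outline by the opening are
      # body and get reattached, detached specks stay background
      diag_px <- sqrt(rstats[k, "bh"]^2 + rstats[k, "bw"]^2)
      is_awn <- rstats[k, "area"] >= config$min_awn_component_px &&
        diag_px >= 4 * config$awn_max_thickness_px &&
        any(comp & near_body) && any(comp & !fringe) && !any(comp & thick)
      if (is_awn) {
        mask[comp] <- MASK_CLASSES[["awn"]]
      } else if (any(comp & touching) && !any(comp & !near_body)) {
        # compact residue hugging the body: outline fringe and sharp tips the
        # opening shaved off; anything reaching further is not body
        mask[comp] <- MASK_CLASSES[["body"]]
      }
    }
  }
  storage.mode(mask) <- "integer"
  mask
}

#' Scale and colour calibration
#'
#' With a chart present in the mask, the scale is
#' `patch_size_mm / median observed patch side (px)` and the colour transform
#' is the least-squares affine map (3 x 4 matrix, RGB plus offset) from
#' observed patch mean RGB to the chart's reference RGB. Without a chart an
#' explicit `mm_per_px` must be supplied and the transform is the identity.
#'
#' @param image RGB array.
#' @param mask label mask aligned with `image`.
#' @param chart reference [chart_spec()]; `NULL` when no chart is in frame.
#' @param mm_per_px explicit scale, required when `chart` is `NULL`.
#' @return object of class `calibration`: list with `mm_per_px`,
#'   `color_transform` (3 x 4), `patch_rmse` and `n_patches`.
#' @export
calibrate <- function(image, mask, chart = NULL, mm_per_px = NULL) {
  if (is.null(chart)) {
    ss_assert(is_scalar_num(mm_per_px) && mm_per_px > 0,
              "mm_per_px must be supplied when no chart is available",
              "spikescan_calibration_error")
    return(structure(list(mm_per_px = mm_per_px,
                          color_transform = cbind(diag(3), 0),
                          patch_rmse = NA_real_, n_patches = 0L),
                     class = "calibration"))
  }
  validate_mask(mask, image)
  chart_px <- mask == MASK_CLASSES[["chart"]]
  lab <- label_components(chart_px)
  if (max(lab) < 6) {
    ss_stop("fewer than 6 chart patches detected", "spikescan_calibration_error")
  }
  stats <- component_stats(lab)
  side <- stats::median((stats[, "bh"] + stats[, "bw"]) / 2)
  mmpp <- chart$patch_size_mm / side

  # observed mean RGB per detected patch
  obs <- t(vapply(seq_len(nrow(stats)), function(k) {
    comp <- lab == stats[k, "id"]
    vapply(1:3, function(ch) mean(image[, , ch][comp]), numeric(1))
  }, numeric(3)))

  # correspondence: predicted patch centres when the grid position is known,
  # otherwise a grid fit anchored at the minimal centroid
  side_px <- side
  pitch <- side_px * 1.25
  if (!is.null(chart$position_px)) {
    ctr <- expand.grid(j = seq_len(chart$cols), i = seq_len(chart$rows))
    pred_r <- chart$position_px[1] + (ctr$i - 1) * round(pitch) + side_px / 2
    pred_c <- chart$position_px[2] + (ctr$j - 1) * round(pitch) + side_px / 2
    ref_idx <- vapply(seq_len(nrow(stats)), function(k) {
      which.min((pred_r - stats[k, "cy"])^2 + (pred_c - stats[k, "cx"])^2)
    }, integer(1))
    ref_idx <- (ctr$i[ref_idx] - 1L) * chart$cols + ctr$j[ref_idx]
  } else {
    gi <- round((stats[, "cy"] - min(stats[, "cy"])) / pitch)
    gj <- round((stats[, "cx"] - min(stats[, "cx"])) / pitch)
    ref_idx <- gi * chart$cols + gj + 1L
  }
  ok <- ref_idx >= 1 & ref_idx <= nrow(chart$reference_rgb) & !duplicated(ref_idx)
  if (sum(ok) < 6) {
    ss_stop("could not match 6 chart patches to the reference grid",
            "spikescan_calibration_error")
  }
  obs <- obs[ok, , drop = FALSE]
  ref <- chart$reference_rgb[ref_idx[ok], , drop = FALSE]

  X <- cbind(obs, 1)
  B <- qr.solve(X, ref)           # 4 x 3
  fit <- X %*% B
  rmse <- sqrt(mean((fit - ref)^2))
  B <- unname(t(B))
  structure(list(mm_per_px = mmpp, color_transform = B,
                 patch_rmse = rmse, n_patches = sum(ok)),
            class = "calibration")
}

#' Apply a calibration's colour transform to an image
#'
#' @param image RGB array (0-255).
#' @param cal a [calibrate()] result.
#' @return colour-corrected RGB array, clipped to [0, 255].
#' @export
apply_color_transform <- function(image, cal) {
  validate_image(image)
  ss_assert(inherits(cal, "calibration"), "cal must be a calibration")
  d <- dim(image)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]), 1)
  out <- px %*% t(cal$color_transform)
  array(clamp(out, 0, 255), d)
}

#' Save / load a calibration as JSON
#' @param cal a `calibration` object.
#' @param path JSON file path.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(list(mm_per_px = cal$mm_per_px,
                            color_transform = cal$color_transform,
                            patch_rmse = cal$patch_rmse,
                            n_patches = cal$n_patches),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- x$color_transform
  if (!is.matrix(m)) m <- matrix(unlist(m), 3, 4, byrow = TRUE)
  structure(list(mm_per_px = x$mm_per_px, color_transform = m,
                 patch_rmse = x$patch_rmse, n_patches = x$n_patches),
            class = "calibration")
}
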