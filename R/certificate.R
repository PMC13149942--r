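#' The digital spike certificate
#'
#' A certificate is the fixed per-spike feature record used to compare
#' accessions: two blocks (frontal and lateral), each holding 24 features —
#' the 11 quadrangle-model parameters, 7 outline descriptors (`c_L`, `c_P`,
#' `c_S`, `c_Ci`, `c_Ro`, `c_So`, `c_Ru`), the mean R, G, B of the spike body
#' and the mean R, G, B of the awns. The awn area `c_Sa` is carried alongside
#' each block (it is reported with the certificate indices in group
#' comparisons although it is not one of the 7 outline descriptors). The
#' frontal block averages the frontal and back views; the lateral block
#' averages the two side views. A spike photographed in a single view gets a
#' certificate populated from that view only.
#'
#' @name certificate
NULL

CERT_VIEWS <- c("frontal", "back", "side1", "side2")
CERT_BLOCK_OF_VIEW <- c(frontal = "frontal", back = "frontal",
                        side1 = "lateral", side2 = "lateral")
CERT_FEATURES <- c("q_L", "q_W", "q_pW", "q_a", "q_b", "q_alpha", "q_beta",
                   "q_gamma", "q_A", "q_P", "q_r",
                   "c_L", "c_P", "c_S", "c_Ci", "c_Ro", "c_So", "c_Ru",
                   "body_R", "body_G", "body_B", "awn_R", "awn_G", "awn_B")

#' Build a per-view feature record
#'
#' @param spike_id spike identifier.
#' @param view one of `"frontal"`, `"back"`, `"side1"`, `"side2"`.
#' @param morpho named vector from [morphometric_features()] (or the
#'   concatenation of [outline_features()] and [fit_quadrangle()]).
#' @param body_rgb,awn_rgb mean R, G, B of body and awn pixels (from
#'   [mean_colors()]); awn values may be `NA` for awnless spikes.
#' @param meta optional named list of acquisition metadata.
#' @return object of class `view_record`.
#' @export
view_record <- function(spike_id, view, morpho, body_rgb, awn_rgb = c(NA, NA, NA),
                        meta = list()) {
  view <- match.arg(view, CERT_VIEWS)
  needed <- setdiff(CERT_FEATURES, c("body_R", "body_G", "body_B",
                                     "awn_R", "awn_G", "awn_B"))
  ss_assert(all(c(needed, "c_Sa") %in% names(morpho)),
            "morpho must contain the 11 q_* and 8 c_* features")
  feats <- c(morpho[needed],
             stats::setNames(as.numeric(body_rgb[1:3]),
                             c("body_R", "body_G", "body_B")),
             stats::setNames(as.numeric(awn_rgb[1:3]),
                             c("awn_R", "awn_G", "awn_B")))
  structure(list(spike_id = spike_id, view = view,
                 features = feats[CERT_FEATURES],
                 c_Sa = unname(morpho[["c_Sa"]]), meta = meta),
            class = "view_record")
}

#' Helper: a view record straight from a mask + image
#'
#' Runs the morphometric and colour stages on one segmented view.
#'
#' @inheritParams view_record
#' @param image RGB array.
#' @param mask label mask.
#' @param cal a `calibration`.
#' @return a [view_record()].
#' @export
view_record_from_mask <- function(spike_id, view, image, mask, cal) {
  morpho <- morphometric_features(mask, cal)
  body_mc <- mean_colors(image, mask, "body", cal)
  awn_mc <- mean_colors(image, mask, "awn", cal)
  view_record(spike_id, view, morpho,
              body_rgb = body_mc[c("R", "G", "B")],
              awn_rgb = awn_mc[c("R", "G", "B")])
}

#' Assemble the digital certificate of one spike
#'
#' @param records list of [view_record()]s for a single spike (>= 1, no
#'   duplicated views).
#' @return object of class `spike_certificate`: `spike_id`, `frontal`,
#'   `lateral` (each a named 24-vector or `NULL` when no view of that block
#'   exists), `c_Sa` per block, and `views_used`.
#' @export
assemble_certificate <- function(records) {
  ss_assert(length(records) >= 1, "at least one view record is required")
  views <- vapply(records, function(r) r$view, character(1))
  ids <- unique(vapply(records, function(r) as.character(r$spike_id), character(1)))
  ss_assert(length(ids) == 1L, "records must belong to a single spike")
  if (anyDuplicated(views)) {
    ss_stop(sprintf("duplicate view label(s): %s",
                    paste(unique(views[duplicated(views)]), collapse = ", ")),
            "spikescan_ambiguity_error")
  }
  blocks <- list(frontal = NULL, lateral = NULL)
  c_sa <- list(frontal = NA_real_, lateral = NA_real_)
  used <- list(frontal = character(0), lateral = character(0))
  for (blk in c("frontal", "lateral")) {
    in_blk <- views[CERT_BLOCK_OF_VIEW[views] == blk]
    if (!length(in_blk)) next
    recs <- records[views %in% in_blk]
    m <- do.call(rbind, lapply(recs, function(r) r$features))
    # average the available views; awn colours of awnless spikes stay missing
    f <- apply(m, 2, function(col) {
      v <- mean(col, na.rm = TRUE)
      if (is.nan(v)) NA_real_ else v
    })
    blocks[[blk]] <- f
    c_sa[[blk]] <- mean(vapply(recs, function(r) r$c_Sa, numeric(1)), na.rm = TRUE)
    used[[blk]] <- sort(in_blk)
  }
  structure(list(spike_id = records[[1]]$spike_id,
                 frontal = blocks$frontal, lateral = blocks$lateral,
                 c_Sa = c_sa, views_used = used),
            class = "spike_certificate")
}

# block matrix (spikes x features, c_Sa appended) from a list of certificates
certificate_block_matrix <- function(certs, block) {
  block <- match.arg(block, c("frontal", "lateral"))
  have <- vapply(certs, function(ct) !is.null(ct[[block]]), logical(1))
  certs <- certs[have]
  if (!length(certs)) return(NULL)
  m <- do.call(rbind, lapply(certs, function(ct) c(ct[[block]],
                                                   c_Sa = ct$c_Sa[[block]])))
  rownames(m) <- vapply(certs, function(ct) as.character(ct$spike_id), character(1))
  m
}

#' Compare certificate features between two groups of spikes
#'
#' Per-feature two-sample location test on one certificate block. The default
#' is Welch's t-test with Benjamini-Hochberg correction across the 25
#' features (24 certificate features plus `c_Sa`); a Mann-Whitney U test and
#' uncorrected p-values are available. Features with zero variance in both
#' groups and equal means get `p = 1` by convention.
#'
#' @param certs_a,certs_b lists of [assemble_certificate()] results; each
#'   group must contribute at least 3 spikes with the requested block.
#' @param block `"frontal"` or `"lateral"`.
#' @param alpha significance level for the `significant` flag.
#' @param correction `"BH"` or `"none"`.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return data.frame, one row per feature: group means and sizes, statistic,
#'   `p_value`, adjusted `p_adj`, `significant`, `method`.
#' @export
compare_groups <- function(certs_a, certs_b, block = "frontal", alpha = 0.05,
                           correction = c("BH", "none"),
                           method = c("welch", "wilcoxon")) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  ma <- certificate_block_matrix(certs_a, block)
  mb <- certificate_block_matrix(certs_b, block)
  ss_assert(!is.null(ma) && nrow(ma) >= 3 && !is.null(mb) && nrow(mb) >= 3,
            "each group needs at least 3 spikes with the requested block",
            "spikescan_precondition_error")
  feats <- colnames(ma)
  res <- lapply(feats, function(f) {
    a <- ma[, f]; b <- mb[, f]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3) {
      return(data.frame(feature = f, mean_a = mean(a), mean_b = mean(b),
                        n_a = length(a), n_b = length(b),
                        statistic = NA_real_, p_value = NA_real_))
    }
    va <- stats::var(a); vb <- stats::var(b)
    if (va < 1e-24 && vb < 1e-24) {
      p <- if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0
      return(data.frame(feature = f, mean_a = mean(a), mean_b = mean(b),
                        n_a = length(a), n_b = length(b),
                        statistic = NA_real_, p_value = p))
    }
    tt <- if (method == "welch") {
      stats::t.test(a, b)
    } else {
      suppressWarnings(stats::wilcox.test(a, b))
    }
    data.frame(feature = f, mean_a = mean(a), mean_b = mean(b),
               n_a = length(a), n_b = length(b),
               statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- if (correction == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$method <- method
  out
}

# kite polygon vertices (x = half-width axis, y = length axis), mm
kite_polygon <- function(q) {
  rbind(c(0, 0),
        c(-q[["q_W"]] / 2, q[["q_pW"]] * q[["q_L"]]),
        c(0, q[["q_L"]]),
        c(q[["q_W"]] / 2, q[["q_pW"]] * q[["q_L"]]))
}

#' Render certificate polygon models
#'
#' Draws each spike's kite polygon as a thin blue outline; with
#' `mean_overlay = TRUE` the polygon of the group's mean parameters is drawn
#' thick in red and filled with the group's mean body colour. Following the
#' usual presentation of such models, the width (x) axis is magnified
#' `width_magnification`-fold relative to the length (y) axis; both axes are
#' in mm.
#'
#' @param certs list of certificates.
#' @param block `"frontal"` or `"lateral"`.
#' @param out_path output figure path (`.pdf`, `.svg` or `.png` decide the
#'   device); `NULL` draws on the current device.
#' @param mean_overlay draw the mean-parameter polygon.
#' @param width_magnification x-axis magnification factor (default 5).
#' @param title plot title.
#' @return invisibly, a list with the individual polygons (mm coordinates)
#'   and the mean polygon (or `NULL`).
#' @export
render_models <- function(certs, block = "frontal", out_path = NULL,
                          mean_overlay = TRUE, width_magnification = 5,
                          title = NULL) {
  m <- certificate_block_matrix(certs, block)
  if (is.null(m)) {
    warning("no certificate carries the requested block; nothing drawn",
            call. = FALSE)
    return(invisible(list(polygons = list(), mean_polygon = NULL)))
  }
  polys <- lapply(seq_len(nrow(m)), function(i) kite_polygon(m[i, ]))
  mean_poly <- NULL
  mean_rgb <- c(200, 200, 200)
  if (mean_overlay) {
    mu <- colMeans(m, na.rm = TRUE)
    mean_poly <- kite_polygon(mu)
    if (all(is.finite(mu[c("body_R", "body_G", "body_B")]))) {
      mean_rgb <- mu[c("body_R", "body_G", "body_B")]
    }
  }
  if (!is.null(out_path)) {
    ext <- tolower(sub(".*\\.", "", out_path))
    switch(ext,
           pdf = grDevices::pdf(out_path, width = 4, height = 6),
           svg = grDevices::svg(out_path, width = 4, height = 6),
           png = grDevices::png(out_path, width = 480, height = 720),
           ss_stop("out_path must end in .pdf, .svg or .png",
                   "spikescan_format_error"))
    on.exit(grDevices::dev.off())
  }
  xr <- range(vapply(polys, function(p) range(p[, 1]), numeric(2)))
  yr <- range(vapply(polys, function(p) range(p[, 2]), numeric(2)))
  graphics::plot(NA, xlim = xr * 1.15, ylim = yr + c(-2, 2),
                 asp = 1 / width_magnification,
                 xlab = "width (mm)", ylab = "length (mm)",
                 main = title %||% sprintf("spike models (%s view)", block))
  for (p in polys) {
    graphics::polygon(p[, 1], p[, 2], border = "steelblue", lwd = 1)
  }
  if (!is.null(mean_poly)) {
    fill <- grDevices::rgb(mean_rgb[1], mean_rgb[2], mean_rgb[3],
                           maxColorValue = 255)
    graphics::polygon(mean_poly[, 1], mean_poly[, 2], border = "red",
                      lwd = 3, col = fill)
  }
  invisible(list(polygons = polys, mean_polygon = mean_poly))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Certificates as a one-row-per-spike data frame
#'
#' @param certs list of certificates.
#' @return data.frame with `spike_id` and `<block>_<feature>` columns
#'   (including `c_Sa`) for both blocks.
#' @export
certificates_to_df <- function(certs) {
  rows <- lapply(certs, function(ct) {
    row <- list(spike_id = ct$spike_id)
    for (blk in c("frontal", "lateral")) {
      v <- ct[[blk]]
      if (is.null(v)) v <- stats::setNames(rep(NA_real_, length(CERT_FEATURES)),
                                           CERT_FEATURES)
      names(v) <- paste0(blk, "_", names(v))
      row <- c(row, as.list(v),
               stats::setNames(list(ct$c_Sa[[blk]]), paste0(blk, "_c_Sa")))
    }
    as.data.frame(row, check.names = FALSE)
  })
  do.call(rbind, rows)
}
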