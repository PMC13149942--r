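#' Colour features of spike body and awns
#'
#' Mean colour is reported in four colour spaces (12 components): RGB; CIELAB
#' (sRGB primaries, D65 white, L in 0-100); HSV (H in degrees, averaged
#' circularly; S, V in 0-1); and YCbCr with the standard-definition luma
#' coefficients (0.299/0.587/0.114, chroma offset 128). Dominant colours are
#' the three k-means cluster centroids of the region's RGB values, ordered by
#' cluster size. An empty region (e.g. awns of an awnless spike) yields
#' missing values, not zeros — zero is a valid black colour.
#'
#' @name colorimetry
NULL

MEAN_COLOR_COMPONENTS <- c("R", "G", "B", "L", "a", "b",
                           "H", "S", "V", "Y", "Cr", "Cb")

region_pixels <- function(image, mask, region) {
  validate_mask(mask, image)
  ss_assert(region %in% c("body", "awn"), "region must be 'body' or 'awn'")
  sel <- region_mask(mask, region)
  cbind(R = image[, , 1][sel], G = image[, , 2][sel], B = image[, , 3][sel])
}

rgb_to_ycbcr <- function(rgb) {
  y <- 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3]
  cb <- 128 - 0.168736 * rgb[, 1] - 0.331264 * rgb[, 2] + 0.5 * rgb[, 3]
  cr <- 128 + 0.5 * rgb[, 1] - 0.418688 * rgb[, 2] - 0.081312 * rgb[, 3]
  cbind(Y = y, Cb = cb, Cr = cr)
}

#' Mean colour components of a region in four colour spaces
#'
#' @param image RGB array (0-255).
#' @param mask label mask aligned with the image.
#' @param region `"body"` or `"awn"`.
#' @param cal optional `calibration`; when given, its colour transform is
#'   applied before averaging.
#' @return named numeric vector of the 12 components
#'   (`R,G,B,L,a,b,H,S,V,Y,Cr,Cb`); all `NA` with attribute `missing = TRUE`
#'   for an empty region.
#' @export
mean_colors <- function(image, mask, region, cal = NULL) {
  validate_image(image)
  if (!is.null(cal)) image <- apply_color_transform(image, cal)
  px <- region_pixels(image, mask, region)
  if (!nrow(px)) {
    out <- stats::setNames(rep(NA_real_, 12L), MEAN_COLOR_COMPONENTS)
    attr(out, "missing") <- TRUE
    return(out)
  }
  lab <- grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
  hsv <- grDevices::rgb2hsv(px[, 1], px[, 2], px[, 3], maxColorValue = 255)
  ycc <- rgb_to_ycbcr(px)
  out <- c(R = mean(px[, 1]), G = mean(px[, 2]), B = mean(px[, 3]),
           L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]),
           H = circular_mean_deg(hsv[1, ] * 360),
           S = mean(hsv[2, ]), V = mean(hsv[3, ]),
           Y = mean(ycc[, 1]), Cr = mean(ycc[, 3]), Cb = mean(ycc[, 2]))
  attr(out, "missing") <- FALSE
  out
}

# seeded k-means++ initialisation
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Dominant colours of a region by k-means
#'
#' Seeded k-means++ initialisation with 10 restarts (Lloyd iterations) on the
#' region's RGB triples; clusters are returned in decreasing order of pixel
#' count. With fewer distinct colours than `k`, the distinct colours are used
#' as degenerate clusters, remaining slots duplicate the largest centroid with
#' zero proportion, and the `merged` attribute is set.
#'
#' @inheritParams mean_colors
#' @param k number of clusters (the certificate uses 3).
#' @param seed RNG seed for the initialisation.
#' @param restarts number of k-means++ restarts.
#' @return data.frame with `k` rows: `R`, `G`, `B` (centroid), `prop`
#'   (proportion of region pixels), ordered by descending `prop`; attribute
#'   `merged` flags degenerate inputs.
#' @export
dominant_colors <- function(image, mask, region, k = 3L, seed = 1L,
                            restarts = 10L, cal = NULL) {
  validate_image(image)
  if (!is.null(cal)) image <- apply_color_transform(image, cal)
  px <- region_pixels(image, mask, region)
  ss_assert(nrow(px) > 0, "region is empty", "spikescan_geometry_error")
  uniq <- unique(px)
  merged <- FALSE
  if (nrow(uniq) <= k) {
    # degenerate: each distinct colour is its own cluster
    merged <- nrow(uniq) < k
    cnt <- vapply(seq_len(nrow(uniq)), function(i) {
      sum(px[, 1] == uniq[i, 1] & px[, 2] == uniq[i, 2] & px[, 3] == uniq[i, 3])
    }, numeric(1))
    o <- order(cnt, decreasing = TRUE)
    centers <- uniq[o, , drop = FALSE]
    prop <- cnt[o] / nrow(px)
    while (nrow(centers) < k) {
      centers <- rbind(centers, centers[1, ])
      prop <- c(prop, 0)
      merged <- TRUE
    }
  } else {
    best <- NULL
    withr::with_seed(as.integer(seed), {
      for (r in seq_len(restarts)) {
        init <- kmeanspp_init(uniq, k)
        km <- tryCatch(
          suppressWarnings(stats::kmeans(px, centers = init, iter.max = 100L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL) # empty-cluster restarts are discarded
        if (!is.null(km) &&
            (is.null(best) || km$tot.withinss < best$tot.withinss)) best <- km
      }
    })
    if (is.null(best)) { # every restart collapsed; fall back to one Lloyd run
      best <- suppressWarnings(
        stats::kmeans(px, centers = uniq[seq_len(k), , drop = FALSE],
                      iter.max = 100L, algorithm = "Lloyd"))
    }
    o <- order(best$size, decreasing = TRUE)
    centers <- best$centers[o, , drop = FALSE]
    prop <- best$size[o] / nrow(px)
  }
  out <- data.frame(R = centers[, 1], G = centers[, 2], B = centers[, 3],
                    prop = prop)
  attr(out, "merged") <- merged
  out
}
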