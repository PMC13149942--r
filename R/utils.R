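#' @keywords internal
"_PACKAGE"

# classed errors so callers can distinguish validation/geometry/format failures
ss_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spikescan_error", "error", "condition")))
}

ss_assert <- function(ok, msg, class = "spikescan_validation_error") {
  if (!isTRUE(ok)) ss_stop(msg, class)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# circular distance between hues in degrees
hue_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# circular mean of angles in degrees, NA if empty
circular_mean_deg <- function(h) {
  h <- h[!is.na(h)]
  if (!length(h)) return(NA_real_)
  r <- h * pi / 180
  m <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  m %% 360
}

rgb_triple <- function(x, what) {
  ss_assert(is.numeric(x) && length(x) == 3L && all(is.finite(x)) &&
              all(x >= 0) && all(x <= 255),
            sprintf("%s must be an RGB triple in [0, 255]", what))
  as.numeric(x)
}
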