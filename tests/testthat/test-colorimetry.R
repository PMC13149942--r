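test_that("uniform regions give exact means in every colour space", {
  img <- array(0, c(12, 12, 3))
  img[, , 1] <- 120; img[, , 2] <- 110; img[, , 3] <- 60
  mc <- mean_colors(img, matrix(2L, 12, 12), "body")
  expect_equal(mc[["R"]], 120)
  expect_equal(mc[["G"]], 110)
  expect_equal(mc[["B"]], 60)
  expect_equal(mc[["V"]], 120 / 255)

  grey <- array(128, c(8, 8, 3))
  g <- mean_colors(grey, matrix(2L, 8, 8), "body")
  expect_lt(abs(g[["a"]]), 0.5)
  expect_lt(abs(g[["b"]]), 0.5)
  expect_equal(g[["Cr"]], 128)
  expect_equal(g[["Cb"]], 128)
})

test_that("hue is averaged circularly", {
  img <- array(0, c(10, 20, 3))
  img[, 1:10, 1] <- 255   # pure red, H = 0
  img[, 11:20, 3] <- 255  # pure blue, H = 240
  mc <- mean_colors(img, matrix(2L, 10, 20), "body")
  # circular mean of 0 and 240 the short way round is 300
  expect_equal(mc[["H"]], 300)
})

test_that("empty regions yield missing values, not zeros", {
  ph <- generate_phantom(fast_kite_spec(mm_per_px = 0.5)) # awnless
  mc <- mean_colors(ph$image, ph$truth_mask, "awn")
  expect_true(all(is.na(mc)))
  expect_true(attr(mc, "missing"))
  expect_error(dominant_colors(ph$image, ph$truth_mask, "awn"),
               class = "spikescan_geometry_error")
})

test_that("dominant colours recover planted 3-colour mixtures", {
  planted <- rbind(c(180, 160, 100), c(120, 90, 60), c(220, 210, 170))
  props <- c(0.5, 0.3, 0.2)
  n <- 40
  img <- array(0, c(n, n, 3))
  cut1 <- round(n * props[1]); cut2 <- round(n * (props[1] + props[2]))
  rows <- list(1:cut1, (cut1 + 1):cut2, (cut2 + 1):n)
  for (b in 1:3) for (ch in 1:3) img[rows[[b]], , ch] <- planted[b, ch]
  # mild noise so the clusters are realistic but well separated
  set.seed(1)
  img <- pmax(pmin(img + array(rnorm(length(img), 0, 2), dim(img)), 255), 0)
  dc <- dominant_colors(img, matrix(2L, n, n), "body", seed = 4L)
  expect_equal(nrow(dc), 3L)
  expect_true(all(abs(as.matrix(dc[, 1:3]) - planted) <= 2))
  expect_true(all(abs(dc$prop - props) <= 0.02))
})

test_that("first dominant colour tracks the mean colour on natural spikes", {
  # unimodal colouring (flat pigment + noise), as on a real spike body
  ph <- generate_phantom(fast_kite_spec(mm_per_px = 0.4, noise_sd = 8,
                                        seed = 12L))
  dc <- dominant_colors(ph$image, ph$truth_mask, "body", seed = 2L)
  mc <- mean_colors(ph$image, ph$truth_mask, "body")
  expect_true(all(abs(unlist(dc[1, 1:3]) - mc[c("R", "G", "B")]) < 10))
})

test_that("dominant colours are deterministic in the seed and degenerate inputs merge", {
  img <- array(0, c(10, 10, 3))
  img[, , 1] <- 77; img[, , 2] <- 66; img[, , 3] <- 55
  dc <- dominant_colors(img, matrix(2L, 10, 10), "body")
  expect_true(attr(dc, "merged"))
  expect_equal(dc$prop, c(1, 0, 0))
  expect_true(all(dc$R == 77))

  ph <- generate_phantom(fast_kite_spec(mm_per_px = 0.4, noise_sd = 6, seed = 2L))
  d1 <- dominant_colors(ph$image, ph$truth_mask, "body", seed = 10L)
  d2 <- dominant_colors(ph$image, ph$truth_mask, "body", seed = 10L)
  expect_identical(d1, d2)
})

test_that("proportions partition the region and reconstruct the mean colour", {
  ph <- generate_phantom(fast_kite_spec(mm_per_px = 0.4, noise_sd = 8, seed = 6L))
  dc <- dominant_colors(ph$image, ph$truth_mask, "body", seed = 1L)
  expect_equal(sum(dc$prop), 1, tolerance = 1e-9)
  mc <- mean_colors(ph$image, ph$truth_mask, "body")
  recon <- colSums(as.matrix(dc[, 1:3]) * dc$prop)
  expect_equal(unname(recon), unname(mc[c("R", "G", "B")]), tolerance = 1e-6)
})
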