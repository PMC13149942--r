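test_that("constant region collapses the GLCM to a single cell", {
  img <- array(100, c(16, 16, 3))
  f <- glcm_features(img, matrix(2L, 16, 16))
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["dissimilarity"]], 0)
  expect_equal(f[["homogeneity"]], 1)
  expect_equal(f[["ASM"]], 1)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["maximum_probability"]], 1)
  expect_equal(f[["correlation"]], 0) # convention for zero variance
  expect_true(attr(f, "constant"))
})

test_that("checkerboard pairs are fully dissimilar along the horizontal", {
  img <- checkerboard_image(16)
  cfg <- texture_config(gray_levels = 2, directions = "0")
  f <- glcm_features(img, matrix(2L, 16, 16), cfg)
  expect_equal(f[["contrast"]], 1)
  expect_equal(f[["homogeneity"]], 0.5)
  expect_equal(f[["ASM"]], 0.5)
})

test_that("regions below 64 px are a size error", {
  img <- array(100, c(7, 7, 3))
  expect_error(glcm_features(img, matrix(2L, 7, 7)),
               class = "spikescan_size_error")
  expect_error(glrm_features(img, matrix(2L, 7, 7)),
               class = "spikescan_size_error")
})

test_that("run statistics match direct enumeration on simple patterns", {
  # constant 16x16, horizontal runs: 16 runs of length 16
  img <- array(100, c(16, 16, 3))
  f <- glrm_features(img, matrix(2L, 16, 16), texture_config(directions = "0"))
  expect_equal(f[["LRE"]], 16^2)
  expect_equal(f[["RP"]], 1 / 16)
  # checkerboard: every run has length 1 in the axial directions
  fc <- glrm_features(checkerboard_image(16), matrix(2L, 16, 16),
                      texture_config(gray_levels = 2,
                                     directions = c("0", "90")))
  expect_equal(fc[["SRE"]], 1)
  expect_equal(fc[["LRE"]], 1)
  expect_equal(fc[["RP"]], 1)
})

test_that("SRE <= 1 <= LRE on arbitrary inputs", {
  set.seed(99)
  for (i in 1:10) {
    img <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), c(16, 16, 3))
    f <- glrm_features(img, matrix(2L, 16, 16), texture_config(gray_levels = 4))
    expect_lte(f[["SRE"]], 1)
    expect_gte(f[["LRE"]], 1)
  }
})

test_that("GLCM matrix is a symmetric probability distribution", {
  ph <- generate_phantom(fast_kite_spec(mm_per_px = 0.4, noise_sd = 10,
                                        seed = 8L))
  cfg <- texture_config()
  q <- spikescan:::quantize_region(ph$image, ph$truth_mask, cfg)
  p <- spikescan:::glcm_matrix(q, cfg)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p, t(p))
})

test_that("features are invariant to a constant luminance shift", {
  ph <- generate_phantom(fast_kite_spec(mm_per_px = 0.4, noise_sd = 6,
                                        seed = 8L))
  shifted <- pmin(ph$image + 20, 255)
  # keep the shift linear on the body: no clipping may occur there
  expect_lt(max(ph$image[ph$truth_mask == 2L]), 236)
  f1 <- texture_features(ph$image, ph$truth_mask)
  f2 <- texture_features(shifted, ph$truth_mask)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("implementation matches brute-force enumeration on random patches", {
  set.seed(7)
  for (i in 1:5) {
    lv <- matrix(sample(0:1, 16 * 16, replace = TRUE), 16, 16)
    img <- array(0, c(16, 16, 3))
    for (ch in 1:3) img[, , ch] <- lv * 255
    mask <- matrix(2L, 16, 16)
    # punch a few holes so masked-pair/run truncation is exercised
    mask[sample(length(mask), 20)] <- 0L
    cfg <- texture_config(gray_levels = 2)
    q <- spikescan:::quantize_region(img, mask, cfg)
    got_glcm <- glcm_features(img, mask, cfg)
    want_glcm <- brute_glcm(q, cfg$directions, g = 2)
    expect_equal(as.numeric(got_glcm), as.numeric(want_glcm), tolerance = 1e-12)
    got_glrm <- glrm_features(img, mask, cfg)
    want_glrm <- brute_glrm(q, cfg$directions)
    expect_equal(as.numeric(got_glrm), as.numeric(want_glrm), tolerance = 1e-12)
  }
})
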