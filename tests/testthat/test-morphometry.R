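test_that("disk hits the circle limits of every outline descriptor", {
  f <- outline_features(disk_mask(200), scale_only_cal(0.1))
  expect_true(all(f[c("c_Ci", "c_Ro", "c_So")] >= 0.95))
  expect_true(all(f[c("c_Ci", "c_Ro", "c_So")] <= 1.02))
  expect_gte(f[["c_Ru"]], 0.98)
  expect_lte(f[["c_Ru"]], 1.05)
  expect_equal(f[["c_Sa"]], 0)
})

test_that("outline area and perimeter match exact polygon values within 1 %", {
  # filled triangle with vertices (300,100), (100,500), (500,500) in px;
  # large enough that the half-pixel boundary layer stays below 1 %
  n <- 600
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  m <- matrix(0L, n, n)
  sel <- g$y >= 100 & g$y <= 500 & abs(g$x - 300) <= (g$y - 100) * 0.5
  m[cbind(g$y[sel], g$x[sel])] <- 2L
  f <- outline_features(m, scale_only_cal(1))
  exact_area <- 0.5 * 400 * 400
  exact_per <- 400 + 2 * sqrt(400^2 + 200^2)
  expect_lt(abs(f[["c_S"]] - exact_area) / exact_area, 0.01)
  expect_lt(abs(f[["c_P"]] - exact_per) / exact_per, 0.01)
})

test_that("axis estimation recovers orientation and length", {
  spec <- fast_kite_spec(mm_per_px = 0.2)
  ph <- generate_phantom(spec)
  ax <- estimate_axis(ph$truth_mask)
  ang <- atan2(ax$unit_axis[["x"]], -ax$unit_axis[["y"]]) * 180 / pi
  expect_lt(abs(ang), 1)
  expect_lt(abs(ax$length_px * spec$mm_per_px - 100) / 100, 0.02)
  expect_gt(ax$base_px[["y"]], ax$tip_px[["y"]]) # base at the lower image end

  rot <- generate_phantom(phantom_spec(body_length_mm = 100,
                                       body_max_width_mm = 20,
                                       width_position_rel = 0.3,
                                       body_profile = "kite",
                                       mm_per_px = 0.2, awn_count = 0L,
                                       rotation_deg = 10, seed = 7L))
  ax2 <- estimate_axis(rot$truth_mask)
  ang2 <- atan2(ax2$unit_axis[["x"]], -ax2$unit_axis[["y"]]) * 180 / pi
  expect_lt(abs(ang2 - 10), 1)
})

test_that("degenerate bodies raise geometry errors", {
  m <- matrix(0L, 10, 10)
  m[5, 5] <- 2L
  expect_error(estimate_axis(m), class = "spikescan_geometry_error")
  expect_error(outline_features(matrix(0L, 5, 5), scale_only_cal(1)),
               class = "spikescan_geometry_error")
})

test_that("width profile is symmetric with the maximum at the spec position", {
  spec <- fast_kite_spec(mm_per_px = 0.2)
  ph <- generate_phantom(spec)
  ax <- estimate_axis(ph$truth_mask)
  cal <- scale_only_cal(spec$mm_per_px)
  prof <- width_profile(ph$truth_mask, ax, cal, n_bins = 64)
  expect_lte(max(abs(prof$left_mm - prof$right_mm)), 2 * spec$mm_per_px)
  t_star <- prof$t[which.max(prof$left_mm + prof$right_mm)]
  expect_lt(abs(t_star - spec$width_position_rel), 0.05)
  expect_error(width_profile(ph$truth_mask, ax, cal, n_bins = 4),
               class = "spikescan_validation_error")
})

test_that("quadrangle fit recovers kite phantom parameters", {
  spec <- fast_kite_spec(mm_per_px = 0.2)
  ph <- generate_phantom(spec)
  q <- fit_quadrangle(ph$truth_mask, cal = scale_only_cal(spec$mm_per_px))
  expect_lt(abs(q[["q_L"]] - 100) / 100, 0.02)
  expect_lt(abs(q[["q_W"]] - 20) / 20, 0.02)
  expect_lt(abs(q[["q_pW"]] - 0.3), 0.05)
})

test_that("the 8 derived kite parameters satisfy their identities exactly", {
  set.seed(42)
  for (i in 1:25) {
    L <- runif(1, 40, 140); W <- runif(1, 5, 0.8 * L); p <- runif(1, 0.05, 0.95)
    q <- spikescan:::kite_parameters(L, W, p)
    expect_equal(q[["q_P"]], 2 * (q[["q_a"]] + q[["q_b"]]))
    expect_equal(q[["q_A"]], q[["q_L"]] * q[["q_W"]] / 2)
    expect_equal(q[["q_alpha"]] + q[["q_beta"]] + 2 * q[["q_gamma"]], 360)
    expect_equal(q[["q_a"]], sqrt((p * L)^2 + (W / 2)^2))
    expect_true(q[["q_r"]] > 0 && q[["q_r"]] < 1)
  }
})

test_that("a near-degenerate strip approaches the thin-kite limits", {
  q <- spikescan:::kite_parameters(100, 1e-6, 0.4)
  expect_lt(q[["q_r"]], 1e-7)
  expect_lt(q[["q_alpha"]], 1e-5)
  expect_lt(q[["q_beta"]], 1e-5)
  expect_equal(q[["q_gamma"]], 180, tolerance = 1e-6)
})

test_that("features are rotation invariant within discretization tolerance", {
  mk <- function(rot) {
    generate_phantom(phantom_spec(body_length_mm = 90, body_max_width_mm = 16,
                                  width_position_rel = 0.35, mm_per_px = 0.25,
                                  awn_count = 0L, rotation_deg = rot,
                                  seed = 5L))
  }
  cal <- scale_only_cal(0.25)
  f0 <- morphometric_features(mk(0)$truth_mask, cal)
  f15 <- morphometric_features(mk(15)$truth_mask, cal)
  rel <- abs(f15 - f0) / pmax(abs(f0), 1e-9)
  expect_true(all(rel < 0.03))
})

test_that("features scale correctly with mm_per_px", {
  ph <- generate_phantom(fast_kite_spec(mm_per_px = 0.25))
  f1 <- morphometric_features(ph$truth_mask, scale_only_cal(0.25))
  f2 <- morphometric_features(ph$truth_mask, scale_only_cal(0.5))
  linear <- c("c_L", "c_P", "q_L", "q_W", "q_a", "q_b", "q_P")
  quadratic <- c("c_S", "c_Sa", "q_A")
  invariant <- c("c_Ci", "c_Ro", "c_So", "c_Ru", "q_pW", "q_r",
                 "q_alpha", "q_beta", "q_gamma")
  expect_equal(f2[linear], 2 * f1[linear])
  expect_equal(f2[quadratic][c("c_S", "q_A")], 4 * f1[quadratic][c("c_S", "q_A")])
  expect_equal(f2[invariant], f1[invariant])
})
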