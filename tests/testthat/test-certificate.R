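make_record <- function(spike_id, view, c_L = 100, body = c(180, 160, 110),
                        awn = c(150, 130, 90)) {
  morpho <- c(spikescan:::kite_parameters(c_L, 18, 0.35),
              c_L = c_L, c_P = 210, c_S = 1100, c_Ci = 0.31, c_Ro = 0.14,
              c_So = 0.98, c_Ru = 1.01, c_Sa = 50)
  view_record(spike_id, view, morpho, body_rgb = body, awn_rgb = awn)
}

test_that("certificate blocks average their views", {
  r1 <- make_record("s1", "frontal", c_L = 100)
  r2 <- make_record("s1", "back", c_L = 102)
  ct <- assemble_certificate(list(r1, r2))
  expect_equal(ct$frontal[["c_L"]], 101)
  expect_length(ct$frontal, 24L)
  expect_null(ct$lateral)
  expect_equal(ct$views_used$frontal, c("back", "frontal"))

  # identical views: averaging is idempotent
  ct2 <- assemble_certificate(list(make_record("s1", "frontal"),
                                   make_record("s1", "back")))
  expect_equal(ct2$frontal, make_record("s1", "frontal")$features)

  # record order never matters
  ct3 <- assemble_certificate(list(r2, r1))
  expect_equal(ct3$frontal, ct$frontal)
})

test_that("single-view spikes yield valid one-block certificates", {
  ct <- assemble_certificate(list(make_record("s1", "side1")))
  expect_null(ct$frontal)
  expect_equal(ct$lateral[["c_L"]], 100)
  df <- certificates_to_df(list(ct))
  expect_true(all(is.na(df[, grepl("^frontal_", names(df))])))
})

test_that("missing awn colours propagate as missing", {
  r <- make_record("s1", "frontal", awn = c(NA, NA, NA))
  ct <- assemble_certificate(list(r))
  expect_true(all(is.na(ct$frontal[c("awn_R", "awn_G", "awn_B")])))
})

test_that("duplicate view labels are an ambiguity error", {
  expect_error(assemble_certificate(list(make_record("s1", "frontal"),
                                         make_record("s1", "frontal"))),
               class = "spikescan_ambiguity_error")
})

test_that("group comparison flags a planted colour shift and needs n >= 3", {
  cal <- scale_only_cal(0.6)
  base_a <- stats_base_spec(seed = 1L)
  base_b <- do.call(phantom_spec,
                    modifyList(unclass(base_a),
                               list(body_rgb = base_a$body_rgb + 40,
                                    awn_rgb = NULL, seed = 2L)))
  certs_a <- cohort_certificates(generate_cohort(6, base_a, stats_jitter(),
                                                 seed = 31), cal)
  certs_b <- cohort_certificates(generate_cohort(6, base_b, stats_jitter(),
                                                 seed = 32), cal)
  cmp <- compare_groups(certs_a, certs_b, block = "frontal")
  colour_feats <- c("body_R", "body_G", "body_B", "awn_R", "awn_G", "awn_B")
  expect_true(all(cmp$significant[cmp$feature %in% colour_feats]))
  expect_error(compare_groups(certs_a[1:2], certs_b),
               class = "spikescan_precondition_error")
})

test_that("zero-variance equal groups give p = 1 by convention", {
  certs <- lapply(1:3, function(i)
    assemble_certificate(list(make_record(paste0("s", i), "frontal"))))
  cmp <- compare_groups(certs, certs, correction = "none")
  expect_true(all(cmp$p_value == 1))
  expect_false(any(cmp$significant))
})

test_that("rendered polygons sit at the analytic kite vertices", {
  ct <- assemble_certificate(list(make_record("s1", "frontal", c_L = 100)))
  p <- withr::local_tempfile(fileext = ".pdf")
  out <- render_models(list(ct), "frontal", out_path = p, mean_overlay = TRUE)
  expect_true(file.exists(p))
  expect_length(out$polygons, 1L)
  poly <- out$polygons[[1]]
  q <- ct$frontal
  expect_equal(poly[1, ], c(0, 0))
  expect_equal(poly[3, ], c(0, q[["q_L"]]))
  expect_equal(poly[2, ], c(-q[["q_W"]] / 2, q[["q_pW"]] * q[["q_L"]]))
  # edge lengths reproduce q_a / q_b, i.e. the kite identities
  expect_equal(sqrt(sum((poly[2, ] - poly[1, ])^2)), q[["q_a"]])
  expect_equal(sqrt(sum((poly[3, ] - poly[2, ])^2)), q[["q_b"]])
  # the mean polygon of identical certificates coincides with the individual
  out2 <- render_models(list(ct, ct), "frontal", out_path = p)
  expect_equal(out2$mean_polygon, out2$polygons[[1]])
})

test_that("rendering an absent block warns and draws nothing", {
  ct <- assemble_certificate(list(make_record("s1", "frontal")))
  expect_warning(out <- render_models(list(ct), "lateral"),
                 "nothing drawn")
  expect_length(out$polygons, 0L)
})
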