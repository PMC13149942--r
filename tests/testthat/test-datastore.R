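test_that("schema creation is complete and idempotent", {
  path <- withr::local_tempfile(fileext = ".json")
  db <- spikedb_init(path)
  expect_length(db$tables, 11L)
  expect_setequal(names(db$tables),
                  c("Collection", "Plant", "Environment", "Spike", "Image",
                    "SpikeData", "QuadrangleModel", "MeanColor",
                    "DominantColor", "GLCMTexture", "GLRMTexture"))
  expect_length(names(db$tables$Plant), 20L)
  # column counts mirror the feature-set sizes
  expect_length(setdiff(names(db$tables$SpikeData), "image_id"), 8L)
  expect_length(setdiff(names(db$tables$QuadrangleModel), "image_id"), 11L)
  expect_length(setdiff(names(db$tables$MeanColor), c("image_id", "region")), 12L)
  expect_length(setdiff(names(db$tables$GLCMTexture), "image_id"), 10L)
  expect_length(setdiff(names(db$tables$GLRMTexture), "image_id"), 6L)
  db2 <- spikedb_init(path) # reopen: same tables, nothing duplicated
  expect_equal(vapply(db2$tables, nrow, integer(1)),
               vapply(db$tables, nrow, integer(1)))
  # incompatible file is a migration error
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(Foo = list()), bad)
  expect_error(spikedb_init(bad), class = "spikescan_migration_error")
})

test_that("unwritable paths raise an I/O error", {
  expect_error(spikedb_init("/no/such/dir/db.json"),
               class = "spikescan_io_error")
})

test_that("batch import inserts the expected rows and is idempotent", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_batch(dir)
  db <- spikedb_init(file.path(dir, "db.json"))
  rep1 <- batch_import(db, fx$manifest, fx$img_dir)
  expect_equal(rep1$n_inserted, 24L)
  expect_equal(rep1$n_rejected, 0L)
  expect_equal(nrow(db$tables$Plant), 6L)
  expect_equal(nrow(db$tables$Spike), 6L)
  expect_equal(nrow(db$tables$Image), 24L)
  expect_equal(nrow(db$tables$Collection), 1L)
  # unknown manifest columns land in the annex, not on the floor
  expect_true(all(grepl("plot_note=field 3", db$tables$Plant$annex)))

  # re-import: everything is a duplicate
  rep2 <- batch_import(db, fx$manifest, fx$img_dir)
  expect_equal(rep2$n_inserted, 0L)
  expect_equal(rep2$n_rejected, 24L)
  expect_true(all(grepl("duplicate", rep2$rejected$reason)))
  expect_equal(nrow(db$tables$Image), 24L)

  # a missing image file rejects that row only
  db2 <- spikedb_init(file.path(dir, "db2.json"))
  file.remove(file.path(fx$img_dir, fx$rows$image_file[1]))
  rep3 <- batch_import(db2, fx$manifest, fx$img_dir)
  expect_equal(rep3$n_inserted, 23L)
  expect_equal(rep3$n_rejected, 1L)
  expect_match(rep3$rejected$reason[1], "not found")
})

test_that("uploaded fields survive an import / reopen round-trip", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_batch(dir)
  db <- spikedb_init(file.path(dir, "db.json"))
  batch_import(db, fx$manifest, fx$img_dir)
  db2 <- spikedb_init(file.path(dir, "db.json"))
  expect_equal(db2$tables$Plant$accession_number,
               db$tables$Plant$accession_number)
  expect_equal(db2$tables$Plant$year_of_cultivation,
               rep(2019L, 6))
  expect_equal(sort(db2$tables$Image$view),
               sort(db$tables$Image$view))
})

test_that("feature storage round-trips at full precision and checks keys", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_batch(dir)
  db <- spikedb_init(file.path(dir, "db.json"))
  batch_import(db, fx$manifest, fx$img_dir)

  outline <- c(c_L = 100 + pi * 1e-8, c_P = 210.123456789, c_S = 1100.1,
               c_Ci = 0.31, c_Ro = 0.14, c_So = 0.98, c_Ru = 1.01,
               c_Sa = 50.5)
  quad <- spikescan:::kite_parameters(100.25, 18.5, 0.353)
  dom <- data.frame(R = c(180.5, 120.1, 220.9), G = c(160, 90, 210),
                    B = c(100, 60, 170), prop = c(0.5, 0.3, 0.2))
  mc <- stats::setNames(rnorm(12), spikescan:::MEAN_COLOR_COMPONENTS)
  store_features(db, 1L, list(outline = outline, quadrangle = quad,
                              mean_color = list(body = mc),
                              dominant = list(body = dom),
                              glcm = stats::setNames(rnorm(10),
                                                     spikescan:::GLCM_FEATURE_NAMES),
                              glrm = stats::setNames(rnorm(6),
                                                     spikescan:::GLRM_FEATURE_NAMES)))
  # full-precision round trip through the JSON store
  db2 <- spikedb_init(file.path(dir, "db.json"))
  expect_identical(db2$tables$SpikeData$c_L, outline[["c_L"]])
  expect_identical(db2$tables$QuadrangleModel$q_a, quad[["q_a"]])
  expect_identical(db2$tables$DominantColor$dom1_R, 180.5)

  expect_error(store_features(db, 999L, list(outline = outline)),
               class = "spikescan_referential_error")
})

test_that("exports filter by view and summaries count categories", {
  dir <- withr::local_tempdir()
  fx <- write_fixture_batch(dir)
  db <- spikedb_init(file.path(dir, "db.json"))
  batch_import(db, fx$manifest, fx$img_dir)
  outline <- c(c_L = 1, c_P = 2, c_S = 3, c_Ci = 4, c_Ro = 5, c_So = 6,
               c_Ru = 7, c_Sa = 8)
  for (iid in db$tables$Image$image_id) {
    store_features(db, iid, list(outline = outline))
  }
  ex <- export_features(db, view = "frontal")
  expect_equal(nrow(ex$SpikeData), 6L)
  out_dir <- withr::local_tempdir()
  export_features(db, view = "frontal", out_dir = out_dir)
  expect_true(file.exists(file.path(out_dir, "SpikeData.csv")))

  st <- summary_stats(db, "country_of_origin")
  expect_equal(st$category[1], "Russia")
  expect_equal(st$n, c(3L, 2L, 1L))
  expect_equal(summary_stats(db, "variety")$n[1], 3L)
  expect_error(summary_stats(db, "height"),
               class = "spikescan_validation_error")
  empty <- spikedb_init(withr::local_tempfile(fileext = ".json"))
  expect_equal(nrow(summary_stats(empty, "variety")), 0L)
})
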