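#' Relational datastore for spike collections
#'
#' Persists the two-block schema used for digital spike collections: an
#' uploaded block of five expert tables (Collection, Plant, Environment,
#' Spike, Image, chained by foreign keys) and an extracted block of six
#' feature tables keyed by image (SpikeData, QuadrangleModel, MeanColor,
#' DominantColor, GLCMTexture, GLRMTexture). The backing store is a single
#' JSON file managed by this package — the schema is dialect-neutral and maps
#' one-to-one onto any SQL engine, but a server deployment is out of scope.
#' Referential integrity is enforced on every insert.
#'
#' The Plant table carries exactly 20 fields: identifier, collection key,
#' accession number, sowing identifier, year of cultivation, reproduction
#' number, Q-gene allele, female/male parent, genus, species, subspecies,
#' botanical variety, variety name, line code, country of origin, originating
#' institution, growth habit, ploidy, and a free-text annex that preserves
#' unrecognized manifest columns.
#'
#' @name datastore
NULL

spikedb_schema <- function() {
  list(
    Collection = list(
      columns = c(collection_id = "integer", name = "character",
                  description = "character"),
      pk = "collection_id", fk = list()),
    Plant = list(
      columns = c(plant_id = "integer", collection_id = "integer",
                  accession_number = "character", sowing_id = "character",
                  year_of_cultivation = "integer",
                  reproduction_number = "integer", q_gene_allele = "character",
                  parent_female = "character", parent_male = "character",
                  genus = "character", species = "character",
                  subspecies = "character", botanical_variety = "character",
                  variety_name = "character", line_code = "character",
                  origin_country = "character",
                  origin_institution = "character",
                  growth_habit = "character", ploidy = "character",
                  annex = "character"),
      pk = "plant_id", fk = list(collection_id = c("Collection", "collection_id"))),
    Environment = list(
      columns = c(environment_id = "integer", plant_id = "integer",
                  sowing_date = "character", harvest_date = "character",
                  location_name = "character", latitude = "numeric",
                  longitude = "numeric", institution_address = "character"),
      pk = "environment_id", fk = list(plant_id = c("Plant", "plant_id"))),
    Spike = list(
      columns = c(spike_id = "integer", plant_id = "integer",
                  spike_number = "integer", length_mm = "numeric",
                  width_frontal_mm = "numeric", width_lateral_mm = "numeric",
                  spike_type = "character", spike_color = "character",
                  grain_count = "integer", awn_color = "character",
                  awn_type = "character", glume_pubescence = "character",
                  threshability = "character", rachis_fragility = "character",
                  awn_attachment = "character"),
      pk = "spike_id", fk = list(plant_id = c("Plant", "plant_id"))),
    Image = list(
      columns = c(image_id = "integer", spike_id = "integer",
                  view = "character", acquisition_date = "character",
                  file_path = "character"),
      pk = "image_id", fk = list(spike_id = c("Spike", "spike_id"))),
    SpikeData = list(
      columns = c(image_id = "integer",
                  stats::setNames(rep("numeric", 8),
                                  c("c_L", "c_P", "c_S", "c_Ci", "c_Ro",
                                    "c_So", "c_Ru", "c_Sa"))),
      pk = "image_id", fk = list(image_id = c("Image", "image_id"))),
    QuadrangleModel = list(
      columns = c(image_id = "integer",
                  stats::setNames(rep("numeric", 11),
                                  c("q_L", "q_W", "q_pW", "q_a", "q_b",
                                    "q_alpha", "q_beta", "q_gamma", "q_A",
                                    "q_P", "q_r"))),
      pk = "image_id", fk = list(image_id = c("Image", "image_id"))),
    MeanColor = list(
      columns = c(image_id = "integer", region = "character",
                  stats::setNames(rep("numeric", 12), MEAN_COLOR_COMPONENTS)),
      pk = c("image_id", "region"), fk = list(image_id = c("Image", "image_id"))),
    DominantColor = list(
      columns = c(image_id = "integer", region = "character",
                  stats::setNames(rep("numeric", 12),
                                  as.vector(outer(c("R", "G", "B", "prop"),
                                                  1:3,
                                                  function(a, b) paste0("dom", b, "_", a))))),
      pk = c("image_id", "region"), fk = list(image_id = c("Image", "image_id"))),
    GLCMTexture = list(
      columns = c(image_id = "integer",
                  stats::setNames(rep("numeric", 10), GLCM_FEATURE_NAMES)),
      pk = "image_id", fk = list(image_id = c("Image", "image_id"))),
    GLRMTexture = list(
      columns = c(image_id = "integer",
                  stats::setNames(rep("numeric", 6), GLRM_FEATURE_NAMES)),
      pk = "image_id", fk = list(image_id = c("Image", "image_id")))
  )
}

empty_table <- function(def) {
  cols <- lapply(def$columns, function(ty) vector(ty, 0L))
  as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Initialize (or open) a spike database
#'
#' Creates the 11-table schema in a single JSON file; idempotent — re-opening
#' an existing store leaves it untouched. A file whose tables do not match
#' the schema raises a migration error.
#'
#' @param db_path path of the JSON store.
#' @return object of class `spike_db` (an environment holding the tables).
#' @export
spikedb_init <- function(db_path) {
  schema <- spikedb_schema()
  db <- new.env(parent = emptyenv())
  db$path <- db_path
  db$schema <- schema
  if (file.exists(db_path)) {
    raw <- jsonlite::read_json(db_path, simplifyVector = TRUE)
    if (!setequal(names(raw), names(schema))) {
      ss_stop("existing file does not hold a compatible spike_db schema",
              "spikescan_migration_error")
    }
    db$tables <- lapply(names(schema), function(tn) {
      t <- raw[[tn]]
      if (is.null(t) || !length(t) || (is.list(t) && !length(t[[1]]))) {
        return(empty_table(schema[[tn]]))
      }
      t <- as.data.frame(t, check.names = FALSE, stringsAsFactors = FALSE)
      if (!setequal(names(t), names(schema[[tn]]$columns))) {
        ss_stop(sprintf("table %s has incompatible columns", tn),
                "spikescan_migration_error")
      }
      t[, names(schema[[tn]]$columns), drop = FALSE]
    })
    names(db$tables) <- names(schema)
  } else {
    db$tables <- lapply(schema, empty_table)
    spikedb_save(db)
  }
  class(db) <- "spike_db"
  db
}

#' Write the database back to its JSON file
#' @param db a `spike_db`.
#' @export
spikedb_save <- function(db) {
  con <- suppressWarnings(try(file(db$path, "w"), silent = TRUE))
  if (inherits(con, "try-error")) {
    ss_stop(sprintf("cannot write database file '%s'", db$path),
            "spikescan_io_error")
  }
  close(con)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(db$tables, db$path, digits = I(17), null = "null",
                       na = "null", dataframe = "columns")
  invisible(db)
}

next_id <- function(db, table) {
  ids <- db$tables[[table]][[db$schema[[table]]$pk[1]]]
  if (length(ids)) max(ids) + 1L else 1L
}

db_insert <- function(db, table, row) {
  def <- db$schema[[table]]
  ss_assert(all(names(row) %in% names(def$columns)),
            sprintf("unknown column(s) for %s: %s", table,
                    paste(setdiff(names(row), names(def$columns)), collapse = ", ")),
            "spikescan_validation_error")
  for (fk_col in names(def$fk)) {
    tgt <- def$fk[[fk_col]]
    if (!is.null(row[[fk_col]]) &&
        !(row[[fk_col]] %in% db$tables[[tgt[1]]][[tgt[2]]])) {
      ss_stop(sprintf("%s.%s = %s references no existing %s row",
                      table, fk_col, row[[fk_col]], tgt[1]),
              "spikescan_referential_error")
    }
  }
  full <- lapply(names(def$columns), function(cn) {
    v <- row[[cn]]
    if (is.null(v) || length(v) == 0L) v <- NA
    ty <- def$columns[[cn]]
    switch(ty, integer = as.integer(v), numeric = as.numeric(v),
           as.character(v))
  })
  names(full) <- names(def$columns)
  db$tables[[table]] <- rbind(db$tables[[table]],
                              as.data.frame(full, check.names = FALSE,
                                            stringsAsFactors = FALSE))
  invisible(row[[def$pk[1]]])
}

MANIFEST_REQUIRED <- c("collection", "accession_number", "spike_number",
                       "view", "image_file")

#' Batch import of a manifest of plants, spikes and images
#'
#' Mirrors the staged batch-upload flow: rows are validated, collections /
#' plants / spikes are created or reused, and each manifest row links one
#' image file to its spike by (accession, spike number, view). Rejected rows
#' (missing image file, duplicate spike/view, malformed values) are reported
#' with reasons and do not block the remaining rows; accepted rows are
#' committed together at the end.
#'
#' Recognized manifest columns are the required five
#' (`collection`, `accession_number`, `spike_number`, `view`, `image_file`)
#' plus any Plant, Spike or Image field name; unrecognized columns are
#' preserved verbatim in the Plant `annex` field.
#'
#' @param db a `spike_db`.
#' @param manifest data.frame or path to a UTF-8 CSV with a header row.
#' @param images_dir directory that `image_file` entries are relative to.
#' @return import report: list with `n_inserted`, `n_rejected`, `rejected`
#'   (data.frame of row index + reason) and the new row counts per table.
#' @export
batch_import <- function(db, manifest, images_dir = ".") {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE,
                                check.names = FALSE, fileEncoding = "UTF-8")
  }
  ss_assert(is.data.frame(manifest), "manifest must be a data.frame or CSV path")
  missing_cols <- setdiff(MANIFEST_REQUIRED, names(manifest))
  ss_assert(!length(missing_cols),
            sprintf("manifest lacks required column(s): %s",
                    paste(missing_cols, collapse = ", ")))
  schema <- db$schema
  plant_cols <- intersect(names(manifest),
                          setdiff(names(schema$Plant$columns),
                                  c("plant_id", "collection_id", "annex")))
  spike_cols <- intersect(names(manifest),
                          setdiff(names(schema$Spike$columns),
                                  c("spike_id", "plant_id", "spike_number")))
  image_cols <- intersect(names(manifest), "acquisition_date")
  known <- unique(c(MANIFEST_REQUIRED, plant_cols, spike_cols, image_cols))
  annex_cols <- setdiff(names(manifest), known)

  before <- vapply(db$tables, nrow, integer(1))
  rejected <- data.frame(row = integer(0), reason = character(0))
  reject <- function(i, why) {
    rejected <<- rbind(rejected, data.frame(row = i, reason = why))
  }
  n_ok <- 0L
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, , drop = FALSE]
    img <- file.path(images_dir, r$image_file)
    if (is.na(r$image_file) || !file.exists(img)) {
      reject(i, sprintf("image file not found: %s", r$image_file)); next
    }
    if (!r$view %in% CERT_VIEWS) {
      reject(i, sprintf("unknown view label: %s", r$view)); next
    }
    # duplicate (accession, spike number, view)?
    pl <- db$tables$Plant
    sp <- db$tables$Spike
    im <- db$tables$Image
    pid <- pl$plant_id[pl$accession_number == as.character(r$accession_number)]
    sid <- sp$spike_id[sp$plant_id %in% pid &
                         sp$spike_number == as.integer(r$spike_number)]
    if (length(sid) && any(im$spike_id %in% sid & im$view == r$view)) {
      reject(i, sprintf("duplicate image for (%s, spike %s, %s)",
                        r$accession_number, r$spike_number, r$view)); next
    }
    # collection: find or create
    co <- db$tables$Collection
    cid <- co$collection_id[co$name == as.character(r$collection)]
    if (!length(cid)) {
      cid <- next_id(db, "Collection")
      db_insert(db, "Collection", list(collection_id = cid,
                                       name = as.character(r$collection)))
    }
    # plant: find or create within the collection
    if (!length(pid)) {
      pid <- next_id(db, "Plant")
      row <- c(list(plant_id = pid, collection_id = cid,
                    accession_number = as.character(r$accession_number)),
               stats::setNames(lapply(plant_cols, function(cn) r[[cn]]),
                               plant_cols))
      if (length(annex_cols)) {
        row$annex <- paste(sprintf("%s=%s", annex_cols,
                                   vapply(annex_cols, function(cn)
                                     as.character(r[[cn]]), character(1))),
                           collapse = "; ")
      }
      db_insert(db, "Plant", row)
    } else {
      pid <- pid[1]
    }
    # spike: find or create
    if (!length(sid)) {
      sid <- next_id(db, "Spike")
      row <- c(list(spike_id = sid, plant_id = pid,
                    spike_number = as.integer(r$spike_number)),
               stats::setNames(lapply(spike_cols, function(cn) r[[cn]]),
                               spike_cols))
      db_insert(db, "Spike", row)
    } else {
      sid <- sid[1]
    }
    iid <- next_id(db, "Image")
    row <- c(list(image_id = iid, spike_id = sid,
                  view = as.character(r$view),
                  file_path = as.character(r$image_file)),
             stats::setNames(lapply(image_cols, function(cn) r[[cn]]),
                             image_cols))
    db_insert(db, "Image", row)
    n_ok <- n_ok + 1L
  }
  spikedb_save(db)
  after <- vapply(db$tables, nrow, integer(1))
  list(n_inserted = n_ok, n_rejected = nrow(rejected), rejected = rejected,
       new_rows = after - before)
}

#' Store extracted features for one image
#'
#' Accepts any subset of the extracted-block records: `outline` (the 8 `c_*`
#' values), `quadrangle` (11 `q_*`), `mean_color` (named list
#' `body` / `awn` of 12-component vectors), `dominant` (named list of
#' [dominant_colors()] data frames), `glcm` (10) and `glrm` (6).
#'
#' @param db a `spike_db`.
#' @param image_id key of an existing Image row.
#' @param features named list as described above.
#' @return invisibly, the table names written.
#' @export
store_features <- function(db, image_id, features) {
  if (!image_id %in% db$tables$Image$image_id) {
    ss_stop(sprintf("image_id %s does not exist", image_id),
            "spikescan_referential_error")
  }
  written <- character(0)
  if (!is.null(features$outline)) {
    db_insert(db, "SpikeData", c(list(image_id = image_id),
                                 as.list(features$outline)))
    written <- c(written, "SpikeData")
  }
  if (!is.null(features$quadrangle)) {
    q <- features$quadrangle
    db_insert(db, "QuadrangleModel", c(list(image_id = image_id),
                                       as.list(q[names(q) != "c_Sa"])))
    written <- c(written, "QuadrangleModel")
  }
  for (region in names(features$mean_color)) {
    db_insert(db, "MeanColor", c(list(image_id = image_id, region = region),
                                 as.list(features$mean_color[[region]])))
    written <- unique(c(written, "MeanColor"))
  }
  for (region in names(features$dominant)) {
    dc <- features$dominant[[region]]
    vals <- as.list(stats::setNames(
      as.vector(t(as.matrix(dc[, c("R", "G", "B", "prop")]))),
      as.vector(t(outer(1:3, c("R", "G", "B", "prop"),
                        function(a, b) paste0("dom", a, "_", b))))))
    db_insert(db, "DominantColor", c(list(image_id = image_id, region = region),
                                     vals))
    written <- unique(c(written, "DominantColor"))
  }
  if (!is.null(features$glcm)) {
    db_insert(db, "GLCMTexture", c(list(image_id = image_id),
                                   as.list(features$glcm)))
    written <- c(written, "GLCMTexture")
  }
  if (!is.null(features$glrm)) {
    db_insert(db, "GLRMTexture", c(list(image_id = image_id),
                                   as.list(features$glrm)))
    written <- c(written, "GLRMTexture")
  }
  spikedb_save(db)
  invisible(written)
}

#' Export extracted features
#'
#' @param db a `spike_db`.
#' @param view optional view-label filter (e.g. `"frontal"`).
#' @param out_dir optional directory; when given, each non-empty extracted
#'   table is written as `<name>.csv` there.
#' @return named list of the six extracted-block data frames (filtered).
#' @export
export_features <- function(db, view = NULL, out_dir = NULL) {
  keep_ids <- db$tables$Image$image_id
  if (!is.null(view)) {
    keep_ids <- keep_ids[db$tables$Image$view == view]
  }
  tabs <- c("SpikeData", "QuadrangleModel", "MeanColor", "DominantColor",
            "GLCMTexture", "GLRMTexture")
  out <- lapply(tabs, function(tn) {
    t <- db$tables[[tn]]
    t[t$image_id %in% keep_ids, , drop = FALSE]
  })
  names(out) <- tabs
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (tn in tabs) {
      if (nrow(out[[tn]])) {
        utils::write.csv(out[[tn]], file.path(out_dir, paste0(tn, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  out
}

#' Frequency summaries of the uploaded block
#'
#' @param db a `spike_db`.
#' @param group_by `"country_of_origin"`, `"variety"` or `"year"`.
#' @param top_k keep only the `top_k` most frequent categories.
#' @return data.frame `category`, `n`, sorted by descending `n`.
#' @export
summary_stats <- function(db, group_by = c("country_of_origin", "variety", "year"),
                          top_k = Inf) {
  group_by <- tryCatch(match.arg(group_by),
                       error = function(e)
                         ss_stop("unknown grouping field",
                                 "spikescan_validation_error"))
  col <- switch(group_by, country_of_origin = "origin_country",
                variety = "variety_name", year = "year_of_cultivation")
  v <- db$tables$Plant[[col]]
  v <- v[!is.na(v)]
  if (!length(v)) {
    return(data.frame(category = character(0), n = integer(0)))
  }
  tab <- sort(table(v), decreasing = TRUE)
  out <- data.frame(category = names(tab), n = as.integer(tab))
  utils::head(out, top_k)
}
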