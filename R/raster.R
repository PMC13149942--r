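#' Raster containers and portable image input/output
#'
#' Images are plain numeric arrays of dimension `height x width x 3` holding
#' 8-bit RGB values (0-255); label masks are integer matrices of the same
#' height/width with the four class codes `0` background, `1` colour chart,
#' `2` spike body, `3` awn. Files are read and written in the portable anymap
#' (PNM) family: colour images as PPM (`P3`/`P6`), masks and grey images as
#' PGM (`P2`/`P5`). These formats are plain, self-describing and supported by
#' every image toolchain, which keeps the package free of compiled image
#' codecs.
#'
#' @name raster-io
NULL

MASK_CLASSES <- c(background = 0L, chart = 1L, body = 2L, awn = 3L)

validate_image <- function(image) {
  ss_assert(is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 3L,
            "image must be a height x width x 3 array")
  ss_assert(all(is.finite(image)) && min(image) >= 0 && max(image) <= 255,
            "image values must lie in [0, 255]")
  invisible(image)
}

validate_mask <- function(mask, image = NULL) {
  ss_assert(is.matrix(mask), "mask must be a matrix", "spikescan_format_error")
  bad <- setdiff(unique(as.integer(mask)), unname(MASK_CLASSES))
  if (length(bad)) {
    ss_stop(sprintf("mask contains unknown class code(s): %s",
                    paste(bad, collapse = ", ")), "spikescan_format_error")
  }
  if (!is.null(image) && !all(dim(mask) == dim(image)[1:2])) {
    ss_stop("mask dimensions do not match image dimensions",
            "spikescan_dimension_error")
  }
  invisible(mask)
}

# ---- PNM codec -------------------------------------------------------------

pnm_read_header <- function(con) {
  magic <- readChar(con, 2L, useBytes = TRUE)
  ss_assert(magic %in% c("P2", "P3", "P5", "P6"),
            sprintf("unsupported PNM magic '%s'", magic), "spikescan_format_error")
  vals <- integer(0)
  while (length(vals) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || !nzchar(ch)) {
      ss_stop("truncated PNM header", "spikescan_format_error")
    }
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || ch %in% c("\n", "\r")) break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      vals <- c(vals, as.integer(tok))
    }
  }
  list(magic = magic, width = vals[1], height = vals[2], maxval = vals[3])
}

#' Read a PNM (PPM/PGM) file
#'
#' @param path file path.
#' @return For PPM input a `height x width x 3` numeric array; for PGM input a
#'   numeric matrix.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- pnm_read_header(con)
  n <- h$width * h$height * if (h$magic %in% c("P3", "P6")) 3L else 1L
  if (h$magic %in% c("P5", "P6")) {
    raw <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  } else {
    raw <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  ss_assert(length(raw) == n, "truncated PNM payload", "spikescan_format_error")
  if (h$magic %in% c("P3", "P6")) {
    # pixel-interleaved, row-major
    arr <- array(0, c(h$height, h$width, 3L))
    for (ch in 1:3) {
      arr[, , ch] <- matrix(raw[seq(ch, n, by = 3L)], h$height, h$width, byrow = TRUE)
    }
    arr
  } else {
    matrix(raw, h$height, h$width, byrow = TRUE)
  }
}

#' Write an RGB array or grey matrix as PNM
#'
#' @param x image array (`H x W x 3`, written as PPM) or matrix (written as PGM).
#' @param path output path.
#' @param maxval maximum sample value declared in the header.
#' @param ascii write the ASCII (`P2`/`P3`) variant instead of binary.
#' @export
write_pnm <- function(x, path, maxval = 255L, ascii = FALSE) {
  colour <- is.array(x) && length(dim(x)) == 3L
  vals <- if (colour) {
    as.integer(round(aperm(x, c(3, 2, 1)))) # interleave channels, row-major
  } else {
    as.integer(round(t(x)))
  }
  ss_assert(all(vals >= 0 & vals <= maxval),
            "sample values out of range for declared maxval",
            "spikescan_format_error")
  dims <- if (colour) dim(x)[1:2] else dim(x)
  magic <- if (colour) (if (ascii) "P3" else "P6") else (if (ascii) "P2" else "P5")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n%d\n", magic, dims[2], dims[1], maxval),
            con, eos = NULL)
  if (ascii) {
    writeLines(paste(vals, collapse = " "), con)
  } else {
    writeBin(vals, con, size = 1L)
  }
  invisible(path)
}

#' Write a 4-class label mask
#'
#' Stored as a PGM whose samples are the class codes themselves
#' (0 background, 1 chart, 2 body, 3 awn).
#'
#' @param mask integer matrix of class codes.
#' @param path output path.
#' @inheritParams write_pnm
#' @export
write_mask <- function(mask, path, ascii = FALSE) {
  validate_mask(mask)
  write_pnm(mask, path, maxval = 255L, ascii = ascii)
}

#' Load a 4-class label mask
#'
#' @param path PGM file holding class codes 0-3.
#' @param image optional image the mask must pair with; dimensions are checked.
#' @return integer matrix of class codes.
#' @export
load_mask <- function(path, image = NULL) {
  m <- read_pnm(path)
  ss_assert(is.matrix(m), "mask file must be single-channel (PGM)",
            "spikescan_format_error")
  storage.mode(m) <- "integer"
  validate_mask(m, image)
  m
}

# ---- binary image primitives ----------------------------------------------

# offsets of a Euclidean disk of radius r (including centre)
disk_offsets <- function(r) {
  r <- as.integer(r)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_logical <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

binary_erode <- function(m, r) {
  off <- disk_offsets(r)
  out <- m
  for (k in seq_len(nrow(off))) {
    if (off$dr[k] == 0 && off$dc[k] == 0) next
    out <- out & shift_logical(m, off$dr[k], off$dc[k], fill = FALSE)
    if (!any(out)) break
  }
  out
}

binary_dilate <- function(m, r) {
  off <- disk_offsets(r)
  out <- m
  for (k in seq_len(nrow(off))) {
    if (off$dr[k] == 0 && off$dc[k] == 0) next
    out <- out | shift_logical(m, off$dr[k], off$dc[k], fill = FALSE)
  }
  out
}

binary_open <- function(m, r) binary_dilate(binary_erode(m, r), r)

# connected-component labelling (8-connectivity) via row runs + union-find
label_components <- function(m) {
  h <- nrow(m); w <- ncol(m)
  runs_row <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  prev <- integer(0) # run indices of previous row
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(h)) {
    row <- m[r, ]
    d <- diff(c(FALSE, row, FALSE))
    s <- which(d == 1L); e <- which(d == -1L) - 1L
    cur <- integer(length(s))
    for (k in seq_along(s)) {
      id <- length(parent) + 1L
      parent[id] <- id
      runs_row[id] <- r; runs_s[id] <- s[k]; runs_e[id] <- e[k]
      cur[k] <- id
      # union with overlapping runs in previous row (8-connectivity)
      for (p in prev) {
        if (runs_s[p] <= e[k] + 1L && runs_e[p] >= s[k] - 1L) {
          ra <- find_root(p); rb <- find_root(id)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    prev <- cur
  }
  labels <- matrix(0L, h, w)
  if (!length(parent)) return(labels)
  roots <- vapply(seq_along(parent), find_root, integer(1))
  lab_of_root <- integer(length(parent))
  uroots <- unique(roots)
  lab_of_root[uroots] <- seq_along(uroots)
  for (id in seq_along(parent)) {
    labels[runs_row[id], runs_s[id]:runs_e[id]] <- lab_of_root[roots[id]]
  }
  labels
}

largest_component <- function(m) {
  lab <- label_components(m)
  if (!any(lab > 0)) return(list(mask = m & FALSE, n_components = 0L, sizes = integer(0)))
  sizes <- tabulate(lab[lab > 0])
  list(mask = lab == which.max(sizes), n_components = length(sizes), sizes = sizes)
}

# Moore boundary tracing of the largest 8-connected region in m.
# Returns boundary pixel coordinates (x = col, y = row) in traversal order.
trace_boundary <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  ss_assert(nrow(idx) > 0, "empty region", "spikescan_geometry_error")
  if (nrow(idx) == 1L) return(cbind(x = idx[1, 2], y = idx[1, 1]))
  # start: topmost row, then leftmost column
  r0 <- min(idx[, 1])
  c0 <- min(idx[idx[, 1] == r0, 2])
  # clockwise Moore neighbourhood starting from W
  nbr <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                ncol = 2, byrow = TRUE) # (dr, dc): W, NW, N, NE, E, SE, S, SW
  h <- nrow(m); w <- ncol(m)
  inside <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && m[r, c]
  path_r <- integer(0); path_c <- integer(0)
  r <- r0; c <- c0
  dir <- 1L # came from W
  start_state <- NULL
  for (step in seq_len(8L * sum(m) + 8L)) {
    path_r <- c(path_r, r); path_c <- c(path_c, c)
    found <- FALSE
    for (k in 0:7) {
      d <- ((dir - 1L + k) %% 8L) + 1L
      rr <- r + nbr[d, 1]; cc <- c + nbr[d, 2]
      if (inside(rr, cc)) {
        # next search starts backtracked from the direction we arrived by
        dir <- ((d - 1L + 6L) %% 8L) + 1L
        r <- rr; c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    state <- c(r, c, dir)
    if (is.null(start_state)) {
      start_state <- state
    } else if (all(state == start_state) && step > 1L) {
      break
    }
  }
  cbind(x = path_c, y = path_r)
}

# polygon area (shoelace) and perimeter for closed polygon given as x/y matrix
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# perimeter of a digitized region from its traced boundary: chords through
# every k-th boundary pixel; damps the ~5 % staircase overestimate of raw
# chain length on smooth outlines while staying exact on straight edges
boundary_perimeter <- function(bnd, step = 4L) {
  n <- nrow(bnd)
  if (n <= 2L * step) return(polygon_perimeter(bnd))
  keep <- seq(1L, n, by = step)
  polygon_perimeter(bnd[keep, , drop = FALSE])
}
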