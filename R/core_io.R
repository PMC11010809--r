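# Readers and writers for the interchange formats the toolkit touches:
# TPS landmark files, binary silhouette masks (PNG/TIFF), coordinate CSV,
# specimen metadata tables, and YAML run configurations.
#
# Coordinate convention: everything downstream of these readers is in
# mathematical axes (x rightward, y upward). Image-derived coordinates are
# flipped from row-major pixel space on load, so a scale photographed with
# the anterior margin leftwards and the dorsal margin upwards keeps that
# orientation in internal coordinates.

#' Construct a binary mask
#'
#' A binary mask is an integer matrix of 0/1 pixel values (row 1 = top image
#' row), the carrier for single-scale silhouettes.
#'
#' @param m matrix coercible to 0/1 values.
#' @param frame optional coordinate frame of the stored grid relative to
#'   the image it came from: list with `orig_height`, `row0`, `col0`,
#'   meaning `m[r, c]` is pixel `(row0 + r - 1, col0 + c - 1)` of an
#'   original image of `orig_height` rows. Lets traced outlines stay in
#'   the coordinate frame landmarks were digitized in even after
#'   cropping. Defaults to the identity frame.
#' @return object of class `binary_mask` with elements `mask`, `height`,
#'   `width`, `frame`.
#' @export
binary_mask <- function(m, frame = NULL) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  if (is.null(frame))
    frame <- list(orig_height = nrow(m), row0 = 1L, col0 = 1L)
  structure(list(mask = m, height = nrow(m), width = ncol(m), frame = frame),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d, %d foreground pixels\n",
              x$height, x$width, sum(x$mask)))
  invisible(x)
}

#' Read a silhouette mask image
#'
#' Loads a PNG or TIFF image of a single scale silhouette, thresholds it at
#' the midpoint of its value range, auto-detects polarity (the colour in the
#' majority on the image border is taken as background), keeps the largest
#' 4-connected foreground component, and normalizes the frame by cropping to
#' the foreground bounding box plus a `pad`-pixel background ring. The
#' normalization makes the reader idempotent: re-reading a written mask
#' reproduces it exactly.
#'
#' @param path PNG or TIFF file.
#' @param pad width of the background ring added around the cropped
#'   foreground (pixels).
#' @param max_discard_frac error when more than this fraction of total
#'   foreground area lies in discarded (non-largest) components.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path, pad = 1L, max_discard_frac = 0.5) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3L) {
    nc <- min(dim(img)[3L], 3L)  # ignore alpha
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
  }
  mid <- (max(img) + min(img)) / 2
  hi <- img > mid
  border <- c(hi[1L, ], hi[nrow(hi), ], hi[, 1L], hi[, ncol(hi)])
  bg_is_hi <- mean(border) >= 0.5
  fg <- if (bg_is_hi) !hi else hi
  if (!any(fg)) stop("no foreground object in mask: ", path)

  lab <- EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  discarded <- sum(sizes[-keep])
  if (discarded > 0) {
    if (discarded / sum(sizes) > max_discard_frac)
      stop(sprintf(
        "mask %s: %d of %d foreground pixels fall outside the largest component",
        path, discarded, sum(sizes)))
    warning(sprintf(
      "mask %s: discarded %d smaller component(s) totalling %d pixel(s)",
      path, length(sizes) - 1L, discarded))
  }
  m <- (lab == keep) * 1L

  orig_height <- nrow(m)
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  m <- m[rows[1L]:rows[2L], cols[1L]:cols[2L], drop = FALSE]
  pad <- as.integer(pad)
  out <- matrix(0L, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  out[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  binary_mask(out, frame = list(orig_height = orig_height,
                                row0 = rows[1L] - pad,
                                col0 = cols[1L] - pad))
}

#' Write a silhouette mask as PNG
#'
#' Foreground is written black on a white background.
#'
#' @param mask a [binary_mask()].
#' @param path output PNG file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(1 - mask$mask, path)
  invisible(path)
}

#' Read a TPS landmark file
#'
#' Parses the TPS dialect used for morphometric landmark interchange:
#' `LM=k` followed by k whitespace-separated `x y` lines, with optional
#' `ID=`, `IMAGE=` and `SCALE=` keys per record. When `SCALE=` is present
#' the coordinates are multiplied by it. `CURVES=`/`POINTS=` blocks are not
#' supported (semilandmarks are constructed, not digitized) and raise an
#' error. The y axis is left in file convention; set `flip_y = TRUE` to
#' negate it for digitizers that use image-row coordinates.
#'
#' @param path TPS file.
#' @param flip_y negate the y coordinate on load.
#' @return list of records, each a list with `shape_id`, `points`
#'   (k x 2 matrix), `declared_count`, `image`, `scale`. An empty file
#'   yields an empty list.
#' @export
read_tps <- function(path, flip_y = FALSE) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  records <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^(CURVES|POINTS)\\s*=", ln, ignore.case = TRUE))
      stop("TPS CURVES/POINTS blocks are not supported (record ",
           length(records) + 1L, "); semilandmarks are constructed, not read")
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("unexpected line outside a record in ", path, ": '", ln, "'")
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 0) stop("malformed LM= count in record ", length(records) + 1L)
    i <- i + 1L
    pts <- matrix(NA_real_, k, 2L)
    for (r in seq_len(k)) {
      if (i > length(lines) || grepl("=", lines[i], fixed = TRUE))
        stop(sprintf(
          "record %d declares LM=%d but only %d coordinate line(s) found",
          length(records) + 1L, k, r - 1L))
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1L]]))
      if (length(xy) != 2L || any(is.na(xy)))
        stop(sprintf("record %d: cannot parse coordinate line '%s'",
                     length(records) + 1L, lines[i]))
      pts[r, ] <- xy
      i <- i + 1L
    }
    id <- NULL; image <- NA_character_; scl <- NA_real_
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      key <- toupper(sub("\\s*=.*$", "", lines[i]))
      val <- sub("^[^=]*=\\s*", "", lines[i])
      switch(key,
        ID = { id <- val },
        IMAGE = { image <- val },
        SCALE = { scl <- suppressWarnings(as.numeric(val)) },
        CURVES = ,
        POINTS = stop("TPS CURVES/POINTS blocks are not supported (record ",
                      length(records) + 1L, ")"),
        stop("unknown TPS key '", key, "' in record ", length(records) + 1L)
      )
      i <- i + 1L
    }
    if (!is.na(scl)) pts <- pts * scl
    if (flip_y) pts[, 2L] <- -pts[, 2L]
    if (is.null(id)) {
      id <- if (!is.na(image)) tools::file_path_sans_ext(basename(image))
            else as.character(length(records) + 1L)
    }
    records[[length(records) + 1L]] <-
      list(shape_id = id, points = pts, declared_count = k,
           image = image, scale = scl)
  }
  records
}

#' Write landmark records as TPS
#'
#' @param records list of records as returned by [read_tps()], or a named
#'   list of k x 2 coordinate matrices.
#' @param path output file.
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_tps <- function(records, path, digits = 10L) {
  if (length(records) && is.matrix(records[[1L]])) {
    ids <- names(records)
    if (is.null(ids)) ids <- as.character(seq_along(records))
    records <- Map(function(p, id) list(shape_id = id, points = p), records, ids)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    p <- rec$points
    writeLines(sprintf("LM=%d", nrow(p)), con)
    writeLines(sprintf("%.*g %.*g", digits, p[, 1L], digits, p[, 2L]), con)
    writeLines(sprintf("ID=%s", rec$shape_id), con)
    if (!is.null(rec$scale) && !is.na(rec$scale))
      writeLines(sprintf("SCALE=%.*g", digits, rec$scale), con)
  }
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Comma-delimited UTF-8 table with one row per scale. Required columns:
#' `scale_id`, `species`. Optional: `specimen_id`, `body_area` (one of
#' C, D, E, H), `group` (e.g. aquaculture facility), `pixels_per_mm`
#' (default 1, i.e. pixel units).
#'
#' @param path CSV file.
#' @return data.frame with one validated row per scale.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("scale_id", "species")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$scale_id <- as.character(df$scale_id)
  dup <- unique(df$scale_id[duplicated(df$scale_id)])
  if (length(dup))
    stop("duplicate scale_id in metadata: ", paste(dup, collapse = ", "))
  if (is.null(df$specimen_id)) df$specimen_id <- NA_character_
  if (is.null(df$group)) df$group <- NA_character_
  if (is.null(df$body_area)) df$body_area <- NA_character_
  bad_area <- setdiff(stats::na.omit(unique(df$body_area)), c("C", "D", "E", "H"))
  if (length(bad_area))
    stop("body_area values outside {C, D, E, H}: ",
         paste(bad_area, collapse = ", "))
  if (is.null(df$pixels_per_mm)) df$pixels_per_mm <- 1
  df$pixels_per_mm[is.na(df$pixels_per_mm)] <- 1
  if (any(df$pixels_per_mm <= 0)) stop("pixels_per_mm must be positive")
  df
}

#' Default run configuration
#'
#' The analysis options shared by the command-line pipelines, overridable
#' from a YAML file via [read_run_config()].
#'
#' @return named list of defaults.
#' @export
default_run_config <- function() {
  list(
    masks = NULL, tps = NULL, metadata = NULL, out_dir = NULL,
    method = "both", grouping = "species",
    slm_counts = c(40L, 10L, 10L, 10L, 10L), slide = "none",
    n_points = 360L, harmonic_threshold = 0.99, max_harmonics = 32L,
    n_permutations = 999L, seed = 1L, flip_y = FALSE
  )
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take the defaults of
#' [default_run_config()].
#'
#' @param path YAML file.
#' @return named configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(cfg)] <- cfg
  defaults$slm_counts <- as.integer(defaults$slm_counts)
  defaults
}
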