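# Outline extraction and preparation for the outline-based pipeline:
# sub-pixel boundary tracing of silhouette masks, equidistant arc-length
# resampling, and centering / unit-centroid-size / orientation
# normalization.

#' Trace the boundary of a silhouette mask
#'
#' Extracts the closed sub-pixel contour of the foreground at the 0.5
#' iso-level of the 0/1 pixel grid (bilinear interpolation between pixel
#' centers), in mathematical axes (x = column, y increases upward). When
#' the mask contains several iso-contours the one enclosing the largest
#' area is kept. The result is counter-clockwise and encloses all
#' foreground pixel centers.
#'
#' Degenerate one-pixel-wide necks can produce a self-touching contour;
#' these are rejected with an error suggesting morphological cleanup.
#'
#' Coordinates are reported in the frame of the image the mask was read
#' from (see the `frame` element of [binary_mask()]), so outlines traced
#' from a cropped mask still line up with landmarks digitized on the
#' original image.
#'
#' @param mask a [binary_mask()] whose foreground does not touch the
#'   border (as guaranteed by [read_mask()]).
#' @return n x 2 vertex matrix (pixel units), counter-clockwise.
#' @export
trace_boundary <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  m <- mask$mask
  h <- nrow(m); w <- ncol(m)
  if (!any(m == 1L)) stop("mask has no foreground pixels")
  if (any(m[1L, ] == 1L) || any(m[h, ] == 1L) ||
      any(m[, 1L] == 1L) || any(m[, w] == 1L))
    stop("foreground touches the image border; re-read the mask with padding")
  # pixel (row r, col c) center sits at (x = c, y = h - r + 1)
  z <- t(m)[, h:1, drop = FALSE]
  cl <- grDevices::contourLines(seq_len(w), seq_len(h), z, levels = 0.5)
  if (!length(cl)) stop("no iso-level contour found")
  polys <- lapply(cl, function(ct) dedup_closed(cbind(ct$x, ct$y)))
  areas <- vapply(polys, function(v) abs(poly_signed_area(v)), numeric(1))
  v <- ensure_ccw(polys[[which.max(areas)]])
  fr <- mask$frame
  if (!is.null(fr)) {
    v[, 1L] <- v[, 1L] + (fr$col0 - 1L)
    v[, 2L] <- v[, 2L] + (fr$orig_height - fr$row0 + 1L - h)
  }
  if (polygon_self_touches(v))
    stop("traced contour touches itself (one-pixel-wide region); ",
         "apply morphological cleanup to the mask first")
  validate_polygon(v)
  v
}

#' Resample a polygon at equal arc-length spacing
#'
#' Places `n` points along the closed boundary at spacing perimeter/n,
#' starting from vertex `start_vertex` and preserving orientation.
#'
#' @param poly n x 2 vertex matrix.
#' @param n number of points (>= 3).
#' @param start_vertex index of the vertex at which resampling starts.
#' @return n x 2 matrix of equidistant boundary points.
#' @export
resample_equidistant <- function(poly, n, start_vertex = 1L) {
  validate_polygon(poly, require_ccw = FALSE)
  if (n < 3L) stop("n must be at least 3")
  per <- poly_perimeter(poly)
  s0 <- poly_arc_coords(poly)[start_vertex]
  s <- s0 + per * (seq_len(n) - 1L) / n
  point_at_arc(poly, s)
}

#' Index of the anterior starting vertex
#'
#' The deterministic starting-point rule for outline resampling: the
#' vertex whose direction from the outline centroid is closest to the
#' anterior direction (polar angle pi, i.e. leftwards for scales imaged
#' anterior leftwards), ties broken by the lower vertex index. Unlike a
#' minimum-x rule, this stays put when a flat or oscillating anterior
#' margin makes the leftmost vertex wander under digitization noise.
#'
#' @param poly n x 2 vertex matrix.
#' @return vertex index.
#' @export
anterior_start <- function(poly) {
  ctr <- colMeans(poly)
  ang <- atan2(poly[, 2L] - ctr[2L], poly[, 1L] - ctr[1L])
  # angular distance to pi (wrapped)
  which.min(abs((ang - pi + pi) %% (2 * pi) - pi))
}

#' Center, scale and optionally orient an outline
#'
#' Translates the vertex mean to the origin and scales the polygon to unit
#' centroid size (root sum of squared vertex distances to the centroid).
#' With `orient = "first_ellipse"` the polygon is additionally rotated so
#' that the major axis of its first-harmonic ellipse lies along +x (defined
#' modulo pi), for datasets not acquired in a standard orientation.
#'
#' @param poly n x 2 vertex matrix.
#' @param orient `"none"` (keep acquisition orientation, the default) or
#'   `"first_ellipse"`.
#' @return normalized n x 2 vertex matrix.
#' @export
normalize_outline <- function(poly, orient = c("none", "first_ellipse")) {
  orient <- match.arg(orient)
  validate_polygon(poly, require_ccw = FALSE)
  ctr <- colMeans(poly)
  v <- sweep(poly, 2L, ctr)
  cs <- sqrt(sum(v^2))
  if (cs <= 0) stop("degenerate polygon: zero centroid size")
  v <- v / cs
  if (orient == "first_ellipse") {
    e1 <- eft_forward(v, 1L, spacing = "chord")$harmonics
    A <- matrix(c(e1[1L, "a"], e1[1L, "b"], e1[1L, "c"], e1[1L, "d"]),
                2L, 2L, byrow = TRUE)
    u1 <- svd(A)$u[, 1L]
    v <- rotate_points(v, -atan2(u1[2L], u1[1L]))
  }
  v
}

#' Export an outline as coordinate CSV
#'
#' One row per vertex, columns `x`, `y`.
#'
#' @param poly n x 2 vertex matrix.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(poly, path) {
  utils::write.csv(data.frame(x = poly[, 1L], y = poly[, 2L]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an outline from coordinate CSV
#' @param path CSV with columns `x`, `y`.
#' @return n x 2 vertex matrix.
#' @export
read_outline_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) stop("outline CSV needs columns x, y")
  as.matrix(df[, c("x", "y")])
}
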