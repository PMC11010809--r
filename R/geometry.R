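# Internal planar-geometry helpers.
#
# Polygons are plain numeric matrices with two columns (x, y), implicitly
# closed (the last vertex connects back to the first) and, once validated,
# counter-clockwise. All internal geometry lives in mathematical axes:
# x rightward, y upward.

#' Validate a closed outline polygon
#'
#' Checks the structural invariants every outline polygon must satisfy:
#' at least 3 vertices, finite coordinates, no two consecutive vertices
#' closer than `tol`, and (optionally) counter-clockwise orientation,
#' i.e. positive signed area.
#'
#' @param v numeric matrix, n x 2, vertices of an implicitly closed polygon.
#' @param require_ccw error when the signed area is not positive.
#' @param tol minimum distance between consecutive vertices.
#' @return `v`, invisibly.
#' @export
validate_polygon <- function(v, require_ccw = TRUE, tol = 1e-12) {
  if (!is.matrix(v) || ncol(v) != 2L || !is.numeric(v))
    stop("polygon must be a numeric matrix with 2 columns")
  if (nrow(v) < 3L)
    stop("polygon must have at least 3 vertices")
  if (!all(is.finite(v)))
    stop("polygon has non-finite coordinates")
  if (any(poly_edge_lengths(v) <= tol))
    stop("polygon has consecutive duplicate vertices")
  if (require_ccw && poly_signed_area(v) <= 0)
    stop("polygon is not counter-clockwise (signed area <= 0)")
  invisible(v)
}

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param v n x 2 vertex matrix.
#' @return signed area.
#' @export
poly_signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

poly_edge_lengths <- function(v) {
  j <- c(2:nrow(v), 1L)
  sqrt(rowSums((v[j, , drop = FALSE] - v)^2))
}

#' Perimeter of a closed polygon
#' @param v n x 2 vertex matrix.
#' @return total edge length, including the closing edge.
#' @export
poly_perimeter <- function(v) sum(poly_edge_lengths(v))

# Arc-length coordinate of each vertex, starting at 0 for vertex 1.
poly_arc_coords <- function(v) {
  el <- poly_edge_lengths(v)
  c(0, cumsum(el))[seq_len(nrow(v))]
}

# Orient counter-clockwise, reversing vertex order if needed.
ensure_ccw <- function(v) {
  if (poly_signed_area(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

# Drop a repeated closing vertex and any consecutive duplicates.
dedup_closed <- function(v, tol = 1e-12) {
  n <- nrow(v)
  if (n > 1L && all(abs(v[n, ] - v[1L, ]) <= tol)) v <- v[-n, , drop = FALSE]
  keep <- c(TRUE, sqrt(rowSums((v[-1L, , drop = FALSE] -
                                  v[-nrow(v), , drop = FALSE])^2)) > tol)
  v[keep, , drop = FALSE]
}

# TRUE when a non-adjacent vertex pair coincides (self-touching chain).
polygon_self_touches <- function(v, digits = 9L) {
  key <- paste(round(v[, 1L], digits), round(v[, 2L], digits))
  any(duplicated(key))
}

#' Point on a polygon at a given arc-length position
#'
#' Arc length is measured along the closed boundary from vertex 1; values
#' are taken modulo the perimeter. Vectorized over `s`.
#'
#' @param v n x 2 vertex matrix.
#' @param s numeric vector of arc-length positions.
#' @return length(s) x 2 matrix of boundary points.
#' @export
point_at_arc <- function(v, s) {
  n <- nrow(v)
  el <- poly_edge_lengths(v)
  arc <- c(0, cumsum(el))
  per <- arc[n + 1L]
  s <- s %% per
  i <- findInterval(s, arc, rightmost.closed = FALSE)
  i[i > n] <- n
  j <- c(2:n, 1L)
  frac <- (s - arc[i]) / el[i]
  v[i, , drop = FALSE] + (v[j[i], , drop = FALSE] - v[i, , drop = FALSE]) * frac
}

# Nearest boundary point to p: list(arc, dist, point).
nearest_on_polygon <- function(v, p) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  a <- v
  d <- v[j, , drop = FALSE] - a
  len2 <- rowSums(d^2)
  tt <- ((p[1L] - a[, 1L]) * d[, 1L] + (p[2L] - a[, 2L]) * d[, 2L]) / len2
  tt <- pmin(pmax(tt, 0), 1)
  px <- a[, 1L] + tt * d[, 1L]
  py <- a[, 2L] + tt * d[, 2L]
  dist2 <- (px - p[1L])^2 + (py - p[2L])^2
  k <- which.min(dist2)
  arc <- poly_arc_coords(v)[k] + tt[k] * sqrt(len2[k])
  list(arc = arc, dist = sqrt(dist2[k]), point = c(px[k], py[k]))
}

# Rotate vertex order so vertex `start` comes first (same orientation).
rotate_start <- function(v, start) {
  n <- nrow(v)
  idx <- ((seq_len(n) + start - 2L) %% n) + 1L
  v[idx, , drop = FALSE]
}

# 2-D rotation of row-vector points by angle theta (counter-clockwise).
rotate_points <- function(pts, theta) {
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L, 2L)
  pts %*% R
}
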