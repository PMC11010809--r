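# The landmark + semilandmark configuration builder.
#
# The default scheme uses 5 fixed landmarks on the scale margin junctions
# (1 dorsal anterior tip, 2 ventral anterior tip, 3 ventral posterior tip,
# 4 middle of the posterior margin, 5 dorsal posterior tip) and 80
# semilandmarks equidistant in arc length along each inter-landmark margin:
# 40 along the anterior margin 1-2 (the most variable trait) and 10 along
# each of 2-3, 3-4, 4-5 and 5-1, for 85 points in total.

#' Snap digitized landmarks onto a traced outline
#'
#' Maps each of the 5 digitized landmark points to the arc-length position
#' of its nearest point on the polygon boundary, then validates the
#' digitization: landmarks closer than `min_sep` of the perimeter are
#' rejected as implausible, and the 5 arc positions must appear in
#' consistent cyclic order 1..5 along the outline. When the order is
#' consistently reversed the outline is re-oriented (vertex order reversed)
#' and snapping repeated; any other order is an error.
#'
#' @param poly n x 2 vertex matrix (counter-clockwise).
#' @param raw_landmarks 5 x 2 matrix of digitized landmarks in label order.
#' @param min_sep minimum landmark separation as a fraction of perimeter.
#' @return list with `arc` (5 arc positions on `poly`), `distance`
#'   (5 snap distances), and `poly` (possibly re-oriented polygon; use this
#'   one downstream).
#' @export
snap_landmarks <- function(poly, raw_landmarks, min_sep = 0.01) {
  validate_polygon(poly, require_ccw = FALSE)
  raw_landmarks <- as.matrix(raw_landmarks)
  if (nrow(raw_landmarks) != 5L || ncol(raw_landmarks) != 2L)
    stop("raw_landmarks must be a 5 x 2 matrix in label order 1..5")
  snap <- function(v) {
    hits <- lapply(seq_len(5L), function(i) nearest_on_polygon(v, raw_landmarks[i, ]))
    list(arc = vapply(hits, `[[`, numeric(1), "arc"),
         dist = vapply(hits, `[[`, numeric(1), "dist"))
  }
  s <- snap(poly)
  per <- poly_perimeter(poly)
  gaps <- outer(s$arc, s$arc, function(a, b) abs(a - b))
  gaps <- pmin(gaps, per - gaps)
  close_pairs <- which(gaps < min_sep * per & upper.tri(gaps), arr.ind = TRUE)
  if (nrow(close_pairs))
    stop(sprintf(
      "landmarks %d and %d snap to arc positions closer than %g%% of the perimeter",
      close_pairs[1L, 1L], close_pairs[1L, 2L], 100 * min_sep))
  ord <- order(s$arc)
  if (!is_cyclic_rotation(ord, seq_len(5L))) {
    if (is_cyclic_rotation(ord, rev(seq_len(5L)))) {
      poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
      # reversal flips orientation; outline polygons must stay CCW, so this
      # branch only triggers for digitizations traversed the other way
      s <- snap(poly)
      ord <- order(s$arc)
      if (!is_cyclic_rotation(ord, seq_len(5L)))
        stop("landmark cyclic order still inconsistent after re-orientation")
    } else {
      stop("landmarks are not in cyclic order 1..5 along the outline ",
           "(observed order: ", paste(ord, collapse = ","), ")")
    }
  }
  list(arc = s$arc, distance = s$dist, poly = poly)
}

# TRUE when perm is a cyclic rotation of ref.
is_cyclic_rotation <- function(perm, ref) {
  n <- length(ref)
  any(vapply(seq_len(n) - 1L, function(k) {
    all(perm == ref[((seq_len(n) + k - 1L) %% n) + 1L])
  }, logical(1)))
}

#' Build a landmark + semilandmark configuration
#'
#' Places the stated number of semilandmarks strictly between consecutive
#' landmarks, equidistant in arc length along each margin (spacing =
#' margin arc length / (count + 1)). Output point order follows the
#' outline: landmark 1, its following semilandmarks, landmark 2, and so on.
#'
#' @param poly n x 2 vertex matrix (counter-clockwise).
#' @param lm_arcs 5 arc-length positions in cyclic order (from
#'   [snap_landmarks()]).
#' @param counts semilandmark counts for margins 1-2, 2-3, 3-4, 4-5, 5-1;
#'   default the 85-point scheme `c(40, 10, 10, 10, 10)`.
#' @return object of class `landmarked_shape`: list with `points`
#'   (k x 2), `roles` (`"fixed"`/`"semi"`), `segment_of` (margin index of
#'   each semilandmark, NA for fixed landmarks), `landmark_index` (row of
#'   each of the 5 landmarks in `points`).
#' @export
build_configuration <- function(poly, lm_arcs, counts = c(40L, 10L, 10L, 10L, 10L)) {
  validate_polygon(poly, require_ccw = FALSE)
  if (length(lm_arcs) != 5L) stop("lm_arcs must hold 5 arc positions")
  if (length(counts) != 5L || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be 5 non-negative integers (margins 1-2 .. 5-1)")
  counts <- as.integer(counts)
  per <- poly_perimeter(poly)
  nxt <- c(2:5, 1L)
  arcs <- numeric(0); roles <- character(0); seg <- integer(0)
  lm_index <- integer(5L)
  for (i in seq_len(5L)) {
    L <- (lm_arcs[nxt[i]] - lm_arcs[i]) %% per
    if (L <= per * 1e-12)
      stop("margin ", i, "-", nxt[i], " has zero arc length")
    lm_index[i] <- length(arcs) + 1L
    arcs <- c(arcs, lm_arcs[i],
              lm_arcs[i] + seq_len(counts[i]) * L / (counts[i] + 1L))
    roles <- c(roles, "fixed", rep("semi", counts[i]))
    seg <- c(seg, NA_integer_, rep(i, counts[i]))
  }
  structure(list(
    points = point_at_arc(poly, arcs),
    roles = roles,
    segment_of = seg,
    landmark_index = stats::setNames(lm_index, as.character(1:5))
  ), class = "landmarked_shape")
}

#' @export
print.landmarked_shape <- function(x, ...) {
  cat(sprintf("landmarked_shape: %d points (%d fixed, %d semilandmarks)\n",
              nrow(x$points), sum(x$roles == "fixed"), sum(x$roles == "semi")))
  invisible(x)
}

#' Write a configuration as TPS plus a JSON role sidecar
#'
#' The TPS record carries all points in configuration order; the sidecar
#' records roles, segment membership and landmark indices.
#'
#' @param shapes named list of `landmarked_shape` objects.
#' @param tps_path output TPS file.
#' @param sidecar_path output JSON file (default: `tps_path` with
#'   `.json` extension).
#' @return `tps_path`, invisibly.
#' @export
write_configuration <- function(shapes, tps_path,
                                sidecar_path = paste0(tools::file_path_sans_ext(tps_path), ".json")) {
  write_tps(lapply(shapes, `[[`, "points"), tps_path)
  first <- shapes[[1L]]
  jsonlite::write_json(
    list(roles = first$roles, segment_of = first$segment_of,
         landmark_index = as.list(first$landmark_index)),
    sidecar_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(tps_path)
}
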