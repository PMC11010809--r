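# Elliptic Fourier decomposition and reconstruction of closed outlines.
#
# The boundary is treated as a piecewise-linear closed curve (x(t), y(t))
# with period equal to the perimeter, and each coordinate expanded in a
# Fourier series: for harmonic n, (a_n, b_n) are the cosine/sine
# coefficients of x(t) and (c_n, d_n) those of y(t); the DC terms are the
# parametric mean point. Two parameter assignments are offered:
#
# - "uniform" (default): vertices are assumed equally spaced in the curve
#   parameter — exactly what resample_equidistant() produces, in which
#   case the parameter IS arc length. Under this convention an ellipse
#   sampled at its natural parameter is exactly one harmonic.
# - "chord": parameter increments equal the chord lengths between
#   consecutive vertices (the classical chain-code formulation), for
#   polygons with irregular vertex spacing.
#
# For equidistantly resampled outlines — the only way the pipelines call
# this code — the two are identical.

#' Forward elliptic Fourier transform of a closed outline
#'
#' @param poly n x 2 vertex matrix of a closed polygon.
#' @param n_harmonics number of harmonics, at most floor(n/2) (Nyquist).
#' @param spacing `"uniform"` or `"chord"` parameter increments (see
#'   package details above).
#' @return object of class `eft_coefs`: list with `dc` (A0, C0),
#'   `harmonics` (n_harmonics x 4 matrix, columns a, b, c, d),
#'   `perimeter`, `n_harmonics`, `spacing`.
#' @export
eft_forward <- function(poly, n_harmonics, spacing = c("uniform", "chord")) {
  spacing <- match.arg(spacing)
  validate_polygon(poly, require_ccw = FALSE)
  m <- nrow(poly)
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("n_harmonics must be positive")
  if (n_harmonics > floor(m / 2))
    stop("n_harmonics = ", n_harmonics, " exceeds the Nyquist bound floor(",
         m, "/2)")
  per <- poly_perimeter(poly)
  dt <- switch(spacing,
    uniform = rep(per / m, m),
    chord = poly_edge_lengths(poly))
  tt <- cumsum(dt)
  t0 <- c(0, tt[-m])
  T <- tt[m]
  j <- c(2:m, 1L)
  dx <- poly[j, 1L] - poly[, 1L]
  dy <- poly[j, 2L] - poly[, 2L]
  n <- seq_len(n_harmonics)
  ang1 <- outer(n, tt) * (2 * pi / T)
  ang0 <- outer(n, t0) * (2 * pi / T)
  dcos <- cos(ang1) - cos(ang0)
  dsin <- sin(ang1) - sin(ang0)
  K <- T / (2 * pi^2 * n^2)
  vx <- dx / dt; vy <- dy / dt
  harmonics <- cbind(
    a = K * as.numeric(dcos %*% vx),
    b = K * as.numeric(dsin %*% vx),
    c = K * as.numeric(dcos %*% vy),
    d = K * as.numeric(dsin %*% vy))
  dc <- c(sum(dt * (poly[, 1L] + poly[j, 1L]) / 2) / T,
          sum(dt * (poly[, 2L] + poly[j, 2L]) / 2) / T)
  structure(list(dc = dc, harmonics = harmonics, perimeter = per,
                 n_harmonics = n_harmonics, spacing = spacing),
            class = "eft_coefs")
}

#' @export
print.eft_coefs <- function(x, ...) {
  cat(sprintf("eft_coefs: %d harmonic(s), perimeter %.4g, spacing %s\n",
              x$n_harmonics, x$perimeter, x$spacing))
  invisible(x)
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Samples the truncated Fourier series at `n_points` equal parameter
#' steps. A reconstruction whose points collapse to the DC term (all
#' harmonic rows zero) is degenerate and flagged with a warning since it
#' is not a valid polygon.
#'
#' @param coef an `eft_coefs` object.
#' @param n_points number of reconstruction points (>= 3).
#' @return n_points x 2 vertex matrix.
#' @export
eft_inverse <- function(coef, n_points) {
  stopifnot(inherits(coef, "eft_coefs"))
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be at least 3")
  H <- coef$harmonics
  n <- seq_len(nrow(H))
  tt <- (seq_len(n_points) - 1L) / n_points   # parameter fraction of period
  ang <- outer(tt, n) * (2 * pi)
  Cs <- cos(ang); Sn <- sin(ang)
  x <- coef$dc[1L] + Cs %*% H[, "a"] + Sn %*% H[, "b"]
  y <- coef$dc[2L] + Cs %*% H[, "c"] + Sn %*% H[, "d"]
  out <- cbind(as.numeric(x), as.numeric(y))
  if (max(stats::dist(out[c(1L, ceiling(n_points / 3), ceiling(2 * n_points / 3)), ])) < 1e-12 ||
      all(abs(H) < 1e-15))
    warning("degenerate reconstruction: all points collapse to the DC term")
  out
}

#' Per-harmonic power and cumulative power fractions
#'
#' Power of harmonic n is (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2; the
#' cumulative fraction is the running sum over the total across all
#' computed harmonics.
#'
#' @param coef an `eft_coefs` object.
#' @return list with `power` and `cumulative` numeric vectors.
#' @export
harmonic_power <- function(coef) {
  stopifnot(inherits(coef, "eft_coefs"))
  p <- rowSums(coef$harmonics^2) / 2
  list(power = p, cumulative = cumsum(p) / sum(p))
}

#' Number of harmonics retaining a power threshold
#'
#' For a single outline, the smallest n whose cumulative power fraction
#' reaches `threshold` (default the 99% criterion). For a dataset (a list
#' of `eft_coefs`), the maximum such n over the outlines, so one shared
#' harmonic count serves the whole analysis.
#'
#' @param x cumulative-fraction vector, an `eft_coefs` object, or a list
#'   of `eft_coefs`.
#' @param threshold power fraction in (0, 1].
#' @return positive integer.
#' @export
choose_n_harmonics <- function(x, threshold = 0.99) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (inherits(x, "eft_coefs"))
    return(choose_n_harmonics(harmonic_power(x)$cumulative, threshold))
  if (is.list(x))
    return(max(vapply(x, choose_n_harmonics, integer(1), threshold = threshold)))
  if (is.unsorted(x, strictly = FALSE))
    stop("cumulative fractions must be non-decreasing")
  n <- which(x >= threshold - 1e-12)[1L]
  if (is.na(n)) stop("threshold not reached by the computed harmonics")
  as.integer(n)
}

#' Assemble the elliptic Fourier coefficient matrix
#'
#' One row per outline, columns a1, b1, c1, d1, a2, ... . DC terms are
#' excluded (outlines are centered before the transform, making them
#' negligible). All outlines must carry at least `n_harmonics` harmonics.
#'
#' @param coefs list of `eft_coefs` for normalized outlines.
#' @param n_harmonics shared harmonic count for the analysis.
#' @return length(coefs) x (4 * n_harmonics) matrix.
#' @export
coefficient_matrix <- function(coefs, n_harmonics) {
  n_harmonics <- as.integer(n_harmonics)
  avail <- vapply(coefs, function(co) co$n_harmonics, integer(1))
  if (any(avail < n_harmonics))
    stop("mixed harmonic counts: ", sum(avail < n_harmonics),
         " outline(s) carry fewer than ", n_harmonics, " harmonics")
  rows <- t(vapply(coefs, function(co)
    as.numeric(t(co$harmonics[seq_len(n_harmonics), , drop = FALSE])),
    numeric(4L * n_harmonics)))
  colnames(rows) <- paste0(rep(c("a", "b", "c", "d"), n_harmonics),
                           rep(seq_len(n_harmonics), each = 4L))
  if (!is.null(names(coefs))) rownames(rows) <- names(coefs)
  rows
}
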