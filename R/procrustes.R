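# Ordinary and generalized Procrustes superimposition of 2-D
# configurations.
#
# gpa() is a partial Procrustes scheme: configurations are centered and
# scaled to unit centroid size once, then only rotated during the
# iterations, so every aligned shape keeps centroid size exactly 1 and
# shape distances to the consensus are plain root-sum-of-squares
# coordinate differences. Optional bending-energy
# sliding lets semilandmarks move along their local tangent direction.

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the points to their
#' centroid — the standard size measure of geometric morphometrics.
#'
#' @param points k x 2 coordinate matrix or a `landmarked_shape`.
#' @return positive scalar.
#' @export
centroid_size <- function(points) {
  if (inherits(points, "landmarked_shape")) points <- points$points
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("centroid size needs at least 2 points")
  cs <- sqrt(sum(sweep(points, 2L, colMeans(points))^2))
  if (cs <= 0) stop("all points identical: centroid size is zero")
  cs
}

# Center and scale to unit centroid size; errors on degenerate input.
center_scale <- function(x) {
  x <- sweep(x, 2L, colMeans(x))
  x / sqrt(sum(x^2))
}

#' Ordinary Procrustes alignment of one shape onto a reference
#'
#' Both configurations are centered and scaled to unit centroid size, then
#' the least-squares optimal rotation of `shape` onto `reference` is found.
#' Reflections are only permitted when `allow_reflection = TRUE` (scales
#' are imaged in a standard orientation, so mirrored fits are normally
#' spurious).
#'
#' @param shape,reference k x 2 coordinate matrices with matching k.
#' @param allow_reflection permit an improper (reflecting) fit.
#' @return list with `aligned` (rotated shape), `angle` (rotation applied,
#'   radians, counter-clockwise), `residual` (root-sum-of-squares
#'   coordinate difference to the reference — the partial Procrustes
#'   distance), `reflected`.
#' @export
opa_align <- function(shape, reference, allow_reflection = FALSE) {
  shape <- as.matrix(shape); reference <- as.matrix(reference)
  if (nrow(shape) != nrow(reference))
    stop("shape and reference must have the same number of points")
  X <- center_scale(shape)
  Y <- center_scale(reference)
  M <- crossprod(X, Y)
  sv <- svd(M)
  S <- diag(2L)
  reflected <- det(sv$u %*% t(sv$v)) < 0
  if (reflected && !allow_reflection) S[2L, 2L] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  aligned <- X %*% R
  list(aligned = aligned,
       angle = atan2(R[1L, 2L], R[1L, 1L]),
       residual = sqrt(sum((aligned - Y)^2)),
       reflected = reflected && allow_reflection)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition: all configurations are centered and scaled
#' to unit centroid size, rotated onto the running consensus, and the
#' consensus recomputed, until its root-mean-square coordinate change
#' falls below `tol`. With `slide = "bending_energy"` each alignment round
#' is followed by a sliding step in which semilandmarks move along their
#' local tangent to minimize thin-plate-spline bending energy against the
#' consensus, are re-projected onto the configuration polyline, and the
#' shape re-normalized; fixed landmarks never move, and a slide is only
#' accepted when it lowers the bending energy.
#'
#' After convergence, when the configurations carry landmark labels, the
#' rotational indeterminacy of GPA is removed by rotating the whole set so
#' the consensus landmark-1 to landmark-4 chord (anterior tip to
#' mid-posterior) is horizontal.
#'
#' @param shapes list of `landmarked_shape` objects or k x 2 matrices, or
#'   a k x 2 x n array; all with identical point counts and role structure.
#' @param slide `"none"` (semilandmarks fixed at their equidistant
#'   positions, the default) or `"bending_energy"`.
#' @param slide_iters number of initial alignment rounds that include a
#'   sliding step; later rounds only rotate, letting the superimposition
#'   converge.
#' @param tol convergence tolerance on the RMS consensus coordinate change.
#' @param max_iter maximum number of alignment rounds.
#' @param allow_reflection permit reflecting fits.
#' @return object of class `aligned_shapes`: list with `coords`
#'   (k x 2 x n aligned array), `consensus` (pointwise mean of the aligned
#'   shapes), `centroid_sizes` (pre-alignment, input units),
#'   `iterations`, `converged`, `ss_history` (total squared Procrustes
#'   residual to the consensus after each round), plus the role metadata
#'   of the input.
#' @export
gpa <- function(shapes, slide = c("none", "bending_energy"),
                slide_iters = 5L, tol = 1e-8, max_iter = 100L,
                allow_reflection = FALSE) {
  slide <- match.arg(slide)
  meta <- NULL
  if (is.array(shapes) && length(dim(shapes)) == 3L) {
    A <- shapes
  } else {
    if (length(shapes) < 2L) stop("gpa needs at least 2 shapes")
    if (inherits(shapes[[1L]], "landmarked_shape")) {
      meta <- shapes[[1L]][c("roles", "segment_of", "landmark_index")]
      mats <- lapply(shapes, function(s) s$points)
    } else {
      mats <- lapply(shapes, as.matrix)
    }
    k <- unique(vapply(mats, nrow, integer(1)))
    if (length(k) != 1L) stop("all shapes must have the same number of points")
    A <- array(unlist(mats), dim = c(k[1L], 2L, length(mats)))
  }
  k <- dim(A)[1L]; n <- dim(A)[3L]
  if (n < 2L) stop("gpa needs at least 2 shapes")

  cs <- apply(A, 3L, centroid_size)
  for (i in seq_len(n)) A[, , i] <- center_scale(A[, , i])

  semis <- if (!is.null(meta)) which(meta$roles == "semi") else integer(0)
  be_mat <- NULL
  ref <- A[, , 1L]
  converged <- FALSE
  iter <- 0L
  ss_history <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      A[, , i] <- opa_align(A[, , i], ref, allow_reflection)$aligned
    if (slide == "bending_energy" && length(semis) && iter <= slide_iters) {
      be_mat <- tps_bending_matrix(ref)
      for (i in seq_len(n))
        A[, , i] <- slide_shape(A[, , i], ref, semis, be_mat)
    }
    cons <- apply(A, c(1L, 2L), mean)
    ss_history <- c(ss_history,
                    sum(sweep(A, c(1L, 2L), cons)^2))
    cons_unit <- center_scale(cons)
    delta <- sqrt(mean((cons_unit - ref)^2))
    ref <- cons_unit
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("gpa did not converge in ", max_iter, " iterations")

  consensus <- apply(A, c(1L, 2L), mean)
  if (!is.null(meta) && !is.null(meta$landmark_index)) {
    li <- meta$landmark_index
    chord <- consensus[li[["4"]], ] - consensus[li[["1"]], ]
    theta <- atan2(chord[2L], chord[1L])
    for (i in seq_len(n)) A[, , i] <- rotate_points(A[, , i], -theta)
    consensus <- rotate_points(consensus, -theta)
  }
  structure(list(
    coords = A, consensus = consensus, centroid_sizes = cs,
    iterations = iter, converged = converged, slide = slide,
    ss_history = ss_history,
    roles = meta$roles, segment_of = meta$segment_of,
    landmark_index = meta$landmark_index
  ), class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf(
    "aligned_shapes: %d shapes x %d points (slide = %s, %d iteration(s), %s)\n",
    dim(x$coords)[3L], dim(x$coords)[1L], x$slide, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Thin-plate-spline bending-energy matrix
#'
#' Upper k x k block of the inverse of the TPS system matrix of the
#' reference configuration, with kernel U(r) = r^2 log(r^2). The bending
#' energy of a displacement field v (one column per coordinate) against
#' the reference is `sum(v * (Be %*% v))`.
#'
#' @param ref k x 2 reference configuration.
#' @return k x k bending-energy matrix.
#' @export
tps_bending_matrix <- function(ref) {
  k <- nrow(ref)
  r2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(r2 > 0, r2 * log(r2), 0)
  P <- cbind(1, ref)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  Li <- solve(L)
  Li[seq_len(k), seq_len(k), drop = FALSE]
}

# Bending energy of shape Y against reference (with Be = tps_bending_matrix(ref)).
bending_energy <- function(Y, ref, be_mat) {
  v <- Y - ref
  sum(v[, 1L] * (be_mat %*% v[, 1L])) + sum(v[, 2L] * (be_mat %*% v[, 2L]))
}

# One sliding step for a single aligned shape: move semilandmarks along
# their local tangents to minimize TPS bending energy against ref, project
# back onto the configuration polyline, renormalize, and accept only if
# the energy decreased (damped line search).
slide_shape <- function(Y, ref, semis, be_mat) {
  k <- nrow(Y)
  prv <- c(k, seq_len(k - 1L)); nxt <- c(2:k, 1L)
  tang <- Y[nxt[semis], , drop = FALSE] - Y[prv[semis], , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  m <- length(semis)
  Ux <- matrix(0, k, m); Uy <- matrix(0, k, m)
  Ux[cbind(semis, seq_len(m))] <- tang[, 1L]
  Uy[cbind(semis, seq_len(m))] <- tang[, 2L]
  BUx <- be_mat %*% Ux; BUy <- be_mat %*% Uy
  H <- crossprod(Ux, BUx) + crossprod(Uy, BUy)
  g <- crossprod(Ux, be_mat %*% (Y[, 1L] - ref[, 1L])) +
       crossprod(Uy, be_mat %*% (Y[, 2L] - ref[, 2L]))
  t_full <- tryCatch(solve(H + diag(1e-10, m), -g), error = function(e) NULL)
  if (is.null(t_full)) return(Y)
  e_old <- bending_energy(Y, ref, be_mat)
  step <- 1
  for (half in 1:8) {
    Y2 <- Y
    Y2[semis, ] <- Y2[semis, ] + (step * as.numeric(t_full)) * tang
    for (s in semis) Y2[s, ] <- nearest_on_polygon(Y, Y2[s, ])$point
    Y2 <- center_scale(Y2)
    if (bending_energy(Y2, ref, be_mat) <= e_old) return(Y2)
    step <- step / 2
  }
  Y
}

# Flatten a k x 2 x n coordinate array to n x 2k (columns x1..xk, y1..yk).
flatten_coords <- function(A) {
  n <- dim(A)[3L]
  t(vapply(seq_len(n), function(i) c(A[, 1L, i], A[, 2L, i]),
           numeric(2L * dim(A)[1L])))
}

# Inverse of flatten_coords for a single flattened row.
unflatten_coords <- function(v, k = length(v) / 2L) {
  cbind(v[seq_len(k)], v[k + seq_len(k)])
}
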