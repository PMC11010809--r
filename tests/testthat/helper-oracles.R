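# Independent oracles, kept deliberately simple and separate from the
# implementation paths they check.

# Elliptic Fourier coefficients by dense trapezoidal quadrature of the
# Fourier projections of the piecewise-linear curve, with vertices at
# equal parameter steps (parameter scaled to [0, 1]).
eft_quadrature_oracle <- function(poly, n_harmonics, oversample = 100L) {
  m <- nrow(poly)
  vert_t <- (0:m) / m
  xs <- c(poly[, 1], poly[1, 1])
  ys <- c(poly[, 2], poly[1, 2])
  ts <- seq(0, 1, length.out = m * oversample + 1L)
  x <- stats::approx(vert_t, xs, xout = ts)$y
  y <- stats::approx(vert_t, ys, xout = ts)$y
  h <- diff(ts)
  trap <- function(f) sum((f[-1] + f[-length(f)]) / 2 * h)
  harm <- t(vapply(seq_len(n_harmonics), function(n) {
    cn <- cos(2 * pi * n * ts)
    sn <- sin(2 * pi * n * ts)
    2 * c(trap(x * cn), trap(x * sn), trap(y * cn), trap(y * sn))
  }, numeric(4)))
  colnames(harm) <- c("a", "b", "c", "d")
  harm
}

# Best rotation angle of X onto Y by brute-force maximization of
# tr(R(theta)^T X^T Y) over a fine grid.
opa_grid_oracle <- function(X, Y, n_grid = 1e6) {
  Xc <- scale(X, scale = FALSE); Xc <- Xc / sqrt(sum(Xc^2))
  Yc <- scale(Y, scale = FALSE); Yc <- Yc / sqrt(sum(Yc^2))
  M <- crossprod(Xc, Yc)
  th <- 2 * pi * (seq_len(n_grid) - 1) / n_grid - pi
  f <- (M[1, 1] + M[2, 2]) * cos(th) + (M[1, 2] - M[2, 1]) * sin(th)
  th[which.max(f)]
}

# One-way PERMANOVA pseudo-F and R2 from first principles for a single
# labeling (plain loops over the distance matrix).
permanova_hand <- function(data, groups) {
  D <- as.matrix(stats::dist(data))
  N <- nrow(D)
  lab <- as.character(groups)
  sstot <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) sstot <- sstot + D[i, j]^2
  sstot <- sstot / N
  ssw <- 0
  for (g in unique(lab)) {
    idx <- which(lab == g)
    s <- 0
    if (length(idx) > 1)
      for (i in seq_along(idx)[-length(idx)])
        for (j in (i + 1):length(idx)) s <- s + D[idx[i], idx[j]]^2
    ssw <- ssw + s / length(idx)
  }
  a <- length(unique(lab))
  ssb <- sstot - ssw
  list(F = (ssb / (a - 1)) / (ssw / (N - a)), R2 = ssb / sstot)
}

# Wrap arc positions of configuration points on a polygon.
arcs_on_polygon <- function(poly, pts) {
  vapply(seq_len(nrow(pts)), function(i)
    scalemorph:::nearest_on_polygon(poly, pts[i, ])$arc, numeric(1))
}
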