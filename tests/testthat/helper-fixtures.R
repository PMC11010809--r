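# Geometric fixtures built in code.

unit_square <- function() {
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
}

# Polygon sampling a circle at equal angles, counter-clockwise.
circle_polygon <- function(n = 1000, r = 1, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# 2:1 ellipse x = 2 cos t, y = sin t sampled densely at equal t.
ellipse_polygon <- function(n = 2000, a = 2, b = 1, rot = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  v <- cbind(a * cos(th), b * sin(th))
  if (rot != 0) {
    R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2)
    v <- v %*% R
  }
  v
}

# Random star-shaped simple polygon (radius a smooth function of angle).
random_star_polygon <- function(n = 400, seed = 1) {
  set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1) / n
  r <- 1
  for (j in 1:4) {
    ab <- stats::rnorm(2, 0, 0.08)
    r <- r + ab[1] * cos(j * th) + ab[2] * sin(j * th)
  }
  cbind(r * cos(th), r * sin(th))
}

# Binary mask with a filled disc of the given radius (pixel units).
disc_mask <- function(r = 50, pad = 5) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  g <- outer(seq_len(n), seq_len(n),
             function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
  binary_mask(g * 1L)
}

# Mask with a centred block of foreground pixels.
block_mask <- function(size = 3, canvas = 10) {
  m <- matrix(0L, canvas, canvas)
  lo <- floor((canvas - size) / 2) + 1
  m[lo:(lo + size - 1), lo:(lo + size - 1)] <- 1L
  binary_mask(m)
}

# A small set of noisy landmark+semilandmark configurations drawn from a
# synthetic template (one group), for Procrustes-level tests.
noisy_configurations <- function(n = 10, seed = 1, noise_sd = 0.03,
                                 counts = c(40L, 10L, 10L, 10L, 10L),
                                 template = make_template("waved")) {
  set.seed(seed)
  seeds <- sample.int(1e6, n)
  lapply(seeds, function(s) {
    sp <- sample_specimen(template, noise_sd = noise_sd, seed = s)
    sn <- snap_landmarks(sp$polygon, sp$landmarks)
    build_configuration(sn$poly, sn$arc, counts = counts)
  })
}

# Random similarity transform of a point matrix.
random_similarity <- function(pts, seed) {
  set.seed(seed)
  th <- stats::runif(1, 0, 2 * pi)
  s <- exp(stats::rnorm(1, 0, 0.5))
  tr <- stats::rnorm(2, 0, 3)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  sweep(s * pts %*% R, 2, -tr)
}
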