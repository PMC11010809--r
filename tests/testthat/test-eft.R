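make_coefs <- function(H, dc = c(0, 0)) {
  colnames(H) <- c("a", "b", "c", "d")
  structure(list(dc = dc, harmonics = H, perimeter = 1,
                 n_harmonics = nrow(H), spacing = "uniform"),
            class = "eft_coefs")
}

test_that("an ellipse is exactly one harmonic", {
  e <- ellipse_polygon(2000)
  co <- eft_forward(e, 5)
  expect_equal(unname(co$harmonics[1, ]), c(2, 0, 0, 1), tolerance = 1e-3)
  expect_true(all(abs(co$harmonics[2:5, ]) < 1e-3))
  hp <- harmonic_power(co)
  expect_equal(hp$power[1], 2.5, tolerance = 1e-3)
  expect_equal(hp$cumulative[1], 1, tolerance = 1e-6)
  expect_equal(choose_n_harmonics(co, 0.99), 1L)
  # parametric mean point is the DC term
  co2 <- eft_forward(e + matrix(rep(c(3, 4), each = 2000), ncol = 2), 2)
  expect_equal(co2$dc, c(3, 4), tolerance = 1e-6)
})

test_that("a unit circle has a1 = d1 and b1 = c1 = 0", {
  co <- eft_forward(circle_polygon(2000), 3)
  expect_equal(unname(co$harmonics[1, "a"]), unname(co$harmonics[1, "d"]),
               tolerance = 1e-3)
  expect_lt(abs(co$harmonics[1, "b"]), 1e-3)
  expect_lt(abs(co$harmonics[1, "c"]), 1e-3)
})

test_that("coefficients match a dense quadrature oracle", {
  poly <- random_star_polygon(400, seed = 13)
  co <- eft_forward(poly, 8)
  oracle <- eft_quadrature_oracle(poly, 8, oversample = 200L)
  expect_equal(unname(co$harmonics), unname(oracle), tolerance = 1e-6)
})

test_that("Nyquist bound and degenerate inverse are flagged", {
  poly <- circle_polygon(20)
  expect_error(eft_forward(poly, 11), "Nyquist")
  co0 <- make_coefs(matrix(0, 2, 4), dc = c(3, 4))
  expect_warning(pts <- eft_inverse(co0, 10), "degenerate")
  expect_equal(pts, matrix(rep(c(3, 4), each = 10), ncol = 2),
               tolerance = 1e-12)
})

test_that("forward then inverse reconstructs an ellipse from one harmonic", {
  e <- ellipse_polygon(2000)
  co <- eft_forward(e, 1)
  back <- eft_inverse(co, 500)
  # every reconstructed point lies on the true ellipse
  expect_equal((back[, 1] / 2)^2 + back[, 2]^2, rep(1, 500), tolerance = 1e-3)
})

test_that("reconstruction error is non-increasing in harmonic count", {
  tm <- make_template("waved")
  poly <- resample_equidistant(tm$vertices, 512)
  errs <- vapply(1:32, function(k) {
    back <- eft_inverse(eft_forward(poly, k), 512)
    sqrt(mean((back - poly)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[32], errs[1])
})

test_that("forward o inverse is a projection on the retained harmonics", {
  poly <- random_star_polygon(360, seed = 3)
  k <- 6
  co <- eft_forward(poly, k)
  back <- eft_inverse(co, 16384)   # dense enough that resampling
                                   # attenuation stays below tolerance
  co2 <- eft_forward(back, k)
  expect_equal(co2$harmonics, co$harmonics, tolerance = 1e-6)
})

test_that("harmonic_power and choose_n_harmonics arithmetic", {
  H <- rbind(c(sqrt(2 * 97), 0, 0, 0),
             c(0, sqrt(2 * 2), 0, 0),
             c(0, 0, sqrt(2 * 1), 0))
  hp <- harmonic_power(make_coefs(H))
  expect_equal(hp$power, c(97, 2, 1), tolerance = 1e-12)
  expect_equal(hp$cumulative, c(0.97, 0.99, 1.00), tolerance = 1e-12)
  expect_equal(choose_n_harmonics(hp$cumulative, 0.99), 2L)
  # dataset rule: the maximum over outlines
  expect_equal(choose_n_harmonics(list(c(rep(0.9, 3), rep(1, 5)),
                                       c(rep(0.9, 5), rep(1, 3)),
                                       c(rep(0.9, 4), rep(1, 4))), 0.99), 6L)
  expect_error(choose_n_harmonics(c(0.5, 1), 0), "threshold")
  expect_error(choose_n_harmonics(c(0.5, 1), 1.2), "threshold")
  # powers non-negative, cumulative non-decreasing to 1, on any outline
  hp2 <- harmonic_power(eft_forward(random_star_polygon(200, 8), 20))
  expect_true(all(hp2$power >= 0))
  expect_true(all(diff(hp2$cumulative) >= -1e-15))
  expect_equal(hp2$cumulative[20], 1, tolerance = 1e-12)
})

test_that("coefficient_matrix has the contracted shape and content", {
  polys <- lapply(1:10, function(i) {
    v <- random_star_polygon(200, seed = i)
    normalize_outline(resample_equidistant(v, 128))
  })
  coefs <- lapply(polys, eft_forward, n_harmonics = 8)
  mat <- coefficient_matrix(coefs, 8)
  expect_equal(dim(mat), c(10, 32))
  expect_equal(colnames(mat)[1:5], c("a1", "b1", "c1", "d1", "a2"))
  # content matches per-outline coefficients recomputed independently
  expect_equal(unname(mat[4, ]),
               as.numeric(t(eft_forward(polys[[4]], 8)$harmonics)))
  # identical outlines give identical rows
  same <- coefficient_matrix(rep(coefs[1], 3), 8)
  expect_true(all(abs(sweep(same, 2, same[1, ])) < 1e-9))
  expect_error(coefficient_matrix(coefs, 80), "fewer than")
})

test_that("normalized-outline coefficients are scale invariant", {
  v <- random_star_polygon(300, seed = 22)
  n1 <- normalize_outline(resample_equidistant(v, 128))
  n2 <- normalize_outline(resample_equidistant(v * 57.3, 128))
  expect_equal(eft_forward(n1, 10)$harmonics, eft_forward(n2, 10)$harmonics,
               tolerance = 1e-9)
})
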