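test_that("centroid_size closed forms and homogeneity", {
  sq <- matrix(c(-0.5, -0.5, 0.5, -0.5, 0.5, 0.5, -0.5, 0.5),
               ncol = 2, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  set.seed(8)
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(centroid_size(3.7 * X), 3.7 * centroid_size(X),
               tolerance = 1e-12)
  # 85-point configuration against direct recomputation from the definition
  cfg <- noisy_configurations(1, seed = 2)[[1]]
  p <- cfg$points
  expect_equal(centroid_size(cfg),
               sqrt(sum((p[, 1] - mean(p[, 1]))^2 + (p[, 2] - mean(p[, 2]))^2)),
               tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 2)), "identical")
})

test_that("opa_align recovers rotations and handles reflection", {
  tri <- matrix(c(0, 0, 2, 0, 1, 3), ncol = 2, byrow = TRUE)
  rot90 <- rotate_pts <- function(p, th)
    p %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  fit <- opa_align(rot90(tri, pi / 2), tri)
  expect_lt(fit$residual, 1e-12)
  expect_equal(abs(fit$angle), pi / 2, tolerance = 1e-9)

  mir <- tri %*% diag(c(-1, 1))
  fit_no <- opa_align(mir, tri, allow_reflection = FALSE)
  expect_gt(fit_no$residual, 0.1)
  fit_yes <- opa_align(mir, tri, allow_reflection = TRUE)
  expect_lt(fit_yes$residual, 1e-12)
  expect_true(fit_yes$reflected)

  expect_error(opa_align(tri, tri[1:2, ]), "same number of points")
})

test_that("opa_align matches a brute-force grid search", {
  set.seed(21)
  for (rep in 1:3) {
    X <- matrix(rnorm(20), 10, 2)
    Y <- matrix(rnorm(20), 10, 2)
    expect_equal(opa_align(X, Y)$angle, opa_grid_oracle(X, Y),
                 tolerance = 1e-3)
  }
})

test_that("gpa aligns transformed copies of one shape exactly", {
  base <- random_star_polygon(40, seed = 5)
  shapes <- lapply(1:8, function(i) random_similarity(base, seed = i))
  res <- gpa(shapes)
  expect_true(res$converged)
  for (i in 2:8)
    expect_equal(res$coords[, , i], res$coords[, , 1], tolerance = 1e-9)
  expect_equal(res$consensus, res$coords[, , 1], tolerance = 1e-9)
  # aligned shapes centered with unit centroid size
  for (i in 1:8) {
    expect_equal(colMeans(res$coords[, , i]), c(0, 0), tolerance = 1e-9)
    expect_equal(sqrt(sum(res$coords[, , i]^2)), 1, tolerance = 1e-9)
  }
})

test_that("gpa consensus is the pointwise mean and bisects two shapes", {
  set.seed(31)
  s1 <- matrix(rnorm(24), 12, 2)
  s2 <- matrix(rnorm(24), 12, 2)
  res <- gpa(list(s1, s2))
  expect_equal(res$consensus, apply(res$coords, c(1, 2), mean),
               tolerance = 1e-12)
  d1 <- sqrt(sum((res$coords[, , 1] - res$consensus)^2))
  d2 <- sqrt(sum((res$coords[, , 2] - res$consensus)^2))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("gpa descent is monotone and invariant to input transforms and order", {
  cfgs <- noisy_configurations(12, seed = 9)
  res <- gpa(cfgs, tol = 1e-12)
  expect_true(all(diff(res$ss_history) <= 1e-12))

  # transforming one input shape does not change the result
  cfgs2 <- cfgs
  cfgs2[[3]]$points <- random_similarity(cfgs[[3]]$points, seed = 77)
  res2 <- gpa(cfgs2, tol = 1e-12)
  expect_equal(res2$coords, res$coords, tolerance = 1e-8)

  # permuting the inputs permutes the outputs identically (landmark-chord
  # gauge removes the rotational indeterminacy)
  perm <- c(5, 1, 12, 3, 8, 2, 11, 7, 4, 10, 6, 9)
  res3 <- gpa(cfgs[perm], tol = 1e-12)
  expect_equal(res3$coords, res$coords[, , perm], tolerance = 1e-6)
  expect_equal(res3$consensus, res$consensus, tolerance = 1e-6)
})

test_that("consensus of noisy squares approaches the true square", {
  sq <- resample_equidistant(unit_square(), 20)
  set.seed(12)
  shapes <- lapply(1:20, function(i) sq + matrix(rnorm(40, 0, 0.01), 20, 2))
  res <- gpa(shapes)
  ref <- opa_align(res$consensus, scalemorph:::center_scale(sq))
  expect_lt(ref$residual, 0.02)   # noise-consistent distance
})

test_that("bending-energy sliding never increases bending energy", {
  cfgs <- noisy_configurations(8, seed = 14, noise_sd = 0.04,
                               counts = c(12L, 6L, 6L, 6L, 6L))
  res0 <- gpa(cfgs, slide = "none")
  res1 <- gpa(cfgs, slide = "bending_energy")
  expect_true(res1$converged)
  # compare both runs against one common reference: the (centered,
  # unit-size) consensus of the sliding run
  ref <- scale(res1$consensus, scale = FALSE)
  ref <- ref / sqrt(sum(ref^2))
  be <- tps_bending_matrix(ref)
  energy <- function(Y) {
    v <- Y - ref
    sum(v[, 1] * (be %*% v[, 1])) + sum(v[, 2] * (be %*% v[, 2]))
  }
  n <- dim(res0$coords)[3]
  e0 <- vapply(seq_len(n), function(i)
    energy(opa_align(res0$coords[, , i], ref)$aligned), numeric(1))
  e1 <- vapply(seq_len(n), function(i)
    energy(opa_align(res1$coords[, , i], ref)$aligned), numeric(1))
  expect_true(all(e1 <= e0 + 1e-10))
  expect_lt(mean(e1), 0.5 * mean(e0))
  # aligned-shape invariants hold in sliding mode too
  for (i in seq_len(n)) {
    expect_equal(colMeans(res1$coords[, , i]), c(0, 0), tolerance = 1e-9)
    expect_equal(sqrt(sum(res1$coords[, , i]^2)), 1, tolerance = 1e-9)
  }
})

test_that("gpa warns when not converged", {
  cfgs <- noisy_configurations(5, seed = 4)
  expect_warning(res <- gpa(cfgs, tol = 0, max_iter = 2L), "did not converge")
  expect_false(res$converged)
})
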