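test_that("pca_fit recovers directions, is complete, and decorrelates", {
  t <- seq(-1, 1, length.out = 40)
  cloud <- cbind(t, t)
  m <- pca_fit(cloud)
  expect_equal(unname(m$eigenvectors[1, ]), c(1, 1) / sqrt(2),
               tolerance = 1e-9)
  expect_equal(m$variance_fractions[1], 1, tolerance = 1e-12)

  set.seed(6)
  X <- matrix(rnorm(60), 10, 6)
  m2 <- pca_fit(X)
  # orthonormal rows
  expect_equal(tcrossprod(m2$eigenvectors), diag(nrow(m2$eigenvectors)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # reconstruction from all components equals the input
  rec <- sweep(m2$scores %*% m2$eigenvectors, 2, m2$mean, `+`)
  expect_equal(rec, X, tolerance = 1e-9, ignore_attr = TRUE)
  # scores covariance is diagonal with the eigenvalues
  cv <- cov(m2$scores)
  expect_equal(diag(cv), m2$eigenvalues[seq_len(ncol(m2$scores))],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-9)
  # deterministic sign convention
  expect_true(all(apply(m2$eigenvectors, 1,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(pca_fit(matrix(1, 5, 3)), "constant")
})

test_that("pc_shape_vectors excursions are symmetric and context-aware", {
  cfgs <- noisy_configurations(10, seed = 17)
  al <- gpa(cfgs)
  dat <- scalemorph:::flatten_coords(al$coords)
  m <- pca_fit(dat)
  sv <- pc_shape_vectors(m, pc = 1, magnitude = 2, context = "procrustes")
  expect_equal(dim(sv$minus), c(85, 2))
  expect_equal((sv$minus + sv$plus) / 2, sv$mean, tolerance = 1e-9)
  # tiny magnitude converges to the mean shape
  sv0 <- pc_shape_vectors(m, 1, magnitude = 1e-9, context = "procrustes")
  expect_equal(sv0$minus, sv0$mean, tolerance = 1e-7)
  expect_error(pc_shape_vectors(m, 1, magnitude = 0), "positive")

  # eft context: a dataset varying only in a1 yields ellipses of
  # different widths
  set.seed(2)
  rows <- t(vapply(seq_len(20), function(i)
    c(2 + 0.3 * rnorm(1), 0, 0, 1), numeric(4)))
  colnames(rows) <- c("a1", "b1", "c1", "d1")
  me <- pca_fit(rows)
  sve <- pc_shape_vectors(me, 1, magnitude = 2, context = "eft",
                          n_points = 200)
  w_minus <- diff(range(sve$minus[, 1]))
  w_plus <- diff(range(sve$plus[, 1]))
  expect_gt(abs(w_plus - w_minus), 0.1)
  expect_equal(diff(range(sve$minus[, 2])), diff(range(sve$plus[, 2])),
               tolerance = 1e-6)
})

test_that("permanova reproduces the hand-enumerated two-group case", {
  x <- matrix(c(0, 1, 2, 3), ncol = 1)
  g <- c("A", "A", "B", "B")
  res <- permanova(x, g)
  expect_equal(res$pseudo_F, 8, tolerance = 1e-12)
  expect_equal(res$R2, 0.8, tolerance = 1e-12)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_permutations, 6)
  expect_equal(res$p_raw, 2 / 6, tolerance = 1e-12)
})

test_that("permanova matches classical ANOVA on univariate data", {
  set.seed(10)
  y <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  res <- permanova(matrix(y, ncol = 1), g, n_permutations = 99, seed = 1)
  f_aov <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$pseudo_F, f_aov, tolerance = 1e-9)
})

test_that("permanova agrees with an independent from-scratch computation", {
  set.seed(11)
  X <- matrix(rnorm(36 * 5), 36, 5)
  g <- rep(c("a", "b", "c"), times = c(10, 14, 12))
  res <- permanova(X, g, n_permutations = 99, seed = 1)
  hand <- permanova_hand(X, g)
  expect_equal(res$pseudo_F, hand$F, tolerance = 1e-9)
  expect_equal(res$R2, hand$R2, tolerance = 1e-9)
})

test_that("permanova agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(12)
  X <- matrix(rnorm(40 * 8), 40, 8)
  g <- factor(rep(c("a", "b", "c", "d"), each = 10))
  res <- permanova(X, g, n_permutations = 99, seed = 1)
  ad <- vegan::adonis2(dist(X) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-9)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-9)
})

test_that("duplicated multisets give a null permanova result", {
  x <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), ncol = 1)
  res <- permanova(x, rep(c("A", "B"), each = 4))
  expect_lt(res$R2, 0.05)
  expect_gt(res$p_raw, 0.5)
})

test_that("Monte-Carlo p matches exhaustive enumeration within 3 SE", {
  set.seed(33)
  X <- matrix(rnorm(10 * 3), 10, 3) + rep(c(0, 0.8), each = 5)
  g <- rep(c("A", "B"), each = 5)
  exact <- permanova(X, g)                    # 252 arrangements
  expect_equal(exact$method, "exhaustive")
  mc <- permanova(X, g, n_permutations = 9999, seed = 5,
                  exhaustive_limit = 1)
  expect_equal(mc$method, "monte_carlo")
  se <- sqrt(exact$p_raw * (1 - exact$p_raw) / 9999)
  expect_lt(abs(mc$p_raw - exact$p_raw), 3 * se + 1e-4)
})

test_that("permanova is invariant to feature rotation and to PCA scores", {
  set.seed(14)
  X <- matrix(rnorm(30 * 6), 30, 6)
  g <- rep(c("a", "b", "c"), each = 10)
  res <- permanova(X, g, n_permutations = 99, seed = 1)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  res_rot <- permanova(X %*% Q, g, n_permutations = 99, seed = 1)
  expect_equal(res_rot$pseudo_F, res$pseudo_F, tolerance = 1e-9)
  expect_equal(res_rot$R2, res$R2, tolerance = 1e-9)
  scores <- pca_fit(X)$scores
  res_pca <- permanova(scores, g, n_permutations = 99, seed = 1)
  expect_equal(res_pca$pseudo_F, res$pseudo_F, tolerance = 1e-9)
  expect_equal(res_pca$R2, res$R2, tolerance = 1e-9)
})

test_that("permanova input validation and seed logging", {
  X <- matrix(rnorm(12), 6, 2)
  expect_error(permanova(X, c("a", "a", "a", "a", "a", "b")),
               "at least 2 members")
  expect_error(permanova(X, rep("a", 6)), "at least 2 groups")
  g <- rep(c("a", "b"), each = 3)
  expect_error(permanova(matrix(rnorm(40), 20, 2),
                         rep(c("a", "b"), each = 10),
                         exhaustive_limit = 10), "seed is required")
  r1 <- permanova(X, g, n_permutations = 199, seed = 7, exhaustive_limit = 1)
  r2 <- permanova(X, g, n_permutations = 199, seed = 7, exhaustive_limit = 1)
  expect_identical(r1$p_raw, r2$p_raw)
  expect_equal(r1$seed, 7L)
  expect_gte(r1$p_raw, 1 / (r1$n_permutations + 1))
})

test_that("pairwise_permanova adjusts over the number of pairs", {
  set.seed(40)
  # four well-separated groups: every raw p is the permutation minimum
  # 1/1000, and Bonferroni over the 6 pairs prints 0.006
  X <- matrix(rnorm(32 * 4, sd = 0.2), 32, 4) +
    rep(c(0, 4, 8, 12), each = 8)
  g <- rep(c("a", "b", "c", "d"), each = 8)
  tab <- pairwise_permanova(X, g, n_permutations = 999, seed = 2)
  expect_equal(nrow(tab), 6)
  # a permuted labeling that reproduces the observed partition can add
  # 1/1000 to a raw p; every pair still sits at (or within a tie of) the
  # permutation minimum
  expect_true(all(tab$p_raw <= 2 / 1000 + 1e-12))
  expect_true(any(abs(tab$p_raw - 0.001) < 1e-12))
  expect_equal(tab$p_adjusted, pmin(1, 6 * tab$p_raw), tolerance = 1e-12)
  # the minimal raw p at 999 permutations prints as 0.006 after Bonferroni
  expect_equal(min(tab$p_adjusted), 0.006, tolerance = 1e-12)
  expect_true(all(tab$signif[abs(tab$p_raw - 0.001) < 1e-12] == "**"))

  tab_none <- pairwise_permanova(X, g, n_permutations = 99, seed = 2,
                                 adjust = "none")
  expect_equal(tab_none$p_adjusted, tab_none$p_raw)
})

test_that("size_group_tests is a symmetric Welch battery", {
  set.seed(3)
  sizes <- c(rnorm(10, 10, 0.01), rnorm(8, 20, 0.01))
  g <- rep(c("A", "B"), c(10, 8))
  tab <- size_group_tests(sizes, g)
  expect_lt(tab$p_value, 1e-6)
  expect_equal(tab$diff, tab$mean1 - tab$mean2)
  # label swap gives the same p-value
  tab2 <- size_group_tests(sizes, factor(g, levels = c("B", "A")))
  expect_equal(tab2$p_value, tab$p_value, tolerance = 1e-12)
  expect_error(size_group_tests(rep(c(1, 2), each = 4), g = rep(c("A", "B"), each = 4)),
               "zero within-group variance")
})

test_that("shape_size_regression matches an OLS oracle and edge cases", {
  # identical shapes: nothing to explain
  A <- array(rep(matrix(rnorm(20), 10, 2), 5), dim = c(10, 2, 5))
  al <- structure(list(coords = A, centroid_sizes = c(1, 2, 3, 4, 5)),
                  class = "aligned_shapes")
  r0 <- shape_size_regression(al, n_permutations = 99, seed = 1)
  expect_equal(r0$R2, 0, tolerance = 1e-9)

  # exact allometry: deformation proportional to log size, no noise
  set.seed(18)
  base <- rnorm(8)
  dirn <- rnorm(8)
  sizes <- exp(seq(0.1, 1, length.out = 12))
  Y <- outer(log(sizes), dirn) + rep(base, each = 12)
  r1 <- shape_size_regression(Y, sizes, n_permutations = 99, seed = 1)
  expect_equal(r1$R2, 1, tolerance = 1e-9)
  expect_lt(r1$p_perm, 0.05)

  # general case against per-column OLS sums of squares
  Yn <- Y + matrix(rnorm(96, 0, 0.5), 12, 8)
  r2 <- shape_size_regression(Yn, sizes, n_permutations = 99, seed = 1)
  x <- log(sizes)
  ssm <- sum(vapply(seq_len(8), function(j) {
    f <- lm(Yn[, j] ~ x)
    sum((fitted(f) - mean(Yn[, j]))^2)
  }, numeric(1)))
  sst <- sum(scale(Yn, scale = FALSE)^2)
  expect_equal(r2$R2, ssm / sst, tolerance = 1e-9)

  expect_error(shape_size_regression(Yn, rep(2, 12), n_permutations = 9,
                                     seed = 1), "constant sizes")
})
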