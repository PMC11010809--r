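# Ordination and inference: PCA with shape-vector back-projection, one-way
# PERMANOVA with exact or Monte-Carlo permutation p-values, pairwise
# comparisons with multiplicity adjustment, Welch tests on centroid size,
# and shape-on-size allometry regression.

#' Principal component analysis of a shape-descriptor matrix
#'
#' Eigendecomposition of the feature covariance (divisor n - 1), with
#' components ordered by eigenvalue and a deterministic sign convention:
#' the largest-magnitude loading of every component is positive.
#'
#' @param data shapes x features matrix (aligned coordinates or Fourier
#'   coefficients).
#' @return object of class `pca_model`: list with `mean`, `eigenvectors`
#'   (orthonormal rows), `eigenvalues`, `scores`, `variance_fractions`.
#' @export
pca_fit <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("pca_fit needs at least 2 rows")
  if (all(apply(data, 2L, stats::var) < .Machine$double.eps))
    stop("constant data: all eigenvalues are zero")
  pc <- stats::prcomp(data, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  scores <- pc$x
  for (jcol in seq_len(ncol(rot))) {
    imax <- which.max(abs(rot[, jcol]))
    if (rot[imax, jcol] < 0) {
      rot[, jcol] <- -rot[, jcol]
      scores[, jcol] <- -scores[, jcol]
    }
  }
  ev <- pc$sdev^2
  structure(list(
    mean = pc$center,
    eigenvectors = t(rot),
    eigenvalues = ev,
    scores = scores,
    variance_fractions = ev / sum(ev)
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d shapes x %d features; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(x$mean),
              100 * x$variance_fractions[1L],
              100 * ifelse(length(x$variance_fractions) > 1L,
                           x$variance_fractions[2L], 0)))
  invisible(x)
}

#' Back-project a principal component into shape space
#'
#' Renders the deformation a PC axis encodes as the pair of shapes at
#' mean -/+ magnitude * sqrt(eigenvalue) * eigenvector. In the
#' `"procrustes"` context the excursions are k x 2 coordinate
#' configurations; in the `"eft"` context the coefficient excursions are
#' reconstructed as outlines via [eft_inverse()].
#'
#' @param model a `pca_model`.
#' @param pc component index.
#' @param magnitude excursion in standard-deviation units (> 0).
#' @param context `"procrustes"` (coordinate data) or `"eft"`
#'   (Fourier-coefficient data).
#' @param reference optional base shape/coefficient row to deform instead
#'   of the model mean (e.g. the consensus).
#' @param n_points reconstruction points for the `"eft"` context.
#' @return list with `minus`, `plus` (the two excursion shapes), `mean`
#'   (the base shape), and `context`.
#' @export
pc_shape_vectors <- function(model, pc = 1L, magnitude = 2,
                             context = c("procrustes", "eft"),
                             reference = NULL, n_points = 200L) {
  context <- match.arg(context)
  stopifnot(inherits(model, "pca_model"))
  if (magnitude <= 0) stop("magnitude must be positive")
  if (pc < 1L || pc > nrow(model$eigenvectors)) stop("pc out of range")
  base <- if (is.null(reference)) model$mean else as.numeric(reference)
  exc <- magnitude * sqrt(model$eigenvalues[pc]) * model$eigenvectors[pc, ]
  lo <- base - exc
  hi <- base + exc
  render <- function(v) {
    if (context == "procrustes") {
      unflatten_coords(v)
    } else {
      nh <- length(v) / 4L
      H <- matrix(v, nh, 4L, byrow = TRUE)
      colnames(H) <- c("a", "b", "c", "d")
      co <- structure(list(dc = c(0, 0), harmonics = H, perimeter = 1,
                           n_harmonics = nh, spacing = "uniform"),
                      class = "eft_coefs")
      eft_inverse(co, n_points)
    }
  }
  list(minus = render(lo), plus = render(hi), mean = render(base),
       context = context)
}

# ---- PERMANOVA -------------------------------------------------------------

# Squared-distance matrix from data / dist / square distance matrix input.
as_squared_dist <- function(data) {
  if (inherits(data, "dist")) {
    D <- as.matrix(data)
  } else {
    data <- as.matrix(data)
    sym <- nrow(data) == ncol(data) &&
      all(abs(diag(data)) < 1e-12) &&
      isTRUE(all.equal(data, t(data), tolerance = 1e-8))
    D <- if (sym) data else as.matrix(stats::dist(data))
  }
  if (!all(is.finite(D))) stop("non-finite distances")
  D^2
}

# All distinct label arrangements for the given group counts (N x M matrix
# of group codes); only called when M is known to be small.
enumerate_labelings <- function(counts) {
  N <- sum(counts)
  res <- list()
  rec <- function(pos, gi, acc) {
    if (gi == length(counts)) {
      acc[pos] <- gi
      res[[length(res) + 1L]] <<- acc
      return(invisible(NULL))
    }
    for (sel in utils::combn(pos, counts[gi], simplify = FALSE)) {
      acc2 <- acc
      acc2[sel] <- gi
      rec(setdiff(pos, sel), gi + 1L, acc2)
    }
  }
  rec(seq_len(N), 1L, integer(N))
  do.call(cbind, res)
}

# Pseudo-F and R2 for every labeling column of P (N x B group codes).
permanova_f_batch <- function(D2, P, counts) {
  N <- nrow(D2); a <- length(counts)
  ss_total <- sum(D2) / (2 * N)
  ssw <- numeric(ncol(P))
  for (g in seq_len(a)) {
    Mg <- (P == g) * 1
    ssw <- ssw + colSums((D2 %*% Mg) * Mg) / (2 * counts[g])
  }
  ssb <- ss_total - ssw
  list(F = (ssb / (a - 1)) / (ssw / (N - a)),
       R2 = ssb / ss_total, ss_total = ss_total,
       ss_within = ssw, ss_between = ssb)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on Euclidean distances
#' (Anderson's one-way formulation). With group sizes n_g and total N:
#' SS_total = (1/N) sum_{i<j} d_ij^2, SS_within = sum_g (1/n_g)
#' sum_{i<j in g} d_ij^2, SS_between = SS_total - SS_within, pseudo-F =
#' (SS_between/(a-1)) / (SS_within/(N-a)), R2 = SS_between / SS_total.
#' Labels are permuted whole; when the number of distinct label
#' arrangements is at most `exhaustive_limit` the permutation distribution
#' is enumerated exactly, otherwise `n_permutations` Monte-Carlo draws are
#' used and the observed statistic is included in numerator and
#' denominator: p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations).
#'
#' @param data shapes x features matrix, a `dist` object, or a square
#'   symmetric distance matrix.
#' @param groups group labels, at least 2 groups with at least 2 members.
#' @param n_permutations Monte-Carlo permutation count.
#' @param seed RNG seed; required (and logged) whenever Monte-Carlo
#'   permutations are used, so identical seed gives identical p.
#' @param exhaustive_limit enumerate exactly when the number of distinct
#'   arrangements does not exceed this.
#' @return object of class `permanova`: list with `pseudo_F`, `R2`,
#'   `ss` (total/between/within), `df`, `p_raw`, `n_permutations`,
#'   `method` ("exhaustive" or "monte_carlo"), `seed`, `group_sizes`.
#' @export
permanova <- function(data, groups, n_permutations = 999L, seed = NULL,
                      exhaustive_limit = 10000L) {
  groups <- factor(groups)
  D2 <- as_squared_dist(data)
  N <- nrow(D2)
  if (length(groups) != N) stop("groups length does not match data rows")
  counts <- as.integer(table(groups))
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L))
    stop("every group needs at least 2 members (group sizes: ",
         paste(counts, collapse = ", "), ")")
  a <- length(counts)
  codes <- as.integer(groups)
  obs <- permanova_f_batch(D2, matrix(codes, ncol = 1L), counts)

  n_arrange <- exp(lgamma(N + 1) - sum(lgamma(counts + 1)))
  if (is.finite(n_arrange) && n_arrange <= exhaustive_limit) {
    P <- enumerate_labelings(counts)
    # enumeration assigns group sizes by code; match observed counts order
    Fall <- permanova_f_batch(D2, P, counts)$F
    p_raw <- mean(Fall >= obs$F - 1e-12)
    method <- "exhaustive"
    n_used <- ncol(P)
  } else {
    if (is.null(seed))
      stop("seed is required for Monte-Carlo permutations")
    old_seed <- get0(".Random.seed", globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    B <- as.integer(n_permutations)
    P <- vapply(seq_len(B), function(b) sample(codes), integer(N))
    Fperm <- permanova_f_batch(D2, P, counts)$F
    p_raw <- (1 + sum(Fperm >= obs$F - 1e-12)) / (1 + B)
    method <- "monte_carlo"
    n_used <- B
  }
  structure(list(
    pseudo_F = obs$F[1L], R2 = obs$R2[1L],
    ss = c(total = obs$ss_total, between = obs$ss_between[1L],
           within = obs$ss_within[1L]),
    df = c(between = a - 1L, within = N - a),
    p_raw = p_raw, n_permutations = n_used, method = method,
    seed = if (method == "monte_carlo") as.integer(seed) else NA_integer_,
    group_sizes = stats::setNames(counts, levels(groups))
  ), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g, R2 = %.3f, p = %.4g (%s, %d permutations)\n",
    x$pseudo_F, x$R2, x$p_raw, x$method, x$n_permutations))
  invisible(x)
}

#' Significance stars at the 0.05 / 0.01 / 0.005 tiers
#' @param p numeric vector of p-values.
#' @return character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
signif_stars <- function(p) {
  as.character(cut(p, c(-Inf, 0.005, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "")))
}

#' Pairwise PERMANOVA with multiplicity adjustment
#'
#' Runs [permanova()] on every pair of groups and adjusts the raw
#' permutation p-values over the number of pairs tested (Bonferroni by
#' default: p_adj = min(1, m * p_raw)).
#'
#' @inheritParams permanova
#' @param adjust `"bonferroni"`, `"holm"` or `"none"`.
#' @return data.frame with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `pseudo_F`, `R2`, `p_raw`, `p_adjusted`, `signif`; the full
#'   `permanova` objects are attached as attribute `"results"`.
#' @export
pairwise_permanova <- function(data, groups, n_permutations = 999L,
                               seed = NULL,
                               adjust = c("bonferroni", "holm", "none"),
                               exhaustive_limit = 10000L) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  data <- if (inherits(data, "dist")) as.matrix(data) else as.matrix(data)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  dist_input <- nrow(data) == ncol(data) &&
    all(abs(diag(data)) < 1e-12) &&
    isTRUE(all.equal(data, t(data), tolerance = 1e-8))
  results <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    idx <- which(groups %in% pr)
    sub <- if (dist_input) data[idx, idx, drop = FALSE]
           else data[idx, , drop = FALSE]
    seed_i <- if (is.null(seed)) NULL
              else as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
    results[[i]] <- permanova(sub, droplevels(groups[idx]),
                              n_permutations = n_permutations,
                              seed = seed_i,
                              exhaustive_limit = exhaustive_limit)
  }
  p_raw <- vapply(results, `[[`, numeric(1), "p_raw")
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  out <- data.frame(
    group1 = vapply(pairs, `[`, character(1), 1L),
    group2 = vapply(pairs, `[`, character(1), 2L),
    n1 = vapply(results, function(r) r$group_sizes[[1L]], integer(1)),
    n2 = vapply(results, function(r) r$group_sizes[[2L]], integer(1)),
    pseudo_F = vapply(results, `[[`, numeric(1), "pseudo_F"),
    R2 = vapply(results, `[[`, numeric(1), "R2"),
    p_raw = p_raw,
    p_adjusted = p_adj,
    signif = signif_stars(p_adj),
    stringsAsFactors = FALSE
  )
  attr(out, "results") <- results
  attr(out, "adjust") <- adjust
  out
}

#' Pairwise Welch tests on centroid sizes
#'
#' Two-sided unequal-variance t tests between every pair of groups,
#' reported unadjusted, with the effect direction (difference of means).
#'
#' @param sizes positive centroid sizes, one per specimen.
#' @param groups group labels (>= 2 members per group).
#' @return data.frame with `group1`, `group2`, `mean1`, `mean2`, `diff`,
#'   `t`, `p_value` per pair.
#' @export
size_group_tests <- function(sizes, groups) {
  groups <- factor(groups)
  if (length(sizes) != length(groups)) stop("sizes/groups length mismatch")
  counts <- table(groups)
  if (any(counts < 2L)) stop("every group needs at least 2 sizes")
  pairs <- utils::combn(levels(groups), 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- sizes[groups == pr[1L]]
    y <- sizes[groups == pr[2L]]
    if (stats::var(x) == 0 && stats::var(y) == 0)
      stop("zero within-group variance in both groups ",
           pr[1L], " and ", pr[2L])
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(group1 = pr[1L], group2 = pr[2L],
               mean1 = mean(x), mean2 = mean(y),
               diff = mean(x) - mean(y),
               t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Shape-on-size allometry regression
#'
#' Multivariate linear regression of superimposed coordinates on log
#' centroid size. R2 is the fraction of the total coordinate sum of
#' squares explained by the size model, and its significance is assessed
#' by permuting sizes across specimens.
#'
#' @param aligned an `aligned_shapes` object (or a shapes x features
#'   coordinate matrix).
#' @param sizes positive centroid sizes, one per shape (defaults to the
#'   sizes recorded in `aligned`).
#' @param n_permutations permutation count.
#' @param seed RNG seed (required, logged).
#' @return object of class `shape_size_regression`: list with `R2`,
#'   `p_perm`, `coefficients` (per-coordinate slopes vs log size),
#'   `n_permutations`, `seed`.
#' @export
shape_size_regression <- function(aligned, sizes = NULL,
                                  n_permutations = 999L, seed = NULL) {
  Y <- if (inherits(aligned, "aligned_shapes")) flatten_coords(aligned$coords)
       else as.matrix(aligned)
  if (is.null(sizes) && inherits(aligned, "aligned_shapes"))
    sizes <- aligned$centroid_sizes
  if (length(sizes) != nrow(Y)) stop("one size per shape is required")
  if (any(sizes <= 0)) stop("sizes must be positive")
  x <- log(sizes)
  if (stats::var(x) == 0) stop("constant sizes: allometry is undefined")
  xc <- x - mean(x)
  Yc <- sweep(Y, 2L, colMeans(Y))
  sxx <- sum(xc^2)
  b <- as.numeric(crossprod(Yc, xc)) / sxx
  ss_total <- sum(Yc^2)
  if (ss_total < .Machine$double.eps) {
    # identical shapes: no shape variation to explain
    return(structure(list(R2 = 0, p_perm = 1, coefficients = b,
                          n_permutations = 0L, seed = NA_integer_),
                     class = "shape_size_regression"))
  }
  ss_model <- sum(b^2) * sxx
  R2 <- ss_model / ss_total
  if (is.null(seed)) stop("seed is required for the permutation test")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  B <- as.integer(n_permutations)
  Xp <- vapply(seq_len(B), function(b2) sample(xc), numeric(length(xc)))
  num <- colSums(crossprod(Yc, Xp)^2) / sxx
  R2p <- num / ss_total
  structure(list(
    R2 = R2, p_perm = (1 + sum(R2p >= R2 - 1e-15)) / (1 + B),
    coefficients = b, n_permutations = B, seed = as.integer(seed)
  ), class = "shape_size_regression")
}

#' @export
print.shape_size_regression <- function(x, ...) {
  cat(sprintf("shape-on-size regression: R2 = %.4f, permutation p = %.4g\n",
              x$R2, x$p_perm))
  invisible(x)
}
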