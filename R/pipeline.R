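# End-to-end pipelines chaining the modules into the study's experiments:
# landmark-based (snap -> 85-point configuration -> GPA -> PCA ->
# pairwise PERMANOVA -> centroid-size tests -> allometry) and
# outline-based (trace -> equidistant resampling -> normalization ->
# elliptic Fourier at the 99% power criterion -> PCA -> pairwise
# PERMANOVA), plus seed-reproducible dataset simulation to and from disk.

#' Write a synthetic dataset to a directory
#'
#' Emits exactly the formats the readers consume: PNG masks (when
#' present) under `masks/`, a `landmarks.tps` file, `metadata.csv`, and a
#' `manifest.json` carrying the generator truth block. When masks are
#' present the TPS coordinates are written in each mask image's pixel
#' frame with a `SCALE=` line carrying the mm-per-pixel factor — the
#' layout a digitizer working on the images would produce, and the frame
#' in which traced outlines and landmarks line up; otherwise coordinates
#' are written in mm directly.
#'
#' @param ds a `scale_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "scale_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  lms <- ds$landmarks
  if (!is.null(ds$masks)) {
    mdir <- file.path(dir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    ppm <- stats::setNames(ds$metadata$pixels_per_mm, ds$metadata$scale_id)
    for (id in names(ds$masks))
      write_mask(ds$masks[[id]], file.path(mdir, paste0(id, ".png")))
    lms <- lapply(stats::setNames(names(lms), names(lms)), function(id) {
      org <- ds$masks[[id]]$origin_px
      if (is.null(org)) return(lms[[id]])
      sweep(lms[[id]] * ppm[[id]], 2L, org - 1)
    })
    recs <- Map(function(p, id) list(shape_id = id, points = p,
                                     scale = 1 / ppm[[id]]),
                lms, names(lms))
    write_tps(recs, file.path(dir, "landmarks.tps"))
  } else {
    write_tps(lms, file.path(dir, "landmarks.tps"))
  }
  utils::write.csv(ds$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(ds$truth, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory
#'
#' Loads `metadata.csv`, `landmarks.tps` and any masks under `masks/`,
#' matching records by scale id. Mask-derived coordinates are converted
#' to mm using each record's `pixels_per_mm` when outlines are traced by
#' the pipelines.
#'
#' @param dir dataset directory as written by [write_dataset()].
#' @return a `scale_dataset` (without generator truth unless a manifest
#'   is present).
#' @export
read_dataset <- function(dir) {
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  tps_path <- file.path(dir, "landmarks.tps")
  landmarks <- NULL
  if (file.exists(tps_path)) {
    recs <- read_tps(tps_path)
    landmarks <- stats::setNames(lapply(recs, `[[`, "points"),
                                 vapply(recs, `[[`, character(1), "shape_id"))
  }
  mdir <- file.path(dir, "masks")
  masks <- NULL
  if (dir.exists(mdir)) {
    files <- list.files(mdir, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
    masks <- stats::setNames(lapply(files, read_mask),
                             tools::file_path_sans_ext(basename(files)))
  }
  manifest <- file.path(dir, "manifest.json")
  truth <- if (file.exists(manifest)) jsonlite::read_json(manifest) else NULL
  structure(list(polygons = NULL, landmarks = landmarks, masks = masks,
                 metadata = meta, truth = truth),
            class = "scale_dataset")
}

# Resolve a dataset argument (object or directory) and return it with
# polygons in mm for every metadata row, tracing masks where needed.
resolve_dataset <- function(ds) {
  if (is.character(ds)) ds <- read_dataset(ds)
  stopifnot(inherits(ds, "scale_dataset"))
  ids <- ds$metadata$scale_id
  if (is.null(ds$polygons)) {
    if (is.null(ds$masks)) stop("dataset has neither polygons nor masks")
    missing_ids <- setdiff(ids, names(ds$masks))
    if (length(missing_ids))
      stop("no mask for scale id(s): ", paste(missing_ids, collapse = ", "))
    ppm <- stats::setNames(ds$metadata$pixels_per_mm, ids)
    ds$polygons <- stats::setNames(lapply(ids, function(id)
      trace_boundary(ds$masks[[id]]) / ppm[[id]]), ids)
  } else {
    missing_ids <- setdiff(ids, names(ds$polygons))
    if (length(missing_ids))
      stop("no outline for scale id(s): ", paste(missing_ids, collapse = ", "))
  }
  ds
}

pipeline_stamp <- function(seed) {
  list(package = "scalemorph",
       version = as.character(utils::packageVersion("scalemorph")),
       seed = as.integer(seed), timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the landmark-based pipeline
#'
#' For every scale: snap the digitized landmarks onto its outline, build
#' the landmark + semilandmark configuration, then superimpose all
#' configurations by GPA and run the inference battery: PCA, overall and
#' pairwise PERMANOVA on the aligned coordinates, pairwise Welch tests on
#' centroid size, and shape-on-size allometry regression.
#'
#' @param ds a `scale_dataset` or a dataset directory.
#' @param grouping metadata column holding the group labels
#'   (`"species"`, `"group"`, or `"body_area"`).
#' @param counts semilandmark plan (see [build_configuration()]).
#' @param slide semilandmark treatment in [gpa()].
#' @param n_permutations,seed permutation settings (seed required).
#' @param adjust p-value adjustment for the pairwise table.
#' @param out_dir optional directory to write result tables to.
#' @return object of class `lm_pipeline`: list with `aligned`, `pca`,
#'   `overall` (PERMANOVA across all groups), `pairwise` (adjusted
#'   table), `size_tests`, `allometry`, `groups`, `config`.
#' @export
run_lm_pipeline <- function(ds, grouping = "species",
                            counts = c(40L, 10L, 10L, 10L, 10L),
                            slide = "none",
                            n_permutations = 999L, seed = 1L,
                            adjust = "bonferroni", out_dir = NULL) {
  ds <- resolve_dataset(ds)
  ids <- ds$metadata$scale_id
  if (is.null(ds$landmarks))
    stop("landmark-based pipeline needs digitized landmarks")
  missing_ids <- setdiff(ids, names(ds$landmarks))
  if (length(missing_ids))
    stop("no landmarks for scale id(s): ", paste(missing_ids, collapse = ", "))
  if (!grouping %in% names(ds$metadata))
    stop("grouping column '", grouping, "' not in metadata")
  groups <- factor(ds$metadata[[grouping]])

  shapes <- lapply(ids, function(id) {
    sn <- snap_landmarks(ds$polygons[[id]], ds$landmarks[[id]])
    build_configuration(sn$poly, sn$arc, counts = counts)
  })
  names(shapes) <- ids
  aligned <- gpa(shapes, slide = slide)
  data <- flatten_coords(aligned$coords)
  rownames(data) <- ids
  pca <- pca_fit(data)
  overall <- permanova(data, groups, n_permutations = n_permutations,
                       seed = seed)
  pairwise <- pairwise_permanova(data, groups,
                                 n_permutations = n_permutations,
                                 seed = seed, adjust = adjust)
  size_tests <- size_group_tests(aligned$centroid_sizes, groups)
  allometry <- shape_size_regression(aligned,
                                     n_permutations = n_permutations,
                                     seed = seed)
  res <- structure(list(
    aligned = aligned, pca = pca, overall = overall, pairwise = pairwise,
    size_tests = size_tests, allometry = allometry, groups = groups,
    ids = ids,
    config = list(method = "lm", grouping = grouping, counts = counts,
                  slide = slide, n_points = nrow(shapes[[1L]]$points),
                  n_permutations = n_permutations, seed = seed,
                  adjust = adjust, stamp = pipeline_stamp(seed))
  ), class = "lm_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Run the outline-based pipeline
#'
#' For every scale: orient the traced outline counter-clockwise, start it
#' at the anterior-most vertex, resample `n_points` equidistant boundary
#' points, normalize (center, unit centroid size), compute the elliptic
#' Fourier transform, calibrate one shared harmonic count at the
#' `harmonic_threshold` power criterion over the dataset, and run PCA and
#' overall plus pairwise PERMANOVA on the coefficient matrix.
#'
#' @inheritParams run_lm_pipeline
#' @param n_points equidistant boundary points per outline.
#' @param harmonic_threshold cumulative power criterion (default 0.99).
#' @param max_harmonics cap on the per-analysis harmonic count.
#' @param orient outline orientation mode for [normalize_outline()].
#' @return object of class `ol_pipeline`: list with `coef_matrix`,
#'   `n_harmonics`, `per_outline_harmonics`, `pca`, `overall`,
#'   `pairwise`, `groups`, `config`.
#' @export
run_ol_pipeline <- function(ds, grouping = "species",
                            n_points = 360L, harmonic_threshold = 0.99,
                            max_harmonics = 32L,
                            orient = "none",
                            n_permutations = 999L, seed = 1L,
                            adjust = "bonferroni", out_dir = NULL) {
  ds <- resolve_dataset(ds)
  ids <- ds$metadata$scale_id
  if (!grouping %in% names(ds$metadata))
    stop("grouping column '", grouping, "' not in metadata")
  groups <- factor(ds$metadata[[grouping]])
  nh_max <- min(as.integer(max_harmonics), floor(n_points / 2))

  coefs <- lapply(ids, function(id) {
    poly <- ensure_ccw(ds$polygons[[id]])
    poly <- resample_equidistant(poly, n_points,
                                 start_vertex = anterior_start(poly))
    poly <- normalize_outline(poly, orient = orient)
    eft_forward(poly, nh_max)
  })
  names(coefs) <- ids
  per_outline <- vapply(coefs, choose_n_harmonics,
                        integer(1), threshold = harmonic_threshold)
  nh <- min(max(per_outline), nh_max)
  mat <- coefficient_matrix(coefs, nh)
  pca <- pca_fit(mat)
  overall <- permanova(mat, groups, n_permutations = n_permutations,
                       seed = seed)
  pairwise <- pairwise_permanova(mat, groups,
                                 n_permutations = n_permutations,
                                 seed = seed, adjust = adjust)
  res <- structure(list(
    coef_matrix = mat, n_harmonics = nh, per_outline_harmonics = per_outline,
    pca = pca, overall = overall, pairwise = pairwise, groups = groups,
    ids = ids,
    config = list(method = "ol", grouping = grouping, n_points = n_points,
                  harmonic_threshold = harmonic_threshold,
                  max_harmonics = max_harmonics, orient = orient,
                  n_permutations = n_permutations, seed = seed,
                  adjust = adjust, stamp = pipeline_stamp(seed))
  ), class = "ol_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.lm_pipeline <- function(x, ...) {
  cat(sprintf("lm_pipeline: %d scales, %d points, %d group(s); allometry R2 = %.3f\n",
              length(x$ids), x$config$n_points, nlevels(x$groups),
              x$allometry$R2))
  print(x$pairwise[, c("group1", "group2", "R2", "p_adjusted", "signif")])
  invisible(x)
}

#' @export
print.ol_pipeline <- function(x, ...) {
  cat(sprintf("ol_pipeline: %d scales, %d harmonic(s), %d group(s)\n",
              length(x$ids), x$n_harmonics, nlevels(x$groups)))
  print(x$pairwise[, c("group1", "group2", "R2", "p_adjusted", "signif")])
  invisible(x)
}

#' Write pipeline result tables
#'
#' Emits the pairwise PERMANOVA table, PCA scores, and (for the
#' landmark pipeline) consensus coordinates, size tests and the allometry
#' report, plus a JSON provenance record with the run configuration and
#' seed.
#'
#' @param res an `lm_pipeline` or `ol_pipeline` result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- res$config$method
  utils::write.csv(res$pairwise,
                   file.path(dir, paste0(prefix, "_pairwise_permanova.csv")),
                   row.names = FALSE)
  scores <- as.data.frame(res$pca$scores)
  scores <- cbind(scale_id = res$ids, group = as.character(res$groups), scores)
  utils::write.csv(scores, file.path(dir, paste0(prefix, "_pca_scores.csv")),
                   row.names = FALSE)
  report <- list(
    config = res$config[setdiff(names(res$config), "stamp")],
    stamp = res$config$stamp,
    overall = res$overall[c("pseudo_F", "R2", "p_raw", "n_permutations",
                            "method")]
  )
  if (inherits(res, "lm_pipeline")) {
    utils::write.csv(
      data.frame(x = res$aligned$consensus[, 1L],
                 y = res$aligned$consensus[, 2L],
                 role = res$aligned$roles),
      file.path(dir, "lm_consensus.csv"), row.names = FALSE)
    utils::write.csv(res$size_tests, file.path(dir, "lm_size_tests.csv"),
                     row.names = FALSE)
    report$allometry <- res$allometry[c("R2", "p_perm", "n_permutations")]
    report$gpa <- list(iterations = res$aligned$iterations,
                       converged = res$aligned$converged,
                       slide = res$aligned$slide)
  } else {
    report$n_harmonics <- res$n_harmonics
    report$per_outline_harmonics <- unname(res$per_outline_harmonics)
  }
  jsonlite::write_json(report, file.path(dir, paste0(prefix, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
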