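# Synthetic scale-silhouette generator.
#
# Templates are star-shaped (radial) outlines built on a rounded-
# quadrilateral base, with the anterior margin (the left side, x < 0)
# modulated by a style-specific oscillation: smooth (none), striated
# (low-amplitude high-count ripple), waved (sinusoidal) or dentate
# (triangular teeth). The five true landmarks sit at the four margin
# junctions (the corners of the base quadrilateral) and at the middle of
# the posterior margin, by construction. Specimens are drawn from a
# template by a smooth random radial deformation field (low-order Fourier
# perturbation), plus small rotation/scale jitter that downstream
# normalization removes. Because every outline stays a radial function of
# the polar angle, generated polygons are always simple.

# Landmark polar angles: LM1 dorsal anterior tip, LM2 ventral anterior
# tip, LM3 ventral posterior tip, LM4 middle of the posterior margin,
# LM5 dorsal posterior tip. Anterior is -x, dorsal +y.
.lm_angles <- c(3 * pi / 4, 5 * pi / 4, 7 * pi / 4, 0, pi / 4)

# Triangle wave with period 1, range [-1, 1], tri(0) = -1.
triangle_wave <- function(z) 4 * abs(z - floor(z + 0.5)) - 1

# Radial modulation of the anterior margin; u in [0,1] across the margin,
# windowed by sin(pi u)^2 so the landmarks at the margin ends stay put.
margin_oscillation <- function(u, style, amplitude, count) {
  if (style == "smooth" || amplitude == 0) return(rep(0, length(u)))
  w <- sin(pi * u)^2
  osc <- switch(style,
    waved = ,
    striated = cos(2 * pi * count * u),
    dentate = triangle_wave(count * u))
  amplitude * w * osc
}

#' Build a synthetic scale template
#'
#' @param margin_style `"smooth"`, `"striated"`, `"waved"` or `"dentate"`
#'   anterior-margin style.
#' @param aspect_ratio anterior-posterior stretch of the base outline
#'   (x radii multiplied by this factor).
#' @param oscillation_amplitude margin oscillation amplitude as a fraction
#'   of the local radius; defaults by style (0, 0.02, 0.08, 0.10).
#' @param oscillation_count number of oscillations along the anterior
#'   margin; defaults by style (0, 20, 6, 8).
#' @param size_mm overall size multiplier (base radius, mm).
#' @param roundness superellipse exponent of the base quadrilateral:
#'   2 is an ellipse, larger values are boxier with sharper corners.
#' @param n_vertices number of boundary vertices (multiple of 8 so the
#'   five landmark angles fall on vertices exactly).
#' @param name template label.
#' @return object of class `scale_template`: list with `name`, `vertices`
#'   (counter-clockwise polygon, anterior at -x, dorsal at +y), `angles`
#'   (polar angle of every vertex), `true_landmarks` (arc positions of the
#'   5 landmarks, label order), `landmark_vertices` (their vertex rows),
#'   and the generating parameters.
#' @export
make_template <- function(margin_style = c("smooth", "striated", "waved", "dentate"),
                          aspect_ratio = 1,
                          oscillation_amplitude = NULL,
                          oscillation_count = NULL,
                          size_mm = 1,
                          roundness = 3.5,
                          n_vertices = 720L,
                          name = margin_style) {
  margin_style <- match.arg(margin_style)
  if (aspect_ratio <= 0) stop("aspect_ratio must be positive")
  if (size_mm <= 0) stop("size_mm must be positive")
  if (roundness < 2) stop("roundness must be at least 2")
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 40L || n_vertices %% 8L != 0L)
    stop("n_vertices must be a multiple of 8, at least 40")
  if (is.null(oscillation_amplitude))
    oscillation_amplitude <- switch(margin_style, smooth = 0, striated = 0.02,
                                    waved = 0.08, dentate = 0.10)
  if (is.null(oscillation_count))
    oscillation_count <- switch(margin_style, smooth = 0L, striated = 20L,
                                waved = 6L, dentate = 8L)
  if (margin_style == "smooth" && oscillation_amplitude != 0)
    stop("smooth templates must have zero oscillation amplitude")
  if (oscillation_amplitude < 0) stop("oscillation_amplitude must be >= 0")
  if (oscillation_amplitude >= 0.5)
    stop("oscillation too large: the outline would self-intersect")

  phi <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  # rounded quadrilateral: superellipse radius, corners at odd pi/4 multiples
  p <- roundness
  r <- (abs(cos(phi))^p + abs(sin(phi))^p)^(-1 / p)
  anterior <- phi > .lm_angles[1L] & phi < .lm_angles[2L]
  u <- (phi[anterior] - .lm_angles[1L]) / (pi / 2)
  r[anterior] <- r[anterior] *
    (1 + margin_oscillation(u, margin_style, oscillation_amplitude,
                            oscillation_count))
  v <- size_mm * cbind(aspect_ratio * r * cos(phi), r * sin(phi))
  lm_vertex <- (round(.lm_angles / (2 * pi) * n_vertices) %% n_vertices) + 1L
  arcs <- poly_arc_coords(v)
  structure(list(
    name = name, vertices = v, angles = phi,
    true_landmarks = arcs[lm_vertex], landmark_vertices = lm_vertex,
    margin_style = margin_style, aspect_ratio = aspect_ratio,
    oscillation_amplitude = oscillation_amplitude,
    oscillation_count = oscillation_count, size_mm = size_mm,
    roundness = roundness
  ), class = "scale_template")
}

#' @export
print.scale_template <- function(x, ...) {
  cat(sprintf("scale_template '%s': %s margin, aspect %.2f, size %.2f mm\n",
              x$name, x$margin_style, x$aspect_ratio, x$size_mm))
  invisible(x)
}

# Apply a deterministic group-effect radial field of magnitude delta to a
# template (a fixed low-order harmonic pattern with a group-specific
# phase), returning a modified template.
apply_group_effect <- function(template, delta, group_index, n_groups) {
  if (delta == 0) return(template)
  phase <- 2 * pi * (group_index - 1L) / max(n_groups, 1L)
  f <- 1 + delta * cos(2 * template$angles + phase)
  if (min(f) <= 0.05) stop("group effect too large: outline degenerates")
  template$vertices <- template$vertices * f
  template$true_landmarks <- poly_arc_coords(template$vertices)[template$landmark_vertices]
  template
}

#' Sample one synthetic specimen from a template
#'
#' Deforms the template by a smooth random radial field
#' `1 + sum_j (alpha_j cos(j phi) + beta_j sin(j phi))` with coefficients
#' drawn from Normal(0, noise_sd^2) for orders j = 1..4, then applies a
#' small random rotation and log-scale jitter (removed downstream by
#' normalization). Deterministic for a given seed. If the deformation
#' degenerates (radial factor near zero) it is redrawn, at most 10 times.
#'
#' @param template a `scale_template`.
#' @param noise_sd standard deviation of the radial Fourier coefficients.
#' @param seed RNG seed for this specimen.
#' @param rotation_sd SD of the rotation jitter (radians).
#' @param scale_sd SD of the log-scale jitter.
#' @return list with `polygon` (counter-clockwise vertices, mm),
#'   `landmarks` (5 x 2 true landmark coordinates, label order), `seed`.
#' @export
sample_specimen <- function(template, noise_sd = 0.03, seed,
                            rotation_sd = 0.03, scale_sd = 0.05) {
  stopifnot(inherits(template, "scale_template"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  phi <- template$angles
  f <- NULL
  for (try in 1:10) {
    if (noise_sd == 0) { f <- rep(1, length(phi)); break }
    ab <- stats::rnorm(8L, 0, noise_sd)
    f <- 1 + ab[1L] * cos(phi) + ab[2L] * sin(phi) +
      ab[3L] * cos(2 * phi) + ab[4L] * sin(2 * phi) +
      ab[5L] * cos(3 * phi) + ab[6L] * sin(3 * phi) +
      ab[7L] * cos(4 * phi) + ab[8L] * sin(4 * phi)
    if (min(f) > 0.05) break
    f <- NULL
  }
  if (is.null(f)) stop("radial deformation degenerated after 10 redraws")
  v <- template$vertices * f
  theta <- if (rotation_sd > 0) stats::rnorm(1L, 0, rotation_sd) else 0
  scl <- if (scale_sd > 0) exp(stats::rnorm(1L, 0, scale_sd)) else 1
  v <- scl * rotate_points(v, theta)
  lms <- v[template$landmark_vertices, , drop = FALSE]
  list(polygon = v, landmarks = lms, seed = as.integer(seed))
}

#' The five species templates of the study design
#'
#' One template per species, mirroring the anterior-margin taxonomy and
#' approximate sizes of the study animals: Sardina pilchardus (smooth),
#' Dicentrarchus labrax (striated), Sparus aurata (waved), Mullus
#' surmuletus (dentate), and Danio rerio (smooth, distinguished from the
#' pilchard by aspect ratio and size).
#'
#' @return named list of `scale_template` objects.
#' @export
species_templates <- function() {
  list(
    Msur = make_template("dentate", aspect_ratio = 1.05, size_mm = 3.5,
                         roundness = 4.5, name = "Msur"),
    Dlab = make_template("striated", aspect_ratio = 1.12, size_mm = 2.5,
                         roundness = 3.0, name = "Dlab"),
    Spil = make_template("smooth", aspect_ratio = 1.50, size_mm = 2.0,
                         roundness = 2.8, name = "Spil"),
    Saur = make_template("waved", aspect_ratio = 0.80, size_mm = 2.5,
                         roundness = 2.4, name = "Saur"),
    Drer = make_template("smooth", aspect_ratio = 1.25, size_mm = 0.7,
                         roundness = 4.0, name = "Drer")
  )
}

# D-area scales per species in the study design (Table 2-like sizes).
default_group_sizes <- function() {
  c(Msur = 35L, Dlab = 29L, Spil = 11L, Saur = 81L, Drer = 28L)
}

#' Generate a synthetic scale dataset
#'
#' Draws `n_per_group` specimens from each group's template (optionally
#' separated further by a deterministic group-effect field of magnitude
#' `effect_delta`), together with true landmarks (optionally jittered to
#' mimic operator error), a metadata table, and, when `pixels_per_mm` is
#' given, rasterized silhouette masks. The `truth` block records
#' everything needed to regenerate the dataset from the seed.
#'
#' @param templates named list of `scale_template`s, one per group.
#' @param n_per_group integer vector (recycled/matched by name), >= 2 each.
#' @param effect_delta magnitude of the deterministic between-group radial
#'   effect field (>= 0).
#' @param noise_sd specimen radial noise SD (see [sample_specimen()]).
#' @param seed master RNG seed.
#' @param pixels_per_mm when non-NA, rasterize each specimen to a mask at
#'   this calibration.
#' @param landmark_jitter_sd operator-error jitter SD added to the true
#'   landmarks (mm).
#' @return object of class `scale_dataset`: list with `polygons`
#'   (named list, mm), `landmarks` (named list of 5 x 2 matrices), `masks`
#'   (named list of [binary_mask()] or NULL), `metadata` (data.frame) and
#'   `truth` (generator parameters and per-specimen seeds).
#' @export
generate_dataset <- function(templates,
                             n_per_group = default_group_sizes(),
                             effect_delta = 0, noise_sd = 0.03, seed = 1L,
                             pixels_per_mm = NA_real_,
                             landmark_jitter_sd = 0) {
  if (is.null(names(templates))) stop("templates must be a named list")
  groups <- names(templates)
  if (!is.null(names(n_per_group))) {
    miss <- setdiff(groups, names(n_per_group))
    if (length(miss)) stop("n_per_group missing groups: ",
                           paste(miss, collapse = ", "))
    n_per_group <- n_per_group[groups]
  } else if (length(n_per_group) == 1L) {
    n_per_group <- stats::setNames(rep(n_per_group, length(groups)), groups)
  } else {
    names(n_per_group) <- groups
  }
  if (any(n_per_group < 2L)) stop("need at least 2 specimens per group")
  if (effect_delta < 0) stop("effect_delta must be >= 0")

  old_seed <- get0(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  total <- sum(n_per_group)
  spec_seeds <- sample.int(2147483646L, total)
  jitters <- if (landmark_jitter_sd > 0)
    matrix(stats::rnorm(total * 10L, 0, landmark_jitter_sd), total, 10L)
  else NULL

  polygons <- list(); landmarks <- list(); masks <- list()
  meta <- list()
  idx <- 0L
  for (g in seq_along(groups)) {
    tmpl <- apply_group_effect(templates[[g]], effect_delta, g, length(groups))
    for (i in seq_len(n_per_group[[g]])) {
      idx <- idx + 1L
      id <- sprintf("%s_%03d", groups[g], i)
      sp <- sample_specimen(tmpl, noise_sd = noise_sd, seed = spec_seeds[idx])
      lms <- sp$landmarks
      if (!is.null(jitters))
        lms <- lms + matrix(jitters[idx, ], 5L, 2L)
      polygons[[id]] <- sp$polygon
      landmarks[[id]] <- lms
      if (!is.na(pixels_per_mm))
        masks[[id]] <- rasterize_polygon(sp$polygon, pixels_per_mm)
      meta[[idx]] <- data.frame(
        scale_id = id, specimen_id = id, species = groups[g],
        body_area = "D", group = groups[g],
        pixels_per_mm = if (is.na(pixels_per_mm)) 1 else pixels_per_mm,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    polygons = polygons, landmarks = landmarks,
    masks = if (length(masks)) masks else NULL,
    metadata = do.call(rbind, meta),
    truth = list(
      groups = groups, n_per_group = as.list(n_per_group),
      effect_delta = effect_delta, noise_sd = noise_sd,
      seed = as.integer(seed), specimen_seeds = spec_seeds,
      pixels_per_mm = pixels_per_mm,
      landmark_jitter_sd = landmark_jitter_sd,
      template_params = lapply(templates, function(tm)
        tm[c("name", "margin_style", "aspect_ratio", "oscillation_amplitude",
             "oscillation_count", "size_mm", "roundness")])
    )
  ), class = "scale_dataset")
}

#' @export
print.scale_dataset <- function(x, ...) {
  cat(sprintf("scale_dataset: %d specimens in %d group(s)%s\n",
              nrow(x$metadata), length(unique(x$metadata$group)),
              if (is.null(x$masks)) "" else ", with masks"))
  invisible(x)
}

#' Simulate the five-species study dataset
#'
#' Convenience wrapper around [generate_dataset()] with the five species
#' templates and Table-2-like D-area group sizes.
#'
#' @inheritParams generate_dataset
#' @param n_per_group specimens per species.
#' @export
simulate_scale_dataset <- function(n_per_group = default_group_sizes(),
                                   noise_sd = 0.03, effect_delta = 0,
                                   seed = 1L, pixels_per_mm = NA_real_,
                                   landmark_jitter_sd = 0) {
  generate_dataset(species_templates(), n_per_group = n_per_group,
                   effect_delta = effect_delta, noise_sd = noise_sd,
                   seed = seed, pixels_per_mm = pixels_per_mm,
                   landmark_jitter_sd = landmark_jitter_sd)
}
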