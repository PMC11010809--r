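---
title: "Methods: landmark- and outline-based geometric morphometrics of fish scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark- and outline-based geometric morphometrics of fish scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalemorph)
```

## The problem

A teleost elasmoid scale is a thin dermal plate whose silhouette carries
species-, population- and body-area-level shape information. Two families
of geometric-morphometric methods quantify that silhouette:

* **Landmark-based (LM)**: a fixed set of homologous points plus
  semilandmarks along homologous curves, superimposed by generalized
  Procrustes analysis (GPA) so that position, scale and rotation are
  removed and only shape remains.
* **Outline-based (OL)**: the whole closed boundary, normalized and
  decomposed into elliptic Fourier descriptors (EFDs).

`scalemorph` implements both pipelines end to end, a shared inference
layer (PCA, PERMANOVA, centroid-size tests, allometry regression), and a
synthetic silhouette generator so that every stage is testable without
digitized specimens.

## The landmark scheme

Five fixed landmarks sit on margin junctions that are recognizable on all
scale types: (1) dorsal anterior tip, (2) ventral anterior tip,
(3) ventral posterior tip, (4) middle of the posterior margin, (5) dorsal
posterior tip. The scale focus is deliberately excluded: it is absent in
regenerated scales, which are common in farmed fish, so a focus-free
scheme stays applicable to them. The often-oscillating anterior margin
carries no fixed landmark either; its shape is captured instead by
semilandmarks.

Semilandmarks are placed equidistantly *in arc length* along each
inter-landmark margin, 40 along the anterior margin 1→2 (the most
variable trait) and 10 along each of 2→3, 3→4, 4→5, 5→1: 85 points in
total. Arc length is the only curve parameterization that is
self-consistent under resampling, which is why `build_configuration()`
uses it. The plan is configurable (`counts =`) to emulate alternative
configurations from the literature, but only the default is exercised by
the test suite.

Digitized landmarks rarely fall exactly on a traced boundary, so
`snap_landmarks()` projects each to its nearest boundary point and then
validates the digitization: landmarks closer than 1% of the perimeter are
rejected as implausible, and the five arc positions must be in cyclic
order 1..5 (a consistently reversed order indicates an outline traversed
the other way and triggers re-orientation; anything else is an error).

## Superimposition

`gpa()` is a *partial* Procrustes scheme: every configuration is centered
and scaled to unit centroid size once, then only rotated during the
iterations. Consequently every aligned shape keeps centroid size exactly
1 and the consensus is the plain pointwise mean — convenient invariants
for downstream code and tests. Convergence is declared when the RMS
consensus coordinate change between rounds falls below `tol` (default
1e-8); the total squared residual to the consensus is recorded per round
(`ss_history`) and decreases monotonically. GPA leaves a global rotation
undetermined; we fix the gauge by rotating the converged set so the
consensus chord from landmark 1 to landmark 4 (anterior tip to
mid-posterior) is horizontal, making results independent of input order.

Semilandmark treatment is an open methodological choice: equidistant
placement is itself a defensible definition, while many packages slide
semilandmarks to minimize thin-plate-spline bending energy against the
consensus. Both modes are first-class here. `slide = "none"` is the
default because equidistant placement is the stated construction of the
configuration; `slide = "bending_energy"` solves the tangent-space
sliding system per shape, re-projects slid points onto the
configuration's own polyline, renormalizes, and accepts a (possibly
damped) step only when bending energy actually decreases. Sliding runs
during the first `slide_iters` (default 5) rounds only, after which the
superimposition is allowed to converge — otherwise semilandmarks can
creep indefinitely along nearly flat margins. Fixed landmarks never move.

## Outline pipeline

Silhouette masks are thresholded at the midpoint of their value range
with polarity auto-detection (the border-majority color is background),
reduced to the largest 4-connected component, and normalized to the
foreground bounding box plus a background ring; the crop offset is
retained so traced coordinates stay in the original image frame that
landmarks were digitized in. `trace_boundary()` extracts the sub-pixel
0.5 iso-level contour (smoother than pixel-edge chain codes at the
moderate magnifications typical of scale imaging; the contour of a 3×3
pixel block has area 8.5, frozen as a regression constant).

Each outline is restarted at a deterministic anterior point, resampled to
`n_points` (default 360) equidistant boundary points, centered, and
scaled to unit centroid size. Orientation is *preserved* by default
(`orient = "none"`) because scale images are acquired in a standard pose
(anterior leftwards, dorsal upwards); `orient = "first_ellipse"` is
available for unoriented material.

**Starting-point rule.** An obvious rule — start at the vertex of minimum
x — proved unstable: on flat or oscillating anterior margins the leftmost
vertex wanders along the margin under digitization noise, which shifts
the Fourier phase of every descriptor and inflates within-group variance
enough to mask real between-group differences. The rule used instead is
robust and still deterministic: start at the vertex whose direction from
the outline centroid is closest to the anterior direction (polar angle
π). Phase normalization by first-harmonic coefficients would be the other
standard option; the geometric rule was chosen to keep the coefficient
definition simple and the acquisition orientation meaningful.

## Elliptic Fourier descriptors

The boundary is treated as a piecewise-linear closed curve
\((x(t), y(t))\) with period equal to the perimeter, and each coordinate
expanded in a Fourier series; harmonic \(n\) contributes the quadruple
\((a_n, b_n, c_n, d_n)\), and the DC terms are the parametric mean point.

Two parameter assignments are offered. The default, `spacing =
"uniform"`, treats the input vertices as equally spaced in the curve
parameter — exactly what `resample_equidistant()` produces, in which case
the parameter *is* arc length. Under this convention an ellipse sampled
at its natural parameter is exactly one harmonic, the property on which
the closed-form tests rest. `spacing = "chord"` uses chord-length
parameter increments (the classical chain-code formulation) for polygons
with irregular vertex spacing. For equidistantly resampled outlines — the
only way the pipelines call the transform — the two are identical.

Harmonic power is \((a_n^2+b_n^2+c_n^2+d_n^2)/2\);
`choose_n_harmonics()` keeps the smallest count whose cumulative fraction
reaches 99%, taking the maximum over the dataset so one shared count
serves the whole analysis (capped at 32; the cap has never bound in
practice — smooth scale outlines at unit size reach 99% within a
handful of harmonics). Size and position are removed geometrically
*before* the transform, so all four coefficients of harmonic 1 are
retained in the feature matrix; no first-harmonic coefficient
normalization is applied.

An important interaction: because the 99% criterion typically retains
only ~3 harmonics on scale-like outlines, fine anterior-margin texture
(striation, small teeth) is essentially invisible to the OL method —
species discrimination by outlines rides on low-order form (aspect,
roundness, margin proportions). The landmark method, whose 40 anterior
semilandmarks sample the margin densely, retains that texture. This
asymmetry shapes the synthetic study design below.

## Inference layer

* **PCA** (`pca_fit()`): covariance eigendecomposition (divisor n−1),
  components ordered by eigenvalue, with a deterministic sign convention
  (the largest-magnitude loading of each component is positive).
  `pc_shape_vectors()` back-projects an axis into shape space — as a
  coordinate displacement pair for Procrustes data or as reconstructed
  outlines for EFD data.
* **PERMANOVA** (`permanova()`): Anderson's one-way formulation on
  Euclidean distances. With group sizes \(n_g\) and total \(N\):
  \(SS_{total} = \frac1N\sum_{i<j} d_{ij}^2\),
  \(SS_{within} = \sum_g \frac1{n_g}\sum_{i<j\in g} d_{ij}^2\),
  pseudo-\(F = \frac{SS_{between}/(a-1)}{SS_{within}/(N-a)}\),
  \(R^2 = SS_{between}/SS_{total}\). Labels are permuted whole; when the
  number of distinct arrangements is ≤ 10 000 the null distribution is
  enumerated exactly, otherwise Monte-Carlo permutations include the
  observed statistic in numerator and denominator (so p is never 0), and
  a seed is a required, logged input. Tests are run on the full
  coordinate/coefficient matrix: Euclidean distances are invariant under
  the orthonormal change of basis to PCA scores, so "testing on the PCA"
  and testing on the raw matrix coincide when all components are kept; a
  top-k restriction is possible by passing `pca_fit()$scores` subsets.
* **Pairwise comparisons** (`pairwise_permanova()`): per-pair PERMANOVA
  with Bonferroni adjustment over the number of pairs by default (Holm
  and none available). At 999 permutations the smallest achievable raw p
  is 1/1000, so 6 pairs print a minimal adjusted p of 0.006 and 10 pairs
  0.01 — the granularity familiar from published tables. Significance
  stars follow the 0.05 / 0.01 / 0.005 convention.
* **Centroid size** (`size_group_tests()`): pairwise two-sided Welch
  (unequal-variance) t tests, reported unadjusted with effect direction.
  The Welch form is an interpretation — the classical alternative
  (pooled-variance t) is nearly identical at these group sizes.
* **Allometry** (`shape_size_regression()`): multivariate regression of
  aligned coordinates on log centroid size; \(R^2\) is the explained
  fraction of the total coordinate sum of squares, with significance by
  permuting sizes. Identical shapes yield \(R^2 = 0\) by definition.

## The synthetic generator

`make_template()` builds star-shaped (radial) outlines on a rounded
quadrilateral base — a superellipse with corners at the four margin
junctions — with the anterior margin modulated by a style-specific
oscillation: smooth (none), striated (amplitude 0.02, 20 ripples), waved
(0.08, 6 oscillations) or dentate (0.10, 8 teeth), amplitudes as
fractions of the local radius. The five true landmarks fall on vertices
by construction. Because templates and all deformations are radial
functions of the polar angle, generated outlines are always simple.

`sample_specimen()` models biological variation as a smooth random radial
field \(1 + \sum_{j=1}^{4}(\alpha_j\cos j\varphi + \beta_j\sin
j\varphi)\) with coefficients \(\sim N(0, \sigma^2)\), plus small
rotation (SD 0.03 rad) and log-scale (SD 0.05) jitter that normalization
removes downstream. The default \(\sigma = 0.03\) was calibrated once so
that the five-species design reproduces the qualitative structure
reported for real scales: every species pair separable by both methods,
pairwise \(R^2\) spanning roughly 0.12–0.70, weakest for the two
smooth-margined species and strongest for the round waved species against
the elongate ones.

The five species templates differ in aspect ratio (0.80–1.50), base
roundness (superellipse exponent 2.4–4.5), margin style, and physical
size (0.7–3.5 mm base radius, mirroring the different magnifications the
species require). Group sizes default to the study design's D-area
counts (35, 29, 11, 81, 28). A deterministic low-order radial field of
magnitude `effect_delta` with group-specific phase adds controlled
between-group separation for power and monotonicity studies.

What the generator does **not** emulate: surface texture (circuli, radii,
cteni interiors — both pipelines see only the silhouette), the focus
(excluded by design), digitizer-specific landmark bias (only isotropic
jitter via `landmark_jitter_sd`), damaged or partially occluded scales,
and non-radial shape families. Passing tests therefore demonstrate
correctness of the machinery and calibration of the inference on
scale-*like* silhouettes, not performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Masks: threshold at the value-range midpoint; border-majority polarity;
  largest 4-connected component kept with a warning (error when discards
  exceed half the foreground); bounding-box crop plus `pad` ring makes
  reading idempotent.
* Tracing: 0.5 iso-level; contours touching themselves (one-pixel necks)
  are rejected with advice to clean the mask; a single isolated pixel
  still yields a valid diamond contour.
* `eft_inverse()` flags an all-zero-harmonic reconstruction (points
  collapse to the DC term) with a warning — it is not a valid polygon.
* TPS: only `LM=`/`ID=`/`IMAGE=`/`SCALE=` keys; `SCALE=` multiplies
  coordinates; `CURVES`/`POINTS` blocks are rejected because
  semilandmarks are constructed, not digitized. The digitizer's y-axis
  convention is not guessable from a file, so the reader exposes
  `flip_y` instead of guessing.
* Units: coordinates are divided by `pixels_per_mm` at pipeline level, so
  centroid sizes are in mm and comparable across magnifications.
* Permutation p-values use a 1e-12 comparison slack so exact ties count
  as "as extreme".
* The Procrustes reflection flag defaults to off: scales are imaged in a
  standard orientation and mirrored fits would be spurious.

## Problem sizes used by the test suite

The suite favors sizes that make the statistical assertions sharp but
keep a full run in the order of a minute or two: calibration of the
PERMANOVA and Welch type-I error uses 1000 null simulations (n = 20 with
200 features and 199 permutations; n = 30 sizes), the five-species power
study uses 20 replicate datasets at the full Table-style group sizes with
999 permutations, the effect-size monotonicity grid uses 3–4 deltas with
6–8 replicates, and the rasterization round-trip runs at 371 pixels/mm.
The law-of-large-numbers check on the generator uses 300 specimens.

## Known limitations

* 2-D only; no missing-landmark estimation (damaged scales must be
  excluded upstream).
* No dispersion test (PERMDISP): a significant PERMANOVA can reflect
  location or spread differences; interpretation of R² as separation
  assumes comparable dispersions.
* The OL pipeline's 99% harmonic criterion discards fine margin texture
  by design; raise the threshold or the cap if texture matters.
* The generator's radial construction cannot produce re-entrant
  (non-star-shaped) outlines; real scales are occasionally concave enough
  to violate this.
* Landmark digitizations are inputs: no automatic landmark detection is
  attempted on real images.
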