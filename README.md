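# scalemorph

Geometric morphometrics of teleost fish scales: can a species, a body
area, or a rearing group be recognized from the silhouette of a single
elasmoid scale? That question matters wherever whole fish are not
available — seafood fraud inspection, forensic and archaeological
material, stomach-content analysis — and shape-based identification is a
cheap, non-destructive alternative to molecular methods.

`scalemorph` implements, as one integrated R toolkit, the two
geometric-morphometric pipelines used for this task, plus the statistics
to compare them:

* **Landmark-based (LM)** — 5 fixed landmarks on the scale's margin
  junctions plus 80 semilandmarks equidistant in arc length along the
  margins (40 on the variable anterior margin, 10 on each other margin;
  85 points total), generalized Procrustes superimposition (partial
  Procrustes: centered, unit centroid size
  \(CS = \sqrt{\sum_i \lVert x_i - \bar x\rVert^2}\), optimal rotations,
  optional bending-energy semilandmark sliding).
* **Outline-based (OL)** — sub-pixel silhouette tracing at the 0.5
  iso-level, equidistant resampling, centering and scaling, and elliptic
  Fourier descriptors \((a_n, b_n, c_n, d_n)\) of \((x(t), y(t))\), with
  the harmonic count chosen so cumulative harmonic power
  \(\sum_n (a_n^2+b_n^2+c_n^2+d_n^2)/2\) reaches 99%.

Both feed a common inference layer: PCA with shape-vector
back-projection, one-way PERMANOVA (pseudo-F, \(R^2 =
SS_{between}/SS_{total}\), exact or Monte-Carlo permutation p), pairwise
comparisons with Bonferroni adjustment, Welch tests on centroid size,
and shape-on-size allometry regression. A synthetic scale generator
(margin styles smooth / striated / waved / dentate, controllable noise
and group effects) makes the whole system testable without images.

The intended users are fish biologists and morphometricians who have
silhouette masks (PNG/TIFF), TPS landmark files, and a specimen metadata
table — or who want to prototype study designs synthetically first.

## Worked example

Simulate the five-species study design (group sizes 35/29/11/81/28,
margin styles per species) and run both pipelines:

```r
library(scalemorph)

ds <- simulate_scale_dataset(seed = 1)    # 184 synthetic scales, 5 species
lm_res <- run_lm_pipeline(ds, grouping = "species", seed = 2)
ol_res <- run_ol_pipeline(ds, grouping = "species", seed = 3)
print(lm_res)
print(ol_res)
```

```
lm_pipeline: 184 scales, 85 points, 5 group(s); allometry R2 = 0.027
   group1 group2        R2 p_adjusted signif
1    Dlab   Drer 0.1330811       0.01     **
...
10   Saur   Spil 0.7013065       0.01     **
ol_pipeline: 184 scales, 3 harmonic(s), 5 group(s)
   group1 group2        R2 p_adjusted signif
1    Dlab   Drer 0.1906568       0.01     **
...
10   Saur   Spil 0.6763911       0.01     **
```

Every species pair is significantly separated by both methods
(Bonferroni-adjusted p = 0.01 at 999 permutations, the smallest value 10
pairs can print). `R2` is the between-group fraction of shape variance
for that pair: the two smooth-margined species (`Drer`/`Spil` for LM,
`Dlab`/`Drer` for OL) are hardest to tell apart, while the round waved
species against elongate ones (`Saur`/`Spil`, `Drer`/`Saur`) exceeds
0.6. The shape-on-size regression (`lm_res$allometry`: R2 = 0.027,
p = 0.014) shows allometry explains almost none of the shape variance,
and `ol_res$n_harmonics` reports that 3 harmonics already carry 99% of
the outline power at unit centroid size.

On real data, point the pipelines at a directory instead:
`run_lm_pipeline("path/to/data", ...)` with `masks/` (one silhouette
per scale), `landmarks.tps`, and `metadata.csv` (columns `scale_id`,
`species`, optional `body_area`, `group`, `pixels_per_mm`). A thin
command-line wrapper is installed at `inst/cli/scalemorph.R`:

```sh
Rscript inst/cli/scalemorph.R simulate --out ds --seed 2 --pixels-per-mm 371
Rscript inst/cli/scalemorph.R both --data ds --out results --seed 2
```

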