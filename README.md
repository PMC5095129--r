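# samorph

Morphometrics and QTL mapping for shoot apical meristem (SAM) shape.

The SAM — the stem-cell dome at a plant shoot tip — has a median-section
outline that is very nearly parabolic. samorph is built for quantitative
geneticists and plant morphologists who want to exploit that fact in either
of two ways, or compare them:

* **Paraboloid estimators.** Modelling the SAM as the surface of revolution
  of `z(x) = h (1 - x²/r²)` turns two easy measurements — height `h` and
  basal radius `r` (μm) — into eight shape/size phenotypes: height, radius,
  H/R, volume `πr²h/2`, lateral surface area, section arc length, parabolic
  coefficient `h/r²`, and cross-sectional area `4hr/3`. `fit_parabola()`
  additionally fits a parabola to any digitized apex contour with an R²
  goodness-of-fit score.
* **DCT outline morphometrics.** Digitized open contours are oriented,
  resampled to equally spaced pseudo-landmarks (default 800), aligned by
  generalized Procrustes analysis (reflections forbidden — left/right
  asymmetry is signal), transformed by an orthonormal DCT-II (12 harmonics
  per axis), and decomposed by PCA into shape components that capture
  elongation, lean and peakedness.
* **BC2S3 QTL scanning.** For a maize × teosinte advanced backcross (two
  backcrosses, three selfings), either kind of phenotype can be genome
  scanned: a pedigree-exact hidden Markov model yields expected
  donor-allele dosages (Kosambi map function, 55:2:7 genotype priors),
  Haley–Knott regression yields LOD curves, phenotype permutations yield
  genome-wide thresholds, and `10^LOD` posteriors yield Bayes 95% location
  intervals. Replicated raw measures are summarised per line as
  BLUP + coefficient (REML, replicate fixed / line random).

A synthetic-data generator (`sim_config()`, `simulate_cross()`,
`simulate_contour()`, `simulate_taxa_panel()`, `simulate_sam_study()`)
produces every input the pipeline needs — crosses with additive QTL on
height/radius, replicated measures, noisy near-parabolic contours with
controllable asymmetry and peakedness, and a diverse-taxa contour panel —
so the whole analysis graph runs and is validated without micrographs.

## Worked example

```r
library(samorph)

cfg <- sim_config(qtl = tibble::tibble(
  chr = c(1, 3), pos = c(30, 65),
  height_effect = c(6, 0), radius_effect = c(0, 5)))
res <- run_sam_study(cfg, seed = 1, n_perm = 1000, n_landmarks = 300)

glance(res$pca)
#>      pc    sdev explained_fraction cumulative_fraction
#> 1     1 0.0420              0.670                0.670
#> 2     2 0.0208              0.165                0.835
#> 3     3 0.0117              0.0517               0.887
```

PC1 dominates the shape space (67% of variance), as expected when
elongation is the main generator of contour variation. The genome scans use
a shared 0.05 genome-wide permutation threshold per trait (LOD ≈ 2.6–2.9
here); Bayes 95% intervals are reported for every significant trait ×
chromosome:

```r
res$intervals
#>    trait                   chr lower  peak upper  prob
#>  1 height                    1  28.6  31    32.7  0.95
#>  2 radius                    3  63.3  65    67.3  0.95
#>  3 h_over_r                  1  26.5  30    32.7  0.95
#>  4 h_over_r                  3  63.3  65    67.3  0.95
#>  ...
#> 15 PC1                       1  26.5  29    32.7  0.95
#> 16 PC1                       3  63.3  66    67.3  0.95
```

Both simulated QTL (height at 30 cM on chromosome 1, radius at 65 cM on
chromosome 3) are localized within a few cM by several parabolic estimators
*and* by shape PC1 — the parametric and comprehensive descriptions identify
the same loci. The two descriptions are also numerically coupled:

```r
dplyr::filter(res$correlations, pc == "PC1")
#>   estimator             pc        r   p_value     n significant
#> 1 height                PC1  -0.469  4.3e-24    400 TRUE
#> 2 radius                PC1   0.616  2.0e-46    400 TRUE
#> 3 h_over_r              PC1  -0.788  3.5e-100   400 TRUE
#> 4 parabolic_coefficient PC1  -0.767  1.1e-90    400 TRUE
#> ...
```

The strongest PC1 correlate is the height-to-radius ratio (|r| ≈ 0.79):
the leading "cryptic" shape axis is largely the dome's aspect ratio. Plot
methods are provided throughout (`autoplot()` on scans, PCA spaces and
alignments; `reconstruct_at_pc()` renders expected shapes at ±SD multiples
along any PC).

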