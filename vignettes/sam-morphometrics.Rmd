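---
title: "Quantifying shoot apical meristem shape: paraboloid estimators, DCT morphometrics, and BC2S3 QTL scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shoot apical meristem shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samorph)
library(dplyr)
```

The shoot apical meristem (SAM) is the dome of stem cells at a plant shoot
tip. Its median-section outline is remarkably close to a parabola, which
makes two complementary phenotyping strategies possible: a *parametric* one —
model the SAM as a paraboloid of revolution and derive a small set of shape
and size estimators from just two measurements — and a *comprehensive* one —
represent the whole digitized outline by discrete cosine transform (DCT)
harmonics and study the principal components of those descriptors. samorph
implements both, plus the quantitative-genetics layer needed to map either
kind of phenotype in an advanced maize x teosinte backcross (BC2S3), and a
synthetic-data generator that stands in for micrographs and germplasm so the
whole pipeline is testable end to end.

## The paraboloid model

The dome is modelled as $z(x) = h\,(1 - x^2/r^2)$ for $x \in [-r, r]$, apex
up, revolved about the $z$ axis. From height $h$ and basal radius $r$ (both
in $\mu m$), `sam_estimators()` derives the remaining six estimators in
closed form:

* volume $\pi r^2 h / 2$,
* cross-sectional area $4 h r / 3$ (between the parabola and its base
  chord),
* arc length $r\sqrt{1 + a^2 r^2} + \operatorname{asinh}(a r)/a$ with
  $a = 2h/r^2$,
* lateral surface $\frac{\pi}{6 b^2}\left[(1 + 4 b^2 r^2)^{3/2} - 1\right]$
  with $b = h/r^2$,
* plus the ratios $h/r$ and the parabolic coefficient $h/r^2$.

Two conventions are worth stating because the geometry does not force them:
the surface is the *lateral* dome surface only (a meristem has no physical
base cap), and the cross-sectional area is bounded below by the base chord.
Both are pinned by flat-dome limit tests ($h \to 0$ gives $2r$ and
$\pi r^2$), and all four non-trivial closed forms are checked against
adaptive-quadrature oracles to $10^{-6}$ relative error in the test suite.
The lateral surface is evaluated via `expm1(1.5 * log1p(...))`; the naive
difference cancels catastrophically for flat domes.

`fit_parabola()` goes the other way: given any digitized open apex contour
it fits $y = apex_y + c\,(x - apex_x)^2$, $c < 0$, by least squares. The
apex abscissa is initialised at the highest point and refined by
one-dimensional search, which keeps the regression itself linear. The fitted
radius is defined as half the contour's basal width — a *convention*, since
where "the radius" should be measured on a living apex (dome base versus
primordium insertion) is not something the fit can decide. A non-negative
fitted curvature is reported as a fit-failure row rather than an error, so
surveys over heterogeneous images degrade gracefully.

## Contour normalisation and DCT shape space

Digitized outlines are ordered base-apex-base traces, y-up, in micrometres
(pixel-coordinate files are flipped at read time). The pipeline is:

1. `orient_contour()` standardises handedness. Traces are recorded with the
   next leaf primordium (P0) on a known side; left/right asymmetry is a real
   biological signal, so orientation is made explicit and reflections are
   *never* allowed later during alignment.
2. `resample_contour()` places `n_points` pseudo-landmarks at equal
   arc-length spacing (default 800, matching common practice for smooth
   apex outlines; endpoints preserved exactly).
3. `procrustes_align()` runs generalized Procrustes analysis with index
   correspondence of landmarks: center, optionally scale to unit centroid
   size, rotate each shape onto the running mean (proper rotations only),
   iterate to a $10^{-8}$ mean-shape tolerance. Scaling defaults to *on* —
   the PC space is then a pure shape space, while size lives in the
   parabolic estimators. The flag exists because a size-retaining alignment
   is the other defensible regime; nothing downstream assumes either.
4. `dct_transform()` takes the orthonormal DCT-II of the x and y landmark
   sequences separately and keeps harmonics $k = 1..12$ per axis. The $k=0$
   (mean) term is dropped — aligned shapes are centered, so it carries no
   information. Twelve harmonics recapture a smooth parabolic outline with
   under 1% of height in RMSE; orthonormal scaling makes Parseval's identity
   exact, which the tests exploit. Both the harmonic count and the
   keep-$k=0$ alternative are arguments, not constants.
5. `shape_pca()` is a covariance PCA of the concatenated
   $[\mathbf{c}_x, \mathbf{c}_y]$ vectors (24 columns at defaults). Columns
   are *not* standardised: coefficients share units, and rescaling would
   erase the natural ordering of harmonic energy. PC signs are fixed
   deterministically (largest-magnitude loading positive), so score signs
   are stable across runs; correlations against other phenotypes should be
   interpreted in magnitude, as any sign convention is arbitrary.

`reconstruct_at_pc()` renders expected shapes at chosen multiples of a PC's
score standard deviation, the standard way to visualise what each component
means. On synthetic populations PC1 tracks elongation (post-like to
dome-like, strongly correlated with $h/r$), a shear generator surfaces as a
lean PC whose reconstructions flip a signed left-right area asymmetry, and a
profile-exponent generator surfaces as a peaked-versus-rounded PC.

## BC2S3 QTL mapping

The genetics layer is self-contained and specific to the cross design: two
backcrosses to the recurrent parent followed by three selfings. Single-locus
genotype priors follow from the pedigree — after BC2 a locus is heterozygous
with probability 1/4; each selfing halves heterozygosity and splits the
remainder equally — giving AA : AB : BB = 55 : 2 : 7 (out of 64).

Rather than postulating a transition matrix, `genotype_probabilities()`
derives it: the ordered two-locus diplotype distribution is propagated
through the pedigree (meiosis with recombination fraction $r$, backcross,
selfing) exactly, and the conditional genotype transition for a map interval
is read off the resulting joint. Interval recombination fractions come from
the inverse Kosambi map function $r = \tanh(d/50)/2$; intervals are treated
independently and the chain as Markov along the chromosome, the standard
interval-mapping assumptions. The forward-backward algorithm (emission with
a genotyping-error rate, default $\epsilon = 0.002$) then yields expected
donor-allele dosages at markers and at pseudomarkers every 1 cM (both
$\epsilon$ and the grid step are arguments). The synthetic cross simulator
uses the *same* generative assumptions, so simulator and scanner share one
genetic model and the marginal genotype frequencies of simulated crosses
reproduce the 55:2:7 priors — both facts are tested.

`scan_qtl()` performs Haley-Knott regression of the phenotype on expected
dosage with $LOD = (n/2)\log_{10}(RSS_0/RSS_1)$; a perfect fit is capped at
$RSS_1 = 10^{-12} RSS_0$ to avoid infinities. `perm_threshold()` permutes
the phenotype (type-7 empirical quantile of genome-wide maxima; seeded).
`bayes_interval()` normalises $10^{LOD}$ over a chromosome as a location
posterior, accumulates highest-density grid points to the target mass, and
expands to flanking genotyped markers. Two numerical points matter: grid
points are weighted by their trapezoid interval widths, because the grid is
uneven where markers interleave with pseudomarkers and equal weights would
double-count mass near markers; and interval coverage degrades measurably
if the scan grid is much coarser than the default 1 cM, because narrow
high-LOD intervals get truncated at grid resolution.

Replicated raw measures are summarised per line by `blup_summarize()`:
$y_{ij} = \mu + rep_j + u_i + \epsilon_{ij}$ fitted by REML (via nlme), with
replicate fixed and line random — the only assignment under which a per-line
"BLUP + coefficient" value is meaningful. Replicate uses sum-to-zero
contrasts so $\mu$ is the replicate-averaged intercept and the summarised
value $\mu + \hat u_i$ is on the trait scale; in the balanced case it equals
the familiar shrinkage $\bar y + \frac{\sigma_u^2}{\sigma_u^2 +
\sigma_e^2/m}(\bar y_i - \bar y)$, which the tests use as an oracle.

## The synthetic study

`sim_config()` fixes the study conditions: 400 lines, 5 chromosomes x 50
evenly spaced markers over 100 cM, two replicates, baseline SAM height
100 $\mu m$ and radius 80 $\mu m$ with 5 $\mu m$ residual SD, 1 $\mu m$
contour displacement noise, and a small systematic replicate offset
(0, 2 $\mu m$) for the BLUP stage to estimate. These are the scale of a
maize vegetative-meristem experiment and of a dense advanced-backcross map;
they are deliberately *not* adjusted per analysis. QTL are specified as
(chromosome, position, per-allele effect on height/radius) and simulated as
extra loci so they need not coincide with markers. Heritability realised by
the simulator matches the analytic value implied by effect sizes and the
55:2:7 genotype frequencies, within sampling error.

What the generator emulates: near-parabolic open contours with controllable
height, radius, lean (shear) and peakedness; BC2S3 genotype structure with
no crossover interference; additive QTL; replicate structure. What it does
not: primordium bulges and other local outline features, measurement
correlation between height and radius, segregation distortion, interference,
genotype-by-replicate interaction, and non-additive QTL. Passing tests
therefore demonstrate the *machinery* is correct under the stated model, not
that real meristems satisfy the model — the parametric assumptions
themselves are exactly what the parabolic-fit $R^2$ survey is for.

Problem sizes in tests are chosen for minutes-scale runs: population shape
analyses use 100-200 contours at 100-150 landmarks (the DCT keeps 12
harmonics regardless, so landmark density beyond ~10x the highest harmonic
adds nothing to the retained coefficients); QTL recovery experiments use 200
lines and 100 repeats; null calibration uses 200 simulations x 500
permutations on the marker grid. The 800-landmark default and the
10,000-permutation study-scale setting remain the defaults for real use.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(qtl = tibble::tibble(
  chr = c(1, 3), pos = c(30, 65),
  height_effect = c(6, 0), radius_effect = c(0, 5)))
res <- run_sam_study(cfg, seed = 1, n_perm = 1000, out_dir = "sam_run")

glance(res$pca)                      # PC variance decomposition
res$threshold                        # genome-wide LOD thresholds per trait
res$intervals                        # Bayes 95% intervals for significant QTL
res$correlations |>
  dplyr::filter(pc == "PC1")         # estimator ~ PC1 correlations
autoplot(res$scans$height, threshold = res$threshold[["height"]])
autoplot(res$pca, pc = 1)            # expected shapes along PC1
```

`run_sam_study()` writes every table (cross, estimators, PC scores, one scan
TSV per trait, intervals, correlations) plus a JSON manifest recording the
seed, configuration, outputs and package version, so a run is reproducible
from the manifest alone.

## Known limitations

* The Markov assumption along a chromosome is exact for the two-locus
  marginals but approximate for the full BC2S3 process, as in standard
  interval-mapping software.
* `fit_parabola()` assumes a single apex; multi-lobed or strongly occluded
  contours yield low $R^2$ rather than a diagnostic.
* Index correspondence of pseudo-landmarks (no sliding) is appropriate for
  consistently traced base-apex-base outlines; badly truncated traces
  violate it.
* The Fisher-transformation p-value is asymptotic; for $n < 10$ prefer the
  rank-based tests.
* One-way ANOVA is the implemented clade comparison; the optional second
  factor is additive only (no interaction term).
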