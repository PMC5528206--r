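---
title: "Testing niche divergence with presence-only models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing niche divergence with presence-only models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichediverge)
```

## The scientific question

Sister species that diverged in allopatry under similar conditions are
expected to retain similar ecological niches (niche conservatism). The
alternative — niche divergence — suggests that ecological selection
contributed to speciation. Simply showing that two species occupy
different environments is not evidence of divergence: species always
differ somewhat because their *accessible areas* (backgrounds) offer
different conditions. A divergence test must therefore ask whether the
species' realized niches differ **more than background availability alone
predicts**.

`nichediverge` implements the two standard inferential routes to that
question, both operating on presence-only data and gridded environmental
layers:

1. the **background-similarity test**, which compares the overlap of the
   two species' fitted suitability surfaces against a null distribution of
   overlaps obtained by modelling random points drawn from the other
   species' background; and
2. the **multivariate (principal-component) test**, which compares the
   difference of the species' mean positions on each retained niche axis
   (`d_actual`) with the range of background mean differences over
   subsampling replicates (`d_background`).

Because the package is validated end to end on synthetic landscapes with
planted truth, every stage — raster I/O, occurrence cleaning, the
maximum-entropy model, overlap statistics, and both tests — is exercised
against known answers.

## The suitability model

The model is a Gibbs (maximum-entropy) distribution over grid cells,

$$ p_w(i) = \frac{\exp(w \cdot f(x_i))}{\sum_{j \in R} \exp(w \cdot f(x_j))}, $$

where $R$ is a reference set of uniformly sampled background cells plus
the presence cells, and $f$ expands each continuous layer into a linear
and a quadratic feature of its standardized value (binary 0/1 layers
contribute a single indicator and are never standardized or squared).
Weights maximize the L1-penalized presence log-likelihood

$$ \sum_{i \in \text{presences}} \log p_w(i) \; - \; \lambda \lVert w \rVert_1 . $$

Choices worth knowing about:

* **Feature class.** Linear + quadratic only. A Gaussian (bell-shaped)
  niche is exactly representable in this family, the likelihood stays
  smooth and convex, and a brute-force grid-search oracle over the weight
  space is feasible in tests. Hinge/product/threshold features of the
  classic MaxEnt implementation are deliberately out of scope.
* **Regularization.** A single global penalty, default
  $\lambda = 0.1\sqrt{\#\text{features}/\#\text{presences}}$. Per-feature
  penalty schedules are not reproduced.
* **Optimizer.** Monotone accelerated proximal gradient (FISTA with a
  fallback plain step whenever the accelerated candidate would increase
  the objective) with backtracking line search; the penalized likelihood
  trace is non-decreasing by construction, and convergence is declared on
  the subgradient (KKT) condition with an infinity-norm tolerance of
  `1e-6` on the per-presence scale. Non-convergence is an error, not a
  silent result.
* **Standardization constants** come from the training background cells
  only, which makes the fitted surface invariant to affine rescaling of
  any continuous input layer (checked in the tests).
* **Output scales.** The *raw* surface is $p_w$ normalized to sum to 1
  over valid cells. The *logistic* surface is
  $\mathrm{raw} \cdot N / (1 + \mathrm{raw} \cdot N)$ with $N$ the number
  of valid cells, a deterministic cell-count calibration under which a
  cell at the uniform baseline $1/N$ scores 0.5. This differs from
  MaxEnt's prevalence-based logistic convention; it is documented here
  precisely because the two are not interchangeable.

Models are evaluated by replicate 75/25 train/test splits (25 replicates
by default) with the Mann–Whitney AUC — the probability that a random
test presence outscores a random background cell, ties counted half.
Variable importance uses leave-one-out jackknife refits on a fixed split:
the drop in test AUC when a layer is removed, clipped at zero and
normalized to percentages. Competing variable sets (climate only,
climate+trees, climate+shapefiles, trees only) are compared by one-way
ANOVA on per-replicate test AUC with Tukey HSD post-hoc contrasts.

## Overlap statistics

Overlap operates on two surfaces standardized to sum to one over a shared
valid-cell set:

* Schoener's $D = 1 - \tfrac12 \sum_i |p_{X,i} - p_{Y,i}|$,
* Hellinger-based $I = 1 - \tfrac12 \sum_i (\sqrt{p_{X,i}} - \sqrt{p_{Y,i}})^2$,

each in $[0, 1]$, with $I \ge D$ for any pair. Note the $\tfrac12$
factor: informal verbal descriptions of these statistics sometimes omit
it, but without it the stated bounds (0 = disjoint, 1 = identical) do not
hold, so the conventional definition is used. Comparing surfaces with
different masks is an error, never a silent re-mask.

The *actual* overlap between two species is computed by default between
their 25-replicate mean raw surfaces (renormalized); replicate averaging
stabilizes the surface against split noise.

## The background-similarity test

For the direction "A actual vs B background": per replicate, draw as many
random points from B's background as B has occurrences, fit the
suitability model to a 75% calibration subset of them, and record D and I
between that null model's surface and A's actual surface. After 100
replicates (default), compare the observed actual–actual overlap with the
percentile 95% interval of the null values:

* actual **below** the interval → the species overlap *less* than
  background availability predicts → **divergence**;
* actual **above** it → **conservatism**;
* otherwise the null is **not rejected**.

The percentile interval is the operative decision rule; a
normal-approximation interval (mean ± 1.96 sd, the form in which null
distributions are often tabulated) is also reported. Backgrounds can be
delineated as distance buffers around occurrences (200 km and 700 km
defaults, reflecting dispersal scales), as the minimum-training-presence
(MTP) threshold mask of a fitted model, or as an explicit mask. The null
replicate sample size equals the occurrence count of the species whose
background is resampled — the null emulates "a species like B with no
habitat selection", so it inherits B's sample size.

## The multivariate test

Layer values are extracted at both species' occurrences and at 1,000
background points per species (drawn once, seeded). One correlation-matrix
PCA is run on all four pooled row groups so that actual and background
means live in a single coordinate system — the only construction under
which `d_actual` and `d_background` are commensurable. PCs explaining at
least 6% of the variance are analyzed. Per retained PC, `d_actual` is the
absolute difference of the species' mean scores; 25 replicates subsample
75% of each background sample and record the background mean difference.
The verdict is `divergence` if `d_actual` exceeds every replicate
background difference, `conservatism` if it is below every one, otherwise
`inconclusive`.

Two honest caveats, quantified during development and visible in the test
suite's design:

* The rule compares a noisy point estimate against a replicate *range*
  with no multiplicity control, so on niche axes with no planted signal
  it can still fire at a non-trivial rate when occurrence samples are
  small or spatially clustered. The axis-recovery validation therefore
  uses dense occurrence sampling (1,000 records per species) on a
  fine-grained landscape.
* Correlation-matrix PCA cannot isolate a divergent layer that is
  uncorrelated with every other layer: with near-equal eigenvalues the
  principal directions are arbitrary rotations and the planted signal
  smears across all PCs. Real bioclimatic variable sets are strongly
  collinear — variables cluster into temperature-like and
  precipitation-like blocks that anchor distinct PCs — and the test is
  only well-posed in that regime. `gen_correlated_env_layers()` generates
  exactly such block-structured layers, and the axis-recovery validation
  runs on them.

## The synthetic landscape

`scenario_config()` + `gen_scenario()` define the study conditions:

* **Grid.** 50 × 70 cells of 0.25°, spanning 100–82.5°W, 42–54.5°N
  (cells of roughly 20–28 km — a desk-scale stand-in for continental
  ~5 km grids). The cell size is a free parameter throughout; nothing in
  the package assumes a particular resolution.
* **Layers.** Five environmental layers by default, each an equal-variance
  sum of a deterministic large-scale pattern and Gaussian-smoothed white
  noise (kernel sd = the autocorrelation length, 4 cells by default,
  truncated at 3 sd), standardized to mean 0, sd 1. The deterministic
  patterns are drawn from a family of mutually orthogonal spatial modes
  so the layers are uncorrelated over the grid; rotated copies of a
  single gradient would be collinear by construction. The 1:1
  gradient:noise mix gives the two accessible areas distinct
  environmental baselines while leaving each species room to select
  habitat within its area.
* **Species.** Gaussian niche responses; by default optima at 0 on every
  layer with breadth 1 (in layer-sd units). A *divergence* scenario
  shifts the layer-1 optima to −1 (species A) and +1 (species B) — a
  separation of two niche breadths, aligned with the species' accessible
  areas so that the planted signal expresses as the species occupying
  environmentally distinct regions rather than cancelling against
  availability. A *conservatism* scenario keeps the niches identical; a
  *partial* scenario shifts by half as much. The truth record carries the
  true surfaces and the declared divergent axes.
* **Accessible areas.** Two 450 km circles whose centers are offset by
  ~0.8 radii, overlapping ~70% by area — partially sympatric sister
  species.
* **Occurrences.** 274 for species A and 534 for species B by default
  (typical cleaned presence-only dataset sizes for a restricted-range
  species and a widespread congener), drawn cell-wise proportional to
  true suitability within the accessible area, at most one record per
  cell (redrawing duplicates, which is exactly successive weighted
  sampling without replacement), uniformly jittered within the cell, and
  stamped with synthetic breeding-season dates and sub-5 km coordinate
  uncertainties so the cleaning filters have something to do.
* **Biotic layers.** Three "tree" suitability surfaces generated from
  their own Gaussian niches (one associated with each species' side of
  the layer-1 axis, one neutral), plus binary "range-map" layers obtained
  by thresholding the tree surfaces at 0.2 — playing the role of
  rasterized published range polygons, and treated as categorical
  indicators by the model.

What the simulator does **not** emulate: observation bias correlated with
environment, temporal climate change, dispersal limitation within the
accessible area, species interactions beyond static tree layers, and
coordinate error in excess of the stated uncertainty. Passing tests on
these landscapes validate the *machinery and its statistical behaviour*,
not the field realism of any particular dataset.

## Occurrence cleaning

Four filters, each idempotent and each appending a reconciling entry
(in − removed = out) to the set's provenance log:

1. **Breeding window** (month-day interval, inclusive, any year) —
   excludes migrants in passage; undated records are dropped.
2. **Coordinate uncertainty** — strict `< 5 km` by default; records with
   missing uncertainty fail (cleaned sets never contain unverifiable
   records).
3. **Per-cell deduplication** — at most one record per grid cell, first
   in input order wins.
4. **Uniform-density thinning** — a seeded greedy pass that keeps a
   record only if it is at least one cell diagonal (default) from every
   record already kept; the reproducible counterpart of thinning by hand.
   Outlier removal based on evidence (specimens, recordings) is
   inherently a human judgment and is supported only as a user-supplied
   exclusion, never a heuristic.

## Numerical and degenerate-input policy

* ESRI ASCII grids round-trip exactly (17 significant digits, canonical
  header order); masked cells serialize as the literal nodata value.
* Cell indexing is half-open with the floor convention; points on an
  interior boundary belong to the larger-index cell; 1-based (row, col)
  with row 1 the northernmost row.
* Constant layers: reported by the correlation screen (not NaN), inert in
  the model fit, and a *named* degeneracy error in the PCA.
* Great-circle distances use the haversine formula with Earth radius
  6371.0088 km.
* Collinear layer pairs (|r| > 0.7 by default) are flagged but never
  dropped automatically — removing variables is an analyst decision.
* All stochastic stages take explicit integer seeds; rerunning any stage
  with the same inputs and seed reproduces its outputs bit-for-bit.

## Validation problem sizes

The test suite fixes these problem sizes as its study conditions: overlap
oracles on 1,000 random 4×5 surfaces; a 20-cell, one-layer fit checked
against a three-level dense grid search (final resolution 2.5 × 10⁻⁴);
AUC behaviour on a breadth-0.5 specialist versus 100 uniformly random
occurrences; jackknife recovery over 20 seeds for a species driven solely
by layer 1 (breadth 0.5, 150 records); background-similarity error rates
over 20 conservatism and 20 divergence scenarios at default occurrence
counts with 25-replicate actual surfaces and 50-replicate nulls; and
multivariate axis recovery over 20 seeds on a 100 × 140 block-structured
landscape (blocks of 3 + 2 layers at within-block r ≈ 0.8,
autocorrelation length 1 cell, optima ±1.5, 1,000 records per species,
500 background points, 25 subsampling replicates).

## Known limitations

* The logistic calibration is a package convention; absolute logistic
  values are not comparable with MaxEnt outputs (relative cell ranking
  is).
* Percent contribution is defined via jackknife AUC drops; path-dependent
  gain attribution used by other software is not reproducible from its
  description and is not attempted.
* The multivariate test's verdict rule is anticonservative on undisturbed
  axes at small occurrence sample sizes (see above); treat per-axis
  verdicts on sparse data with caution and prefer the
  background-similarity test's explicit null when samples are small.
* No reprojection, polygon rasterization, GeoTIFF/NetCDF support, or map
  rendering: rasters enter and leave as ESRI ASCII grids.
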