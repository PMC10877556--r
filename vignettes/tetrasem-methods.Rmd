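---
title: "Methods: climate, community-wide traits, and tetrapod richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate, community-wide traits, and tetrapod richness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrasem)
```

## The question and the model

Large-scale species richness tracks contemporary climate (annual mean
temperature and precipitation) and climate *instability* — the change in
those variables since the Last Glacial Maximum (~21 ka BP).  But taxa
respond asymmetrically, and one candidate explanation is that climate acts
partly *through* community-wide traits: the typical body size of an
assemblage, the spread of body sizes, and the trophic structure of the
community.  This package implements that analysis as a piecewise
structural equation model (pSEM) over grid-cell assemblages:

* **Exogenous composites.**  Contemporary climate (temperature +
  precipitation) and climate instability (temperature anomaly +
  precipitation anomaly), each collapsed into a single node as a
  regression-weighted sum of its operational variables.
* **Mediators.**  Three community-wide traits per cell and taxon group:
  `body_size` = log10 median body mass (g), `size_variance` = sample
  variance of log10 mass, and `trophic_structure` = mean trophic weight
  (primary consumer 2, omnivore 2.5, secondary consumer 3; a cell near 2
  is a bottom-heavy pyramid, near 3 top-heavy).
* **Response.**  Species richness per cell, modelled by OLS.

The pSEM is estimated as four OLS submodels (one per endogenous node),
with the errors of the three traits free to covary.  Global consistency of
the causal structure is assessed by tests of directed separation: each
non-adjacent node pair yields an independence claim tested by regression,
and the claim p-values combine into Fisher's
$C = -2\sum_i \ln p_i \sim \chi^2_{2k}$.  Standardized effects are
decomposed as direct (the edge coefficient), indirect (sum over mediated
paths of the product of standardized coefficients along each path), and
total = direct + indirect — an exact identity by construction.

Spatial autocorrelation is absorbed with distance-based Moran's
eigenvector maps (dbMEM): from the cell centroids we build a truncated
spatial weighting matrix ($t$ = longest edge of the Euclidean minimum
spanning tree; $w_{ij} = 1 - (d_{ij}/4t)^2$ for $0 < d_{ij} \le t$),
doubly centre it, and keep the positive-eigenvalue eigenvectors.  Each
submodel then receives the eigenvectors chosen by *minimisation of
residual autocorrelation* (MIR): forward selection of the candidate that
most reduces |Moran's I| of the residuals, stopping when a seeded
permutation test no longer rejects spatial independence.

## Data-facing stages

With real inputs the pipeline consumes range polygons, a species trait
table (body mass in grams, diet fractions), and paired current/LGM climate
rasters.  The stages mirror the study design:

* a regular analysis grid (2° cells on an equal-area Mollweide projection
  in the empirical design; extent and resolution are configurable, and
  synthetic runs use planar unit cells);
* presence of a species in a cell iff any of its range polygons contains
  the **cell centroid**, with boundary points counted as inside — a
  deterministic tie-break.  An `overlap` mode is provided because
  centroid-versus-overlap membership is not fully determinate in the
  original description; centroid mode is the default;
* cells with fewer than 3 species (per group) are excluded;
* trophic levels from diet fractions with *strict* >90% thresholds;
* climate extracted at centroids by nearest-cell lookup, and anomalies as
  the **signed** difference current − LGM by default.  The source
  description is ambiguous between signed and absolute anomalies; both are
  implemented (`compute_anomaly(mode = "absolute")`) and the synthetic
  analyses use signed values.

Two further choices were genuinely open and are fixed as follows.  Size
variance is computed on log10 mass, not raw grams: the raw-scale variance
is dominated by the largest species, and the same skew argument that
motivates logging the median applies to the spread (a raw-scale flag
exists).  Composite indicators are z-scored before the weighting
regression and composite scores are z-scored after, because standardized
path coefficients downstream require unit-variance nodes; scores are
oriented so the first indicator's weight is positive, since a weighted sum
is sign-indeterminate as a model node.

## The synthetic study system

Every stage is testable without downloads because the generator produces
all inputs with known ground truth from one seed (independent per-stage
substreams, so stages regenerate in isolation):

* **Climate fields** — Gaussian-kernel-smoothed white noise (bandwidth =
  `spatial_range`, default 3 cells) plus a latitudinal gradient, in
  natural units (°C, mm); LGM layers add an independent smooth
  perturbation and a colder/drier offset, so anomalies vary over space.
* **Ranges and traits** — disc-shaped ranges centred where the
  temperature field matches a random per-species optimum; log-normal body
  masses whose mean follows the group's assumed climate–size direction
  (smaller endotherms and larger squamates in warm cells, no trend for
  amphibians); diets from a three-component mixture with one species of
  each trophic class pinned per group.
* **Structural table** — variables generated in topological order; each
  endogenous node is the coefficient-weighted sum of its parents plus
  Gaussian noise whose SD is derived from the implied covariance so every
  node has unit population variance.  True coefficients are then directly
  the standardized coefficients a correctly specified OLS path analysis
  estimates.  Configurations whose systematic variance would exceed 1 are
  rejected.  Richness is generated on a latent continuous standardized
  scale, matching the OLS treatment of richness in the analysis; a
  count transform (`richness_to_counts()`) exists for gridding tests but
  is not used in recovery tests.

The default true coefficients (see `default_true_paths()`) encode the
study's qualitative expectations — climate and instability shape all three
traits with opposing signs and drive richness directly (0.4 and 0.2), with
trait effects of |0.15–0.25| on richness.

What the generator does *not* emulate: realistic range shapes and
dispersal, phylogenetic trait correlation, count noise in richness, and
non-linear climate–trait relationships.  Passing recovery tests therefore
demonstrate correctness of the estimation machinery under the linear
Gaussian design, not robustness to those features of real data.

## Numerical choices and conventions

* **Collinearity prefilter**: iteratively, for the worst pair with
  |r| > 0.7, drop the member whose single-predictor model for the
  submodel's response has the higher AIC, until no pair exceeds the
  threshold.
* **d-separation basis set**: non-adjacent ordered pairs (topological
  order; the later node is the regression response), conditioning on the
  union of both nodes' parents; pairs of two exogenous nodes are excluded
  (their covariance is unconstrained), as are declared correlated-error
  pairs.  Claim p-values are floored at the smallest positive double
  before logging.  A saturated model reports C as undefined with df 0.
* **MEM retention**: eigenvalues above `1e-8` of the largest magnitude;
  only positive-autocorrelation eigenvectors are kept or selected.
* **MIR stopping**: the default rule stops when the residual permutation
  test is non-significant at `alpha` (default 0.05, 999 permutations,
  seed mandatory in pipeline mode).  An alternative `"ceiling"` rule stops
  once |Moran's I| < 0.8, mirroring the unusually permissive bound quoted
  in the source description — possibly a typo for 0.08; both thresholds
  are exposed and neither is asserted as the original intent.  Ties in
  |I| reduction break to the lowest eigenvector rank.
* **No multiple-testing correction** on submodel coefficients (raw
  p < .05 flags in reports), matching the reporting convention of the
  analysis this mirrors.

### A note on transect eigenvectors

On a regularly spaced 1-D transect the MST truncation keeps only
nearest-neighbour weights, and the leading eigenvector of the doubly
centred weight matrix is exactly $\sin(2\pi i/(n+1))$ — one full sine
period (the even-index path-graph sines have zero mean and survive the
centring unchanged; the half-sine "bump" does not).  Its correlation with
a half-cosine over the transect is 0.88 regardless of $n$.  The
half-cosine shape often sketched for spatial eigenvectors emerges only
when the truncation distance spans a third or more of the transect, which
the MST rule never produces on regular spacing.  The test suite asserts
the closed form; the looser half-cosine description is retained in the
acceptance checks for comparability and is expected to fail by this
margin.

## Problem sizes used by the tests

The suite and the acceptance script fit everything at desk scale, chosen
so that sampling error is well inside the asserted bands: recovery at
n = 2000 cells (|error| < 0.08 single fit ≈ 3·SE; max |mean bias| < 0.02
over 100 seeds), Fisher's C calibration over 500 simulations of n = 300
(rejection rate 0.05 ± 0.025), Moran's I type-I error over 1000 i.i.d.
replicates with 999 permutations each (0.05 ± 0.02), and an end-to-end
synthetic run at 400 cells checking sign recovery of strong paths
(|β| ≥ 0.3).

The end-to-end route deserves a caveat: with 400 spatially autocorrelated
cells the effective sample size is far below 400, and the exogenous
composites are *estimated* (weighted by richness), so coefficient errors
of ±0.1–0.15 and occasional prefilter drops of a genuinely collinear
composite pair are expected behaviour, not failures of the machinery —
the iid-indicator recovery harness is the calibrated check.  On small
smooth grids, two independent random fields can easily show |r| > 0.7;
the prefilter then behaves exactly as designed.

## Limitations

Richness is modelled by OLS on a continuous (latent) scale; no count
likelihood is offered.  Negative-autocorrelation eigenvectors are never
selected.  Composite weights are estimated once and treated as fixed
regressors (two-step estimation); no latent-variable SEM, measurement
error model, or phylogenetic correction is attempted.  Polygon handling
covers simple (multi)polygons without holes; self-intersecting polygons
are skipped with a warning rather than repaired.
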