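---
title: "Methods: random-forest habitat models and snakebite-risk overlays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest habitat models and snakebite-risk overlays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

`sdmrisk` implements a complete presence/pseudo-absence species
distribution modelling (SDM) workflow for venomous pit vipers (*Gloydius*
spp.) and the downstream epidemiological overlays that turn habitat maps
into snakebite-risk statements:

1. **Terrain derivation.** Slope (degrees, Horn 3×3 operator) and the
   topographic position index (TPI: a cell's elevation minus the mean of
   its square neighborhood, center excluded) are computed from a 30 m DEM.
   Negative TPI marks valley bottoms — where these snakes' amphibian and
   fish prey concentrate.
2. **Occurrence preparation.** Survey presences are thinned to one point
   per 30 m pixel (survey records cluster; record order is not
   meaningful, so the retained point is drawn uniformly under a seed).
   Pseudo-absences are drawn uniformly without replacement from analyzable
   cells that contain no presence, standing in for unrecorded absences.
3. **Collinearity screening.** For every pair of candidate predictors the
   Pearson, Spearman and Kendall coefficients are computed on the model
   points; while any pair exceeds |r| > 0.75 on *any* of the three, the
   member with the lower univariate percent deviance explained (binomial
   GAM, linear GLM fallback) is dropped. The screening is performed once
   on the pooled dataset (all species' presences plus a shared
   pseudo-absence pool), giving a single predictor set for all species
   models.
4. **Model fitting.** One random forest of 1000 unpruned classification
   trees per species, grown on bootstrap resamples; the number of split
   candidates (`mtry`) minimizes out-of-bag error over a doubling/halving
   ladder around `floor(sqrt(p))`. Presence probability is the tree-vote
   fraction. A stratified 70/30 split provides train/test evaluation
   (AUC, TSS); stratified 10-fold cross-validation of the training split
   (with per-fold re-tuning, avoiding leakage) gives a second AUC
   estimate.
5. **Binarization and union.** Each suitability surface is thresholded at
   the value maximizing sensitivity + specificity *on the training
   scores* (the threshold is then applied unchanged to the test split —
   selecting it per split would leak information). The per-species binary
   maps are OR-ed into a composite potential-habitat map: 1 wherever at
   least one species is predicted present.
6. **Risk statistics.** Per administrative region: habitat proportion
   (habitat cells / region cells), incidence per 10,000 residents
   (10⁴ × count / population), and their Spearman rank correlation. Per
   national park: habitat ratio and the fraction of rasterized trail
   cells on habitat. Over all habitat cells: mean percent land cover.

## Evaluation primitives

The evaluation core is implemented directly and oracle-tested:

* **AUC** uses the Mann–Whitney formulation (mid-ranks; ties count ½) —
  the probability that a random presence outscores a random absence. It
  is invariant under strictly increasing transforms of the scores.
* **Threshold selection** scans the midpoints between consecutive sorted
  unique scores plus {0, 1}; presence is predicted at `score ≥ t`; ties
  in sensitivity + specificity resolve to the smallest threshold, making
  the scan deterministic and exhaustive over distinct confusion matrices.
* **TSS** is sensitivity + specificity − 1, audited as an exact identity
  in every emitted report.
* **Spearman's test** transforms to mid-ranks and correlates; the p-value
  uses the two-sided t-approximation with n − 2 degrees of freedom,
  adequate at the regional n = 16 of this analysis and documented as
  approximate. Exact full-permutation enumeration is available for
  n ≤ 8 — the package's "small n", chosen because full enumeration beyond
  8! permutations costs minutes in R for no practical gain here.
* **Kendall's τ-b** is Knight's O(n log n) algorithm in compiled code
  (the `stats` implementation is quadratic and dominates repeated
  screening runs); it is tested against both `stats::cor` and a
  brute-force pair-counting oracle.

# The synthetic study system

The real inputs for a national-scale analysis of this kind (survey occurrences, 30 m
national DEM and land-cover products, WorldClim climate, trail and park
geometries, insurance-claim incidence counts) are not redistributable, so
the package ships a generator that reproduces the *statistical structure*
the analysis assumes, making every stage testable end to end.

## What the generator emulates

* **Terrain:** a two-scale spectrally filtered Gaussian random field
  (broad structure with a 25-cell correlation length plus a 20% share of
  fine 3-cell relief), rescaled to 0–1200 m on a 256 × 256 grid of 30 m
  cells. The fine component gives 30 m TPI and slope realistic local
  variability (TPI SD ≈ 3 m, mean slope ≈ 25°).
* **Climate:** temperature = 22 °C − 6.5 °C/km × elevation + smooth
  noise. The noise is scaled *relative to the lapse signal* (default
  0.62) so the engineered temperature–elevation correlation lands near
  |r| ≈ 0.85 on any landscape realization — reliably above the 0.75
  screening threshold even on the model points, whose presence clustering
  restricts the elevation range and pulls the sample correlation below
  the map-wide value; the generator verifies the correlation and redraws
  the noise up to five times. Precipitation is an independent smooth
  field (900–1600 mm).
* **Land cover:** four percent-cover fields clipped to [0, 100];
  shrubland is 0.75 × herbaceous + smooth noise, putting the pair's
  correlation near 0.85 — the second engineered collinear pair.
* **Species:** suitability is a logistic model with a valley preference
  (TPI coefficient −0.3 per meter), a Gaussian slope bump centered at 15°
  (SD 8°, amplitude 4), a plateau temperature window with 0.5 °C
  logistic shoulders (amplitude 5.5), and a weak herbaceous term (0.09
  per percent). Windows: 18–20 °C for the *G. brevicaudus*-like species,
  14–19 °C for *G. ussuriensis*, 14–17.5 °C for *G. saxatilis* — the
  lowered upper shoulder for the saxatilis-like species produces the
  high-altitude/low-altitude split between its map and the others', which
  otherwise would not emerge from two identical windows. Presence counts
  default to 700 / 1500 / 100, echoing the real survey's species balance;
  2000 pseudo-absences keep a moderate class imbalance at this grid size.
* **Incidents:** regions tile the grid (default 16); populations are
  log-uniform on 10⁵–10⁷; incident counts are
  Poisson(population × (a + b × habitat proportion)/10⁴) with a = 0.1 and
  b = 4 per 10,000 — the simplest mechanism producing a monotone
  association between habitat proportion and incidence, with rates in the
  0.1–2.5 per-10,000 range of the published regional table.
* **Trails and parks:** trails are random walks biased down the TPI
  gradient (trails follow valleys); parks are random rectangles of at
  least 100 cells.

All outputs are deterministic functions of (configuration, seed); every
stage seed derives from the master seed by fixed offsets.

## Deliberate design choices in the generator

Two choices deserve emphasis because they were forced by the statistics,
not convenience:

* **The herbaceous term.** With no cover layer carrying real signal, the
  univariate deviances of the engineered herbaceous/shrubland pair would
  both be estimation noise, and which member screens out would be a coin
  flip. The weak herbaceous term gives the pair asymmetric signal:
  shrubland, being herbaceous plus independent noise, always carries an
  attenuated copy, so screening drops shrubland — the asymmetry the
  screening stage exists to exploit. A side effect is that herbaceous
  cover can top the variable-importance ranking in full-pipeline runs; it
  is real signal, by construction.
* **Balanced effect sizes.** Each suitability term contributes roughly
  1–1.5 logit SD. Three failure modes observed during design drove this:
  a dominant TPI term leaks into *elevation* (in any Gaussian field a
  cell's value is positively correlated with its local convexity, r ≈
  0.2 here — as on real terrain, where ridges are convex), which can
  invert the temperature-vs-elevation deviance ordering; a too-high
  baseline pushes cells into the saturated part of the logistic where
  discrimination compresses; and a too-weak temperature amplitude fails
  to concentrate presences inside the window, starving the screening
  stage of its temperature signal.

## What the generator does *not* emulate

Real Korean topography and climatology; spatial survey bias (roadside or
accessibility bias in occurrence records); multifractal drainage-carved
terrain; seasonal snake activity; imperfect detection; and the regional
confounders (medical access, farming activity, reporting bias) that
moderate any real regional incidence correlation. Passing
recovery tests therefore demonstrates that the *pipeline machinery*
recovers known structure under its own assumptions — not that those
assumptions hold for the real data.

# Numerical choices

* **Grid convention:** origin at the top-left corner, row index increasing
  southward, half-open pixels, point-to-pixel by `floor`; areas are cell
  counts × cell². A single CRS is assumed; there is no reprojection.
* **Raster I/O** uses the plain-text ESRI ASCII grid format with a `.prj`
  sidecar for the CRS tag; values are written with 17 significant digits
  so round trips are bit-exact. Vector data use GeoJSON.
* **Rasterization:** lines are "all-touched" (a cell is marked if the
  segment passes through its square — conservative for trail-risk
  flagging, so trails cannot vanish by clipping cell corners), resolved
  by splitting segments at grid-line crossings and assigning interval
  midpoints under the half-open convention, which also makes the result
  invariant to polyline direction. Polygons label cell centers; overlaps
  warn and the lowest id wins.
* **Bilinear resampling** interpolates between the four nearest source
  cell centers; target centers outside the source extent are nodata, and
  centers between the extent edge and the outermost center ring clamp to
  the edge value. It reproduces affine surfaces exactly within the source
  center lattice and must not be applied to categorical layers.
* **Terrain edges:** slope and TPI use border replication / truncated
  neighborhoods rather than shrinking the study area; nodata propagates.
  The TPI radius defaults to 1 (3 × 3) — the analysis resolution — and is
  a first-class parameter because the appropriate landform scale is a
  modelling choice.
* **Ties:** thinning tie-breaks are seeded-random; screening deviance
  ties drop the alphabetically later name; threshold ties take the
  smallest candidate; `mtry` ties take the smaller value. Every tie rule
  is deterministic given the seed.
* **Degenerate inputs:** constant predictors screen as uncorrelated with
  deviance 0; perfect separation caps deviance at 100 with a warning;
  empty polyline sets rasterize to zeros; empty parks and trail-free
  zones are errors or NA-with-warning respectively.

# Problem sizes

The recovery studies in the test suite run 100 seeds each at the
generator defaults (256 × 256 cells), with 100-tree forests at the
default `mtry` — forest size and tuning effort matter little for rank
recovery at these data sizes, and the smaller forests keep the full suite
quick. The pipeline default remains 1000 trees with out-of-bag tuning and
10-fold cross-validation — standard settings for presence/background
random forests; a
full pipeline run at defaults takes a few minutes on one core.

# Known limitations

* The spatial unit is the 30 m cell throughout; trail overlap counts
  rasterized cells, not trail length, so sinuous trails weigh slightly
  more per meter.
* Pseudo-absences are uniform background; target-group or bias-corrected
  background sampling is out of scope.
* The Spearman p-value is approximate except for n ≤ 8.
* Cross-validation is random-stratified, not spatially blocked, so it
  shares the optimism of random-split evaluation under spatial
  autocorrelation.
* One model family (random forest); no MaxEnt/GAM/BRT ensemble.
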