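---
title: "Quantifying cell migration on curved cylindrical substrates"
author: "curvtracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell migration on curved cylindrical substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvtracks)
```

## The problem

Corneal keratocytes live in a curved tissue and, after injury, adopt either
a fibroblastic or a TGF-beta-induced myofibroblastic phenotype. A standard
way to probe how these phenotypes sense substrate geometry is to culture
the cells on chips carrying semi-cylindrical grooves of different diameters
(D = 125 to 2000 um, principal curvature $\kappa = 2/D$ in the
circumferential direction, plus flat control areas), film them at 20-minute
intervals for 22 hours, and quantify each cell's trajectory and shape.
`curvtracks` implements that quantification end to end — geometry,
trajectory metrics, shape morphometrics and group statistics — together
with synthetic-data generators that emulate the tracked-cell and mask data,
so every estimator in the package can be validated against cohorts whose
true parameters are known.

## Geometry: chord versus arc coordinates

A confocal maximum-intensity projection flattens the cylinder: a surface
point at azimuth $\theta$ (measured from the deepest line of the groove)
appears at the chord coordinate $y = R\sin\theta$ rather than at its arc
position $s = R\theta$. Circumferential displacements measured on the
projection are therefore compressed. `chordToArc()` applies the exact
correction $s = R\,\mathrm{asin}(y/R)$; `unwrapTracks()` applies it to a
whole `TrackSet`, leaving longitudinal ($x$) displacements untouched.

The correction matters most on small cylinders. On D = 500 um, a band of
|y| <= 100 um is stretched by at most $\mathrm{asin}(0.4)/0.4 - 1 \approx
2.9\%$, which is why projections of large cylinders are often analyzed
as-is. The package remaps every non-flat surface by default (the exact
treatment costs nothing), and `policy = "paper_thresholded"` reproduces the
thresholded convention of remapping only D <= 250 um. Convex cylinders use
the same formulas; concavity is carried as metadata for grouping. The
imaged circumferential band is not standardized anywhere, so the
generators default to |y_chord| <= 0.8 R.

## The synthetic cohorts

`simulatePRWTracks()` draws persistent random walks whose heading
$\varphi$ (relative to the cylinder axis) evolves per step as

$$\varphi \leftarrow \varphi - g\,\kappa\,\sin(2\varphi)\,dt
  + \sigma\sqrt{dt}\,\mathcal{N}(0,1).$$

Two modelling choices are deliberate. First, the curvature bias is a
torque on the heading, not a modulation of speed: observed migration
speeds are largely curvature-insensitive while direction is strongly
curvature-sensitive, so curvature enters only through the alignment
dynamics. Second, the coupling is nematic ($\sin 2\varphi$): cells align
with the axis, not with a particular end of the cylinder, so both
$\varphi = 0$ and $\varphi = \pi$ are attractors. The stationary heading
density is then $p(\varphi) \propto \exp\!\big((g\kappa/\sigma^2)\cos
2\varphi\big)$, which the test suite checks by simulation against numeric
integration.

Per-cell mean speeds are drawn from a log-normal truncated to 10–80 um/h,
the range observed for motile keratocytes; within a cell, step speeds get
multiplicative gamma noise (CV 0.3) that is renormalized so the realized
per-cell mean equals the drawn value exactly. This makes the 10–80 um/h
band a hard guarantee of the generator rather than a distributional
tendency, and keeps "per-cell mean speed" a true simulation parameter.

The two presets encode the qualitative phenotype contrast only —
fibroblastic: mean speed 45 um/h, curvature gain 60; myofibroblastic:
25 um/h, gain 20; both with $\sigma = 0.8\ \mathrm{rad}/\sqrt{h}$. No
published per-condition speed means or coupling constants exist to
calibrate against, so these are configurable placeholders chosen once to
respect the documented orderings (fibroblastic faster and more strongly
curvature-coupled); analyses that need real parameters should fit them to
their own data.

`simulateMixtureTracks()` is a different kind of generator: each step's
orientation is drawn from a uniform band within 30 degrees of the axis
(with probability `p_band`, nematically) or uniformly otherwise, so the
marginal probability of an aligned step is exactly
$p_\mathrm{band} + (1 - p_\mathrm{band})/3$. It exists to give the
alignment estimator an analytically known target.

What the generators do *not* emulate: cell division, death, collisions,
detachment (relevant on convex structures, where adhesion is unstable),
confluence effects, and any coupling between shape and motility. Passing
recovery tests on these cohorts validates the estimators, not the
biology; on real data the estimators inherit whatever violations of the
random-walk picture the cells exhibit.

## Trajectory metrics

All metrics operate on unwrapped coordinates with x longitudinal.

* **Mean speed** — mean over steps of step length / step duration
  (20-minute steps by default).
* **Directionality index dx/dy** — maximum absolute displacement from the
  starting position along x divided by the same along y. "Maximum
  displacement" is read as displacement-from-origin; the coordinate-range
  alternative is available via `mode = "range"`. A 1-um floor on dy
  prevents infinities on perfectly axial synthetic tracks; measured tracks
  never reach it.
* **Ensemble MSD** — mean of $|r(t + \Delta t) - r(t)|^2$ over all
  overlapping ordered pairs pooled across cells (maximal statistical use
  of the data). "Ensemble averaged" is ambiguous between pair-pooling and
  per-cell-then-mean; both are implemented (`mode =` `"pooled"` /
  `"percell"`) and the pooled curve equals the pair-count-weighted mean of
  per-cell curves, an identity the tests assert numerically.
* **MSD exponent** $\alpha$ — OLS slope of log MSD vs log lag over lags in
  [dt, 5 h] by default, the short-interval window in which migrating cells
  follow $\Delta t^\alpha$; $\alpha = 1$ diffusive, $> 1$ persistent,
  $= 2$ ballistic.
* **Aligned fraction** — a step is aligned when
  $\arctan(|\Delta y| / |\Delta x|) < 30^\circ$, strictly. A step at
  exactly the threshold is *not* aligned; because constructed 30-degree
  steps are not exactly representable in floating point, the strictness of
  the boundary is unit-tested at 45 degrees, where the orientation is
  exact. Steps shorter than $10^{-3}$ um have no defined orientation and
  are excluded from numerator and denominator; real pauses are otherwise
  retained, since no convention for them is established.
* **Aligned speed ratio** — mean step speed in the aligned class over the
  non-aligned class; `NA` when either class is empty.

## Morphometrics

`measureShapes()` reproduces the standard CellProfiler-style descriptors
from an integer-labeled mask: major axis length and eccentricity from the
moments ellipse (normalized central second moments of pixel centres;
$e = \sqrt{1 - (b/a)^2}$, identical to the focal-distance / major-axis
definition, 0 for a circle and 1 for a line), area from the pixel count,
and solidity as object pixels over rasterized convex-hull pixels. The
hull is built on pixel centres and rasterized (points on or inside the
polygon), matching the pixel-proportion definition of solidity rather
than a polygon-area ratio. Border-touching objects are excluded by
default (partial cells bias shape statistics) and objects under 50 px are
dropped as debris; both filters are configurable, and are declared
defaults, not reconstructions of any particular study's settings.

## Tracking

For synthetic movies, `detectCentroids()` thresholds each frame (Otsu or
fixed), labels connected components and returns intensity-weighted
centroids; `linkTracks()` joins them greedily in ascending-distance order
under a gate (default 100 um/h x dt ≈ 33 um, ~25% above the fastest
expected cells), with no gap closing. Greedy linking is deterministic and
adequate at the low densities typical of these experiments; the tests
compare it frame-by-frame against a brute-force minimal-total-distance
matching and bound the disagreement rate on crossing paths. Tracks
shorter than 10 frames are dropped before metrics, as MSD and
directionality are unstable on very short tracks.

## Group statistics

`kruskalWallis()` and `dunnBH()` implement the tie-corrected
Kruskal-Wallis omnibus test and Dunn's pairwise z statistics on pooled
mid-ranks, with Benjamini-Hochberg adjustment (via `stats::p.adjust`)
over a declared family. The post-hoc is computed regardless of omnibus
significance, with the omnibus p reported alongside, because pairwise
outcomes are conventionally annotated per panel whether or not the
omnibus is shown. The default family is all pairwise comparisons within
one metric's analysis (one "panel"); wider families can be declared
explicitly. Tests are two-sided; stars follow the usual convention
(`****` for p < 0.0001).

## Pipeline and reproducibility

`runPipeline()` executes simulate → (optionally render + detect + link) →
unwrap → per-cell summary → MSD → stats for a list of cohort blocks, each
with its own seed, and writes deterministic CSVs plus a manifest carrying
a digest of the configuration. Re-running an identical configuration
reproduces the tables byte for byte. The rendered-movie route projects
unwrapped tracks back to chord coordinates, renders Gaussian-blob frames
with Poisson noise, re-tracks them, and unwraps again — on well-separated
cohorts it agrees with the direct route within tracking tolerance, which
the acceptance tests verify.

The package's interface is R functions plus the YAML run-configuration;
no shell wrapper is shipped, as users of an analysis package drive it
from R scripts.

### Problem sizes used in validation

The shipped checks use cohorts of 40–200 cells with 66 steps (the
20-min/22-h scheme), 500 cells for the diffusive-limit exponent check,
and 1000 null simulations of 3 x 30 observations for the type-I-error
check of the omnibus test — sizes at which Monte-Carlo error is well
below the tested tolerances while the whole suite runs in well under a
minute.

## Known limitations

* The projection model assumes negligible out-of-plane motion inside the
  imaged band; near the cylinder rim (|y| → R) the chord→arc derivative
  diverges and localization noise is amplified.
* Unwrapped coordinates are treated as an infinite plane: a simulated
  cell can drift beyond a quarter circumference, where re-projection is
  undefined; rendering routes should use durations or bands that keep
  |arc| < πR/2.
* Greedy linking can mismatch crossing cells; it reports no confidence.
* Preset parameters are qualitative placeholders (see above), so
  simulated effect sizes should not be read as quantitative predictions.
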