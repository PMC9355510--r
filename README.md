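# curvtracks

Quantitative analysis of single-cell migration on curved cylindrical
substrates, written for experiments in which cells — typified by corneal
keratocytes in their fibroblastic and TGF-β-induced myofibroblastic
states — are cultured on chips carrying semi-cylindrical grooves of
diameter D = 125–2000 µm (principal curvature κ = 2/D) plus flat control
areas, filmed every 20 min for 22 h, and scored for how strongly they
sense and follow the substrate curvature.

The package provides:

* **Geometry** — `cylinderSpec()`, `principalCurvature()`,
  `chordToArc()` / `arcToChord()` and `unwrapTracks()`: exact remapping of
  maximum-intensity-projection (chord) coordinates to arc length on the
  cylinder surface, s = R·asin(y/R).
* **Synthetic cohorts** — `simulatePRWTracks()`: persistent random walks
  whose heading φ feels a nematic curvature torque,
  φ ← φ − g·κ·sin(2φ)·dt + σ√dt·N(0,1), with fibroblastic and
  myofibroblastic presets; `simulateMixtureTracks()` with analytically
  known alignment statistics; `generateShapeMask()` and
  `generateTimelapse()` for labeled masks and noisy blob movies.
* **Tracking** — `detectCentroids()` (Otsu threshold, intensity-weighted
  centroids) and `linkTracks()` (greedy nearest-neighbour, gated).
* **Migration metrics** — `meanSpeed()`, directionality index dx/dy
  (`directionalityIndex()`), ensemble mean-squared displacement and its
  power-law exponent α (`ensembleMSD()`, `fitMSDExponent()`; α = 1
  diffusive, α = 2 ballistic), and the strict-30° alignment statistics
  `alignedFraction()` and `alignedSpeedRatio()`.
* **Morphometrics** — `measureShapes()`: major axis, area, eccentricity
  (moments ellipse; 0 = circle, 1 = line) and convex-hull solidity from
  labeled masks.
* **Group statistics** — tie-corrected Kruskal–Wallis (`kruskalWallis()`)
  and Dunn's post-hoc z tests with Benjamini–Hochberg adjustment
  (`dunnBH()`, `groupStats()`).
* **Pipeline** — `runPipeline()` / `readRunConfig()`: configuration-driven
  simulate → track → unwrap → metrics → stats runs with per-cohort seeds
  and byte-reproducible CSV output.

## Worked example

Simulate a fibroblastic cohort on the highest-curvature cylinder and
score it:

```r
library(curvtracks)

sp  <- cylinderSpec(125)                     # concave, kappa = 1/62.5 um^-1
cfg <- simConfig(sp, n_cells = 30, preset = "fibroblastic", seed = 1)
ts  <- simulatePRWTracks(cfg)

head(migrationSummary(ts)[, c("cell_id", "mean_speed_umh",
                              "directionality", "aligned_fraction")], 4)
#>   cell_id mean_speed_umh directionality aligned_fraction
#> 1 cell001           34.6           2.46            0.379
#> 2 cell002           38.1           9.10            0.682
#> 3 cell003           44.7           1.67            0.515
#> 4 cell004           62.9           4.86            0.545

fitMSDExponent(ensembleMSD(ts))
#> MSDCurve: 67 lag(s), max lag 22 h, alpha = 1.849 over [0.333, 5] h
```

Per-cell speeds sit in the 10–80 µm/h band of motile keratocytes, the
directionality indices dx/dy above 1 reflect migration biased along the
cylinder axis, and the MSD exponent α ≈ 1.85 over lags below 5 h marks
strongly persistent (superdiffusive) motion. Comparing against a
myofibroblastic cohort on the same cylinder:

```r
myo <- simulatePRWTracks(simConfig(sp, n_cells = 30,
                                   preset = "myofibroblastic", seed = 2))
both <- rbind(cbind(migrationSummary(ts),  grp = "fibroblastic"),
              cbind(migrationSummary(myo), grp = "myofibroblastic"))
groupStats(both$mean_speed_umh, both$grp, metric = "mean_speed_umh")
#> StatsResult [mean_speed_umh]: Kruskal-Wallis H = 25.57, df = 1, p = 4.28e-07
#>   1 pairwise Dunn comparison(s), BH-adjusted:
#>         group1          group2        z        p_raw        p_adj stars
#> 1 fibroblastic myofibroblastic 5.056273 4.275281e-07 4.275281e-07  ****
```

The fibroblastic preset migrates significantly faster, mirroring the
phenotype contrast the presets encode. A full 2-phenotype × 6-surface
screen is one call: `runPipeline(demoRunConfig(n_cells = 30), "out/")`.

## Documentation

The methods vignette (`vignettes/curved-migration-analysis.Rmd`) explains
the projection model, the random-walk generators and their deliberate
simplifications, the metric definitions and tie-break conventions, and
the package's known limitations.
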