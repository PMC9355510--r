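# Migration metrics: speed, directionality index, ensemble MSD, exponent
# fitting, alignment statistics.

test_that("mean speed matches arithmetic and a brute-force step loop", {
  two <- make_track(c(0, 8), c(0, 6), dt_h = 1 / 3)    # 10 um in 20 min
  expect_equal(unname(meanSpeed(two)), 30)
  still <- make_track(rep(1, 5), rep(2, 5))
  expect_equal(unname(meanSpeed(still)), 0)

  set.seed(31)
  x <- cumsum(rnorm(67)); y <- cumsum(rnorm(67))
  ts <- make_track(x, y, dt_h = 1 / 3)
  # independent loop
  manual <- 0
  for (i in 1:66)
    manual <- manual + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2) / (1 / 3)
  expect_equal(unname(meanSpeed(ts)), manual / 66, tolerance = 1e-9)
})

test_that("directionality index reproduces the worked examples", {
  axial <- make_track(c(0, 50, 100), c(0, 0, 0))
  d <- directionalityIndex(axial, dy_floor_um = 1)
  expect_equal(d$dx_um, 100)
  expect_equal(d$dy_um, 0)
  expect_equal(d$directionality, 100)

  ell <- make_track(c(0, 50, 50), c(0, 0, 50))
  expect_equal(directionalityIndex(ell)$directionality, 1)

  hand <- make_track(c(0, 3, 5, 4), c(0, 1, -2, 4))
  dh <- directionalityIndex(hand)
  expect_equal(dh$dx_um, 5)     # max |x - x0|
  expect_equal(dh$dy_um, 4)     # max |y - y0|
  expect_equal(dh$directionality, 1.25)
})

test_that("directionality index is invariant under translation and reflection", {
  set.seed(37)
  x <- cumsum(rnorm(30, 1)); y <- cumsum(rnorm(30))
  base <- directionalityIndex(make_track(x, y))$directionality
  expect_equal(directionalityIndex(make_track(x + 100, y - 55))$directionality, base)
  expect_equal(directionalityIndex(make_track(-x, y))$directionality, base)
  expect_equal(directionalityIndex(make_track(x, -y))$directionality, base)
  # range mode differs in general but agrees for monotone coordinates
  mono <- make_track(seq(0, 29), seq(0, 58, by = 2))
  expect_equal(directionalityIndex(mono, mode = "range")$directionality,
               directionalityIndex(mono, mode = "origin")$directionality)
})

test_that("ensemble MSD matches hand-enumerated and closed-form cases", {
  # 3-point track (0,0), (1,0), (1,1) at unit lag
  t3 <- make_track(c(0, 1, 1), c(0, 0, 1), dt_h = 1)
  curve <- ensembleMSD(t3)
  expect_equal(curve@lags_h, c(0, 1, 2))
  expect_equal(curve@msd_um2, c(0, 1, 2))      # (1+1)/2 then 2
  expect_equal(curve@n_pairs, c(0, 2, 1))

  # ballistic: MSD = v^2 dt^2 exactly
  v <- 24
  ball <- make_track(v * (0:20) / 3, rep(0, 21), dt_h = 1 / 3)
  cb <- ensembleMSD(ball)
  expect_equal(cb@msd_um2, v^2 * cb@lags_h^2, tolerance = 1e-9)

  # stationary cohort: identically zero
  stat <- make_tracks(list(rep(0, 10), rep(5, 10)), list(rep(0, 10), rep(1, 10)))
  expect_true(all(ensembleMSD(stat)@msd_um2 == 0))
})

test_that("pooled MSD equals the pair-count-weighted mean of per-track curves", {
  cfg <- simConfig(flatSpec(), n_cells = 6, duration_h = 10, seed = 41)
  ts <- simulatePRWTracks(cfg)
  pooled <- ensembleMSD(ts, mode = "pooled")
  tr <- tracks(ts)
  # per-track curves via single-track calls, then weight by pair counts
  ids <- unique(tr$cell_id)
  per <- lapply(ids, function(id) {
    d <- tr[tr$cell_id == id, ]
    ensembleMSD(trackSet(d, surface = surface(ts), unwrapped = TRUE))
  })
  for (k in 2:length(pooled@lags_h)) {
    num <- sum(vapply(per, function(c) c@msd_um2[k] * c@n_pairs[k], 1))
    den <- sum(vapply(per, function(c) c@n_pairs[k], 1))
    expect_equal(pooled@msd_um2[k], num / den, tolerance = 1e-9)
  }
  # per-cell mode gives the unweighted mean instead
  pc <- ensembleMSD(ts, mode = "percell")
  k <- 3
  expect_equal(pc@msd_um2[k],
               mean(vapply(per, function(c) c@msd_um2[k], 1)),
               tolerance = 1e-9)
})

test_that("MSD exponent fitting recovers constructed power laws", {
  lags <- seq(1 / 3, 8, by = 1 / 3)
  curve <- new("MSDCurve", lags_h = c(0, lags), msd_um2 = c(0, 3 * lags^1.4),
               n_pairs = c(0, rep(10, length(lags))), alpha = NA_real_,
               fit_window_h = c(NA_real_, NA_real_))
  expect_equal(msdAlpha(fitMSDExponent(curve, window = c(NA, 5))), 1.4,
               tolerance = 1e-6)
  # ballistic tracks: alpha = 2
  ball <- make_tracks(list(10 * (0:30), 25 * (0:30)),
                      list(rep(0, 31), 5 * (0:30)), dt_h = 1 / 3)
  expect_equal(msdAlpha(fitMSDExponent(ensembleMSD(ball))), 2, tolerance = 1e-3)
  expect_error(fitMSDExponent(curve, window = c(0.3, 0.4)), "at least 3")
})

test_that("zero-persistence walks are diffusive and persistent walks are not", {
  cfg <- simConfig(flatSpec(), n_cells = 500, step_cv = 0, seed = 43)
  rw <- simulateMixtureTracks(0, cfg)          # fresh uniform heading per step
  curve <- fitMSDExponent(ensembleMSD(rw), window = c(2 / 3, 5))
  expect_gt(msdAlpha(curve), 0.9)
  expect_lt(msdAlpha(curve), 1.1)

  prw <- simulatePRWTracks(simConfig(flatSpec(), n_cells = 100,
                                     preset = "fibroblastic", seed = 44))
  a_prw <- msdAlpha(fitMSDExponent(ensembleMSD(prw), window = c(NA, 5)))
  expect_gt(a_prw, 1.1)                         # superdiffusive below 5 h
})

test_that("alignment classification uses a strict 30-degree threshold", {
  ang29 <- 29 * pi / 180
  t29 <- make_track(10 * cos(ang29) * (0:10), 10 * sin(ang29) * (0:10))
  expect_equal(unname(alignedFraction(t29)), 1)
  ang31 <- 31 * pi / 180
  t31 <- make_track(10 * cos(ang31) * (0:10), 10 * sin(ang31) * (0:10))
  expect_equal(unname(alignedFraction(t31)), 0)
  # a step exactly at the threshold counts as NOT aligned (strict
  # inequality); probed at 45 degrees where the orientation is exact in
  # floating point
  t45 <- make_track(10 * (0:10), 10 * (0:10))
  expect_equal(unname(alignedFraction(t45, threshold_deg = 45)), 0)
  expect_equal(unname(alignedFraction(t45, threshold_deg = 45 + 1e-9)), 1)
  circum <- make_track(rep(0, 6), 10 * (0:5))
  expect_equal(unname(alignedFraction(circum)), 0)
})

test_that("aligned fraction is nematic and ~1/3 under uniform orientations", {
  set.seed(47)
  ang <- runif(1e5, 0, 2 * pi)
  x <- c(0, cumsum(cos(ang))); y <- c(0, cumsum(sin(ang)))
  ts <- make_track(x, y)
  f <- unname(alignedFraction(ts))
  se <- sqrt(1 / 3 * 2 / 3 / 1e5)
  expect_lt(abs(f - 1 / 3), 3 * se)
  # invariance under axis reversals
  expect_equal(unname(alignedFraction(make_track(-x, y))), f)
  expect_equal(unname(alignedFraction(make_track(x, -y))), f)
})

test_that("sub-threshold steps are excluded and undefined cases marked", {
  # pauses (zero steps) do not dilute the fraction
  paused <- make_track(c(0, 10, 10, 20), c(0, 1, 1, 2))
  expect_equal(unname(alignedFraction(paused)), 1)
  frozen <- make_track(rep(0, 4), rep(0, 4))
  expect_true(is.na(alignedFraction(frozen)))
  expect_true(is.na(alignedSpeedRatio(frozen)))
})

test_that("aligned speed ratio reflects class speeds and nulls at 1", {
  # alternate aligned (fast) and circumferential (slow) steps
  dx <- rep(c(20, 0), 10); dy <- rep(c(0, 10), 10)
  ts <- make_track(c(0, cumsum(dx)), c(0, cumsum(dy)))
  expect_equal(unname(alignedSpeedRatio(ts)), 2)
  all_aligned <- make_track(10 * (0:10), rep(0, 11))
  expect_true(is.na(alignedSpeedRatio(all_aligned)))

  # class-independent speeds: cohort mean ratio near 1
  cfg <- simConfig(flatSpec(), n_cells = 100, seed = 53)
  mx <- simulateMixtureTracks(0.4, cfg)
  ratios <- alignedSpeedRatio(mx)
  expect_gt(mean(ratios, na.rm = TRUE), 0.9)
  expect_lt(mean(ratios, na.rm = TRUE), 1.1)
})

test_that("mixture cohorts recover the analytic aligned fraction end-to-end", {
  for (p_band in c(0, 0.7)) {
    cfg <- simConfig(cylinderSpec(250), n_cells = 150, seed = 60 + p_band * 10)
    af <- alignedFraction(simulateMixtureTracks(p_band, cfg))
    expected <- p_band + (1 - p_band) / 3
    se <- stats::sd(af) / sqrt(length(af))
    expect_lt(abs(mean(af) - expected), 3 * se + 1e-12)
  }
})

test_that("mean directionality rises with curvature gain times curvature", {
  gains <- c(0, 20, 60)
  med <- vapply(seq_along(gains), function(i) {
    cfg <- simConfig(cylinderSpec(125), n_cells = 120, curvature_gain = gains[i],
                     seed = 70 + i)
    mean(directionalityIndex(simulatePRWTracks(cfg))$directionality)
  }, 1)
  expect_true(all(diff(med) > 0))
})

test_that("migration summaries assemble per-cell metrics with cohort labels", {
  cfg <- simConfig(cylinderSpec(500), n_cells = 8, preset = "myofibroblastic",
                   seed = 77)
  ts <- simulatePRWTracks(cfg)
  ts@metadata$phenotype <- "myofibroblastic"
  s <- migrationSummary(ts)
  expect_equal(nrow(s), 8L)
  expect_identical(s$phenotype, rep("myofibroblastic", 8))
  expect_identical(s$diameter_um, rep(500, 8))
  expect_equal(s$n_steps, rep(66L, 8))
  expect_true(all(s$mean_speed_umh >= 0))
  expect_true(all(s$aligned_fraction >= 0 & s$aligned_fraction <= 1))
  expect_equal(unname(meanSpeed(ts)[s$cell_id]), s$mean_speed_umh)
})
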