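# Synthetic generators: persistent random walks, orientation mixtures,
# shape masks, time-lapse rendering.

test_that("simulation configs validate sampling scheme and cohort size", {
  cfg <- simConfig(cylinderSpec(125), n_cells = 10, seed = 1)
  expect_equal(nTimePoints(cfg), 67L)          # 22 h at 20-min intervals
  expect_error(simConfig(n_cells = 0), "n_cells")
  expect_error(simConfig(dt_h = 0.3, duration_h = 1), "integer multiple")
  expect_error(simConfig(speed_range_umh = c(80, 10)), "increasing")
})

test_that("identical seeds reproduce tracks bit-for-bit; different seeds decorrelate", {
  cfg <- simConfig(cylinderSpec(250), n_cells = 8, seed = 42)
  a <- simulatePRWTracks(cfg)
  b <- simulatePRWTracks(cfg)
  expect_identical(tracks(a), tracks(b))
  cfg2 <- simConfig(cylinderSpec(250), n_cells = 8, seed = 43)
  expect_false(isTRUE(all.equal(tracks(a)$x_um,
                                tracks(simulatePRWTracks(cfg2))$x_um)))
})

test_that("noise-free PRW with zero gain runs perfectly straight", {
  cfg <- simConfig(flatSpec(), n_cells = 1, rot_sigma = 0, curvature_gain = 0,
                   step_cv = 0, speed_mean_umh = 30, speed_sd_umh = 0,
                   duration_h = 2, seed = 7)
  ts <- simulatePRWTracks(cfg)
  st <- tracks(ts)
  steps <- sqrt(diff(st$x_um)^2 + diff(st$y_um)^2)
  expect_equal(steps, rep(30 / 3, 6), tolerance = 1e-12)  # speed * dt
  # heading never changes: displacement directions all identical
  ang <- atan2(diff(st$y_um), diff(st$x_um))
  expect_lt(diff(range(ang)), 1e-12)
})

test_that("drift-free walk with strong rotational noise has uniform step orientations", {
  cfg <- simConfig(flatSpec(), n_cells = 50, curvature_gain = 0,
                   rot_sigma = 40, dt_h = 1 / 3, duration_h = 67,
                   seed = 11)                      # 50 x 201 = 10050 steps
  ts <- simulatePRWTracks(cfg)
  tr <- tracks(ts)
  ang <- unlist(lapply(split(tr, tr$cell_id), function(d) {
    o <- order(d$frame)
    atan2(diff(d$y_um[o]), diff(d$x_um[o]))
  }))
  counts <- table(cut(ang, breaks = seq(-pi, pi, length.out = 13)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("PRW aligned-time fraction matches the stationary heading density", {
  # stationary density p(phi) proportional to exp(c cos 2phi), c = g k / sigma^2
  c_target <- 3
  sigma <- 1.2
  kap <- principalCurvature(cylinderSpec(125))
  gain <- c_target * sigma^2 / kap
  cfg <- simConfig(cylinderSpec(125), n_cells = 40, dt_h = 0.02,
                   duration_h = 24, rot_sigma = sigma, curvature_gain = gain,
                   step_cv = 0, seed = 19)
  ts <- simulatePRWTracks(cfg)
  tr <- tracks(ts)
  ang <- unlist(lapply(split(tr, tr$cell_id), function(d) {
    o <- order(d$frame)
    a <- atan2(abs(diff(d$y_um[o])), abs(diff(d$x_um[o])))
    a[-seq_len(200)]                               # drop burn-in
  }))
  observed <- mean(ang < pi / 6)
  dens <- function(phi) exp(c_target * cos(2 * phi))
  expected <- integrate(dens, 0, pi / 6)$value / integrate(dens, 0, pi / 2)$value
  expect_equal(observed, expected, tolerance = 0.06)
})

test_that("fibroblastic preset outruns and out-aligns the myofibroblastic preset", {
  fib <- phenotypePreset("fibroblastic")
  myo <- phenotypePreset("myofibroblastic")
  expect_gt(fib$speed_mean_umh, myo$speed_mean_umh)
  expect_gt(fib$curvature_gain, myo$curvature_gain)
  sp <- cylinderSpec(125)
  ts_f <- simulatePRWTracks(simConfig(sp, n_cells = 100, preset = "fibroblastic", seed = 21))
  ts_m <- simulatePRWTracks(simConfig(sp, n_cells = 100, preset = "myofibroblastic", seed = 22))
  expect_lt(stats::wilcox.test(meanSpeed(ts_f), meanSpeed(ts_m),
                               alternative = "greater")$p.value, 0.01)
  expect_lt(stats::wilcox.test(alignedFraction(ts_f), alignedFraction(ts_m),
                               alternative = "greater")$p.value, 0.01)
})

test_that("aligned-time fraction increases with curvature at fixed gain", {
  diameters <- c(2000, 1000, 500, 250, 125)
  frac <- vapply(seq_along(diameters), function(i) {
    cfg <- simConfig(cylinderSpec(diameters[i]), n_cells = 120,
                     preset = "fibroblastic", seed = 30 + i)
    mean(alignedFraction(simulatePRWTracks(cfg)))
  }, 1)
  flat_cfg <- simConfig(flatSpec(), n_cells = 120, preset = "fibroblastic",
                        seed = 30)
  frac_flat <- mean(alignedFraction(simulatePRWTracks(flat_cfg)))
  kappas <- 2 / diameters
  # monotone trend over the series, Monte-Carlo tolerance on single steps
  expect_gt(cor(kappas, frac, method = "spearman"), 0.8)
  expect_gt(frac[length(frac)], frac_flat + 0.05)   # strongest curvature wins
  expect_equal(frac_flat, 1 / 3, tolerance = 0.05)  # isotropic baseline
})

test_that("mixture generator recovers the analytic aligned fraction", {
  for (p_band in c(0, 0.3, 0.7, 1)) {
    cfg <- simConfig(cylinderSpec(125), n_cells = 150,
                     seed = 100 + round(100 * p_band))
    ts <- simulateMixtureTracks(p_band, cfg)
    af <- alignedFraction(ts)
    expected <- p_band + (1 - p_band) / 3
    se <- stats::sd(af) / sqrt(length(af))
    expect_lt(abs(mean(af) - expected), max(3 * se, 1e-12))
  }
})

test_that("degenerate mixture probabilities hit their limits exactly", {
  cfg <- simConfig(flatSpec(), n_cells = 5, seed = 3)
  expect_equal(unname(alignedFraction(simulateMixtureTracks(1, cfg))),
               rep(1, 5))
  expect_error(simulateMixtureTracks(1.2, cfg))
})

test_that("shape masks match their generating parameters", {
  # single disk: convex and isotropic
  disk_preset <- phenotypePreset("myofibroblastic")
  disk_preset$shape$axis_ratio_meanlog <- 0
  disk_preset$shape$axis_ratio_sdlog <- 0
  disk_preset$shape$protrusion_amp <- 0
  disk_preset$shape$area_cv <- 0.01
  g <- generateShapeMask(disk_preset, n_objects = 1, canvas_px = c(400, 400),
                         pixel_size_um = 0.25, seed = 5)
  m <- measureShapes(g$mask, min_area_px = 10)
  expect_lt(m$eccentricity, 0.05)
  expect_gt(m$solidity, 0.98)

  # 4:1 ellipse: eccentricity from the axis ratio
  ell_preset <- disk_preset
  ell_preset$shape$axis_ratio_meanlog <- log(4)
  g2 <- generateShapeMask(ell_preset, n_objects = 1, canvas_px = c(400, 400),
                          seed = 6)
  m2 <- measureShapes(g2$mask, min_area_px = 10)
  expect_equal(m2$eccentricity, sqrt(1 - 1 / 16), tolerance = 0.01)

  # star with 4 protrusions: solidity agrees with the independent hull oracle
  star_preset <- disk_preset
  star_preset$shape$n_protrusions <- 4L
  star_preset$shape$protrusion_amp <- 0.35
  g3 <- generateShapeMask(star_preset, n_objects = 1, canvas_px = c(300, 300),
                          seed = 7)
  m3 <- measureShapes(g3$mask, min_area_px = 10)
  expect_lt(m3$solidity, 0.95)
  expect_equal(m3$solidity, oracle_solidity(g3$mask@grid), tolerance = 0.02)
})

test_that("mask generation is seeded, non-overlapping, and fails gracefully", {
  a <- generateShapeMask("fibroblastic", n_objects = 6, seed = 9)
  b <- generateShapeMask("fibroblastic", n_objects = 6, seed = 9)
  expect_identical(a$mask@grid, b$mask@grid)
  expect_identical(sort(unique(as.vector(a$mask@grid))), 0:6)
  expect_equal(nrow(a$truth), 6L)
  expect_error(generateShapeMask("fibroblastic", n_objects = 100,
                                 canvas_px = c(128, 128), seed = 1,
                                 max_tries = 10),
               "could not place")
})

test_that("time-lapse rendering respects the sampling scheme and geometry", {
  cfg <- simConfig(flatSpec(), n_cells = 3, seed = 13)
  ts <- simulatePRWTracks(cfg)
  st <- generateTimelapse(ts, photon_scale = Inf)
  expect_equal(length(st@frames), 67L)          # 22 h / 20 min + 1
  expect_equal(st@times_h, seq(0, 22, by = 1 / 3))

  # noise-free single blob: argmax pixel within 1 px of the truth
  one <- make_track(c(100, 100), c(80, 80), dt_h = 1)
  st1 <- generateTimelapse(one, photon_scale = Inf, pixel_size_um = 2)
  fr <- st1@frames[[1]]
  am <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  x_px <- (100 - st1@origin_um[1]) / 2
  y_px <- (80 - st1@origin_um[2]) / 2
  expect_lt(abs(am["col"] - 0.5 - x_px), 1)
  expect_lt(abs(am["row"] - 0.5 - y_px), 1)

  # empty track table: background-only frames
  empty_ts <- trackSet(data.frame(cell_id = character(0), frame = integer(0),
                                  time_h = numeric(0), x_um = numeric(0),
                                  y_um = numeric(0)))
  st0 <- generateTimelapse(empty_ts, photon_scale = Inf, background = 0.05)
  expect_true(all(vapply(st0@frames, function(f) all(f == 0.05), TRUE)))
})

test_that("time-lapse stacks round-trip through multi-frame TIFF", {
  one <- make_track(c(50, 60, 70), c(40, 40, 40), dt_h = 1 / 3)
  st <- generateTimelapse(one, photon_scale = Inf, pixel_size_um = 2)
  path <- tempfile(fileext = ".tiff")
  norm <- writeTimelapseTIFF(st, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_equal(length(pages), 3L)
  expect_equal(pages[[2]] * norm, st@frames[[2]], tolerance = 1e-6)
})
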