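# Synthetic-data generators: curvature-biased persistent random walks,
# orientation-mixture tracks with analytically known alignment statistics,
# labeled shape masks, and noisy blob time-lapse stacks.

#' Phenotype presets for the synthetic generators
#'
#' Two presets emulate the qualitative contrast between fibroblastic
#' keratocytes (faster migration, stronger curvature coupling, elongated and
#' protrusive shapes) and TGF-beta-induced myofibroblastic keratocytes
#' (slower, weaker coupling, rounder and more convex shapes). The numeric
#' values are configurable modelling placeholders chosen to respect the
#' documented orderings and the 10-80 um/h cohort speed band; they are not
#' measured quantities.
#'
#' @param name \code{"fibroblastic"} or \code{"myofibroblastic"}.
#' @return A list of simulation overrides (\code{speed_mean_umh},
#'   \code{speed_sd_umh}, \code{curvature_gain}, \code{rot_sigma},
#'   \code{step_cv}) plus a \code{shape} sub-list with mask-generation
#'   parameters (area distribution, axis-ratio distribution, protrusion
#'   count and amplitude).
#' @examples
#' phenotypePreset("fibroblastic")$speed_mean_umh
#' @export
phenotypePreset <- function(name = c("fibroblastic", "myofibroblastic")) {
  name <- match.arg(name)
  presets <- list(
    fibroblastic = list(
      name = "fibroblastic",
      speed_mean_umh = 45, speed_sd_umh = 15,
      curvature_gain = 60, rot_sigma = 0.8, step_cv = 0.3,
      shape = list(area_mean_um2 = 1500, area_cv = 0.35,
                   axis_ratio_meanlog = log(3.2), axis_ratio_sdlog = 0.35,
                   n_protrusions = 5L, protrusion_amp = 0.25)),
    myofibroblastic = list(
      name = "myofibroblastic",
      speed_mean_umh = 25, speed_sd_umh = 10,
      curvature_gain = 20, rot_sigma = 0.8, step_cv = 0.3,
      shape = list(area_mean_um2 = 1000, area_cv = 0.3,
                   axis_ratio_meanlog = log(1.7), axis_ratio_sdlog = 0.3,
                   n_protrusions = 3L, protrusion_amp = 0.10))
  )
  presets[[name]]
}

#' Build a simulation configuration
#'
#' Assembles a [SimulationConfig-class] from a phenotype preset (or explicit
#' values). Defaults emulate the study conditions: sampling every 20 min
#' (\code{dt_h = 1/3}) for 22 h (67 time points), per-cell mean speeds drawn
#' from a log-normal truncated to 10-80 um/h.
#'
#' @param surface a [CylinderSpec-class].
#' @param n_cells number of cells in the cohort.
#' @param preset preset name or list from [phenotypePreset()]; \code{NULL}
#'   uses the fibroblastic defaults.
#' @param dt_h sampling interval (h).
#' @param duration_h track duration (h); must be a multiple of \code{dt_h}.
#' @param speed_mean_umh,speed_sd_umh per-cell mean-speed distribution (um/h).
#' @param speed_range_umh truncation band for per-cell mean speeds (um/h).
#' @param step_cv within-cell step-speed coefficient of variation.
#' @param rot_sigma rotational diffusion of the heading (rad per sqrt hour).
#' @param curvature_gain nematic curvature-coupling gain g.
#' @param seed RNG seed (\code{NA} = do not seed).
#' @return A [SimulationConfig-class].
#' @export
simConfig <- function(surface = flatSpec(), n_cells = 30, preset = NULL,
                      dt_h = 1 / 3, duration_h = 22,
                      speed_mean_umh = NULL, speed_sd_umh = NULL,
                      speed_range_umh = c(10, 80),
                      step_cv = NULL, rot_sigma = NULL, curvature_gain = NULL,
                      seed = NA) {
  if (is.character(preset)) preset <- phenotypePreset(preset)
  if (is.null(preset)) preset <- phenotypePreset("fibroblastic")
  pick <- function(explicit, key) if (is.null(explicit)) preset[[key]] else explicit
  new("SimulationConfig",
      surface = surface, n_cells = as.integer(n_cells),
      dt_h = dt_h, duration_h = duration_h,
      speed_mean_umh = pick(speed_mean_umh, "speed_mean_umh"),
      speed_sd_umh = pick(speed_sd_umh, "speed_sd_umh"),
      speed_range_umh = as.numeric(speed_range_umh),
      step_cv = pick(step_cv, "step_cv"),
      rot_sigma = pick(rot_sigma, "rot_sigma"),
      curvature_gain = pick(curvature_gain, "curvature_gain"),
      seed = as.numeric(seed))
}

#' Number of time points implied by a simulation configuration
#' @param config a [SimulationConfig-class].
#' @return \code{round(duration_h / dt_h) + 1}.
#' @export
nTimePoints <- function(config) as.integer(round(config@duration_h / config@dt_h)) + 1L

# Draw per-cell mean speeds from a log-normal (moment-matched to the
# configured mean/sd) truncated to speed_range_umh by inverse-CDF sampling,
# so the RNG stream consumes exactly one draw per cell.
.draw_cell_speeds <- function(config) {
  m <- config@speed_mean_umh; s <- config@speed_sd_umh
  lo <- config@speed_range_umh[1]; hi <- config@speed_range_umh[2]
  if (s == 0) return(rep(min(max(m, lo), hi), config@n_cells))
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  u <- stats::runif(config@n_cells, plo, phi)
  stats::qlnorm(u, meanlog, sdlog)
}

# Per-step speed multipliers: gamma with unit mean and the configured CV,
# renormalized within the cell so the realized mean step speed equals the
# drawn per-cell speed exactly.
.step_multipliers <- function(n_steps, cv) {
  if (cv <= 0) return(rep(1, n_steps))
  shape <- 1 / cv^2
  g <- stats::rgamma(n_steps, shape = shape, rate = shape)
  g / mean(g)
}

.initial_positions <- function(config, n) {
  sp <- config@surface
  half_band <- if (isFlat(sp)) 250 else .radius(sp) * asin(0.8)
  list(x = stats::runif(n, 0, sp@length_um),
       y = stats::runif(n, -half_band, half_band))
}

.assemble_trackset <- function(xs, ys, times, config, generator, extra = list()) {
  n <- length(xs)
  n_pts <- length(times)
  tr <- data.frame(
    cell_id = rep(sprintf("cell%03d", seq_len(n)), each = n_pts),
    frame = rep(seq_len(n_pts) - 1L, times = n),
    time_h = rep(times, times = n),
    x_um = unlist(xs), y_um = unlist(ys))
  trackSet(tr, surface = config@surface, unwrapped = TRUE,
           metadata = c(list(generator = generator,
                             dt_h = config@dt_h,
                             n_cells = config@n_cells,
                             seed = config@seed), extra))
}

#' Simulate curvature-biased persistent random walk tracks
#'
#' Each cell performs a persistent random walk in unwrapped surface
#' coordinates. Per step the heading evolves as
#' \deqn{\varphi \leftarrow \varphi - g\,\kappa\,\sin(2\varphi)\,dt +
#'       \sigma\sqrt{dt}\,\mathcal{N}(0,1),}
#' where \eqn{\kappa} is the principal curvature of the surface (0 on flat),
#' \eqn{g} the curvature gain and \eqn{\sigma} the rotational diffusion.
#' The \eqn{\sin 2\varphi} torque is nematic: both the +x and -x headings
#' are attractors, so cells align with the longitudinal axis without a
#' preferred end. The position advances by the per-step speed along the
#' heading at the start of the step.
#'
#' @param config a [SimulationConfig-class].
#' @return An unwrapped [TrackSet-class] with \code{n_cells} tracks of
#'   \code{nTimePoints(config)} points; bit-reproducible given
#'   \code{config@seed}.
#' @examples
#' ts <- simulatePRWTracks(simConfig(cylinderSpec(125), n_cells = 5, seed = 1))
#' nTracks(ts)
#' @export
simulatePRWTracks <- function(config) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  n_steps <- as.integer(round(config@duration_h / config@dt_h))
  dt <- config@dt_h
  kap <- principalCurvature(config@surface)
  g <- config@curvature_gain
  sig <- config@rot_sigma
  speeds <- .draw_cell_speeds(config)
  pos0 <- .initial_positions(config, config@n_cells)
  xs <- vector("list", config@n_cells); ys <- xs
  for (i in seq_len(config@n_cells)) {
    phi <- stats::runif(1, 0, 2 * pi)
    mult <- .step_multipliers(n_steps, config@step_cv)
    noise <- stats::rnorm(n_steps, 0, sig * sqrt(dt))
    x <- numeric(n_steps + 1L); y <- numeric(n_steps + 1L)
    x[1] <- pos0$x[i]; y[1] <- pos0$y[i]
    for (t in seq_len(n_steps)) {
      step <- speeds[i] * mult[t] * dt
      x[t + 1L] <- x[t] + step * cos(phi)
      y[t + 1L] <- y[t] + step * sin(phi)
      phi <- phi - g * kap * sin(2 * phi) * dt + noise[t]
    }
    xs[[i]] <- x; ys[[i]] <- y
  }
  .assemble_trackset(xs, ys, seq(0, by = dt, length.out = n_steps + 1L),
                     config, "prw",
                     extra = list(curvature_gain = g, rot_sigma = sig))
}

#' Simulate orientation-mixture tracks with known alignment statistics
#'
#' Each step's orientation is drawn independently: with probability
#' \code{p_band} uniformly within 30 degrees of the longitudinal axis
#' (nematically, towards either end); otherwise uniformly over all
#' orientations. The marginal probability that a step is aligned (strictly
#' below 30 degrees) is therefore exactly
#' \code{p_band + (1 - p_band) / 3}, which makes this generator an
#' exact-recovery oracle for the alignment estimator.
#'
#' @param p_band probability of drawing from the aligned band (0..1).
#' @param config a [SimulationConfig-class].
#' @return An unwrapped [TrackSet-class].
#' @export
simulateMixtureTracks <- function(p_band, config) {
  stopifnot(length(p_band) == 1L, p_band >= 0, p_band <= 1)
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  n_steps <- as.integer(round(config@duration_h / config@dt_h))
  dt <- config@dt_h
  speeds <- .draw_cell_speeds(config)
  pos0 <- .initial_positions(config, config@n_cells)
  band <- pi / 6
  xs <- vector("list", config@n_cells); ys <- xs
  for (i in seq_len(config@n_cells)) {
    in_band <- stats::runif(n_steps) < p_band
    ang <- stats::runif(n_steps, 0, 2 * pi)
    flip <- stats::runif(n_steps) < 0.5
    band_ang <- stats::runif(n_steps, -band, band) + ifelse(flip, pi, 0)
    phi <- ifelse(in_band, band_ang, ang)
    mult <- .step_multipliers(n_steps, config@step_cv)
    step <- speeds[i] * mult * dt
    xs[[i]] <- pos0$x[i] + c(0, cumsum(step * cos(phi)))
    ys[[i]] <- pos0$y[i] + c(0, cumsum(step * sin(phi)))
  }
  .assemble_trackset(xs, ys, seq(0, by = dt, length.out = n_steps + 1L),
                     config, "mixture", extra = list(p_band = p_band))
}

# --- Shape masks ------------------------------------------------------------

# Rasterize a star-perturbed ellipse: polar radius
#   r(phi) = r_ellipse(phi) * (1 + amp * cos(k * (phi - phase)))
# in the object frame (semi-axes a >= b, orientation theta). amp = 0, k = 0
# gives a plain ellipse; amp > 0 with k >= 3 carves convexity defects.
.rasterShape <- function(canvas_dim, center_px, a_px, b_px, theta = 0,
                         k = 0L, amp = 0, phase = 0) {
  rmax <- a_px * (1 + amp) + 1
  i0 <- max(1L, floor(center_px[2] - rmax)); i1 <- min(canvas_dim[1], ceiling(center_px[2] + rmax))
  j0 <- max(1L, floor(center_px[1] - rmax)); j1 <- min(canvas_dim[2], ceiling(center_px[1] + rmax))
  if (i0 > i1 || j0 > j1) return(NULL)
  jj <- j0:j1; ii <- i0:i1
  xc <- rep(jj - 0.5, each = length(ii)) - center_px[1]
  yc <- rep(ii - 0.5, times = length(jj)) - center_px[2]
  ct <- cos(theta); st <- sin(theta)
  u <- ct * xc + st * yc
  v <- -st * xc + ct * yc
  phi <- atan2(v / b_px, u / a_px)       # elliptic anomaly
  r_ell <- sqrt((a_px * cos(phi))^2 + (b_px * sin(phi))^2)
  ang <- atan2(v, u)
  r_obj <- r_ell * (1 + amp * cos(k * (ang - phase)))
  inside <- sqrt(u^2 + v^2) <= r_obj
  cbind(row = rep(ii, times = length(jj))[inside],
        col = rep(jj, each = length(ii))[inside])
}

#' Generate a labeled mask of synthetic cell shapes
#'
#' Places non-overlapping star-perturbed ellipses whose axis-ratio, area and
#' protrusion parameters follow the phenotype preset's shape distributions,
#' and returns the integer-labeled mask together with a ground-truth table
#' of each object's generating parameters.
#'
#' @param preset preset name or list from [phenotypePreset()].
#' @param n_objects number of objects to place.
#' @param canvas_px integer(2): mask dimensions (rows, cols).
#' @param pixel_size_um micrometres per pixel.
#' @param seed RNG seed (\code{NA} = do not seed).
#' @param max_tries placement retries per object before failing.
#' @return List with \code{mask} (a [LabeledMask-class]) and \code{truth}
#'   (data.frame: label, centre, semi-axes in um, orientation, protrusion
#'   count/amplitude, rasterized area in px).
#' @export
generateShapeMask <- function(preset = "fibroblastic", n_objects = 10,
                              canvas_px = c(1024L, 1024L), pixel_size_um = 0.5,
                              seed = NA, max_tries = 200L) {
  if (is.character(preset)) preset <- phenotypePreset(preset)
  sh <- preset$shape
  if (!is.na(seed)) set.seed(seed)
  grid <- matrix(0L, canvas_px[1], canvas_px[2])
  placed_c <- matrix(numeric(0), ncol = 2)
  placed_r <- numeric(0)
  truth <- vector("list", n_objects)
  for (lab in seq_len(n_objects)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      area_sdlog <- sqrt(log(1 + sh$area_cv^2))
      area <- stats::rlnorm(1, log(sh$area_mean_um2) - area_sdlog^2 / 2, area_sdlog)
      ratio <- stats::rlnorm(1, sh$axis_ratio_meanlog, sh$axis_ratio_sdlog)
      ratio <- max(ratio, 1)
      b_um <- sqrt(area / (pi * ratio)); a_um <- ratio * b_um
      theta <- stats::runif(1, 0, pi)
      phase <- stats::runif(1, 0, 2 * pi)
      amp <- sh$protrusion_amp; k <- sh$n_protrusions
      a_px <- a_um / pixel_size_um; b_px <- b_um / pixel_size_um
      rad <- a_px * (1 + amp) + 2
      if (2 * (rad + 1) >= min(canvas_px)) next   # cannot fit this draw
      cx <- stats::runif(1, rad + 1, canvas_px[2] - rad - 1)
      cy <- stats::runif(1, rad + 1, canvas_px[1] - rad - 1)
      if (nrow(placed_c) &&
          any(sqrt((placed_c[, 1] - cx)^2 + (placed_c[, 2] - cy)^2) <
              placed_r + rad + 2)) next
      px <- .rasterShape(canvas_px, c(cx, cy), a_px, b_px, theta, k, amp, phase)
      if (is.null(px) || nrow(px) == 0L) next
      grid[px] <- lab
      placed_c <- rbind(placed_c, c(cx, cy))
      placed_r <- c(placed_r, rad)
      truth[[lab]] <- data.frame(
        label = lab, center_x_px = cx, center_y_px = cy,
        a_um = a_um, b_um = b_um, theta_rad = theta,
        n_protrusions = k, protrusion_amp = amp, area_px = nrow(px))
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("could not place object %d within %d tries; reduce n_objects or enlarge canvas",
                   lab, max_tries))
  }
  list(mask = labeledMask(grid, pixel_size_um), truth = do.call(rbind, truth))
}

# --- Time-lapse rendering ---------------------------------------------------

#' Render tracks as a noisy fluorescence time-lapse stack
#'
#' One frame per time point; each cell is drawn as an isotropic Gaussian
#' intensity blob centred on its position, on a constant background, with
#' Poisson shot noise at the given photon scale
#' (\code{counts ~ Pois(photon_scale * intensity) / photon_scale};
#' \code{photon_scale = Inf} disables noise).
#'
#' @param ts a [TrackSet-class] in planar image coordinates (use
#'   [projectTracks()] first for curved surfaces).
#' @param blob_sigma_um Gaussian blob width (um).
#' @param photon_scale photons per intensity unit; larger = less noise.
#' @param pixel_size_um micrometres per pixel.
#' @param background background intensity level.
#' @param canvas_px optional integer(2) frame size (rows, cols); computed
#'   from the track extent plus a 4-sigma margin when \code{NULL}.
#' @param origin_um optional numeric(2) physical position of the frame
#'   corner; computed with the canvas when \code{NULL}.
#' @param seed RNG seed for the shot noise (\code{NA} = do not seed).
#' @return A [TimelapseStack-class].
#' @export
generateTimelapse <- function(ts, blob_sigma_um = 8, photon_scale = 100,
                              pixel_size_um = 2, background = 0.05,
                              canvas_px = NULL, origin_um = NULL, seed = NA) {
  if (!is.na(seed)) set.seed(seed)
  tr <- tracks(ts)
  times <- sort(unique(tr$time_h))
  margin <- 4 * blob_sigma_um
  if (is.null(origin_um)) {
    if (nrow(tr)) {
      origin_um <- c(min(tr$x_um) - margin, min(tr$y_um) - margin)
    } else origin_um <- c(0, 0)
  }
  if (is.null(canvas_px)) {
    if (nrow(tr)) {
      canvas_px <- c(ceiling((max(tr$y_um) + margin - origin_um[2]) / pixel_size_um),
                     ceiling((max(tr$x_um) + margin - origin_um[1]) / pixel_size_um))
    } else canvas_px <- c(64L, 64L)
  }
  if (!length(times)) times <- 0
  xc <- (seq_len(canvas_px[2]) - 0.5) * pixel_size_um + origin_um[1]
  yc <- (seq_len(canvas_px[1]) - 0.5) * pixel_size_um + origin_um[2]
  frames <- lapply(times, function(tm) {
    fr <- matrix(background, canvas_px[1], canvas_px[2])
    pts <- tr[abs(tr$time_h - tm) < 1e-9, , drop = FALSE]
    for (r in seq_len(nrow(pts))) {
      gx <- exp(-(xc - pts$x_um[r])^2 / (2 * blob_sigma_um^2))
      gy <- exp(-(yc - pts$y_um[r])^2 / (2 * blob_sigma_um^2))
      fr <- fr + outer(gy, gx)
    }
    if (is.finite(photon_scale))
      fr <- matrix(stats::rpois(length(fr), photon_scale * fr) / photon_scale,
                   nrow(fr), ncol(fr))
    fr
  })
  new("TimelapseStack", frames = frames, origin_um = as.numeric(origin_um),
      pixel_size_um = pixel_size_um, times_h = as.numeric(times))
}

#' Write a time-lapse stack to a multi-frame TIFF
#'
#' Frames are stored as 32-bit float TIFF pages, normalized to the stack
#' maximum (TIFF sample values live in [0, 1]).
#'
#' @param stack a [TimelapseStack-class].
#' @param path output file path.
#' @return The normalization factor (stack maximum), invisibly.
#' @export
writeTimelapseTIFF <- function(stack, path) {
  mx <- max(1e-12, vapply(stack@frames, max, 1))
  tiff::writeTIFF(lapply(stack@frames, function(f) f / mx), path,
                  bits.per.sample = 32L)
  invisible(mx)
}
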