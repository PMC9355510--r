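#' @import methods
NULL

# ---------------------------------------------------------------------------
# CylinderSpec
# ---------------------------------------------------------------------------

#' Cylinder substrate specification
#'
#' Describes one semi-cylindrical culture structure: its diameter, whether it
#' is groove-like (\code{"concave"}), ridge-like (\code{"convex"}) or a flat
#' control area (\code{"flat"}), its fixed longitudinal length and depth, and
#' the orientation of its longitudinal axis in the image frame. The principal
#' curvature in the circumferential direction is \eqn{\kappa = 2/D}; flat
#' areas have \eqn{\kappa = 0} and their diameter is ignored.
#'
#' Coordinate convention throughout the package: \code{x} runs along the
#' longitudinal axis of the cylinder, \code{y} along the circumferential
#' direction, with the origin of \code{y} at the deepest line of a concave
#' groove. All lengths are in micrometres, all times in hours.
#'
#' @slot diameter_um cylinder diameter in micrometres (\code{NA} for flat).
#' @slot concavity one of \code{"concave"}, \code{"convex"}, \code{"flat"}.
#' @slot length_um longitudinal extent of the structure (default 1000).
#' @slot depth_um depth/height of the structure (default 170).
#' @slot axis_angle_deg orientation of the longitudinal axis in the image
#'   frame, degrees (0 = image x-axis).
#'
#' @seealso [cylinderSpec()], [principalCurvature()], [chordToArc()]
#' @export
setClass("CylinderSpec", slots = c(
  diameter_um   = "numeric",
  concavity     = "character",
  length_um     = "numeric",
  depth_um      = "numeric",
  axis_angle_deg = "numeric"
))

setValidity("CylinderSpec", function(object) {
  msg <- character()
  if (length(object@concavity) != 1L ||
      !object@concavity %in% c("concave", "convex", "flat"))
    msg <- c(msg, "concavity must be one of 'concave', 'convex', 'flat'")
  if (!identical(object@concavity, "flat")) {
    d <- object@diameter_um
    if (length(d) != 1L || !is.finite(d) || d <= 0)
      msg <- c(msg, "non-flat cylinder specs require a single positive finite diameter_um")
  }
  if (length(object@length_um) != 1L || object@length_um <= 0)
    msg <- c(msg, "length_um must be a single positive number")
  if (length(object@depth_um) != 1L || object@depth_um <= 0)
    msg <- c(msg, "depth_um must be a single positive number")
  if (length(object@axis_angle_deg) != 1L || !is.finite(object@axis_angle_deg))
    msg <- c(msg, "axis_angle_deg must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a cylinder substrate specification
#'
#' @param diameter_um cylinder diameter in micrometres; ignored (may be
#'   \code{NA}) when \code{concavity = "flat"}.
#' @param concavity \code{"concave"}, \code{"convex"} or \code{"flat"}.
#' @param length_um longitudinal length of the structure (micrometres).
#' @param depth_um depth/height of the structure (micrometres).
#' @param axis_angle_deg orientation of the longitudinal axis in the image
#'   frame (degrees).
#'
#' @return A [CylinderSpec-class] object.
#' @examples
#' cylinderSpec(125)                  # concave, D = 125 um
#' cylinderSpec(concavity = "flat")   # flat control area
#' @export
cylinderSpec <- function(diameter_um = NA_real_,
                         concavity = c("concave", "convex", "flat"),
                         length_um = 1000, depth_um = 170,
                         axis_angle_deg = 0) {
  concavity <- match.arg(concavity)
  if (identical(concavity, "flat")) diameter_um <- NA_real_
  new("CylinderSpec",
      diameter_um = as.numeric(diameter_um), concavity = concavity,
      length_um = as.numeric(length_um), depth_um = as.numeric(depth_um),
      axis_angle_deg = as.numeric(axis_angle_deg))
}

#' Flat control-surface specification
#'
#' Convenience constructor for the flat areas of a curvature chip
#' (\eqn{\kappa = 0}).
#'
#' @inheritParams cylinderSpec
#' @return A flat [CylinderSpec-class].
#' @export
flatSpec <- function(length_um = 1000, axis_angle_deg = 0) {
  cylinderSpec(concavity = "flat", length_um = length_um,
               axis_angle_deg = axis_angle_deg)
}

setMethod("show", "CylinderSpec", function(object) {
  if (isFlat(object)) {
    cat("CylinderSpec: flat control area (kappa = 0)\n")
  } else {
    cat(sprintf("CylinderSpec: %s cylinder, D = %g um (kappa = %g um^-1)\n",
                object@concavity, object@diameter_um,
                principalCurvature(object)))
  }
  cat(sprintf("  length = %g um, depth = %g um, axis angle = %g deg\n",
              object@length_um, object@depth_um, object@axis_angle_deg))
})

# ---------------------------------------------------------------------------
# TrackSet
# ---------------------------------------------------------------------------

.track_columns <- c("cell_id", "frame", "time_h", "x_um", "y_um")

#' Set of cell migration tracks
#'
#' Time-ordered centroid positions for a cohort of cells on one substrate,
#' stored as a long-format table with one row per cell per time point,
#' together with the [CylinderSpec-class] of the surface and a flag recording
#' whether the \code{y} coordinate is an unwrapped arc length (planar surface
#' coordinates) or a projected chord coordinate.
#'
#' @slot tracks \code{data.frame} with columns \code{cell_id}, \code{frame},
#'   \code{time_h}, \code{x_um}, \code{y_um} (additional columns preserved).
#' @slot surface the [CylinderSpec-class] the cells migrated on.
#' @slot unwrapped \code{TRUE} when \code{y_um} is arc length on the surface.
#' @slot metadata free-form list (phenotype, generator parameters, ...).
#'
#' @seealso [trackSet()], [unwrapTracks()], [migrationSummary()]
#' @export
setClass("TrackSet", slots = c(
  tracks    = "data.frame",
  surface   = "CylinderSpec",
  unwrapped = "logical",
  metadata  = "list"
))

setValidity("TrackSet", function(object) {
  tr <- object@tracks
  msg <- character()
  miss <- setdiff(.track_columns, names(tr))
  if (length(miss))
    return(paste("tracks is missing column(s):", paste(miss, collapse = ", ")))
  for (col in c("frame", "time_h", "x_um", "y_um"))
    if (!is.numeric(tr[[col]]))
      msg <- c(msg, sprintf("column '%s' must be numeric", col))
  if (length(msg)) return(msg)
  if (nrow(tr)) {
    by_cell <- split(tr, tr$cell_id)
    n_pts <- vapply(by_cell, nrow, 1L)
    if (any(n_pts < 2L))
      msg <- c(msg, "every track needs at least 2 time points")
    dts <- unlist(lapply(by_cell, function(d) diff(d$time_h[order(d$frame)])))
    if (any(dts <= 0))
      msg <- c(msg, "time_h must be strictly increasing within each track")
    else if (diff(range(dts)) > 1e-6)
      msg <- c(msg, "sampling interval must be uniform across the set (tolerance 1e-6 h)")
  }
  if (length(object@unwrapped) != 1L || is.na(object@unwrapped))
    msg <- c(msg, "unwrapped must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a TrackSet
#'
#' @param tracks data.frame with columns \code{cell_id}, \code{frame},
#'   \code{time_h}, \code{x_um}, \code{y_um}.
#' @param surface a [CylinderSpec-class]; defaults to a flat area.
#' @param unwrapped whether \code{y_um} is already an unwrapped arc length.
#' @param metadata list of free-form annotations.
#' @return A [TrackSet-class].
#' @export
trackSet <- function(tracks, surface = flatSpec(), unwrapped = FALSE,
                     metadata = list()) {
  tracks <- as.data.frame(tracks)
  o <- order(tracks$cell_id, tracks$frame)
  new("TrackSet", tracks = tracks[o, , drop = FALSE], surface = surface,
      unwrapped = isTRUE(unwrapped), metadata = metadata)
}

setMethod("show", "TrackSet", function(object) {
  tr <- object@tracks
  n <- length(unique(tr$cell_id))
  cat(sprintf("TrackSet: %d track(s), %d points, %s coordinates\n",
              n, nrow(tr),
              if (object@unwrapped) "unwrapped (arc-length)" else "projected (chord)"))
  show(object@surface)
  if (!is.null(object@metadata$phenotype))
    cat(sprintf("  phenotype: %s\n", object@metadata$phenotype))
})

# ---------------------------------------------------------------------------
# MSDCurve
# ---------------------------------------------------------------------------

#' Ensemble mean-squared displacement curve
#'
#' Lag times, ensemble-averaged squared displacements, the number of
#' displacement pairs contributing to each lag, and (after
#' [fitMSDExponent()]) the fitted power-law exponent \eqn{\alpha} of
#' \eqn{MSD \propto \Delta t^\alpha} with the lag window used for the fit.
#'
#' @slot lags_h lag times (hours), starting at 0.
#' @slot msd_um2 ensemble MSD per lag (\eqn{\mu m^2}); \code{msd_um2[1] = 0}.
#' @slot n_pairs displacement pairs per lag.
#' @slot alpha fitted log-log slope (\code{NA} until fitted).
#' @slot fit_window_h numeric(2), lag bounds used for the fit.
#' @seealso [ensembleMSD()], [fitMSDExponent()]
#' @export
setClass("MSDCurve", slots = c(
  lags_h       = "numeric",
  msd_um2      = "numeric",
  n_pairs      = "numeric",
  alpha        = "numeric",
  fit_window_h = "numeric"
))

setValidity("MSDCurve", function(object) {
  msg <- character()
  if (length(object@lags_h) != length(object@msd_um2) ||
      length(object@lags_h) != length(object@n_pairs))
    msg <- c(msg, "lags_h, msd_um2 and n_pairs must have equal length")
  if (any(object@msd_um2 < 0, na.rm = TRUE))
    msg <- c(msg, "msd_um2 must be non-negative")
  if (is.unsorted(object@lags_h))
    msg <- c(msg, "lags_h must be sorted increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MSDCurve", function(object) {
  cat(sprintf("MSDCurve: %d lag(s), max lag %.3g h", length(object@lags_h),
              max(object@lags_h)))
  if (!is.na(object@alpha))
    cat(sprintf(", alpha = %.3f over [%.3g, %.3g] h",
                object@alpha, object@fit_window_h[1], object@fit_window_h[2]))
  cat("\n")
})

# ---------------------------------------------------------------------------
# LabeledMask
# ---------------------------------------------------------------------------

#' Integer-labeled segmentation mask
#'
#' A 2D grid in which 0 marks background and each positive integer k marks
#' the pixels of object k, together with the physical pixel size. Rows index
#' the y direction and columns the x direction; the centre of pixel
#' \code{[i, j]} sits at \code{((j - 0.5), (i - 0.5)) * pixel_size_um}.
#'
#' @slot grid integer matrix of labels.
#' @slot pixel_size_um micrometres per pixel (> 0).
#' @seealso [measureShapes()], [generateShapeMask()]
#' @export
setClass("LabeledMask", slots = c(grid = "matrix", pixel_size_um = "numeric"))

setValidity("LabeledMask", function(object) {
  g <- object@grid
  msg <- character()
  if (!is.numeric(g) || any(g < 0) || any(g != round(g)))
    msg <- c(msg, "grid must contain non-negative integer labels")
  if (length(object@pixel_size_um) != 1L || !is.finite(object@pixel_size_um) ||
      object@pixel_size_um <= 0)
    msg <- c(msg, "pixel_size_um must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledMask
#' @param grid matrix of non-negative integer labels (0 = background).
#' @param pixel_size_um micrometres per pixel.
#' @return A [LabeledMask-class].
#' @export
labeledMask <- function(grid, pixel_size_um = 1) {
  storage.mode(grid) <- "integer"
  new("LabeledMask", grid = grid, pixel_size_um = as.numeric(pixel_size_um))
}

setMethod("show", "LabeledMask", function(object) {
  labs <- setdiff(unique(as.vector(object@grid)), 0L)
  cat(sprintf("LabeledMask: %d x %d px (%g um/px), %d object(s)\n",
              nrow(object@grid), ncol(object@grid), object@pixel_size_um,
              length(labs)))
})

# ---------------------------------------------------------------------------
# SimulationConfig
# ---------------------------------------------------------------------------

#' Configuration of a synthetic migration cohort
#'
#' Parameters of the curvature-biased persistent random walk used to emulate
#' tracked-cell data: the substrate, cohort size, the 20-min/22-h default
#' sampling scheme, the per-cell mean-speed distribution (truncated
#' log-normal), within-cell step-speed variability, rotational diffusion of
#' the heading and the nematic curvature-coupling gain.
#'
#' @slot surface [CylinderSpec-class] of the substrate.
#' @slot n_cells number of cells.
#' @slot dt_h sampling interval (hours; default 1/3 = 20 min).
#' @slot duration_h track duration (hours; default 22, i.e. 67 time points).
#' @slot speed_mean_umh mean of the per-cell mean-speed distribution (um/h).
#' @slot speed_sd_umh sd of the per-cell mean-speed distribution (um/h).
#' @slot speed_range_umh numeric(2) truncation band for per-cell speeds.
#' @slot step_cv coefficient of variation of within-cell step speeds.
#' @slot rot_sigma rotational diffusion of the heading (rad per sqrt hour).
#' @slot curvature_gain nematic alignment gain g; the heading drifts by
#'   \eqn{-g\,\kappa\,\sin(2\varphi)\,dt} per step.
#' @slot seed RNG seed (\code{NA} = do not seed).
#' @seealso [simConfig()], [simulatePRWTracks()]
#' @export
setClass("SimulationConfig", slots = c(
  surface        = "CylinderSpec",
  n_cells        = "integer",
  dt_h           = "numeric",
  duration_h     = "numeric",
  speed_mean_umh = "numeric",
  speed_sd_umh   = "numeric",
  speed_range_umh = "numeric",
  step_cv        = "numeric",
  rot_sigma      = "numeric",
  curvature_gain = "numeric",
  seed           = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n_cells < 1L) msg <- c(msg, "n_cells must be >= 1")
  if (object@dt_h <= 0) msg <- c(msg, "dt_h must be positive")
  if (object@duration_h <= 0) msg <- c(msg, "duration_h must be positive")
  steps <- object@duration_h / object@dt_h
  if (abs(steps - round(steps)) > 1e-8)
    msg <- c(msg, "duration_h must be an integer multiple of dt_h")
  if (object@speed_mean_umh <= 0 || object@speed_sd_umh < 0)
    msg <- c(msg, "speed_mean_umh must be positive and speed_sd_umh non-negative")
  if (length(object@speed_range_umh) != 2L ||
      diff(object@speed_range_umh) <= 0 || object@speed_range_umh[1] < 0)
    msg <- c(msg, "speed_range_umh must be an increasing non-negative pair")
  if (object@step_cv < 0) msg <- c(msg, "step_cv must be non-negative")
  if (object@rot_sigma < 0) msg <- c(msg, "rot_sigma must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d cell(s), dt = %.4g h, duration = %g h ",
                     "(%d time points)\n"),
              object@n_cells, object@dt_h, object@duration_h, nTimePoints(object)))
  cat(sprintf("  speed ~ lognormal(mean %g, sd %g) um/h truncated to [%g, %g]\n",
              object@speed_mean_umh, object@speed_sd_umh,
              object@speed_range_umh[1], object@speed_range_umh[2]))
  cat(sprintf("  step_cv = %g, rot_sigma = %g rad/sqrt(h), curvature_gain = %g\n",
              object@step_cv, object@rot_sigma, object@curvature_gain))
  show(object@surface)
})

# ---------------------------------------------------------------------------
# TimelapseStack
# ---------------------------------------------------------------------------

#' Synthetic fluorescence time-lapse stack
#'
#' One single-channel frame per time point, with the physical position of the
#' frame origin so detections can be mapped back to surface coordinates.
#'
#' @slot frames list of numeric matrices (rows = y, cols = x).
#' @slot origin_um numeric(2): surface coordinates (x, y) of the outer corner
#'   of pixel \code{[1, 1]}.
#' @slot pixel_size_um micrometres per pixel.
#' @slot times_h frame acquisition times (hours).
#' @seealso [generateTimelapse()], [trackTimelapse()]
#' @export
setClass("TimelapseStack", slots = c(
  frames        = "list",
  origin_um     = "numeric",
  pixel_size_um = "numeric",
  times_h       = "numeric"
))

setValidity("TimelapseStack", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@times_h))
    msg <- c(msg, "one acquisition time per frame is required")
  if (length(object@frames) && is.unsorted(object@times_h, strictly = TRUE))
    msg <- c(msg, "times_h must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TimelapseStack", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1]]) else c(0L, 0L)
  cat(sprintf("TimelapseStack: %d frame(s) of %d x %d px (%g um/px)\n",
              length(object@frames), d[1], d[2], object@pixel_size_um))
})

# ---------------------------------------------------------------------------
# StatsResult
# ---------------------------------------------------------------------------

#' Nonparametric group-comparison result
#'
#' Bundles the tie-corrected Kruskal-Wallis omnibus test with the Dunn
#' pairwise post-hoc table (Benjamini-Hochberg adjusted) for one metric.
#'
#' @slot metric name of the compared metric.
#' @slot H Kruskal-Wallis statistic (tie-corrected).
#' @slot df degrees of freedom (groups - 1).
#' @slot p_omnibus chi-square p-value of the omnibus test.
#' @slot pairwise data.frame: group1, group2, z, p_raw, p_adj, stars.
#' @seealso [groupStats()], [kruskalWallis()], [dunnBH()]
#' @export
setClass("StatsResult", slots = c(
  metric    = "character",
  H         = "numeric",
  df        = "integer",
  p_omnibus = "numeric",
  pairwise  = "data.frame"
))

setMethod("show", "StatsResult", function(object) {
  cat(sprintf("StatsResult [%s]: Kruskal-Wallis H = %.4g, df = %d, p = %.3g\n",
              object@metric, object@H, object@df, object@p_omnibus))
  cat(sprintf("  %d pairwise Dunn comparison(s), BH-adjusted:\n",
              nrow(object@pairwise)))
  print(utils::head(object@pairwise, 10L))
})
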