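# Per-cell and cohort migration statistics on unwrapped tracks: speed,
# directionality index dx/dy, ensemble MSD and power-law exponent,
# 30-degree alignment classification and derived fractions/ratios.

# Step table for one ordered track data.frame: one row per step.
.steps_of <- function(d) {
  o <- order(d$frame)
  dt <- diff(d$time_h[o])
  dx <- diff(d$x_um[o])
  dy <- diff(d$y_um[o])
  len <- sqrt(dx^2 + dy^2)
  data.frame(dt_h = dt, dx_um = dx, dy_um = dy, len_um = len,
             speed_umh = len / dt,
             orientation_deg = atan2(abs(dy), abs(dx)) * 180 / pi)
}

.per_cell <- function(ts, fun, ...) {
  by_cell <- split(tracks(ts), tracks(ts)$cell_id)
  vapply(by_cell, function(d) fun(.steps_of(d), d, ...), numeric(1))
}

#' @rdname meanSpeed
#' @export
setMethod("meanSpeed", "TrackSet", function(x, ...) {
  .per_cell(x, function(st, d) mean(st$speed_umh))
})

#' Directionality index dx/dy
#'
#' For each cell, \code{dx} is the maximum absolute displacement from the
#' starting position along the longitudinal axis, \code{dy} the same along
#' the circumferential axis, and the directionality index is
#' \code{dx / max(dy, dy_floor_um)}. An index near 1 indicates randomly
#' oriented migration; values above 1 indicate migration biased along the
#' cylinder axis. With \code{mode = "range"} the coordinate range
#' (max - min) is used instead of displacement-from-origin.
#'
#' @param ts an unwrapped [TrackSet-class].
#' @param dy_floor_um floor applied to \code{dy} to avoid division by zero
#'   on perfectly axial tracks (default 1 um).
#' @param mode \code{"origin"} (displacement from the starting point,
#'   default) or \code{"range"}.
#' @return data.frame: \code{cell_id}, \code{dx_um}, \code{dy_um},
#'   \code{directionality}.
#' @export
directionalityIndex <- function(ts, dy_floor_um = 1,
                                mode = c("origin", "range")) {
  mode <- match.arg(mode)
  by_cell <- split(tracks(ts), tracks(ts)$cell_id)
  res <- lapply(names(by_cell), function(id) {
    d <- by_cell[[id]]
    o <- order(d$frame)
    x <- d$x_um[o]; y <- d$y_um[o]
    if (mode == "origin") {
      dx <- max(abs(x - x[1])); dy <- max(abs(y - y[1]))
    } else {
      dx <- diff(range(x)); dy <- diff(range(y))
    }
    data.frame(cell_id = id, dx_um = dx, dy_um = dy,
               directionality = dx / max(dy, dy_floor_um))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of time spent migrating aligned with the cylinder axis
#'
#' A step is "aligned" when the orientation of the step vector relative to
#' the longitudinal axis, \code{atan(|dy|/|dx|)} in [0, 90] degrees, is
#' strictly below the threshold (default 30 degrees). The classification is
#' nematic: reversing either axis leaves it unchanged. Steps shorter than
#' \code{min_step_um} have no defined orientation and are excluded from
#' both numerator and denominator.
#'
#' @param ts an unwrapped [TrackSet-class].
#' @param threshold_deg alignment threshold in degrees, in (0, 90).
#' @param min_step_um minimum step length with a defined orientation.
#' @return Named numeric vector of per-cell fractions (NA when a cell
#'   retains no steps).
#' @export
alignedFraction <- function(ts, threshold_deg = 30, min_step_um = 1e-3) {
  stopifnot(threshold_deg > 0, threshold_deg < 90)
  .per_cell(ts, function(st, d) {
    st <- st[st$len_um >= min_step_um, , drop = FALSE]
    if (!nrow(st)) return(NA_real_)
    mean(st$orientation_deg < threshold_deg)
  })
}

#' Ratio of migration speed while aligned vs non-aligned
#'
#' Mean step speed over aligned steps divided by mean step speed over
#' non-aligned steps (classification as in [alignedFraction()]); \code{NA}
#' when either class is empty. A ratio near 1 means cells move equally fast
#' whether or not they follow the cylinder axis.
#'
#' @inheritParams alignedFraction
#' @return Named numeric vector of per-cell ratios.
#' @export
alignedSpeedRatio <- function(ts, threshold_deg = 30, min_step_um = 1e-3) {
  stopifnot(threshold_deg > 0, threshold_deg < 90)
  .per_cell(ts, function(st, d) {
    st <- st[st$len_um >= min_step_um, , drop = FALSE]
    al <- st$orientation_deg < threshold_deg
    if (!any(al) || all(al)) return(NA_real_)
    mean(st$speed_umh[al]) / mean(st$speed_umh[!al])
  })
}

#' Ensemble mean-squared displacement
#'
#' For each lag \eqn{k\,dt} the MSD is the mean of
#' \eqn{|r(t + k\,dt) - r(t)|^2} over all overlapping ordered pairs, pooled
#' across all tracks (\code{mode = "pooled"}, default) or averaged per cell
#' first and then over cells (\code{mode = "percell"}). The pooled curve
#' equals the pair-count-weighted mean of the per-track curves.
#'
#' @param ts a [TrackSet-class] with a common sampling interval.
#' @param mode pooling mode, see above.
#' @param max_lag_h largest lag to evaluate (default: longest track).
#' @return A [MSDCurve-class] (alpha unset; see [fitMSDExponent()]).
#' @export
ensembleMSD <- function(ts, mode = c("pooled", "percell"), max_lag_h = Inf) {
  mode <- match.arg(mode)
  dt <- samplingInterval(ts)
  by_cell <- split(tracks(ts), tracks(ts)$cell_id)
  if (!length(by_cell)) stop("ensembleMSD needs at least one track")
  max_pts <- max(vapply(by_cell, nrow, 1L))
  kmax <- min(max_pts - 1L, floor(max_lag_h / dt + 1e-9))
  sums <- numeric(kmax); counts <- numeric(kmax)
  pc_sum <- numeric(kmax); pc_n <- numeric(kmax)
  for (d in by_cell) {
    o <- order(d$frame)
    x <- d$x_um[o]; y <- d$y_um[o]
    n <- length(x)
    for (k in seq_len(min(kmax, n - 1L))) {
      sq <- (x[(1 + k):n] - x[1:(n - k)])^2 + (y[(1 + k):n] - y[1:(n - k)])^2
      sums[k] <- sums[k] + sum(sq)
      counts[k] <- counts[k] + length(sq)
      pc_sum[k] <- pc_sum[k] + mean(sq)
      pc_n[k] <- pc_n[k] + 1
    }
  }
  have <- counts > 0
  msd <- if (mode == "pooled") sums[have] / counts[have] else pc_sum[have] / pc_n[have]
  new("MSDCurve",
      lags_h = c(0, (seq_len(kmax)[have]) * dt),
      msd_um2 = c(0, msd),
      n_pairs = c(0, counts[have]),
      alpha = NA_real_, fit_window_h = c(NA_real_, NA_real_))
}

#' Fit the MSD power-law exponent
#'
#' Ordinary least-squares slope of \code{log(MSD)} against
#' \code{log(lag)} over a lag window, excluding lag 0. The default window
#' runs from the first positive lag up to 5 h, the short-interval regime in
#' which migrating cells show power-law behaviour
#' (\eqn{\alpha = 1} diffusive, \eqn{\alpha > 1} persistent,
#' \eqn{\alpha = 2} ballistic).
#'
#' @param curve a [MSDCurve-class].
#' @param window numeric(2) lag bounds in hours; \code{NA} lower bound means
#'   the smallest positive lag.
#' @return The curve with \code{alpha} and \code{fit_window_h} filled in;
#'   extract the exponent with [msdAlpha()].
#' @export
fitMSDExponent <- function(curve, window = c(NA, 5)) {
  lo <- window[1]; hi <- window[2]
  pos <- curve@lags_h > 0 & curve@msd_um2 > 0
  if (is.na(lo)) lo <- min(curve@lags_h[pos])
  if (is.na(hi)) hi <- max(curve@lags_h[pos])
  use <- pos & curve@lags_h >= lo - 1e-9 & curve@lags_h <= hi + 1e-9
  if (sum(use) < 3L)
    stop("fitMSDExponent needs at least 3 positive-MSD lags inside the window")
  fit <- stats::lm(log(curve@msd_um2[use]) ~ log(curve@lags_h[use]))
  curve@alpha <- unname(stats::coef(fit)[2])
  curve@fit_window_h <- c(lo, hi)
  curve
}

#' @rdname fitMSDExponent
#' @export
setMethod("msdAlpha", "MSDCurve", function(curve) curve@alpha)

#' @rdname ensembleMSD
#' @param curve a [MSDCurve-class].
#' @export
setMethod("msdTable", "MSDCurve", function(curve) {
  data.frame(lag_h = curve@lags_h, msd_um2 = curve@msd_um2,
             n_pairs = curve@n_pairs)
})

#' Per-cell migration summary table
#'
#' One row per cell with the full migration phenotype: mean speed,
#' maximum longitudinal/circumferential displacements and their ratio
#' (directionality index), aligned-time fraction and aligned/non-aligned
#' speed ratio, plus the surface and phenotype labels carried by the track
#' set.
#'
#' @param ts an unwrapped [TrackSet-class].
#' @param threshold_deg alignment threshold (degrees).
#' @param min_step_um minimum step length for orientation classification.
#' @param dy_floor_um floor for the directionality denominator.
#' @param dxdy_mode \code{"origin"} or \code{"range"}, see
#'   [directionalityIndex()].
#' @return data.frame with columns \code{cell_id}, \code{phenotype},
#'   \code{concavity}, \code{diameter_um}, \code{n_steps},
#'   \code{mean_speed_umh}, \code{dx_um}, \code{dy_um},
#'   \code{directionality}, \code{aligned_fraction},
#'   \code{aligned_speed_ratio}.
#' @export
migrationSummary <- function(ts, threshold_deg = 30, min_step_um = 1e-3,
                             dy_floor_um = 1,
                             dxdy_mode = c("origin", "range")) {
  if (!isUnwrapped(ts))
    warning("tracks are not unwrapped; metrics assume planar surface coordinates")
  di <- directionalityIndex(ts, dy_floor_um = dy_floor_um,
                            mode = match.arg(dxdy_mode))
  sp <- meanSpeed(ts)
  af <- alignedFraction(ts, threshold_deg, min_step_um)
  ar <- alignedSpeedRatio(ts, threshold_deg, min_step_um)
  ns <- vapply(split(tracks(ts), tracks(ts)$cell_id), nrow, 1L) - 1L
  sp_df <- data.frame(cell_id = names(sp), mean_speed_umh = unname(sp),
                      aligned_fraction = unname(af[names(sp)]),
                      aligned_speed_ratio = unname(ar[names(sp)]),
                      n_steps = unname(ns[names(sp)]))
  out <- merge(di, sp_df, by = "cell_id", sort = TRUE)
  surf <- surface(ts)
  out$phenotype <- if (is.null(ts@metadata$phenotype)) NA_character_ else ts@metadata$phenotype
  out$concavity <- surf@concavity
  out$diameter_um <- surf@diameter_um
  out[, c("cell_id", "phenotype", "concavity", "diameter_um", "n_steps",
          "mean_speed_umh", "dx_um", "dy_um", "directionality",
          "aligned_fraction", "aligned_speed_ratio")]
}
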