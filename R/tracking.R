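# Blob detection and greedy nearest-neighbour track linking for synthetic
# movies (automated replacement for manual centroid clicking).

#' Detect blob centroids in a single frame
#'
#' Thresholds the frame (Otsu by default), labels connected components
#' (EBImage) and returns the intensity-weighted centroid of each component
#' in physical coordinates.
#'
#' @param frame numeric matrix (rows = y, cols = x).
#' @param pixel_size_um micrometres per pixel.
#' @param origin_um numeric(2) physical position of the frame corner.
#' @param threshold \code{"otsu"} or a fixed numeric intensity threshold.
#' @param min_area_px discard components smaller than this.
#' @return data.frame: \code{x_um}, \code{y_um}, \code{intensity} (summed
#'   above-background intensity), \code{n_px}. Empty for blank frames.
#' @export
detectCentroids <- function(frame, pixel_size_um = 1, origin_um = c(0, 0),
                            threshold = "otsu", min_area_px = 4L) {
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), n_px = integer(0))
  rng <- range(frame)
  if (!is.finite(diff(rng)) || diff(rng) == 0) return(empty)
  thr <- if (is.numeric(threshold)) {
    threshold
  } else {
    norm <- (frame - rng[1]) / diff(rng)
    rng[1] + EBImage::otsu(EBImage::Image(norm)) * diff(rng)
  }
  bw <- frame > thr
  if (!any(bw)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  idx <- which(lab > 0)
  rows <- ((idx - 1L) %% nrow(frame)) + 1L
  cols <- ((idx - 1L) %/% nrow(frame)) + 1L
  w <- frame[idx]
  comp <- as.integer(lab[idx])
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_area_px)
  if (!length(keep)) return(empty)
  res <- do.call(rbind, lapply(keep, function(k) {
    sel <- comp == k
    wi <- w[sel]
    data.frame(
      x_um = origin_um[1] + (sum((cols[sel] - 0.5) * wi) / sum(wi)) * pixel_size_um,
      y_um = origin_um[2] + (sum((rows[sel] - 0.5) * wi) / sum(wi)) * pixel_size_um,
      intensity = sum(wi), n_px = sum(sel))
  }))
  rownames(res) <- NULL
  res
}

#' Link per-frame detections into tracks
#'
#' Frame-by-frame greedy assignment: candidate (active track, new
#' detection) pairs are taken in ascending distance order; pairs beyond
#' \code{gate_um} are never matched. Unmatched active tracks terminate (no
#' gap closing), unmatched detections start new tracks. Deterministic and
#' adequate in the low-density regime; see the optimal-assignment
#' comparison in the package tests for its deviation behaviour.
#'
#' @param detections list of data.frames (one per frame, columns
#'   \code{x_um}, \code{y_um}), e.g. from [detectCentroids()].
#' @param times_h frame times (hours), same length as \code{detections}.
#' @param gate_um maximum allowed per-step displacement (um).
#' @param surface [CylinderSpec-class] to attach to the output.
#' @param unwrapped whether the detection coordinates are already unwrapped.
#' @param min_frames tracks shorter than this many frames are dropped
#'   (default 10; short tracks destabilize MSD and directionality).
#' @return A [TrackSet-class].
#' @export
linkTracks <- function(detections, times_h, gate_um, surface = flatSpec(),
                       unwrapped = FALSE, min_frames = 10L) {
  stopifnot(gate_um > 0, length(detections) == length(times_h))
  next_id <- 1L
  active <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  rows <- list()
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    n_new <- if (is.null(det)) 0L else nrow(det)
    matched_new <- rep(FALSE, n_new)
    matched_old <- rep(FALSE, nrow(active))
    assign_id <- integer(n_new)
    if (n_new && nrow(active)) {
      d <- outer(active$x, det$x_um, "-")^2 + outer(active$y, det$y_um, "-")^2
      ord <- order(d)
      for (o in ord) {
        if (d[o] > gate_um^2) break
        i <- ((o - 1L) %% nrow(d)) + 1L
        j <- ((o - 1L) %/% nrow(d)) + 1L
        if (matched_old[i] || matched_new[j]) next
        matched_old[i] <- TRUE
        matched_new[j] <- TRUE
        assign_id[j] <- active$id[i]
      }
    }
    if (n_new) {
      for (j in which(!matched_new)) {
        assign_id[j] <- next_id
        next_id <- next_id + 1L
      }
      rows[[f]] <- data.frame(cell_id = assign_id, frame = f - 1L,
                              time_h = times_h[f],
                              x_um = det$x_um, y_um = det$y_um)
      active <- data.frame(id = assign_id, x = det$x_um, y = det$y_um)
    } else {
      active <- active[0, , drop = FALSE]
    }
  }
  tr <- do.call(rbind, rows)
  if (is.null(tr)) tr <- data.frame(cell_id = integer(0), frame = integer(0),
                                    time_h = numeric(0), x_um = numeric(0),
                                    y_um = numeric(0))
  keep <- names(which(table(tr$cell_id) >= max(2L, min_frames)))
  tr <- tr[tr$cell_id %in% as.integer(keep), , drop = FALSE]
  tr$cell_id <- sprintf("track%03d", as.integer(factor(tr$cell_id)))
  trackSet(tr, surface = surface, unwrapped = unwrapped,
           metadata = list(generator = "linker", gate_um = gate_um))
}

#' Detect and link a whole time-lapse stack
#'
#' Convenience wrapper: [detectCentroids()] on every frame of a
#' [TimelapseStack-class], then [linkTracks()]. The default gate corresponds
#' to 100 um/h at the stack's sampling interval, about 25 percent above the
#' fastest expected cells.
#'
#' @param stack a [TimelapseStack-class].
#' @param gate_um linking gate (um); default \code{100 * dt}.
#' @param surface [CylinderSpec-class] for the output tracks.
#' @param unwrapped whether stack coordinates are already unwrapped.
#' @param threshold,min_area_px passed to [detectCentroids()].
#' @param min_frames passed to [linkTracks()].
#' @return A [TrackSet-class].
#' @export
trackTimelapse <- function(stack, gate_um = NULL, surface = flatSpec(),
                           unwrapped = FALSE, threshold = "otsu",
                           min_area_px = 4L, min_frames = 10L) {
  dt <- if (length(stack@times_h) > 1L) stats::median(diff(stack@times_h)) else 1 / 3
  if (is.null(gate_um)) gate_um <- 100 * dt
  dets <- lapply(stack@frames, detectCentroids,
                 pixel_size_um = stack@pixel_size_um,
                 origin_um = stack@origin_um,
                 threshold = threshold, min_area_px = min_area_px)
  linkTracks(dets, stack@times_h, gate_um, surface = surface,
             unwrapped = unwrapped, min_frames = min_frames)
}
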