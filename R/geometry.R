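# Cylinder geometry: principal curvature and chord <-> arc remapping.
#
# A maximum-intensity projection of a cylinder maps the surface point at
# azimuth theta (theta = 0 at the deepest/lowest line) to the chord
# coordinate y_chord = R sin(theta); the unwrapped circumferential
# coordinate is the arc length R theta = R asin(y_chord / R).

#' @rdname principalCurvature
#' @export
setMethod("principalCurvature", "CylinderSpec", function(spec) {
  if (isFlat(spec)) 0 else 2 / spec@diameter_um
})

#' Is a substrate specification flat?
#' @param spec a [CylinderSpec-class].
#' @return \code{TRUE} for flat control areas.
#' @export
isFlat <- function(spec) identical(spec@concavity, "flat")

.radius <- function(spec) spec@diameter_um / 2

#' Remap projected chord coordinates to unwrapped arc length
#'
#' Converts the circumferential coordinate of a point seen in a
#' maximum-intensity projection (a chord coordinate \eqn{y = R\sin\theta})
#' to the arc length along the cylinder surface
#' (\eqn{s = R\,\mathrm{asin}(y/R)}). The mapping is odd, monotone and
#' expansive (\eqn{|s| \ge |y|}); flat specifications pass through
#' unchanged. \code{arcToChord} is the exact inverse.
#'
#' @param y_chord_um signed chord coordinate(s), micrometres.
#' @param spec a [CylinderSpec-class].
#' @return Signed arc length(s), micrometres.
#' @examples
#' sp <- cylinderSpec(500)
#' chordToArc(125, sp)           # R asin(0.5) = pi R / 6
#' arcToChord(chordToArc(125, sp), sp)
#' @export
chordToArc <- function(y_chord_um, spec) {
  if (isFlat(spec)) return(y_chord_um)
  R <- .radius(spec)
  bad <- which(abs(y_chord_um) > R * (1 + 1e-12))
  if (length(bad))
    stop(sprintf("point(s) off the projected surface: |y_chord| > R = %g um at index %s",
                 R, paste(utils::head(bad, 5L), collapse = ", ")))
  R * asin(pmin(1, pmax(-1, y_chord_um / R)))
}

#' @rdname chordToArc
#' @param arc_um signed arc length(s), micrometres (|arc| <= pi R / 2).
#' @export
arcToChord <- function(arc_um, spec) {
  if (isFlat(spec)) return(arc_um)
  R <- .radius(spec)
  bad <- which(abs(arc_um) > (pi / 2) * R * (1 + 1e-12))
  if (length(bad))
    stop(sprintf("arc length(s) beyond the projected quarter circumference (pi R/2 = %g um) at index %s",
                 pi * R / 2, paste(utils::head(bad, 5L), collapse = ", ")))
  R * sin(arc_um / R)
}

.rotate_xy <- function(x, y, angle_deg) {
  a <- angle_deg * pi / 180
  list(x = cos(a) * x + sin(a) * y, y = -sin(a) * x + cos(a) * y)
}

#' Unwrap projected tracks onto the cylinder surface
#'
#' Replaces the circumferential coordinate of every track point by its arc
#' length on the cylinder surface, after rotating the image frame so that
#' \code{x} runs along the longitudinal axis. Longitudinal displacements are
#' preserved exactly. Under \code{policy = "paper_thresholded"} only
#' cylinders with \eqn{D \le 250\,\mu m} are remapped (out-of-plane motion
#' being negligible on larger cylinders) and larger projections are accepted
#' as planar; the default remaps every non-flat surface.
#'
#' @param ts a projected [TrackSet-class] (\code{isUnwrapped(ts)} FALSE).
#' @param policy \code{"always"} or \code{"paper_thresholded"}.
#' @return An unwrapped [TrackSet-class]; flat surfaces are returned with the
#'   flag set and coordinates untouched.
#' @seealso [projectTracks()] for the inverse.
#' @export
unwrapTracks <- function(ts, policy = c("always", "paper_thresholded")) {
  policy <- match.arg(policy)
  if (isUnwrapped(ts)) return(ts)
  sp <- surface(ts)
  tr <- tracks(ts)
  if (sp@axis_angle_deg != 0) {
    rot <- .rotate_xy(tr$x_um, tr$y_um, sp@axis_angle_deg)
    tr$x_um <- rot$x; tr$y_um <- rot$y
  }
  remap <- !isFlat(sp) &&
    (policy == "always" || sp@diameter_um <= 250)
  if (remap) {
    R <- .radius(sp)
    bad <- which(abs(tr$y_um) > R * (1 + 1e-12))
    if (length(bad)) {
      b <- bad[1]
      stop(sprintf("track point off the surface (|y| > R = %g um): cell '%s', frame %g",
                   R, tr$cell_id[b], tr$frame[b]))
    }
    tr$y_um <- chordToArc(tr$y_um, sp)
  }
  md <- ts@metadata
  md$remap_policy <- policy
  md$remapped <- remap
  trackSet(tr, surface = sp, unwrapped = TRUE, metadata = md)
}

#' Project unwrapped tracks back to chord coordinates
#'
#' Inverse of [unwrapTracks()]: maps arc-length coordinates back to the
#' chord coordinates of a maximum-intensity projection (and rotates back
#' into the image frame). Used when rendering synthetic movies of cells on
#' curved substrates.
#'
#' @param ts an unwrapped [TrackSet-class].
#' @return A projected [TrackSet-class].
#' @export
projectTracks <- function(ts) {
  if (!isUnwrapped(ts)) return(ts)
  sp <- surface(ts)
  tr <- tracks(ts)
  if (!isFlat(sp)) tr$y_um <- arcToChord(tr$y_um, sp)
  if (sp@axis_angle_deg != 0) {
    rot <- .rotate_xy(tr$x_um, tr$y_um, -sp@axis_angle_deg)
    tr$x_um <- rot$x; tr$y_um <- rot$y
  }
  trackSet(tr, surface = sp, unwrapped = FALSE, metadata = ts@metadata)
}

# --- TrackSet accessors -----------------------------------------------------

#' @rdname trackSet
#' @export
setMethod("tracks", "TrackSet", function(x) x@tracks)

#' @rdname trackSet
#' @export
setMethod("surface", "TrackSet", function(x) x@surface)

#' @rdname trackSet
#' @export
setMethod("isUnwrapped", "TrackSet", function(x) x@unwrapped)

#' @rdname trackSet
#' @export
setMethod("nTracks", "TrackSet", function(x) length(unique(x@tracks$cell_id)))

#' @rdname trackSet
#' @export
setMethod("cellIds", "TrackSet", function(x) unique(x@tracks$cell_id))

#' @rdname trackSet
#' @export
setMethod("samplingInterval", "TrackSet", function(x) {
  d <- unlist(lapply(split(x@tracks$time_h, x@tracks$cell_id), diff))
  if (!length(d)) return(NA_real_)
  stats::median(d)
})
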