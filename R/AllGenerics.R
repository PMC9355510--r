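#' Principal curvature of a substrate
#'
#' \eqn{\kappa = 2/D} for a cylinder of diameter D (in \eqn{\mu m^{-1}}),
#' 0 for flat areas.
#'
#' @param spec a [CylinderSpec-class].
#' @return Principal curvature in \eqn{\mu m^{-1}}.
#' @examples
#' principalCurvature(cylinderSpec(125))   # 1/62.5
#' principalCurvature(flatSpec())          # 0
#' @export
setGeneric("principalCurvature", function(spec) standardGeneric("principalCurvature"))

#' @rdname trackSet
#' @param x a [TrackSet-class].
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))

#' @rdname trackSet
#' @export
setGeneric("surface", function(x) standardGeneric("surface"))

#' @rdname trackSet
#' @export
setGeneric("isUnwrapped", function(x) standardGeneric("isUnwrapped"))

#' @rdname trackSet
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname trackSet
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname trackSet
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))

#' Per-cell mean migration speed
#'
#' Mean over track steps of Euclidean step length divided by step duration.
#'
#' @param x a [TrackSet-class].
#' @param ... unused.
#' @return Named numeric vector of speeds (um/h), one per cell.
#' @export
setGeneric("meanSpeed", function(x, ...) standardGeneric("meanSpeed"))

#' @rdname fitMSDExponent
#' @param curve a [MSDCurve-class].
#' @export
setGeneric("msdAlpha", function(curve) standardGeneric("msdAlpha"))

#' @rdname ensembleMSD
#' @export
setGeneric("msdTable", function(curve) standardGeneric("msdTable"))
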