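# Shape morphometrics from labeled masks, CellProfiler-compatible:
# ellipse fit from normalized central second moments, convex-hull pixel
# solidity, physical scaling by the pixel size.

# Convex-hull pixel count: hull vertices from the pixel centres
# (grDevices::chull), then the rasterized hull = pixel centres inside or on
# the polygon. Degenerate (collinear) objects are their own hull.
.hull_pixel_count <- function(xc, yc) {
  n <- length(xc)
  if (n <= 2L) return(n)
  h <- grDevices::chull(xc, yc)
  if (length(h) < 3L) return(n)
  px <- xc[h]; py <- yc[h]
  if (abs(pracma::polyarea(px, py)) < 1e-9) return(n)
  jr <- floor(min(xc)):ceiling(max(xc))
  ir <- floor(min(yc)):ceiling(max(yc))
  gx <- rep(jr, times = length(ir))
  gy <- rep(ir, each = length(jr))
  sum(pracma::inpolygon(gx, gy, px, py, boundary = TRUE))
}

#' Measure cell-shape descriptors on a labeled mask
#'
#' Computes, for each labeled object, the four descriptors used to
#' characterize keratocyte phenotype: major axis length, area, eccentricity
#' and solidity. The best-fit ellipse comes from the normalized central
#' second moments of the pixel centres; its eccentricity
#' \eqn{\sqrt{1 - (b/a)^2}} equals the classical focal-distance /
#' major-axis-length ratio (0 for a circle, 1 for a line). Solidity is the
#' proportion of the pixels in the rasterized convex hull that belong to the
#' object, so values below 1 indicate protrusive, irregular outlines.
#' Lengths are reported in micrometres and areas in square micrometres via
#' the mask's pixel size.
#'
#' @param mask a [LabeledMask-class] (or an integer matrix, then
#'   \code{pixel_size_um} applies).
#' @param min_area_px objects smaller than this many pixels are dropped (and
#'   reported via a message).
#' @param exclude_border drop objects touching the mask border (default
#'   TRUE; partial cells bias shape statistics).
#' @param pixel_size_um pixel size when \code{mask} is a bare matrix.
#' @return data.frame with one row per retained object: \code{label},
#'   \code{area_px}, \code{major_axis_um}, \code{minor_axis_um},
#'   \code{area_um2}, \code{eccentricity}, \code{solidity},
#'   \code{touches_border}.
#' @examples
#' m <- matrix(0L, 60, 60); m[21:40, 21:40] <- 1L
#' measureShapes(labeledMask(m, 0.5), min_area_px = 1)
#' @export
measureShapes <- function(mask, min_area_px = 50L, exclude_border = TRUE,
                          pixel_size_um = 1) {
  if (is.matrix(mask)) mask <- labeledMask(mask, pixel_size_um)
  stopifnot(is(mask, "LabeledMask"), min_area_px >= 1)
  g <- mask@grid
  px <- mask@pixel_size_um
  labs <- sort(setdiff(unique(as.vector(g)), 0L))
  if (!length(labs)) return(.empty_shape_df())
  idx <- which(g > 0L)
  rows <- ((idx - 1L) %% nrow(g)) + 1L
  cols <- ((idx - 1L) %/% nrow(g)) + 1L
  lab_of <- g[idx]
  out <- vector("list", length(labs))
  dropped <- 0L
  for (k in seq_along(labs)) {
    sel <- lab_of == labs[k]
    r <- rows[sel]; cl <- cols[sel]
    n <- length(r)
    touches <- any(r == 1L | r == nrow(g) | cl == 1L | cl == ncol(g))
    if (n < min_area_px) { dropped <- dropped + 1L; next }
    if (exclude_border && touches) next
    xc <- cl - 0.5; yc <- r - 0.5          # pixel centres
    mx <- mean(xc); my <- mean(yc)
    mu20 <- mean((xc - mx)^2); mu02 <- mean((yc - my)^2)
    mu11 <- mean((xc - mx) * (yc - my))
    tr2 <- (mu20 + mu02) / 2
    det_rt <- sqrt(max(0, ((mu20 - mu02) / 2)^2 + mu11^2))
    l1 <- tr2 + det_rt; l2 <- max(0, tr2 - det_rt)
    ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
    hull_n <- .hull_pixel_count(xc, yc)
    out[[k]] <- data.frame(
      label = labs[k], area_px = n,
      major_axis_um = 4 * sqrt(l1) * px,
      minor_axis_um = 4 * sqrt(l2) * px,
      area_um2 = n * px^2,
      eccentricity = ecc,
      solidity = min(1, n / hull_n),
      touches_border = touches)
  }
  if (dropped)
    message(sprintf("measureShapes: dropped %d object(s) below min_area_px = %d",
                    dropped, as.integer(min_area_px)))
  res <- do.call(rbind, out)
  if (is.null(res)) .empty_shape_df() else res
}

.empty_shape_df <- function() {
  data.frame(label = integer(0), area_px = integer(0),
             major_axis_um = numeric(0), minor_axis_um = numeric(0),
             area_um2 = numeric(0), eccentricity = numeric(0),
             solidity = numeric(0), touches_border = logical(0))
}

#' Write shape metrics to CSV
#' @param metrics data.frame from [measureShapes()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeShapeMetricsCSV <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled mask from a TIFF or PNG file
#'
#' Integer labels are recovered from the stored intensities; masks written
#' by [writeLabeledMask()] round-trip exactly (16-bit TIFF for up to 65535
#' labels, 8-bit PNG for up to 255).
#'
#' @param path image file (single-channel TIFF or PNG).
#' @param pixel_size_um micrometres per pixel.
#' @return A [LabeledMask-class].
#' @export
readLabeledMask <- function(path, pixel_size_um = 1) {
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  img <- if (is_png) png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  scale <- if (is_png) 255 else 65535
  labeledMask(matrix(as.integer(round(img * scale)), nrow(img), ncol(img)),
              pixel_size_um)
}

#' Write a labeled mask as an integer-valued image
#' @param mask a [LabeledMask-class]; labels must fit the bit depth
#'   (65535 for TIFF, 255 for PNG).
#' @param path output path (.tiff or .png).
#' @return \code{path}, invisibly.
#' @export
writeLabeledMask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(mask@grid) > 255) stop("PNG masks support at most 255 labels")
    png::writePNG(mask@grid / 255, path)
  } else {
    if (max(mask@grid) > 65535) stop("TIFF masks support at most 65535 labels")
    tiff::writeTIFF(mask@grid / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}
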