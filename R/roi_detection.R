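# Polygonal ROIs and adaptive-threshold patch detection.
#
# Detection is deliberately local: the user outlines rough polygonal regions
# of interest, and within each region the cutoff adapts to the region's own
# brightness (global threshold x region maximum). Regions drawn over shady
# and well-lit areas therefore segment reliably under uneven illumination,
# which a single global cutoff cannot do.

#' Construct a polygonal region of interest
#'
#' Vertices are (x, y) floats in 0-based pixel coordinates; the polygon is
#' implicitly closed. A rough contour suffices — the region only needs to
#' enclose the candidate patch and delimit an area of roughly even
#' illumination; the adaptive threshold does the actual segmentation.
#'
#' @param x,y Numeric vectors of vertex coordinates (at least 3 vertices).
#' @return An object of class `polygon_roi`.
#' @export
polygon_roi <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("a polygon ROI needs at least 3 (x, y) vertices")
  }
  if (anyNA(x) || anyNA(y)) {
    stop("polygon vertices must be finite")
  }
  structure(
    list(vertices = cbind(x = as.numeric(x), y = as.numeric(y))),
    class = "polygon_roi"
  )
}

#' @export
print.polygon_roi <- function(x, ...) {
  cat("Polygon ROI with", nrow(x$vertices), "vertices\n")
  invisible(x)
}

#' Rasterize a polygon ROI to a binary region mask
#'
#' A pixel belongs to the region iff its centre lies inside or on the polygon
#' boundary under the even-odd rule. Pixel (row r, col c) has centre
#' (x, y) = (c - 1, r - 1).
#'
#' @param roi A [polygon_roi()].
#' @param height,width Output mask dimensions in pixels.
#' @return Logical `height x width` matrix.
#' @export
#' @examples
#' sq <- polygon_roi(c(10, 20, 20, 10), c(10, 10, 20, 20))
#' sum(rasterize_roi(sq, 30, 30)) # 11 x 11 = 121
rasterize_roi <- function(roi, height = VT_HEIGHT, width = VT_WIDTH) {
  stopifnot(inherits(roi, "polygon_roi"))
  vx <- roi$vertices[, "x"]
  vy <- roi$vertices[, "y"]
  mask <- matrix(FALSE, nrow = height, ncol = width)
  # only test pixel centres inside the polygon's bounding box
  c0 <- max(1L, floor(min(vx)) + 1L)
  c1 <- min(width, ceiling(max(vx)) + 1L)
  r0 <- max(1L, floor(min(vy)) + 1L)
  r1 <- min(height, ceiling(max(vy)) + 1L)
  if (c0 > c1 || r0 > r1) {
    stop("polygon ROI lies entirely outside the image frame")
  }
  px <- rep((c0:c1) - 1, each = r1 - r0 + 1L)
  py <- rep((r0:r1) - 1, times = c1 - c0 + 1L)
  inside <- pracma::inpolygon(px, py, vx, vy, boundary = TRUE)
  mask[r0:r1, c0:c1] <- matrix(inside, nrow = r1 - r0 + 1L)
  if (!any(mask)) {
    stop("polygon ROI rasterizes to zero area")
  }
  mask
}

#' Detect vitiligo patches by per-ROI adaptive thresholding
#'
#' The output mask starts all zero. Each ROI is processed independently: the
#' filtered image is masked to the ROI, the maximum gray level over the ROI is
#' computed, and the adaptive threshold for that ROI is
#' `global_threshold * max`. ROI pixels whose filtered value is greater than
#' or equal to the adaptive threshold are marked as vitiligo; the per-ROI
#' detections combine by union. At `global_threshold = 0` every ROI pixel is
#' detected; at 1 only the pixels attaining the ROI maximum are.
#'
#' A ROI whose maximum gray level is 0 carries no contrast signal; it is
#' flagged with a warning and its pixels are detected only when
#' `global_threshold = 0`, so flat-dark regions cannot produce spurious
#' full-ROI detections.
#'
#' @param filtered `H x W` matrix from [apply_filter()].
#' @param rois Non-empty list of [polygon_roi()].
#' @param global_threshold Number in \[0, 1\]; default 0.5, which generally
#'   separates high-intensity patch pixels from healthy skin.
#' @return Logical `H x W` mask with attributes `provenance` (integer matrix;
#'   index of the first ROI that detected each pixel, 0 for background) and
#'   `adaptive_thresholds` (numeric, one per ROI).
#' @export
detect_patches <- function(filtered, rois, global_threshold = 0.5) {
  if (!is.matrix(filtered) || !is.numeric(filtered)) {
    stop("filtered must be a numeric matrix")
  }
  if (!is.list(rois) || length(rois) == 0L) {
    stop("at least one ROI is required")
  }
  if (!is.numeric(global_threshold) || length(global_threshold) != 1L ||
      is.na(global_threshold) ||
      global_threshold < 0 || global_threshold > 1) {
    stop("global_threshold must be a number in [0, 1]")
  }
  h <- nrow(filtered)
  w <- ncol(filtered)
  mask <- matrix(FALSE, h, w)
  provenance <- matrix(0L, h, w)
  adaptive <- numeric(length(rois))
  for (i in seq_along(rois)) {
    region <- rasterize_roi(rois[[i]], h, w)
    roi_max <- max(filtered[region])
    adaptive[i] <- global_threshold * roi_max
    if (roi_max == 0) {
      warning("ROI ", i, " has maximum gray level 0; ",
        "its pixels are detected only at global_threshold = 0")
      detected <- region & (global_threshold == 0)
    } else {
      detected <- region & (filtered >= adaptive[i])
    }
    provenance[detected & provenance == 0L] <- i
    mask <- mask | detected
  }
  attr(mask, "provenance") <- provenance
  attr(mask, "adaptive_thresholds") <- adaptive
  mask
}

#' Manually contour a patch
#'
#' Fallback for low-contrast or ambiguous patches: a finely drawn polygon is
#' taken as the patch itself, equivalent to running [detect_patches()] on that
#' single ROI with the global threshold at 0 (every ROI pixel detected).
#'
#' @param roi A [polygon_roi()] tightly contouring the patch.
#' @param height,width Mask dimensions.
#' @return Logical `height x width` mask.
#' @export
manual_patch <- function(roi, height = VT_HEIGHT, width = VT_WIDTH) {
  rasterize_roi(roi, height, width)
}
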