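# Validation against gold-standard masks and threshold-robustness analysis.

#' Compare a detected mask against a gold-standard mask
#'
#' Pixelwise confusion against a dermatologist-marked gold standard:
#' true positives are pixels detected by both, false positives are detected
#' but not marked, false negatives are marked but not detected. The success
#' rate is the true-positive area over the total (union) area,
#' `100 * tp / (tp + fp + fn)` — 100 iff the masks agree perfectly, 0 iff
#' they are disjoint. Pixels that are background in both masks never affect
#' the score. When both masks are empty there is no lesion and no
#' disagreement; the success rate is defined as 100 with a warning.
#'
#' The overlay raster uses the conventional coloring: green for successful
#' detection, red for false positives, blue for false negatives.
#'
#' @param detected,gold Logical masks of identical dimensions.
#' @param image Optional RGB image to underlay the overlay colors on.
#' @return An object of class `validation_result`: list with `tp_pixels`,
#'   `fp_pixels`, `fn_pixels`, `success_rate` (percent), and `overlay`
#'   (`H x W x 3` array).
#' @export
#' @examples
#' a <- matrix(FALSE, 10, 10); b <- a
#' a[2:5, 2:5] <- TRUE; b[3:6, 2:5] <- TRUE
#' compare_masks(a, b)$success_rate
compare_masks <- function(detected, gold, image = NULL) {
  detected <- as_binary_mask(detected)
  gold <- as_binary_mask(gold)
  if (!all(dim(detected) == dim(gold))) {
    stop("detected and gold masks must have identical dimensions")
  }
  tp <- detected & gold
  fp <- detected & !gold
  fn <- !detected & gold
  n_tp <- sum(tp)
  n_fp <- sum(fp)
  n_fn <- sum(fn)
  total <- n_tp + n_fp + n_fn
  if (total == 0L) {
    warning("both masks are empty; success rate defined as 100")
    rate <- 100
  } else {
    rate <- 100 * n_tp / total
  }
  overlay <- if (is.null(image)) {
    array(0, dim = c(dim(detected), 3L))
  } else {
    stopifnot(all(dim(image)[1:2] == dim(detected)))
    image * 0.4 # dim the photograph so the coding reads clearly
  }
  paint <- function(img, where, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[where] <- col[ch]
      img[, , ch] <- plane
    }
    img
  }
  overlay <- paint(overlay, tp, c(0, 0.8, 0))
  overlay <- paint(overlay, fp, c(0.9, 0, 0))
  overlay <- paint(overlay, fn, c(0, 0.2, 0.9))
  structure(
    list(
      tp_pixels = n_tp, fp_pixels = n_fp, fn_pixels = n_fn,
      success_rate = rate, overlay = overlay
    ),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "tp: %d  fp: %d  fn: %d  success rate: %.2f%%\n",
    x$tp_pixels, x$fp_pixels, x$fn_pixels, x$success_rate
  ))
  invisible(x)
}

#' Sweep the global threshold and map per-pixel detection stability
#'
#' Runs [detect_patches()] at `n_steps` evenly spaced global thresholds
#' between `t_min` and `t_max` (endpoints included) and records, per pixel,
#' the percentage of runs that detected it. Because detection is monotone in
#' the threshold, the runs detecting any given pixel form a prefix of the
#' ascending threshold list, so each cell equals `100 * k / n_steps`; cells
#' at 100 are detected across the entire swept range and mark the stable core
#' of the patches, while lower values trace the threshold-sensitive contour.
#' The default range 0.35–0.65 probes robustness around the default global
#' threshold of 0.5 (plus or minus 30 percent).
#'
#' @param filtered `H x W` matrix from [apply_filter()].
#' @param rois Non-empty list of [polygon_roi()].
#' @param t_min,t_max Swept range, `0 <= t_min < t_max <= 1`.
#' @param n_steps Number of thresholds (>= 2).
#' @return An object of class `stability_map`: list with `matrix`
#'   (`H x W` percentages) and `thresholds` (ascending numeric vector).
#' @export
threshold_sweep <- function(filtered, rois, t_min = 0.35, t_max = 0.65,
                            n_steps = 7L) {
  if (!is.numeric(t_min) || !is.numeric(t_max) ||
      t_min < 0 || t_max > 1 || t_min >= t_max) {
    stop("need 0 <= t_min < t_max <= 1")
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 2L) {
    stop("n_steps must be at least 2")
  }
  thresholds <- seq(t_min, t_max, length.out = n_steps)
  counts <- matrix(0L, nrow(filtered), ncol(filtered))
  for (t in thresholds) {
    counts <- counts + detect_patches(filtered, rois, t)
  }
  structure(
    list(matrix = 100 * counts / n_steps, thresholds = thresholds),
    class = "stability_map"
  )
}

#' @export
print.stability_map <- function(x, ...) {
  cat(sprintf(
    "Stability map over %d thresholds in [%.3g, %.3g]: %d pixel(s) stable at 100%%\n",
    length(x$thresholds), min(x$thresholds), max(x$thresholds),
    sum(x$matrix == 100)
  ))
  invisible(x)
}
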