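# Black-light contrast filters.
#
# Under ~365 nm (Wood's lamp) illumination, depigmented vitiligo patches
# fluoresce: their signal concentrates in the blue channel (and, weaker, the
# green one), while the red channel mostly carries the overall skin tone.
# The four filters exploit this to map the RGB photograph to a single-channel
# image in which patch pixels are bright and healthy skin is dark, which is
# what the per-ROI adaptive thresholding operates on.

LUMA_WEIGHTS <- c(r = 0.2989, g = 0.5870, b = 0.1140) # ITU-R BT.601

#' Apply one of the four black-light contrast filters
#'
#' * Filter 1 — the blue channel alone, where black-light patch contrast is
#'   strongest.
#' * Filter 2 — each channel is divided elementwise by the blue channel, the
#'   ratio image is converted to gray with the BT.601 luma weights
#'   (0.2989, 0.5870, 0.1140), and the complement is taken so patches come out
#'   bright. Where B falls below 1/255 the divisor is floored at 1/255 so dark
#'   background pixels cannot produce infinities.
#' * Filter 3 — blue minus red, clipped to \[0, 1\].
#' * Filter 4 — green plus blue minus red, clipped to \[0, 1\]. Summing the
#'   two fluorescence channels and subtracting red normalizes against the
#'   skin tone; it is generally the most effective choice and the default
#'   throughout the package.
#'
#' Negative differences are clipped to 0 (not rescaled), preserving the
#' absolute-intensity semantics the adaptive threshold relies on.
#'
#' @param image `H x W x 3` numeric array in \[0, 1\] from [load_image()].
#' @param filter_id Integer in 1..4.
#' @return `H x W` numeric matrix with values in \[0, 1\].
#' @export
#' @examples
#' img <- array(c(0.5, 0.3, 0.4), c(1, 1, 3))
#' apply_filter(img, 4) # 0.3 + 0.4 - 0.5 = 0.2
apply_filter <- function(image, filter_id) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) {
    stop("image must be an H x W x 3 array")
  }
  filter_id <- as.integer(filter_id)
  if (length(filter_id) != 1L || is.na(filter_id) || !filter_id %in% 1:4) {
    stop("filter_id must be an integer in 1..4")
  }
  r <- image[, , 1L]
  g <- image[, , 2L]
  b <- image[, , 3L]
  out <- switch(filter_id,
    b,
    {
      eps <- 1 / 255
      bp <- pmax(b, eps)
      luma <- LUMA_WEIGHTS[["r"]] * (r / bp) +
        LUMA_WEIGHTS[["g"]] * (g / bp) +
        LUMA_WEIGHTS[["b"]] * (b / bp)
      1 - luma
    },
    b - r,
    g + b - r
  )
  clip01(out)
}
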