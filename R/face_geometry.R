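# Face-contour ellipse, area measures, and registration onto the face
# template.
#
# The face contour is approximated by an axis-aligned ellipse: it gives the
# face area against which patch areas are expressed, and it drives the
# normalization that makes photographs taken at different distances, scales
# and frame positions comparable. Registration scales each axis by the ratio
# of template to patient semi-axes and translates the patient's ellipse
# centre onto the template's.

#' Construct a face-contour ellipse
#'
#' @param cx,cy Centre in 0-based pixel coordinates.
#' @param a Horizontal semi-axis in pixels (> 0).
#' @param b Vertical semi-axis in pixels (> 0).
#' @return An object of class `face_ellipse`.
#' @export
face_ellipse <- function(cx, cy, a, b) {
  vals <- c(cx, cy, a, b)
  if (length(vals) != 4L || anyNA(vals) || !is.numeric(vals)) {
    stop("face_ellipse needs numeric cx, cy, a, b")
  }
  if (a <= 0 || b <= 0) {
    stop("ellipse semi-axes must be positive")
  }
  structure(
    list(cx = as.numeric(cx), cy = as.numeric(cy),
         a = as.numeric(a), b = as.numeric(b)),
    class = "face_ellipse"
  )
}

#' @export
print.face_ellipse <- function(x, ...) {
  cat(sprintf(
    "Face ellipse: centre (%.1f, %.1f), semi-axes a = %.1f, b = %.1f\n",
    x$cx, x$cy, x$a, x$b
  ))
  invisible(x)
}

#' Area of a face ellipse
#'
#' @param e A [face_ellipse()].
#' @return Area in pixels squared, `pi * a * b`.
#' @export
#' @examples
#' ellipse_area(face_ellipse(0, 0, 10, 10)) # 100 * pi
ellipse_area <- function(e) {
  stopifnot(inherits(e, "face_ellipse"))
  pi * e$a * e$b
}

#' Patch area as a fraction of the face area
#'
#' Patch area is the pixel count of the detection mask; face area is the
#' analytic ellipse area.
#'
#' @param mask Logical patch mask.
#' @param e The face ellipse drawn on the same image.
#' @return Non-negative real; 0 for an empty mask, about 1 for a mask filling
#'   the ellipse.
#' @export
patch_area_fraction <- function(mask, e) {
  sum(as_binary_mask(mask)) / ellipse_area(e)
}

#' Rasterize the interior of an ellipse
#'
#' @param e A [face_ellipse()].
#' @param height,width Mask dimensions.
#' @return Logical matrix; pixel centres with
#'   `((x-cx)/a)^2 + ((y-cy)/b)^2 <= 1` are set.
#' @export
rasterize_ellipse <- function(e, height = VT_HEIGHT, width = VT_WIDTH) {
  stopifnot(inherits(e, "face_ellipse"))
  x <- matrix((seq_len(width) - 1 - e$cx) / e$a, height, width, byrow = TRUE)
  y <- matrix((seq_len(height) - 1 - e$cy) / e$b, height, width)
  x^2 + y^2 <= 1
}

#' Map image coordinates onto the face template
#'
#' Each coordinate is scaled by the ratio of template to patient semi-axes
#' (horizontal axis pairs with x, vertical with y) and translated so the
#' patient's ellipse centre lands on the template's, then rounded
#' half-away-from-zero to integer pixel coordinates. Points falling outside
#' the template frame are dropped with a warning rather than clamped, so no
#' spurious mass piles up on the frame border.
#'
#' @param points Two-column matrix of (x, y) 0-based coordinates.
#' @param patient_e,template_e The patient's and the template's
#'   [face_ellipse()].
#' @param height,width Template frame bounds used to drop out-of-frame points.
#' @return Integer two-column matrix of template (x, y) coordinates.
#' @export
to_template <- function(points, patient_e, template_e,
                        height = VT_HEIGHT, width = VT_WIDTH) {
  stopifnot(inherits(patient_e, "face_ellipse"),
            inherits(template_e, "face_ellipse"))
  points <- matrix(as.numeric(points), ncol = 2L,
                   dimnames = list(NULL, c("x", "y")))
  sx <- template_e$a / patient_e$a
  sy <- template_e$b / patient_e$b
  x <- round_half_away(template_e$cx + (points[, 1L] - patient_e$cx) * sx)
  y <- round_half_away(template_e$cy + (points[, 2L] - patient_e$cy) * sy)
  keep <- x >= 0 & x <= width - 1 & y >= 0 & y <= height - 1
  if (any(!keep)) {
    warning(sum(!keep), " point(s) mapped outside the template frame; dropped")
  }
  cbind(x = as.integer(x[keep]), y = as.integer(y[keep]))
}

#' Register a patch mask onto the face template
#'
#' Maps every detected pixel with [to_template()] and re-binarizes: a template
#' cell is set if at least one of the patient's detected pixels maps to it, so
#' a patient can contribute at most 1 to any occurrence-map cell.
#'
#' @param mask Logical patient-space mask.
#' @param patient_e,template_e Patient and template [face_ellipse()].
#' @return Logical mask in the template frame (same dimensions as `mask`).
#' @export
register_mask <- function(mask, patient_e, template_e) {
  mask <- as_binary_mask(mask)
  h <- nrow(mask)
  w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(out)
  }
  pts <- cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
  mapped <- to_template(pts, patient_e, template_e, height = h, width = w)
  out[cbind(mapped[, "y"] + 1L, mapped[, "x"] + 1L)] <- TRUE
  out
}

#' The built-in face template
#'
#' A neutral, synthetically drawn 610 x 407 face raster with its reference
#' ellipse. The raster is generated in code (no clinical template image is
#' bundled); any user template can replace it via a template JSON config.
#'
#' @return List with elements `image` (407 x 610 x 3 array) and `ellipse`
#'   (the template [face_ellipse()]).
#' @export
default_template <- function() {
  e <- face_ellipse(cx = 305, cy = 203.5, a = 230, b = 150)
  img <- array(0.12, dim = c(VT_HEIGHT, VT_WIDTH, 3L))
  face <- rasterize_ellipse(e)
  skin <- c(0.85, 0.78, 0.70)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[face] <- skin[ch]
    img[, , ch] <- plane
  }
  dark <- list(
    face_ellipse(305 - 90, 203.5 - 45, 32, 16), # left eye
    face_ellipse(305 + 90, 203.5 - 45, 32, 16), # right eye
    face_ellipse(305, 203.5 + 28, 12, 30),      # nose
    face_ellipse(305, 203.5 + 95, 55, 14)       # mouth
  )
  for (d in dark) {
    reg <- rasterize_ellipse(d)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[reg] <- plane[reg] * 0.45
      img[, , ch] <- plane
    }
  }
  list(image = img, ellipse = e)
}

#' Load a face template from a JSON config
#'
#' Schema: `{"image": "<path or omitted>", "ellipse": {"cx","cy","a","b"}}`.
#' When `image` is omitted the built-in raster is used.
#'
#' @param path JSON path; `NULL` returns [default_template()].
#' @return List with `image` and `ellipse` as in [default_template()].
#' @export
load_template <- function(path = NULL) {
  if (is.null(path)) {
    return(default_template())
  }
  j <- jsonlite::fromJSON(path)
  e <- j$ellipse
  ell <- face_ellipse(e$cx, e$cy, e$a, e$b)
  img <- if (!is.null(j$image)) {
    p <- j$image
    if (!file.exists(p)) {
      # resolve relative to the config file
      p <- file.path(dirname(path), j$image)
    }
    load_image(p)
  } else {
    default_template()$image
  }
  list(image = img, ellipse = ell)
}
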