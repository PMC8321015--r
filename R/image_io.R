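# Image, mask, session and cohort I/O.
#
# Internal raster convention: an RGB image is a height x width x 3 numeric
# array with intensities in [0, 1] and channels ordered red, green, blue.
# Pixel (row r, col c) has 0-based centre coordinates (x, y) = (c - 1, r - 1);
# polygon vertices and ellipse centres are stored as (x, y) floats.

eb_to_array <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) {
    t(as.array(img))
  } else {
    aperm(as.array(img), c(2L, 1L, 3L))
  }
}

array_to_eb <- function(px) {
  if (length(dim(px)) == 2L) {
    EBImage::Image(t(px))
  } else {
    EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
  }
}

#' Load a photograph and rescale it to the working resolution
#'
#' Reads a 3-channel PNG or JPEG photograph (typically acquired under
#' black-light illumination), maps intensities from the native bit depth to
#' \[0, 1\], and rescales to the fixed 610 x 407 working resolution with
#' bilinear interpolation, ignoring any aspect-ratio mismatch. Clinical
#' photographs are acquired at much higher resolution; the working resolution
#' keeps pixel-count based area measures comparable across cameras and matches
#' the face template used for population mapping.
#'
#' @param path Path to a PNG or JPEG file.
#' @return A `height x width x 3` numeric array in \[0, 1\] (407 x 610 x 3),
#'   channels ordered red, green, blue.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' save_image(array(runif(20 * 10 * 3), c(10, 20, 3)), f)
#' dim(load_image(f))
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file does not exist: ", path)
  }
  img <- EBImage::readImage(path)
  d <- dim(img)
  nch <- if (length(d) == 2L) 1L else d[3L]
  if (nch != 3L) {
    stop(
      "expected a 3-channel RGB image, got ", nch, " channel",
      if (nch > 1L) "s" else "", ": ", path
    )
  }
  if (d[1L] != VT_WIDTH || d[2L] != VT_HEIGHT) {
    img <- EBImage::resize(img, w = VT_WIDTH, h = VT_HEIGHT, filter = "bilinear")
  }
  clip01(eb_to_array(img))
}

#' Save an RGB image
#'
#' @param image `H x W x 3` numeric array in \[0, 1\].
#' @param path Output path; format chosen from the extension (.png or .jpg).
#' @return Invisibly, `path`.
#' @export
save_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  EBImage::writeImage(array_to_eb(clip01(image)), path)
  invisible(path)
}

#' Save a binary patch mask as an 8-bit grayscale PNG
#'
#' Detected pixels are written as 255, background as 0; the file round-trips
#' bit-exactly through [load_mask()].
#'
#' @param mask Logical (or 0/1) matrix.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
save_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Load a binary patch mask from a grayscale PNG
#'
#' @param path PNG path written by [save_mask()] (or any grayscale raster;
#'   pixels at or above half intensity count as detected).
#' @return Logical matrix.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read mask: file does not exist: ", path)
  }
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3L) {
    img <- img[, , 1L]
  }
  t(as.array(img)) >= 0.5
}

as_binary_mask <- function(mask) {
  if (anyNA(mask)) {
    stop("mask must be binary (logical or 0/1), without NA")
  }
  if (is.logical(mask)) {
    m <- mask
  } else {
    v <- unique(as.vector(mask))
    if (!all(v %in% c(0, 1))) {
      stop("mask must be binary (logical or 0/1)")
    }
    m <- mask == 1
  }
  m
}

#' Construct an annotation session
#'
#' A session gathers the per-patient annotations the detector needs: the
#' polygonal regions of interest, the face-contour ellipse, the contrast
#' filter, and the global threshold shared by all regions.
#'
#' @param rois List of polygons from [polygon_roi()]; at least one is required
#'   before detection.
#' @param ellipse Face-contour [face_ellipse()].
#' @param filter_id Contrast filter, integer in 1..4 (default 4, the
#'   blue-plus-green-minus-red filter).
#' @param global_threshold Global threshold in \[0, 1\] (default 0.5).
#' @return An object of class `vt_session`.
#' @export
session <- function(rois, ellipse, filter_id = 4L, global_threshold = 0.5) {
  stopifnot(is.list(rois))
  rois <- lapply(rois, function(r) {
    if (!inherits(r, "polygon_roi")) polygon_roi(r[, 1L], r[, 2L]) else r
  })
  if (!inherits(ellipse, "face_ellipse")) {
    stop("ellipse must be a face_ellipse")
  }
  filter_id <- as.integer(filter_id)
  if (length(filter_id) != 1L || is.na(filter_id) || !filter_id %in% 1:4) {
    stop("filter_id must be an integer in 1..4")
  }
  if (!is.numeric(global_threshold) || length(global_threshold) != 1L ||
      global_threshold < 0 || global_threshold > 1) {
    stop("global_threshold must be a number in [0, 1]")
  }
  structure(
    list(
      rois = rois, ellipse = ellipse,
      filter_id = filter_id, global_threshold = global_threshold
    ),
    class = "vt_session"
  )
}

#' @export
print.vt_session <- function(x, ...) {
  cat(
    "Annotation session:", length(x$rois), "ROI(s), filter", x$filter_id,
    ", global threshold", x$global_threshold, "\n"
  )
  invisible(x)
}

#' Read an annotation session from JSON
#'
#' Schema:
#' `{"rois": [[[x,y],...],...], "ellipse": {"cx","cy","a","b"},
#'  "filter_id": 1-4, "global_threshold": t}`.
#'
#' @param path JSON file path.
#' @return A `vt_session`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read session: file does not exist: ", path)
  }
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  rois <- j$rois
  if (is.array(rois) && length(dim(rois)) == 3L) {
    # uniform vertex counts collapse to one array on parse
    rois <- lapply(seq_len(dim(rois)[1L]), function(i) rois[i, , ])
  }
  rois <- lapply(rois, function(v) polygon_roi(v[, 1L], v[, 2L]))
  e <- j$ellipse
  session(
    rois = rois,
    ellipse = face_ellipse(e$cx, e$cy, e$a, e$b),
    filter_id = j$filter_id,
    global_threshold = j$global_threshold
  )
}

#' Write an annotation session to JSON
#'
#' @param x A `vt_session`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x, "vt_session"))
  obj <- list(
    rois = lapply(x$rois, function(r) unclass(r$vertices)),
    ellipse = list(
      cx = x$ellipse$cx, cy = x$ellipse$cy,
      a = x$ellipse$a, b = x$ellipse$b
    ),
    filter_id = x$filter_id,
    global_threshold = x$global_threshold
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

cohort_columns <- c(
  "patient_id", "gender", "familiarity",
  "onset_date", "first_visit_date", "image_path"
)

# "2003" -> 2003; "2003-05-12" -> 2003 + fractional part, kept as the Date
parse_date_or_year <- function(x) {
  out <- rep(NA_real_, length(x))
  x <- trimws(as.character(x))
  is_year <- grepl("^\\d{4}$", x)
  out[is_year] <- as.numeric(x[is_year])
  full <- !is_year & !is.na(x) & nzchar(x)
  if (any(full)) {
    d <- as.Date(x[full])
    out[full] <- 1970 + as.numeric(d) / 365.2425
  }
  out
}

#' Load a patient cohort from a metadata CSV and a directory of session files
#'
#' The metadata CSV must have columns `patient_id`, `gender`, `familiarity`,
#' `onset_date`, `first_visit_date`, `image_path` (ISO-8601 dates or bare
#' years); an optional `birth_date` column enables onset-age cohort filters.
#' For each row, a session file `<patient_id>.json` is looked up in
#' `sessions_dir`; records without one load with an absent session. Image
#' files are not touched here — a missing image only errors at detection time.
#'
#' @param metadata_path CSV path.
#' @param sessions_dir Directory containing `<patient_id>.json` session files;
#'   may be `NULL` to skip session lookup.
#' @return A data.frame with one row per patient, the parsed year columns
#'   (`onset_year`, `first_visit_year`, `birth_year`, `delay_years`), and a
#'   `session` list-column of `vt_session` or `NULL`.
#' @export
load_cohort <- function(metadata_path, sessions_dir = NULL) {
  if (!file.exists(metadata_path)) {
    stop("cannot read cohort metadata: ", metadata_path)
  }
  df <- utils::read.csv(metadata_path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(cohort_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "cohort metadata is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup) > 0L) {
    stop("duplicate patient_id in cohort: ", paste(dup, collapse = ", "))
  }
  df$gender <- ifelse(
    toupper(substr(trimws(df$gender), 1L, 1L)) %in% c("F", "M"),
    c(F = "female", M = "male")[toupper(substr(trimws(df$gender), 1L, 1L))],
    "unspecified"
  )
  fam <- tolower(trimws(df$familiarity))
  df$familiarity <- ifelse(
    fam %in% c("true", "t", "1", "yes"), TRUE,
    ifelse(fam %in% c("false", "f", "0", "no"), FALSE, NA)
  )
  df$onset_year <- parse_date_or_year(df$onset_date)
  df$first_visit_year <- parse_date_or_year(df$first_visit_date)
  if ("birth_date" %in% names(df)) {
    df$birth_year <- parse_date_or_year(df$birth_date)
  } else {
    df$birth_year <- NA_real_
  }
  bad <- !is.na(df$onset_year) & !is.na(df$first_visit_year) &
    df$onset_year > df$first_visit_year
  if (any(bad)) {
    stop(
      "onset_date after first_visit_date for patient(s): ",
      paste(df$patient_id[bad], collapse = ", ")
    )
  }
  df$delay_years <- floor(df$first_visit_year - df$onset_year)
  sessions <- vector("list", nrow(df))
  if (!is.null(sessions_dir)) {
    for (i in seq_len(nrow(df))) {
      sp <- file.path(sessions_dir, paste0(df$patient_id[i], ".json"))
      if (file.exists(sp)) {
        sessions[[i]] <- read_session(sp)
      }
    }
  }
  df$session <- I(sessions)
  df
}
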