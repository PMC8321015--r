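# Population occurrence map.
#
# Template-registered binary masks are summed cell by cell: the count at a
# cell is the number of patients with detected vitiligo there, and dividing
# by the cohort size gives the occurrence percentage displayed over the face
# template. Cohort filters select sub-populations before aggregation.

#' Accumulate registered patch masks into an occurrence map
#'
#' Starting from a zero matrix, each patient's binary template-space mask is
#' added; the accumulated count at a cell equals the number of patients
#' showing vitiligo at that template coordinate. The returned matrix is the
#' count normalized by the number of patients, in percent: 100 where every
#' patient shows vitiligo, 0 where none does.
#'
#' @param masks Non-empty list of logical 407 x 610 masks, already registered
#'   onto the template frame (see [register_mask()]).
#' @param filter_description Free-text description of the cohort filter that
#'   produced this sub-population (kept for the legend).
#' @return An object of class `occurrence_map`: list with `matrix`
#'   (407 x 610 percentages in \[0, 100\]), `n_patients`, and
#'   `filter_description`.
#' @export
#' @examples
#' m0 <- matrix(FALSE, 407, 610); m1 <- m0; m1[200, 300] <- TRUE
#' om <- accumulate_masks(list(m1, m1, m0, m0, m0))
#' om$matrix[200, 300] # 40: 2 of 5 patients
accumulate_masks <- function(masks, filter_description = "all patients") {
  if (!is.list(masks) || length(masks) == 0L) {
    stop("at least one mask is required")
  }
  masks <- lapply(masks, as_binary_mask)
  dims <- vapply(masks, function(m) paste(dim(m), collapse = "x"), "")
  want <- paste(c(VT_HEIGHT, VT_WIDTH), collapse = "x")
  if (any(dims != want)) {
    stop(
      "all masks must be ", VT_HEIGHT, " x ", VT_WIDTH,
      "; got dimensions: ", paste(unique(dims), collapse = ", ")
    )
  }
  counts <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  structure(
    list(
      matrix = 100 * counts / length(masks),
      n_patients = length(masks),
      filter_description = filter_description
    ),
    class = "occurrence_map"
  )
}

#' @export
print.occurrence_map <- function(x, ...) {
  cat(
    "Occurrence map over", x$n_patients, "patient(s) [",
    x$filter_description, "]\n"
  )
  cat(sprintf(
    "  nonzero cells: %d, max occurrence: %.1f%%\n",
    sum(x$matrix > 0), max(x$matrix)
  ))
  invisible(x)
}

#' Write an occurrence map matrix to CSV
#'
#' Plain numeric CSV, one row per image row (407 rows x 610 columns).
#'
#' @param map An `occurrence_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "occurrence_map"))
  utils::write.table(map$matrix, path,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Construct a cohort filter
#'
#' All criteria are optional; an empty filter selects every patient. Onset
#' age requires a `birth_date` metadata column; delay is the whole-year gap
#' between vitiligo onset and the first visit.
#'
#' @param gender `"female"` or `"male"`.
#' @param familiarity Logical: familial vitiligo.
#' @param onset_age_range Numeric `c(min, max)` in years, inclusive.
#' @param first_visit_year_range Numeric `c(min, max)` calendar years.
#' @param delay_range Numeric `c(min, max)` whole years between onset and
#'   first visit.
#' @return An object of class `cohort_filter`.
#' @export
cohort_filter <- function(gender = NULL, familiarity = NULL,
                          onset_age_range = NULL,
                          first_visit_year_range = NULL,
                          delay_range = NULL) {
  if (!is.null(gender) && !gender %in% c("female", "male")) {
    stop('gender must be "female" or "male"')
  }
  for (rng in list(onset_age_range, first_visit_year_range, delay_range)) {
    if (!is.null(rng) && (length(rng) != 2L || rng[1L] > rng[2L])) {
      stop("ranges must be c(min, max) with min <= max")
    }
  }
  structure(
    list(
      gender = gender, familiarity = familiarity,
      onset_age_range = onset_age_range,
      first_visit_year_range = first_visit_year_range,
      delay_range = delay_range
    ),
    class = "cohort_filter"
  )
}

filter_description <- function(f) {
  parts <- character(0)
  if (!is.null(f$gender)) parts <- c(parts, paste0("gender=", f$gender))
  if (!is.null(f$familiarity)) {
    parts <- c(parts, paste0("familiarity=", f$familiarity))
  }
  fmt_rng <- function(name, rng) paste0(name, "=[", rng[1L], ",", rng[2L], "]")
  if (!is.null(f$onset_age_range)) {
    parts <- c(parts, fmt_rng("onset_age", f$onset_age_range))
  }
  if (!is.null(f$first_visit_year_range)) {
    parts <- c(parts, fmt_rng("first_visit_year", f$first_visit_year_range))
  }
  if (!is.null(f$delay_range)) {
    parts <- c(parts, fmt_rng("delay", f$delay_range))
  }
  if (length(parts) == 0L) "all patients" else paste(parts, collapse = ", ")
}

#' Select a sub-population of a cohort
#'
#' Keeps the records satisfying every non-empty criterion of the filter. A
#' criterion on a field that is missing from every record (e.g. onset age
#' without a `birth_date` column) is skipped with a warning rather than
#' silently emptying the cohort.
#'
#' @param records Cohort data.frame from [load_cohort()].
#' @param f A [cohort_filter()].
#' @return The filtered data.frame.
#' @export
select_cohort <- function(records, f = cohort_filter()) {
  stopifnot(inherits(f, "cohort_filter"))
  keep <- rep(TRUE, nrow(records))
  apply_range <- function(keep, values, rng, what) {
    if (all(is.na(values))) {
      warning(what, " is unavailable for every record; criterion skipped")
      return(keep)
    }
    keep & !is.na(values) & values >= rng[1L] & values <= rng[2L]
  }
  if (!is.null(f$gender)) {
    keep <- keep & records$gender == f$gender
  }
  if (!is.null(f$familiarity)) {
    if (all(is.na(records$familiarity))) {
      warning("familiarity is unavailable for every record; criterion skipped")
    } else {
      keep <- keep & !is.na(records$familiarity) &
        records$familiarity == f$familiarity
    }
  }
  if (!is.null(f$onset_age_range)) {
    onset_age <- floor(records$onset_year - records$birth_year)
    keep <- apply_range(keep, onset_age, f$onset_age_range, "onset age")
  }
  if (!is.null(f$first_visit_year_range)) {
    keep <- apply_range(
      keep, floor(records$first_visit_year),
      f$first_visit_year_range, "first visit year"
    )
  }
  if (!is.null(f$delay_range)) {
    keep <- apply_range(keep, records$delay_years, f$delay_range, "delay")
  }
  records[keep, , drop = FALSE]
}

# piecewise-linear jet-style colormap on [0, 1]
occurrence_color <- function(f) {
  f <- pmin(pmax(f, 0), 1)
  r <- pmin(pmax(1.5 - abs(4 * f - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * f - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * f - 1), 0), 1)
  cbind(r, g, b)
}

#' Render an occurrence map over the face template
#'
#' Cells with zero occurrence show the template unchanged; cells with nonzero
#' occurrence are painted with a blue-to-red colormap proportional to the
#' occurrence percentage. A discrete legend column on the right edge shows one
#' swatch per occurrence level (0..n_patients), encoding the cohort size in
#' the rendering. Rendering is fully deterministic.
#'
#' @param map An `occurrence_map`.
#' @param template Template list from [default_template()] or
#'   [load_template()].
#' @return `407 x 610 x 3` numeric array in \[0, 1\].
#' @export
render_map <- function(map, template = default_template()) {
  stopifnot(inherits(map, "occurrence_map"))
  img <- template$image
  if (!all(dim(img)[1:2] == dim(map$matrix))) {
    stop("occurrence map and template dimensions differ")
  }
  pct <- map$matrix
  hit <- pct > 0
  cols <- occurrence_color(pct[hit] / 100)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[hit] <- cols[, ch]
    img[, , ch] <- plane
  }
  # legend: one swatch per occurrence level, bottom (0) to top (n_patients)
  n <- map$n_patients
  levels <- 0:n
  sw_h <- max(4L, min(20L, VT_HEIGHT %/% (n + 2L)))
  x0 <- VT_WIDTH - 24L
  for (k in levels) {
    y1 <- VT_HEIGHT - 4L - k * sw_h
    y0 <- y1 - sw_h + 1L
    if (y0 < 1L) break
    col <- if (k == 0L) c(0.25, 0.25, 0.35) else occurrence_color(k / n)[1, ]
    for (ch in 1:3) {
      img[y0:y1, x0:(x0 + 18L), ch] <- col[ch]
    }
    img[c(y0, y1), x0:(x0 + 18L), ] <- 0
    img[y0:y1, c(x0, x0 + 18L), ] <- 0
  }
  img
}
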