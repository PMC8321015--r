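# Independent brute-force oracles and small fixture builders.
# These re-derive the geometry and detection results pixel by pixel, with no
# shared code with the package internals.

# even-odd point-in-polygon with inclusive boundary, one point at a time
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (px - vx[i]) * (vy[j] - vy[i]) - (py - vy[i]) * (vx[j] - vx[i])
    if (abs(cross) < 1e-9 &&
        px >= min(vx[i], vx[j]) - 1e-9 && px <= max(vx[i], vx[j]) + 1e-9 &&
        py >= min(vy[i], vy[j]) - 1e-9 && py <= max(vy[i], vy[j]) + 1e-9) {
      return(TRUE) # on the boundary
    }
  }
  crossings <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

oracle_rasterize <- function(roi, height, width) {
  vx <- roi$vertices[, "x"]
  vy <- roi$vertices[, "y"]
  mask <- matrix(FALSE, height, width)
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      mask[r, c] <- oracle_point_in_polygon(c - 1, r - 1, vx, vy)
    }
  }
  mask
}

# per-ROI adaptive thresholding, re-derived with explicit loops
oracle_detect <- function(filtered, rois, global_threshold) {
  h <- nrow(filtered)
  w <- ncol(filtered)
  out <- matrix(FALSE, h, w)
  for (roi in rois) {
    region <- oracle_rasterize(roi, h, w)
    roi_max <- max(filtered[region])
    for (r in seq_len(h)) {
      for (c in seq_len(w)) {
        if (region[r, c]) {
          if (roi_max == 0) {
            if (global_threshold == 0) out[r, c] <- TRUE
          } else if (filtered[r, c] >= global_threshold * roi_max) {
            out[r, c] <- TRUE
          }
        }
      }
    }
  }
  out
}

random_convex_polygon <- function(n_vertices, cx, cy, radius) {
  t <- sort(runif(n_vertices, 0, 2 * pi))
  polygon_roi(cx + radius * cos(t), cy + radius * sin(t))
}

# a minimal cohort metadata CSV; rows built from a data.frame
write_cohort_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

make_cohort_df <- function(n = 3L) {
  ids <- sprintf("P%02d", seq_len(n))
  data.frame(
    patient_id = ids,
    gender = rep_len(c("F", "M"), n),
    familiarity = rep_len(c("true", "false"), n),
    birth_date = as.character(1960 + seq_len(n)),
    onset_date = as.character(1990 + seq_len(n)),
    first_visit_date = as.character(2000 + seq_len(n)),
    image_path = paste0(ids, ".png"),
    stringsAsFactors = FALSE
  )
}

full_frame_mask <- function(value = FALSE) {
  matrix(value, working_resolution()["height"], working_resolution()["width"])
}
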