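# Seedable synthetic black-light face scenes with known ground truth.
#
# The generator emulates what makes clinical black-light photographs hard:
# an elliptical face on a dark background, skin whose intensity is dominated
# by the red channel, vitiligo patches that fluoresce in blue (and weaker in
# green), uneven illumination across the frame, overexposed highlights,
# beard-like texture, and dark occlusion bars (hair strands). Every scene
# carries an exact ground-truth mask and an annotation session (one ROI per
# patch, radially dilated by a stated margin), so every pipeline stage is
# testable without patient data.

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify one synthetic vitiligo patch
#'
#' @param center `c(x, y)` centre in 0-based pixel coordinates.
#' @param radii `c(rx, ry)` ellipse semi-axes in pixels.
#' @param blue_boost Additive blue-channel excess of patch over skin
#'   (must be > 0; default 0.3).
#' @param green_boost Additive green-channel excess (default 0.15).
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(center, radii, blue_boost = 0.3, green_boost = 0.15) {
  if (blue_boost <= 0) {
    stop("blue_boost must be positive")
  }
  list(
    center = as.numeric(center), radii = as.numeric(radii),
    blue_boost = blue_boost, green_boost = green_boost
  )
}

#' Specify a synthetic black-light face scene
#'
#' @param seed Integer seed; a fixed seed reproduces the scene byte for byte.
#' @param face_ellipse Face contour; default fits the working frame with
#'   margin.
#' @param skin_rgb Base skin color, red-dominant as under black light.
#' @param patches List of [patch_spec()].
#' @param illumination List `list(direction, strength)`: a linear
#'   multiplicative intensity ramp of the given relative strength along the
#'   given direction (radians).
#' @param overexposed List of [face_ellipse()] regions pushed to near-1
#'   intensity in all channels.
#' @param beard Optional `list(polygon, amplitude)`: multiplicative speckle
#'   texture of the given amplitude inside the polygon (stubble darkening).
#' @param occlusions List of [polygon_roi()] drawn as dark bars over the
#'   scene; ground truth excludes occluded pixels (a black hair strand is not
#'   detectable as vitiligo).
#' @param noise_sigma Per-channel additive Gaussian noise sd (default 0.01).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(seed,
                       face_ellipse = vitimap::face_ellipse(305, 203.5, 260, 170),
                       skin_rgb = c(0.55, 0.30, 0.25),
                       patches = list(),
                       illumination = list(direction = 0, strength = 0.2),
                       overexposed = list(),
                       beard = NULL,
                       occlusions = list(),
                       noise_sigma = 0.01) {
  stopifnot(inherits(face_ellipse, "face_ellipse"), length(skin_rgb) == 3L)
  structure(
    list(
      seed = as.integer(seed), face_ellipse = face_ellipse,
      skin_rgb = skin_rgb, patches = patches,
      illumination = illumination, overexposed = overexposed,
      beard = beard, occlusions = occlusions, noise_sigma = noise_sigma
    ),
    class = "scene_spec"
  )
}

#' Polygonal approximation of an ellipse (optionally radially dilated)
#'
#' @param e A [face_ellipse()].
#' @param margin Added to both semi-axes before polygonization; the ROIs a
#'   synthetic scene emits use margin 5 to mimic rough manual contouring.
#' @param n_vertices Number of polygon vertices.
#' @param height,width Frame bounds the vertices are clamped to.
#' @return A [polygon_roi()].
#' @export
ellipse_polygon <- function(e, margin = 0, n_vertices = 32L,
                            height = VT_HEIGHT, width = VT_WIDTH) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  x <- pmin(pmax(e$cx + (e$a + margin) * cos(t), 0), width - 1)
  y <- pmin(pmax(e$cy + (e$b + margin) * sin(t), 0), height - 1)
  polygon_roi(x, y)
}

#' Generate a synthetic black-light face photograph with ground truth
#'
#' Deterministic for a fixed spec. The face interior gets the base skin
#' color; each patch adds its blue/green boosts, so by construction patch
#' pixels exceed the surrounding skin in B and in G + B - R by at least the
#' boost (up to noise). The illumination ramp, overexposed highlights, beard
#' texture, occlusion bars and Gaussian noise are then applied in that order.
#' The ground-truth mask is the exact union of rasterized patch blobs inside
#' the face, minus occluded pixels. The emitted session holds one ROI per
#' patch (the patch ellipse dilated by 5 px), the face ellipse, filter 4 and
#' global threshold 0.5.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (407 x 610 x 3), `mask` (logical ground truth),
#'   and `session` (a `vt_session`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- VT_HEIGHT
    w <- VT_WIDTH
    planes <- lapply(1:3, function(i) matrix(0.05, h, w))
    face <- rasterize_ellipse(spec$face_ellipse, h, w)
    for (ch in 1:3) {
      planes[[ch]][face] <- spec$skin_rgb[ch]
    }
    gt <- matrix(FALSE, h, w)
    for (p in spec$patches) {
      pe <- face_ellipse(p$center[1L], p$center[2L], p$radii[1L], p$radii[2L])
      reg <- rasterize_ellipse(pe, h, w) & face
      planes[[2L]][reg] <- planes[[2L]][reg] + p$green_boost
      planes[[3L]][reg] <- planes[[3L]][reg] + p$blue_boost
      gt <- gt | reg
    }
    il <- spec$illumination
    if (!is.null(il) && il$strength > 0) {
      ux <- cos(il$direction)
      uy <- sin(il$direction)
      proj <- outer(seq_len(h) - 1, seq_len(w) - 1,
                    function(r, c) c * ux + r * uy)
      rng <- range(proj)
      ramp <- 1 - il$strength * (proj - rng[1L]) / (rng[2L] - rng[1L])
      for (ch in 1:3) {
        planes[[ch]] <- planes[[ch]] * ramp
      }
    }
    for (o in spec$overexposed) {
      reg <- rasterize_ellipse(o, h, w)
      for (ch in 1:3) {
        planes[[ch]][reg] <- 0.98
      }
    }
    if (!is.null(spec$beard)) {
      reg <- rasterize_roi(spec$beard$polygon, h, w) & face
      u <- runif(sum(reg))
      fac <- 1 - spec$beard$amplitude * u
      for (ch in 1:3) {
        planes[[ch]][reg] <- planes[[ch]][reg] * fac
      }
    }
    for (oc in spec$occlusions) {
      reg <- rasterize_roi(oc, h, w)
      for (ch in 1:3) {
        planes[[ch]][reg] <- 0.03
      }
      gt[reg] <- FALSE
    }
    if (spec$noise_sigma > 0) {
      for (ch in 1:3) {
        planes[[ch]] <- planes[[ch]] + rnorm(h * w, sd = spec$noise_sigma)
      }
    }
    img <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      img[, , ch] <- clip01(planes[[ch]])
    }
    rois <- lapply(spec$patches, function(p) {
      ellipse_polygon(
        face_ellipse(p$center[1L], p$center[2L], p$radii[1L], p$radii[2L]),
        margin = 5
      )
    })
    list(
      image = img, mask = gt,
      session = session(
        rois = rois, ellipse = spec$face_ellipse,
        filter_id = 4L, global_threshold = 0.5
      )
    )
  })
}

# map a template-frame ellipse region into a patient's frame
design_region_to_patient <- function(region, patient_e, template_e) {
  sx <- patient_e$a / template_e$a
  sy <- patient_e$b / template_e$b
  list(
    center = c(
      patient_e$cx + (region$center[1L] - template_e$cx) * sx,
      patient_e$cy + (region$center[2L] - template_e$cy) * sy
    ),
    radii = c(region$radii[1L] * sx, region$radii[2L] * sy)
  )
}

sample_cohort_spec <- function(i, n_random_patches, template_e, designed) {
  a <- runif(1, 235, 290)
  b <- runif(1, 152, 190)
  cx <- 305 + runif(1, -10, 10)
  cy <- 203.5 + runif(1, -10, 10)
  pe <- face_ellipse(cx, cy, a, b)
  n_over <- sample(0:2, 1L)
  overexposed <- lapply(seq_len(n_over), function(k) {
    phi <- runif(1, 0, 2 * pi)
    rad <- runif(1, 0.55, 0.8)
    face_ellipse(
      cx + rad * a * cos(phi), cy + rad * b * sin(phi),
      runif(1, 12, 25), runif(1, 12, 25)
    )
  })
  patches <- lapply(designed, function(d) {
    m <- design_region_to_patient(d, pe, template_e)
    patch_spec(m$center, m$radii)
  })
  keep_out <- c(overexposed, lapply(patches, function(p) {
    face_ellipse(p$center[1L], p$center[2L], p$radii[1L], p$radii[2L])
  }))
  n_rand <- if (n_random_patches[2L] > n_random_patches[1L]) {
    sample(n_random_patches[1L]:n_random_patches[2L], 1L)
  } else {
    n_random_patches[1L]
  }
  for (k in seq_len(n_rand)) {
    for (try in 1:50) {
      phi <- runif(1, 0, 2 * pi)
      rad <- 0.68 * sqrt(runif(1))
      px <- cx + rad * a * cos(phi)
      py <- cy + rad * b * sin(phi)
      rx <- runif(1, 8, 22)
      ry <- runif(1, 8, 22)
      inside <- ((abs(px - cx) + rx) / a)^2 + ((abs(py - cy) + ry) / b)^2 <= 0.92
      clear <- all(vapply(keep_out, function(o) {
        sqrt((px - o$cx)^2 + (py - o$cy)^2) >
          max(rx, ry) + max(o$a, o$b) + 12
      }, logical(1L)))
      if (inside && clear) {
        patches[[length(patches) + 1L]] <- patch_spec(c(px, py), c(rx, ry))
        keep_out[[length(keep_out) + 1L]] <- face_ellipse(px, py, rx, ry)
        break
      }
    }
  }
  beard <- NULL
  if (runif(1) < 0.4) {
    t <- seq(0.22 * pi, 0.78 * pi, length.out = 12L)
    beard <- list(
      polygon = polygon_roi(
        pmin(pmax(cx + 0.97 * a * cos(t), 0), VT_WIDTH - 1),
        pmin(pmax(cy + 0.97 * b * sin(t), 0), VT_HEIGHT - 1)
      ),
      amplitude = 0.15
    )
  }
  occlusions <- list()
  if (runif(1) < 0.3) {
    bx <- cx + runif(1, -0.4, 0.4) * a
    by <- cy - b
    len <- 0.5 * b
    wid <- runif(1, 3, 7)
    tilt <- runif(1, -0.3, 0.3)
    dx <- sin(tilt) * len
    dy <- cos(tilt) * len
    occlusions <- list(polygon_roi(
      pmin(pmax(c(bx - wid, bx + wid, bx + dx + wid, bx + dx - wid), 0), VT_WIDTH - 1),
      pmin(pmax(c(by, by, by + dy, by + dy), 0), VT_HEIGHT - 1)
    ))
  }
  scene_spec(
    seed = sample.int(.Machine$integer.max, 1L),
    face_ellipse = pe,
    patches = patches,
    illumination = list(direction = runif(1, 0, 2 * pi), strength = 0.2),
    overexposed = overexposed,
    beard = beard,
    occlusions = occlusions,
    noise_sigma = 0.01
  )
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n` synthetic face photographs (`P<i>.png`), annotation sessions
#' (`P<i>.json`), ground-truth masks (`P<i>_truth.png`; synthetic ground
#' truth, not clinical annotation), and a `metadata.csv`, in the cohort
#' layout the detection and aggregation commands consume.
#'
#' `occurrence_design` plants patches at known template coordinates in known
#' patient subsets, so aggregation tests can predict exact occurrence
#' percentages: each element is
#' `list(center = c(x, y), radii = c(rx, ry), patients = c(...))`
#' with `center`/`radii` in template coordinates and `patients` 1-based
#' indices. Patient face ellipses are sampled at least as large as the
#' template ellipse, so registration is contractive and a designed region
#' maps onto its template footprint without rounding gaps.
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed controlling every random choice.
#' @param dir Output directory (created if needed).
#' @param occurrence_design List of designed regions (see above); default
#'   none.
#' @param n_random_patches `c(min, max)` random patches per face
#'   (default 3 to 6; use `c(0, 0)` for design-only cohorts).
#' @return Invisibly, a manifest list with `dir`, `metadata` (data.frame),
#'   and the per-patient `specs`.
#' @export
generate_cohort <- function(n, seed, dir,
                            occurrence_design = list(),
                            n_random_patches = c(3L, 6L)) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  for (d in occurrence_design) {
    if (any(d$patients < 1L) || any(d$patients > n)) {
      stop("occurrence_design references patients outside 1..n")
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  template_e <- default_template()$ellipse
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      designed <- Filter(function(d) i %in% d$patients, occurrence_design)
      sample_cohort_spec(i, n_random_patches, template_e, designed)
    })
  })
  ids <- sprintf("P%02d", seq_len(n))
  meta <- with_seed(seed + 1L, {
    birth <- sample(1950:1995, n, replace = TRUE)
    onset <- pmin(birth + sample(5:40, n, replace = TRUE), 2018)
    visit <- pmin(onset + sample(0:10, n, replace = TRUE), 2020)
    data.frame(
      patient_id = ids,
      gender = sample(c("F", "M"), n, replace = TRUE),
      familiarity = sample(c("true", "false"), n, replace = TRUE),
      birth_date = as.character(birth),
      onset_date = as.character(onset),
      first_visit_date = as.character(visit),
      image_path = paste0(ids, ".png"),
      stringsAsFactors = FALSE
    )
  })
  for (i in seq_len(n)) {
    scene <- generate_scene(specs[[i]])
    save_image(scene$image, file.path(dir, paste0(ids[i], ".png")))
    save_mask(scene$mask, file.path(dir, paste0(ids[i], "_truth.png")))
    write_session(scene$session, file.path(dir, paste0(ids[i], ".json")))
  }
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(list(dir = dir, metadata = meta, specs = specs))
}
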