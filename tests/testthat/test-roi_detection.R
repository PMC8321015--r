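test_that("polygon rasterization counts pixel centres inside or on the boundary", {
  sq <- polygon_roi(c(10, 20, 20, 10), c(10, 10, 20, 20))
  m <- rasterize_roi(sq, 30, 30)
  expect_equal(sum(m), 121) # 11 x 11 including the boundary
  expect_identical(m, oracle_rasterize(sq, 30, 30))

  full <- polygon_roi(c(-1, 610, 610, -1), c(-1, -1, 407, 407))
  expect_equal(sum(rasterize_roi(full)), 610 * 407)

  outside <- polygon_roi(c(700, 710, 705), c(10, 10, 20))
  expect_error(rasterize_roi(outside), "outside")
})

test_that("rasterization agrees with the brute-force even-odd oracle", {
  set.seed(21)
  for (rep in 1:6) {
    roi <- random_convex_polygon(
      n_vertices = sample(3:7, 1),
      cx = runif(1, 8, 24), cy = runif(1, 8, 24), radius = runif(1, 4, 8)
    )
    expect_identical(
      rasterize_roi(roi, 32, 32),
      oracle_rasterize(roi, 32, 32),
      label = sprintf("rasterization rep %d", rep)
    )
  }
  # a non-convex (arrow-head) polygon exercises the even-odd rule proper
  arrow <- polygon_roi(c(2, 28, 10, 28), c(15, 2, 15, 28))
  expect_identical(rasterize_roi(arrow, 32, 32),
                   oracle_rasterize(arrow, 32, 32))
})

test_that("detection matches a brute-force reimplementation on small images", {
  set.seed(22)
  for (rep in 1:5) {
    h <- sample(16:32, 1)
    w <- sample(16:32, 1)
    filtered <- matrix(runif(h * w), h, w)
    rois <- lapply(seq_len(sample(1:3, 1)), function(i) {
      random_convex_polygon(
        sample(3:6, 1),
        cx = runif(1, 4, w - 5), cy = runif(1, 4, h - 5),
        radius = runif(1, 3, 6)
      )
    })
    t <- runif(1)
    got <- detect_patches(filtered, rois, t)
    want <- oracle_detect(filtered, rois, t)
    expect_identical(unname(got[, ]), want,
                     label = sprintf("detection rep %d (t = %.3f)", rep, t))
  }
})

test_that("the adaptive threshold scales per ROI and honours the limits", {
  filtered <- matrix(0, 40, 60)
  bright <- polygon_roi(c(5, 25, 25, 5), c(5, 5, 20, 20))
  dim_roi <- polygon_roi(c(35, 55, 55, 35), c(5, 5, 20, 20))
  filtered[10:15, 10:20] <- 0.8 # bright ROI content, max 0.8
  filtered[8, 8] <- 0.3
  filtered[10:15, 40:50] <- 0.2 # dim ROI content, max 0.2
  filtered[8, 38] <- 0.05

  mask <- detect_patches(filtered, list(bright, dim_roi), 0.5)
  at <- attr(mask, "adaptive_thresholds")
  expect_equal(at, c(0.4, 0.1)) # each ROI uses its own cutoff
  expect_true(all(mask[10:15, 10:20]))
  expect_false(mask[9, 9]) # 0.3 < 0.4 in the bright ROI
  expect_true(all(mask[10:15, 40:50])) # 0.2 >= 0.1 despite being dim
  expect_false(mask[9, 39])

  # threshold 0: every ROI pixel detected
  m0 <- detect_patches(filtered, list(bright), 0)
  expect_identical(unname(m0[, ]), rasterize_roi(bright, 40, 60))
  # threshold 1: only pixels at the ROI maximum
  m1 <- detect_patches(filtered, list(bright), 1)
  expect_identical(which(m1), which(filtered == 0.8 &
                                      rasterize_roi(bright, 40, 60)))
})

test_that("detection is monotone in the threshold and scale invariant", {
  set.seed(23)
  filtered <- matrix(runif(30 * 30), 30, 30)
  rois <- list(
    random_convex_polygon(5, 10, 10, 7),
    random_convex_polygon(4, 20, 20, 6)
  )
  ts <- sort(runif(5))
  masks <- lapply(ts, function(t) detect_patches(filtered, rois, t))
  for (i in seq_len(length(ts) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]),
                label = sprintf("mask(t=%.3f) subset of mask(t=%.3f)",
                                ts[i + 1], ts[i]))
  }
  ref <- detect_patches(filtered, rois, 0.5)
  for (c_scale in c(0.2, 0.5, 2)) {
    # the adaptive cutoff scales with the ROI max, so the mask cannot change
    expect_identical(
      unname(detect_patches(filtered * c_scale, rois, 0.5)[, ]),
      unname(ref[, ])
    )
  }
})

test_that("pixels outside every ROI never influence the result", {
  set.seed(24)
  filtered <- matrix(runif(30 * 30), 30, 30)
  roi <- polygon_roi(c(5, 15, 15, 5), c(5, 5, 15, 15))
  region <- rasterize_roi(roi, 30, 30)
  perturbed <- filtered
  perturbed[!region] <- runif(sum(!region))
  expect_identical(
    unname(detect_patches(filtered, list(roi), 0.5)[, ]),
    unname(detect_patches(perturbed, list(roi), 0.5)[, ])
  )
})

test_that("manual contouring equals detection at threshold zero", {
  fine <- polygon_roi(c(3, 12, 14, 8, 2), c(4, 3, 10, 14, 9))
  filtered <- matrix(runif(20 * 20), 20, 20)
  manual <- manual_patch(fine, 20, 20)
  auto <- detect_patches(filtered, list(fine), 0)
  expect_identical(manual, unname(auto[, ]))
  expect_error(manual_patch(polygon_roi(c(100, 110, 105), c(100, 100, 110)),
                            20, 20), "outside")
})

test_that("an all-dark ROI is flagged and detects nothing above threshold 0", {
  filtered <- matrix(0, 20, 20)
  roi <- polygon_roi(c(2, 10, 10, 2), c(2, 2, 10, 10))
  expect_warning(m <- detect_patches(filtered, list(roi), 0.5), "maximum gray")
  expect_equal(sum(m), 0)
  expect_warning(m0 <- detect_patches(filtered, list(roi), 0), "maximum gray")
  expect_identical(unname(m0[, ]), rasterize_roi(roi, 20, 20))
})

test_that("detection requires at least one ROI and a threshold in range", {
  filtered <- matrix(runif(10 * 10), 10, 10)
  roi <- polygon_roi(c(1, 5, 5, 1), c(1, 1, 5, 5))
  expect_error(detect_patches(filtered, list(), 0.5), "at least one ROI")
  expect_error(detect_patches(filtered, list(roi), -0.1), "\\[0, 1\\]")
  expect_error(detect_patches(filtered, list(roi), 1.5), "\\[0, 1\\]")
})
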