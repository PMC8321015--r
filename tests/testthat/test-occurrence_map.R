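test_that("occurrence percentages count patients per cell", {
  # 5 patients; cells covered by 0, 1, 2, 3, and all 5 of them
  masks <- lapply(1:5, function(i) full_frame_mask(FALSE))
  cells <- list(one = c(100, 100), two = c(150, 200),
                three = c(200, 300), all = c(250, 400))
  covered_by <- list(one = 1L, two = 1:2, three = 1:3, all = 1:5)
  for (nm in names(cells)) {
    for (i in covered_by[[nm]]) {
      masks[[i]][cells[[nm]][1], cells[[nm]][2]] <- TRUE
    }
  }
  om <- accumulate_masks(masks)
  expect_equal(om$n_patients, 5L)
  expect_equal(om$matrix[100, 100], 20)
  expect_equal(om$matrix[150, 200], 40)
  expect_equal(om$matrix[200, 300], 60)
  expect_equal(om$matrix[250, 400], 100)
  expect_equal(om$matrix[10, 10], 0)
  # every cell is 100 k / N for integer k
  expect_true(all(om$matrix * 5 / 100 == round(om$matrix * 5 / 100)))
  expect_true(all(om$matrix >= 0 & om$matrix <= 100))
})

test_that("accumulation conserves mass and ignores patient order", {
  set.seed(51)
  masks <- lapply(1:4, function(i) {
    m <- full_frame_mask(FALSE)
    m[sample(length(m), 500)] <- TRUE
    m
  })
  om <- accumulate_masks(masks)
  expect_equal(
    sum(om$matrix * om$n_patients / 100),
    sum(vapply(masks, sum, numeric(1)))
  )
  perm <- accumulate_masks(masks[c(3, 1, 4, 2)])
  expect_identical(perm$matrix, om$matrix)

  # adding an all-empty patient rescales every cell by N / (N + 1)
  om5 <- accumulate_masks(c(masks, list(full_frame_mask(FALSE))))
  expect_equal(om5$matrix, om$matrix * 4 / 5)
})

test_that("accumulation validates its inputs", {
  expect_error(accumulate_masks(list()), "at least one")
  expect_error(accumulate_masks(list(matrix(FALSE, 10, 10))), "407 x 610")
  bad <- full_frame_mask(FALSE)
  bad[1, 1] <- NA
  expect_error(accumulate_masks(list(bad)), "binary")
})

test_that("occurrence maps round-trip to CSV", {
  m <- full_frame_mask(FALSE)
  m[100:120, 200:260] <- TRUE
  om <- accumulate_masks(list(m, full_frame_mask(FALSE)))
  f <- tempfile(fileext = ".csv")
  write_map_csv(om, f)
  back <- as.matrix(read.csv(f, header = FALSE))
  expect_equal(unname(back), unname(om$matrix))
})

test_that("cohort filters select exactly the matching records", {
  dir <- withr::local_tempdir()
  df <- make_cohort_df(6L)
  df$gender <- c("F", "F", "M", "M", "F", "M")
  df$birth_date <- c("1960", "1970", "1980", "1990", "1955", "1985")
  df$onset_date <- c("1975", "1980", "2000", "2005", "2010", "1995")
  df$first_visit_date <- c("1980", "1981", "2010", "2006", "2012", "2004")
  write_cohort_csv(df, file.path(dir, "meta.csv"))
  rec <- load_cohort(file.path(dir, "meta.csv"))

  expect_equal(nrow(select_cohort(rec, cohort_filter())), 6L)
  expect_equal(select_cohort(rec, cohort_filter(gender = "female"))$patient_id,
               c("P01", "P02", "P05"))
  # no record matches: empty selection, not an error
  males_only <- rec[rec$gender == "male", , drop = FALSE]
  expect_equal(nrow(select_cohort(males_only, cohort_filter(gender = "female"))),
               0L)

  # brute-force predicate over onset age (onset year - birth year)
  f <- cohort_filter(onset_age_range = c(0, 18))
  got <- select_cohort(rec, f)$patient_id
  onset_age <- as.numeric(df$onset_date) - as.numeric(df$birth_date)
  want <- df$patient_id[onset_age >= 0 & onset_age <= 18]
  expect_equal(got, want)

  # delay between onset and first visit, in whole years
  got_d <- select_cohort(rec, cohort_filter(delay_range = c(0, 2)))$patient_id
  delay <- as.numeric(df$first_visit_date) - as.numeric(df$onset_date)
  expect_equal(got_d, df$patient_id[delay >= 0 & delay <= 2])

  # combined criteria intersect
  both <- select_cohort(rec, cohort_filter(gender = "male",
                                           delay_range = c(0, 2)))
  expect_equal(both$patient_id, intersect(c("P03", "P04", "P06"), got_d))
})

test_that("criteria on universally missing fields are skipped with a warning", {
  dir <- withr::local_tempdir()
  df <- make_cohort_df(3L)
  df$birth_date <- NULL
  write_cohort_csv(df, file.path(dir, "meta.csv"))
  rec <- load_cohort(file.path(dir, "meta.csv"))
  expect_warning(
    out <- select_cohort(rec, cohort_filter(onset_age_range = c(0, 18))),
    "skipped"
  )
  expect_equal(nrow(out), 3L) # criterion skipped, not applied as empty
})

test_that("map rendering is deterministic and keeps the template visible at zero", {
  tpl <- default_template()
  m <- full_frame_mask(FALSE)
  m[180:220, 280:330] <- TRUE
  om <- accumulate_masks(list(m, full_frame_mask(FALSE)))
  r1 <- render_map(om, tpl)
  r2 <- render_map(om, tpl)
  expect_identical(r1, r2)

  # zero-occurrence pixels away from the legend strip show the template
  zero_region <- r1[1:100, 1:100, ]
  expect_identical(zero_region, tpl$image[1:100, 1:100, ])
  # occurrence pixels are recolored
  expect_false(identical(r1[200, 300, ], tpl$image[200, 300, ]))

  # distinct occurrence levels get distinct colors: render one cell per
  # level of a 5-patient cohort and compare the painted pixels
  masks5 <- lapply(1:5, function(i) full_frame_mask(FALSE))
  for (lvl in 1:5) {
    for (i in seq_len(lvl)) {
      masks5[[i]][100, 100 + lvl] <- TRUE
    }
  }
  r5 <- render_map(accumulate_masks(masks5), tpl)
  painted <- t(sapply(1:5, function(lvl) r5[100, 100 + lvl, ]))
  expect_equal(nrow(unique(painted)), 5L)
})
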