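# Skeleton recording I/O and joint-feature selection.

test_that("CSV write/read round-trips a recording bit-exactly", {
  set.seed(1)
  tr <- toy_trial(list(PELVIS = matrix(rnorm(15), 5),
                       HEAD = matrix(rnorm(15), 5)),
                  subject_id = "S9", group = "stroke")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(tr, path)
  back <- read_trial(path, subject_id = "S9", group = "stroke")
  expect_identical(as.matrix(back[-(1:2)]), as.matrix(tr[-(1:2)]))
  expect_identical(back$frame, tr$frame)
  expect_equal(trial_group(back), "stroke")
})

test_that("JSON mirror round-trips and carries metadata", {
  set.seed(2)
  tr <- toy_trial(list(PELVIS = matrix(rnorm(12), 4)),
                  subject_id = "S1", group = "older_adult")
  path <- withr::local_tempfile(fileext = ".json")
  write_trial(tr, path)
  back <- read_trial(path)
  expect_equal(as.matrix(back[-(1:2)]), as.matrix(tr[-(1:2)]), tolerance = 1e-12)
  expect_equal(trial_subject(back), "S1")
  expect_equal(trial_group(back), "older_adult")
})

test_that("fps is inferred from 1/30 s timestamp spacing", {
  tr <- toy_trial(list(PELVIS = matrix(0, 60, 3) + rnorm(180, sd = 1e-3)),
                  fps = 30)
  expect_equal(trial_fps(tr), 30)
  expect_equal(trial_duration(tr), 2)
})

test_that("schema violations are rejected", {
  set.seed(3)
  tr <- toy_trial(list(PELVIS = matrix(rnorm(9), 3)))
  # drop one coordinate column of a triple
  broken <- tr; broken$PELVIS_z <- NULL
  expect_error(validate_tug_trial(broken), class = "tug_format_error")
  # unknown joint name
  bad <- tr; bad$NOTAJOINT_x <- 0; bad$NOTAJOINT_y <- 0; bad$NOTAJOINT_z <- 0
  expect_error(validate_tug_trial(bad), class = "tug_format_error")
  # NaN positions refused at write time
  nan <- tr; nan$PELVIS_x[2] <- NaN
  expect_error(write_trial(nan, withr::local_tempfile(fileext = ".csv")),
               class = "tug_validation_error")
  # non-monotone timestamps
  tw <- tr; tw$timestamp <- c(0, 2, 1) / 30
  expect_error(validate_tug_trial(tw), class = "tug_validation_error")
})

test_that("select_features returns joint-major 3k columns and validates", {
  set.seed(4)
  tr <- toy_trial(list(PELVIS = matrix(rnorm(30), 10),
                       HEAD = matrix(rnorm(30), 10),
                       SPINE_CHEST = matrix(rnorm(30), 10)))
  f1 <- select_features(tr, "PELVIS")
  expect_equal(dim(f1), c(10, 3))
  expect_equal(colnames(f1), c("PELVIS_x", "PELVIS_y", "PELVIS_z"))
  f2 <- select_features(tr, c("PELVIS", "HEAD"))
  expect_equal(dim(f2), c(10, 6))
  expect_equal(f2[, 4:6], select_features(tr, "HEAD"), ignore_attr = TRUE)
  expect_error(select_features(tr, character()), class = "tug_lookup_error")
  expect_error(select_features(tr, "ANKLE_LEFT"), class = "tug_lookup_error")
})

test_that("the joint enumeration covers the study's input configurations", {
  j <- azure_kinect_joints()
  expect_length(j, 32)
  expect_length(unique(j), 32)
  # the five single-feature inputs and their combinations are addressable
  study_inputs <- list(
    "PELVIS", "SPINE_CHEST", "HEAD",
    c("HAND_LEFT", "HAND_RIGHT"), c("ANKLE_LEFT", "ANKLE_RIGHT")
  )
  for (sel in study_inputs) expect_true(all(sel %in% j))
  all15 <- unique(unlist(study_inputs))
  expect_true(all(all15 %in% j))
})

test_that("event sidecar round-trips and validates ordering", {
  ev <- tug_events(c(1, 2.5, 5, 6, 9, 10.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$time_s, ev$time_s)
  expect_equal(back$label, 0:5)
  expect_error(tug_events(c(1, 2, 2, 3, 4, 5)), class = "tug_validation_error")
})
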