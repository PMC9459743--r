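# Frame metrics, event-timing errors, ICC and subtask durations.

test_that("confusion counts partition the frames for every class", {
  set.seed(41)
  pred <- random_labels(60)
  truth <- random_labels(60)
  cm <- frame_confusion(pred, truth)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, rep(60L, 5))
  # perfect prediction: no false positives or negatives
  cm0 <- frame_confusion(truth, truth)
  expect_true(all(cm0$fp == 0 & cm0$fn == 0))
  # everything predicted as one class with truth half that class
  cm1 <- frame_confusion(rep("walk", 20), c(rep("walk", 10), rep("sit", 10)))
  w <- cm1[cm1$class == "walk", ]
  expect_equal(c(w$tp, w$fp, w$fn, w$tn), c(10, 10, 0, 0))
  expect_error(frame_confusion(pred, truth[-1]), class = "tug_input_error")
})

test_that("precision/recall/F1 follow their defining ratios", {
  cm <- tibble::tibble(class = "walk", tp = 30, fp = 10, fn = 6, tn = 54)
  out <- precision_recall_f1(cm)
  expect_equal(out$precision, 0.75)
  expect_equal(out$recall, 30 / 36)
  expect_equal(out$f1, 2 * 0.75 * (30 / 36) / (0.75 + 30 / 36))
  expect_equal(f1_score(1, 1), 1)
  # absent class: undefined metrics become NA with a warning
  cm2 <- tibble::tibble(class = "turn", tp = 0, fp = 0, fn = 0, tn = 100)
  expect_warning(out2 <- precision_recall_f1(cm2),
                 class = "tug_undefined_metric")
  expect_true(is.na(out2$precision))
})

test_that("accuracy is the fraction of correct frames (micro-averaged)", {
  truth <- c(rep("sit", 3), rep("walk", 3), rep("turn", 3))
  pred <- c("sit", "sit", "walk", "walk", "walk", "walk", "turn", "turn", "sit")
  expect_equal(frame_accuracy(pred, truth), 7 / 9)
  # equals Eq-style micro average over one-vs-rest counts
  cm <- frame_confusion(pred, truth)
  expect_equal(sum(cm$tp) / 9, 7 / 9)
  expect_equal(frame_accuracy(truth, truth), 1)
  half <- truth; half[1:4] <- "stand_to_sit"; half[5] <- "turn"
  expect_equal(frame_accuracy(half, truth), 4 / 9)
  expect_error(frame_accuracy(character(), character()), class = "tug_input_error")
})

test_that("event errors capture shifts and total-time cancellation", {
  truth <- tug_events(c(1, 2, 5, 6, 9, 10))
  expect_equal(event_errors(truth, truth)$abs_error, rep(0, 7))
  shifted <- tug_events(c(1, 2, 5, 6, 9, 10) + 3 / 30)
  err <- event_errors(shifted, truth)
  expect_equal(err$abs_error[1:6], rep(0.1, 6))
  expect_equal(err$abs_error[err$event == "total_tug_time"], 0)
  # aggregate MAE and population STD
  errs <- tibble::tibble(event = rep("total_tug_time", 2),
                         abs_error = c(0.1, 0.3))
  s <- event_error_summary(errs)
  expect_equal(s$mae, 0.2)
  expect_equal(s$std, 0.1)
})

test_that("ICC(2,1) matches an explicit ANOVA mean-squares oracle", {
  ratings <- cbind(c(9, 8, 7, 10, 6), c(9.5, 8.1, 7.2, 10.4, 6.3))
  expect_equal(icc(ratings), icc_oracle(ratings), tolerance = 1e-12)
  # frozen reference value (pingouin ICC(A,1)) for the same table
  expect_equal(icc(ratings), 0.979478, tolerance = 1e-6)
  set.seed(43)
  r2 <- matrix(rnorm(24), 12, 2)
  expect_equal(icc(r2), icc_oracle(r2), tolerance = 1e-12)
  # duplicated rater: perfect agreement
  expect_equal(icc(cbind(1:5, 1:5)), 1)
  # constant offset is penalized under absolute agreement
  expect_lt(icc(cbind(1:5, 1:5 + 10)), 1)
  expect_warning(v <- icc(matrix(3, 4, 2)), class = "tug_undefined_metric")
  expect_true(is.na(v))
  expect_error(icc(cbind(1:2, 2:3)), class = "tug_input_error")
})

test_that("subtask durations and walk speeds derive from boundaries", {
  # walk of 90 frames at 30 fps over 3 m
  b <- c(30, 60, 150, 180, 270, 300)
  d <- subtask_durations(b, fps = 30, walk_distance = 3, n_frames = 330)
  expect_equal(d$duration[d$subtask == "walk"], 3)
  expect_equal(d$speed[d$subtask == "walk"], 1)
  expect_equal(sum(d$duration), 11)
  expect_true(all(is.na(d$speed[!grepl("walk", d$subtask)])))
  # noiseless synthetic trial durations equal the phase plan
  sim <- noiseless_trial("older_adult", seed = 19)
  seg <- dtw_correct(sim$labels$label)
  ds <- subtask_durations(seg, fps = 30)
  expect_equal(ds$duration, sim$plan$duration, tolerance = 1 / 30 + 1e-9,
               ignore_attr = TRUE)
})

test_that("metric rates stay in [0,1] on fuzzed inputs", {
  set.seed(44)
  for (rep in 1:30) {
    T0 <- sample(5:60, 1)
    pred <- random_labels(T0); truth <- random_labels(T0)
    acc <- frame_accuracy(pred, truth)
    expect_true(acc >= 0 && acc <= 1)
    out <- suppressWarnings(precision_recall_f1(frame_confusion(pred, truth)))
    rates <- c(out$precision, out$recall, out$f1)
    expect_true(all(is.na(rates) | (rates >= 0 & rates <= 1)))
    ok <- !is.na(out$f1)
    expect_true(all(out$f1[ok] <= pmax(out$precision[ok], out$recall[ok]) + 1e-12))
    expect_true(all(out$f1[ok] >= pmin(out$precision[ok], out$recall[ok]) - 1e-12))
  }
})

test_that("report generation is pure and carries all sections", {
  set.seed(45)
  mk <- function() {
    tibble::tibble(
      pred_labels = list(random_labels(40), random_labels(50)),
      truth_labels = list(random_labels(40), random_labels(50)),
      pred_events = list(tug_events(c(1, 2, 4, 5, 7, 8)),
                         tug_events(c(1, 2, 5, 6, 8, 9))),
      truth_events = list(tug_events(c(1.1, 2, 4, 5.2, 7, 8)),
                          tug_events(c(1, 2.2, 5, 6, 8, 9.4)))
    )
  }
  set.seed(46); r1 <- suppressWarnings(segmentation_report(mk()))
  set.seed(46); r2 <- suppressWarnings(segmentation_report(mk()))
  expect_identical(r1, r2)
  expect_s3_class(tidy(r1), "tbl_df")
  g <- glance(r1)
  expect_true(g$accuracy >= 0 && g$accuracy <= 1)
  expect_gte(g$total_tug_mae, 0)
})
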