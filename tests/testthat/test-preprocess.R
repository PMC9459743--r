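# Filtering, normalization, axis alignment and windowing.

test_that("Butterworth design matches the reference discrete design", {
  co <- butter_coefficients(4, 0.3, 30)
  # frozen scipy.signal.butter(4, 0.3/15) reference values
  b_ref <- c(8.984861464e-07, 3.593944586e-06, 5.390916878e-06,
             3.593944586e-06, 8.984861464e-07)
  a_ref <- c(1, -3.835825541, 5.520819137, -3.533535219, 0.8485559993)
  expect_equal(co$b, b_ref, tolerance = 1e-8)
  expect_equal(co$a, a_ref, tolerance = 1e-9)
  expect_equal(sum(co$b) / sum(co$a), 1, tolerance = 1e-12)
})

test_that("constant and zero signals pass through the zero-phase filter", {
  spec <- filter_spec()
  expect_equal(butterworth_lowpass(rep(2.5, 200), spec), rep(2.5, 200),
               tolerance = 1e-9)
  expect_equal(butterworth_lowpass(numeric(200) , spec), numeric(200))
  expect_error(filter_spec(cutoff_hz = 20, fs_hz = 30),
               class = "tug_parameter_error")
  expect_error(butterworth_lowpass(rnorm(10), spec),
               class = "tug_parameter_error")
})

test_that("1 Hz attenuation matches the analytic squared magnitude", {
  spec <- filter_spec(order = 4, cutoff_hz = 0.3, fs_hz = 30)
  t <- (0:2699) / 30
  x <- sin(2 * pi * 1 * t)
  y <- butterworth_lowpass(x, spec)
  mid <- 300:2400
  measured <- sqrt(2 * mean(y[mid]^2))
  analytic <- butter_gain(spec, 1)^2
  expect_lt(abs(measured - analytic), 1e-3)
  # the single-pass gain approximates the analog prototype value (~0.008)
  expect_equal(butter_gain(spec, 1), (1 + (1 / 0.3)^8)^-0.5, tolerance = 0.02)
})

test_that("min-max normalization maps columns onto [0,1] and flags constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  m <- cbind(a = c(0, 0.25, 1), b = c(5, -3, 7))
  out <- minmax_normalize(m)
  expect_equal(out[, "a"], c(0, 0.25, 1), ignore_attr = TRUE)
  expect_equal(range(out), c(0, 1))
  expect_warning(z <- minmax_normalize(cbind(c(1, 2, 3), c(4, 4, 4))),
                 class = "tug_degenerate_warning")
  expect_equal(z[, 2], rep(0, 3))
})

test_that("axis alignment recovers the walking axis from any azimuth", {
  sim <- noiseless_trial("older_adult", seed = 21, azimuth = 37 * pi / 180)
  al <- align_axes(sim$trial)
  # outbound displacement lies along +x within 1 degree
  ref <- noiseless_trial("older_adult", seed = 21, azimuth = 0)
  i <- which.max(ref$trial$PELVIS_x)
  ang <- atan2(al$PELVIS_z[i] - al$PELVIS_z[1], al$PELVIS_x[i] - al$PELVIS_x[1])
  expect_lt(abs(ang) * 180 / pi, 1)
  expect_gt(al$PELVIS_x[i] - al$PELVIS_x[1], 2.9)
  # vertical coordinate untouched
  expect_identical(al$PELVIS_y, sim$trial$PELVIS_y)
  # idempotent within tolerance
  al2 <- align_axes(al)
  expect_equal(al2$PELVIS_x, al$PELVIS_x, tolerance = 1e-9)
  expect_equal(al2$HEAD_z, al$HEAD_z, tolerance = 1e-9)
})

test_that("axis alignment is rigid: inter-joint distances preserved", {
  sim <- noiseless_trial("stroke", seed = 2, azimuth = 1.1)
  al <- align_axes(sim$trial)
  d_before <- sqrt((sim$trial$PELVIS_x - sim$trial$HEAD_x)^2 +
                   (sim$trial$PELVIS_y - sim$trial$HEAD_y)^2 +
                   (sim$trial$PELVIS_z - sim$trial$HEAD_z)^2)
  d_after <- sqrt((al$PELVIS_x - al$HEAD_x)^2 + (al$PELVIS_y - al$HEAD_y)^2 +
                  (al$PELVIS_z - al$HEAD_z)^2)
  expect_equal(d_after, d_before, tolerance = 1e-9)
  # degenerate: no walking displacement
  still <- toy_trial(list(PELVIS = matrix(rnorm(300, sd = 0.01), 100)))
  expect_error(align_axes(still), class = "tug_alignment_error")
})

test_that("windows are per-frame with replicated edges and match direct slices", {
  f <- matrix(seq_len(100 * 2), 100, 2)   # arithmetic ramp
  wn <- make_windows(f, window_spec(8))
  expect_equal(wn$n, 100)
  expect_equal(wn$centers, 0:99)
  # brute-force slice oracle with clamped indices
  for (i in c(1, 2, 5, 50, 99, 100)) {
    idx <- pmin(pmax(i + (-4:3), 1), 100)
    expect_equal(window_at(wn, i), f[idx, , drop = FALSE], ignore_attr = TRUE)
  }
  # frame 1: first frame replicated into the left half
  w1 <- window_at(wn, 1)
  expect_true(all(w1[1:5, 1] == f[1, 1]))
  # degenerate single-frame input
  w <- make_windows(matrix(1:3, 1, 3), window_spec(8))
  expect_equal(w$n, 1)
  expect_true(all(window_at(w, 1) == rep(1:3, each = 8)))
})

test_that("preprocessing pipeline output is normalized and ordered filter-then-normalize", {
  sim <- noiseless_trial("healthy_young", seed = 13)
  f <- preprocess_trial(sim$trial)
  expect_equal(dim(f), c(nrow(sim$trial), 3))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(apply(f, 2, min), rep(0, 3), ignore_attr = TRUE)
  expect_equal(apply(f, 2, max), rep(1, 3), ignore_attr = TRUE)
})
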