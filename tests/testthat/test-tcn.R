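# Dilated TCN: architecture, parameter counts, prediction contracts,
# training behavior and subject-wise splits.

test_that("a blockless model is a plain dense softmax with 20 parameters", {
  cfg <- tcn_config(window_size = 1, n_blocks = 0, input_dim = 3, n_classes = 5)
  model <- build_tcn(cfg, seed = 1)
  expect_equal(count_parameters(model), 20)
  probs <- predict_frames(model, matrix(rnorm(12), 4, 3))
  expect_equal(dim(probs), c(4, 5))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
})

test_that("parameter count matches an independent per-layer tally", {
  expected_count <- function(cfg) {
    k <- cfg$kernel_size
    total <- 0
    cin <- cfg$input_dim
    for (b in seq_len(cfg$n_blocks)) {
      cout <- cfg$channels[b]
      block_in <- cin
      for (l in seq_len(cfg$layers_per_block)) {
        total <- total + k * cin * cout + cout
        cin <- cout
      }
      if (block_in != cout) total <- total + block_in * cout + cout
    }
    cl <- if (cfg$n_blocks > 0) cin else cfg$input_dim
    total + cfg$window_size * cl * cfg$n_classes + cfg$n_classes
  }
  cfgs <- list(
    tcn_config(),
    tcn_config(kernel_size = 5, channels = c(8, 8, 8)),
    tcn_config(n_blocks = 2, layers_per_block = 3, channels = c(12, 20)),
    tcn_config(window_size = 16, input_dim = 6)
  )
  for (cfg in cfgs) {
    expect_equal(count_parameters(build_tcn(cfg, seed = 2)), expected_count(cfg))
  }
  # doubling every channel width strictly increases the count
  n1 <- count_parameters(build_tcn(tcn_config(channels = c(16, 16, 24))))
  n2 <- count_parameters(build_tcn(tcn_config(channels = c(32, 32, 48))))
  expect_gt(n2, n1)
})

test_that("architecture invariants are validated", {
  expect_error(tcn_config(kernel_size = 4), class = "tug_parameter_error")
  # window too small to host the largest dilation
  expect_error(tcn_config(window_size = 4, n_blocks = 3),
               class = "tug_parameter_error")
  cfg <- tcn_config()
  expect_equal(cfg$dilations, c(1, 2, 4))
  model <- build_tcn(cfg)
  expect_error(predict_frames(model, matrix(0, 10, 6)), class = "tug_shape_error")
})

test_that("predictions are proper distributions and depend only on the window", {
  cfg <- tcn_config()
  model <- build_tcn(cfg, seed = 5)
  set.seed(6)
  f <- matrix(rnorm(300), 100, 3)
  p1 <- predict_frames(model, f)
  expect_equal(rowSums(p1), rep(1, 100), tolerance = 1e-6)
  # perturbing frames outside frame 50's window (offsets -4..3) leaves it alone
  f2 <- f
  f2[c(1:40, 60:100), ] <- rnorm(81 * 3, sd = 5)
  p2 <- predict_frames(model, f2)
  expect_equal(p2[50, ], p1[50, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(p2[44, ], p1[44, ])))
  # single-frame recording still yields one distribution (edge replication)
  p3 <- predict_frames(model, matrix(rnorm(3), 1, 3))
  expect_equal(dim(p3), c(1, 5))
})

test_that("training is deterministic in the seed and records history", {
  ds <- prepare_dataset(simulate_tug(6, groups = "healthy_young", seed = 55))
  tc <- train_config(max_epochs = 3, patience = 50, seed = 8)
  f1 <- tcn_train(ds, train = tc)
  f2 <- tcn_train(ds, train = tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$history), 3)
  expect_true(all(c("train_loss", "val_loss", "val_acc") %in% names(f1$history)))
  # tidiers
  expect_equal(tidy(f1), f1$history)
  expect_equal(glance(f1)$n_parameters, count_parameters(f1))
})

test_that("early stopping halts after patience epochs without improvement", {
  ds <- prepare_dataset(simulate_tug(6, groups = "healthy_young", seed = 56))
  # zero learning rate: the validation loss can never improve after epoch 1
  fit <- tcn_train(ds, train = train_config(learning_rate = 0, patience = 1,
                                            max_epochs = 50, seed = 3))
  expect_equal(nrow(fit$history), 2)
  expect_equal(fit$best_epoch, 1)
  expect_equal(fit$stop_reason, "early_stopping")
  # best-epoch weights restored: constant loss means params equal the init
  expect_equal(fit$history$val_loss[1], fit$history$val_loss[2])
})

test_that("subject-wise splits are disjoint, exhaustive and seeded", {
  subj <- sprintf("S%02d", 1:50)
  folds <- kfold_split(subj, k = 5, seed = 4)
  expect_length(folds, 5)
  expect_equal(lengths(folds), rep(10L, 5), ignore_attr = TRUE)
  expect_setequal(unlist(folds), subj)
  expect_equal(sum(lengths(folds)), 50)   # pairwise disjoint given the union
  expect_identical(folds, kfold_split(subj, k = 5, seed = 4))
  expect_false(identical(folds, kfold_split(subj, k = 5, seed = 5)))
  expect_error(kfold_split(subj[1:3], k = 5), class = "tug_parameter_error")

  ho <- holdout_split(subj, fractions = c(0.6, 0.2, 0.2), seed = 4)
  expect_equal(lengths(ho), c(train = 30L, val = 10L, test = 10L))
  expect_setequal(unlist(ho), subj)
  expect_length(intersect(ho$train, ho$test), 0)
  expect_length(intersect(ho$train, ho$val), 0)
  # uneven sizes stay as balanced as integer division allows
  ho7 <- holdout_split(sprintf("S%d", 1:7))
  expect_equal(sum(lengths(ho7)), 7)
  expect_true(all(lengths(ho7) >= 1))
})

test_that("compiled kernels agree with the pure-R reference implementation", {
  ns <- asNamespace("tugseg")
  set.seed(77)
  for (rep in 1:3) {
    cfg <- tcn_config(n_blocks = rep - 1, layers_per_block = 2,
                      channels = c(5, 7, 9), kernel_size = c(3, 5, 3)[rep])
    model <- build_tcn(cfg, seed = rep)
    n <- 11
    xs <- matrix(rnorm(n * cfg$window_size * 3), n * cfg$window_size, 3)
    y <- sample(1:5, n, replace = TRUE)
    fR <- ns$tcn_forward(model, xs, n, cache = TRUE)
    gR <- ns$tcn_backward(model, fR, y, n)
    pC <- ns$.tcn_probs_cpp(xs, n, model$params, ns$cfg_ints(cfg))
    st <- ns$.tcn_step_cpp(xs, n, y, model$params, ns$cfg_ints(cfg))
    expect_equal(pC, fR$probs, tolerance = 1e-12, ignore_attr = TRUE)
    for (nm in names(gR)) {
      expect_equal(st$grads[[nm]], gR[[nm]], tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("reference backprop matches finite-difference gradients", {
  ns <- asNamespace("tugseg")
  set.seed(88)
  cfg <- tcn_config(n_blocks = 2, layers_per_block = 2, channels = c(4, 6))
  model <- build_tcn(cfg, seed = 9)
  n <- 7
  xs <- matrix(rnorm(n * 8 * 3), n * 8, 3)
  y <- sample(1:5, n, replace = TRUE)
  fwd <- ns$tcn_forward(model, xs, n, cache = TRUE)
  grads <- ns$tcn_backward(model, fwd, y, n)
  loss_at <- function(m) {
    f <- ns$tcn_forward(m, xs, n)
    mean(-log(f$probs[cbind(seq_len(n), y)]))
  }
  for (nm in c("b1_l1_W", "b2_l2_W", "b1_proj_W", "head_W", "head_b")) {
    p <- model$params[[nm]]
    for (ii in sample(length(p), min(4, length(p)))) {
      eps <- 1e-6
      m1 <- model; m1$params[[nm]][ii] <- p[ii] + eps
      m2 <- model; m2$params[[nm]][ii] <- p[ii] - eps
      num <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4)
    }
  }
})
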