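# Dilated temporal convolutional network frame classifier, implemented on
# base matrix primitives (no deep-learning framework is assumed). Input is a
# batch of W-frame windows; each temporal block stacks dilated convolutions
# (dilation doubling per block) with a residual connection, and a dense
# softmax head maps the window's features to class scores for its center
# frame. Windows are stacked window-major into (N*W) x C matrices so every
# convolution is an im2col gather plus one BLAS matrix multiply.

#' Model architecture configuration
#'
#' Defaults are the tuned architecture: kernel size 3, window size 8, three
#' temporal blocks of two convolutional layers each, dilation doubling per
#' block (1, 2, 4), five classes. The channel plan is a package default
#' chosen for single-CPU training speed; published parameter counts for this
#' architecture family are treated as a reference, not a constraint (see the
#' methods vignette).
#'
#' @param kernel_size Odd convolution kernel size.
#' @param window_size Frames per input window.
#' @param n_blocks Number of temporal blocks (0 = dense head only).
#' @param layers_per_block Dilated convolution layers per block.
#' @param channels Per-block channel widths (recycled to `n_blocks`).
#' @param n_classes Number of output classes.
#' @param input_dim Input channels (3 per selected joint).
#' @return A `tug_tcn_config` list with the dilation plan attached.
#' @export
tcn_config <- function(kernel_size = 3, window_size = 8, n_blocks = 3,
                       layers_per_block = 2, channels = c(16, 16, 24),
                       n_classes = 5, input_dim = 3) {
  if (kernel_size < 1 || kernel_size %% 2 == 0) {
    abort("kernel_size must be odd and >= 1", class = "tug_parameter_error")
  }
  if (window_size < 1 || n_blocks < 0 || layers_per_block < 1 ||
      n_classes < 2 || input_dim < 1) {
    abort("invalid architecture sizes", class = "tug_parameter_error")
  }
  channels <- if (n_blocks > 0) rep_len(channels, n_blocks) else integer()
  dilations <- if (n_blocks > 0) 2^(0:(n_blocks - 1)) else integer()
  if (n_blocks > 0 && kernel_size > 1 && window_size < max(dilations) + 1) {
    abort("window smaller than the receptive-field minimum for the dilation plan",
          class = "tug_parameter_error")
  }
  structure(
    list(kernel_size = kernel_size, window_size = window_size,
         n_blocks = n_blocks, layers_per_block = layers_per_block,
         channels = channels, dilations = dilations,
         n_classes = n_classes, input_dim = input_dim),
    class = "tug_tcn_config"
  )
}

#' Optimization configuration
#'
#' Defaults follow the tuned training protocol: Adam, learning rate 7e-5,
#' batch size 1024, early stopping on validation loss with patience 50, and a
#' subject-wise 6:2:2 train/validation/test split.
#'
#' @param learning_rate Optimizer step size.
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param patience Early-stopping patience in epochs.
#' @param batch_size Windows per minibatch.
#' @param max_epochs Hard epoch cap.
#' @param split Length-3 positive fractions summing to 1.
#' @param seed Seed for weight init, splitting and shuffling.
#' @return A `tug_train_config` list.
#' @export
train_config <- function(learning_rate = 7e-5, optimizer = c("adam", "rmsprop"),
                         patience = 50, batch_size = 1024, max_epochs = 300,
                         split = c(0.6, 0.2, 0.2), seed = 1) {
  optimizer <- match.arg(optimizer)
  if (learning_rate < 0 || patience < 1 || batch_size < 1 || max_epochs < 1) {
    abort("invalid training parameters", class = "tug_parameter_error")
  }
  if (length(split) != 3 || any(split <= 0) || abs(sum(split) - 1) > 1e-8) {
    abort("split must be 3 positive fractions summing to 1",
          class = "tug_parameter_error")
  }
  structure(list(learning_rate = learning_rate, optimizer = optimizer,
                 patience = patience, batch_size = batch_size,
                 max_epochs = max_epochs, split = split, seed = seed),
            class = "tug_train_config")
}

#' Build a dilated TCN with randomly initialized weights
#'
#' @param config A [tcn_config()].
#' @param seed Seed for He/Glorot weight initialization.
#' @return A `tug_tcn` model handle (configuration plus named parameter list).
#' @export
build_tcn <- function(config = tcn_config(), seed = 1) {
  stopifnot(inherits(config, "tug_tcn_config"))
  set.seed(seed)
  k <- config$kernel_size
  params <- list()
  cin <- config$input_dim
  for (b in seq_len(config$n_blocks)) {
    cout <- config$channels[b]
    block_in <- cin
    for (l in seq_len(config$layers_per_block)) {
      fan_in <- k * cin
      params[[sprintf("b%d_l%d_W", b, l)]] <-
        matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
      params[[sprintf("b%d_l%d_b", b, l)]] <- numeric(cout)
      cin <- cout
    }
    if (block_in != cout) {
      params[[sprintf("b%d_proj_W", b)]] <-
        matrix(stats::rnorm(block_in * cout, 0, sqrt(1 / block_in)), block_in, cout)
      params[[sprintf("b%d_proj_b", b)]] <- numeric(cout)
    }
  }
  c_last <- if (config$n_blocks > 0) cin else config$input_dim
  fan_in <- config$window_size * c_last
  params[["head_W"]] <- matrix(
    stats::rnorm(fan_in * config$n_classes, 0,
                 sqrt(2 / (fan_in + config$n_classes))),
    fan_in, config$n_classes
  )
  params[["head_b"]] <- numeric(config$n_classes)
  structure(list(config = config, params = params), class = "tug_tcn")
}

#' Count trainable parameters
#'
#' @param model A `tug_tcn` or `tug_tcn_fit`.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "tug_tcn_fit")) model <- model$model
  stopifnot(inherits(model, "tug_tcn"))
  sum(vapply(model$params, length, integer(1)))
}

# Batches are stacked position-major: rows (t-1)*n + (1:n) of a (n*W) x C
# matrix hold window position t of all n windows. A dilated kernel tap with
# offset o then maps contiguous row block [positions t0..t1] to contiguous
# row block [t0+o..t1+o]: each tap is one BLAS product plus a block add, with
# zero padding implicit in the skipped positions.
#
# Production training and inference run through the compiled kernels in
# src/tcn_kernels.cpp (same arithmetic on windows x channels x positions
# cubes); tcn_forward()/tcn_backward() below are the pure-R reference
# implementation, kept for verification.

# config fields coerced for the C++ side
cfg_ints <- function(config) {
  list(kernel_size = as.integer(config$kernel_size),
       window_size = as.integer(config$window_size),
       n_blocks = as.integer(config$n_blocks),
       layers_per_block = as.integer(config$layers_per_block),
       n_classes = as.integer(config$n_classes),
       channels = as.integer(config$channels),
       dilations = as.integer(config$dilations))
}

# forward pass over a position-major (n*W) x d batch; returns probabilities
# and (optionally) the per-layer cache needed for backprop
tcn_forward <- function(model, xs, n, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernel_size
  W <- cfg$window_size
  X <- xs
  caches <- list()
  for (b in seq_len(cfg$n_blocks)) {
    offs <- cfg$dilations[b] * (seq_len(k) - (k + 1) / 2)
    inp <- X
    layers <- list()
    for (l in seq_len(cfg$layers_per_block)) {
      cin <- ncol(X)
      Wl <- p[[sprintf("b%d_l%d_W", b, l)]]
      # each dilated kernel tap maps a contiguous block of window positions
      # onto a shifted contiguous block: one BLAS product and one block add
      Z <- matrix(rep(p[[sprintf("b%d_l%d_b", b, l)]], each = n * W), n * W)
      for (j in seq_len(k)) {
        o <- offs[j]
        t0 <- max(1, 1 - o); t1 <- min(W, W - o)
        if (t0 > t1) next
        rows_out <- ((t0 - 1) * n + 1):(t1 * n)
        Wj <- Wl[((j - 1) * cin + 1):(j * cin), , drop = FALSE]
        Z[rows_out, ] <- Z[rows_out, , drop = FALSE] +
          X[rows_out + o * n, , drop = FALSE] %*% Wj
      }
      A <- Z * (Z > 0)
      if (cache) layers[[l]] <- list(X = X, mask = Z > 0, cin = cin)
      X <- A
    }
    pw <- p[[sprintf("b%d_proj_W", b)]]
    res <- if (is.null(pw)) inp else
      inp %*% pw + rep(p[[sprintf("b%d_proj_b", b)]], each = nrow(inp))
    X <- X + res
    if (cache) caches[[b]] <- list(inp = inp, layers = layers, offs = offs)
  }
  cl <- ncol(X)
  # flatten to n x (W*cl), channel fastest within each window position,
  # matching the compiled kernels' cube memory order
  Xh <- matrix(aperm(array(X, c(n, W, cl)), c(1, 3, 2)), nrow = n)
  logits <- Xh %*% p$head_W + rep(p$head_b, each = n)
  ex <- exp(logits - apply(logits, 1, max))
  probs <- ex / rowSums(ex)
  out <- list(probs = probs)
  if (cache) {
    out$Xh <- Xh
    out$caches <- caches
    out$cl <- cl
  }
  out
}

# backprop of mean cross-entropy; y are 1-based class indices
tcn_backward <- function(model, fwd, y, n) {
  cfg <- model$config
  p <- model$params
  k <- cfg$kernel_size
  W <- cfg$window_size
  grads <- list()
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits / n
  grads$head_W <- crossprod(fwd$Xh, dlogits)
  grads$head_b <- colSums(dlogits)
  dXh <- dlogits %*% t(p$head_W)
  dX <- matrix(aperm(array(dXh, c(n, fwd$cl, W)), c(1, 3, 2)),
               nrow = n * W, ncol = fwd$cl)
  for (b in rev(seq_len(cfg$n_blocks))) {
    cc <- fwd$caches[[b]]
    dRes <- dX
    pw <- p[[sprintf("b%d_proj_W", b)]]
    if (is.null(pw)) {
      dInp <- dRes
    } else {
      grads[[sprintf("b%d_proj_W", b)]] <- crossprod(cc$inp, dRes)
      grads[[sprintf("b%d_proj_b", b)]] <- colSums(dRes)
      dInp <- dRes %*% t(pw)
    }
    dA <- dX
    for (l in rev(seq_len(cfg$layers_per_block))) {
      lc <- cc$layers[[l]]
      dZ <- dA * lc$mask
      Wl <- p[[sprintf("b%d_l%d_W", b, l)]]
      grads[[sprintf("b%d_l%d_b", b, l)]] <- colSums(dZ)
      dW <- matrix(0, nrow(Wl), ncol(Wl))
      dprev <- matrix(0, nrow(dZ), lc$cin)
      for (j in seq_len(k)) {
        o <- cc$offs[j]
        t0 <- max(1, 1 - o); t1 <- min(W, W - o)
        if (t0 > t1) next
        rows_out <- ((t0 - 1) * n + 1):(t1 * n)
        rows_in <- rows_out + o * n
        cols <- ((j - 1) * lc$cin + 1):(j * lc$cin)
        dZj <- dZ[rows_out, , drop = FALSE]
        dW[cols, ] <- crossprod(lc$X[rows_in, , drop = FALSE], dZj)
        dprev[rows_in, ] <- dprev[rows_in, , drop = FALSE] +
          tcrossprod(dZj, Wl[cols, , drop = FALSE])
      }
      grads[[sprintf("b%d_l%d_W", b, l)]] <- dW
      dA <- dprev
    }
    dX <- dA + dInp
  }
  grads
}

# one optimizer step in place; state holds first/second moments
optim_step <- function(params, grads, state, cfg, t) {
  lr <- cfg$learning_rate
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (cfg$optimizer == "adam") {
      state$m[[nm]] <- 0.9 * state$m[[nm]] + 0.1 * g
      state$v[[nm]] <- 0.999 * state$v[[nm]] + 0.001 * g^2
      mhat <- state$m[[nm]] / (1 - 0.9^t)
      vhat <- state$v[[nm]] / (1 - 0.999^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
    } else {
      state$v[[nm]] <- 0.9 * state$v[[nm]] + 0.1 * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(state$v[[nm]]) + 1e-8)
    }
  }
  list(params = params, state = state)
}

# stack per-trial feature matrices into one position-major window matrix +
# label vector; global window i, position t lives at row (t-1)*N + i
stack_windows <- function(features, labels, window) {
  ws <- window_spec(window)
  per <- lapply(features, function(f) make_windows(f, ws))
  ns <- vapply(per, function(w) w$n, integer(1))
  N <- sum(ns)
  xs <- matrix(0, N * window, per[[1]]$d)
  off <- c(0L, cumsum(ns))
  for (k in seq_along(per)) {
    for (t in seq_len(window)) {
      xs[(t - 1) * N + off[k] + seq_len(ns[k]), ] <-
        per[[k]]$x[(t - 1) * ns[k] + seq_len(ns[k]), , drop = FALSE]
    }
  }
  y <- match(unlist(labels, use.names = FALSE), tug_classes())
  if (anyNA(y) || length(y) != N) {
    abort("labels do not match the windowed frames", class = "tug_data_error")
  }
  list(xs = xs, y = y, n = N)
}

# rows of windows s:e (all positions, position-major) in a stacked matrix
window_rows <- function(s, e, n, W) {
  as.vector(outer(s:e, (0:(W - 1)) * n, "+"))
}

# mean cross-entropy loss and frame accuracy over a (possibly large) set,
# evaluated in bounded-memory chunks
tcn_evaluate_loss <- function(model, xs, y, n, chunk = 8192) {
  W <- model$config$window_size
  d <- ncol(xs)
  cfg <- cfg_ints(model$config)
  tot_loss <- 0; tot_correct <- 0
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    nb <- e - s + 1
    xb <- xs[window_rows(s, e, n, W), , drop = FALSE]
    probs <- .tcn_probs_cpp(xb, nb, model$params, cfg)
    pr <- probs[cbind(seq_len(nb), y[s:e])]
    tot_loss <- tot_loss + sum(-log(pmax(pr, 1e-12)))
    tot_correct <- tot_correct + sum(max.col(probs) == y[s:e])
  }
  list(loss = tot_loss / n, acc = tot_correct / n)
}

#' Train the dilated TCN frame classifier
#'
#' Splits the dataset subject-wise into train/validation/test sets, minimizes
#' categorical cross-entropy with the configured optimizer, stops early when
#' the validation loss has not improved for `patience` epochs, and restores
#' the best-epoch weights. All randomness (split, initialization, shuffling)
#' is governed by `train$seed`.
#'
#' @param data A tibble with columns `subject`, `features` (list of T x d
#'   matrices) and `labels` (list of length-T class-name vectors), e.g. from
#'   [prepare_dataset()].
#' @param config A [tcn_config()]; its `input_dim` must match the features.
#' @param train A [train_config()].
#' @param verbose Print one line per epoch.
#' @return A `tug_tcn_fit`: the trained model, an epoch-by-epoch `history`
#'   tibble, `best_epoch`, `stop_reason`, and the subject `split`.
#' @export
tcn_train <- function(data, config = tcn_config(), train = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(config, "tug_tcn_config"), inherits(train, "tug_train_config"))
  if (nrow(data) == 0) abort("empty dataset", class = "tug_data_error")
  d <- ncol(data$features[[1]])
  if (d != config$input_dim) {
    abort(sprintf("feature dimension %d does not match config input_dim %d",
                  d, config$input_dim), class = "tug_shape_error")
  }
  split <- holdout_split(unique(data$subject), fractions = train$split,
                         seed = train$seed)
  sets <- lapply(split, function(subj) {
    rows <- data$subject %in% subj
    if (!any(rows)) abort("empty split", class = "tug_data_error")
    stack_windows(data$features[rows], data$labels[rows], config$window_size)
  })
  tr <- sets$train; va <- sets$val
  model <- build_tcn(config, seed = train$seed)
  state <- list(
    m = lapply(model$params, function(p) p * 0),
    v = lapply(model$params, function(p) p * 0)
  )
  W <- config$window_size
  d <- config$input_dim
  cfg <- cfg_ints(config)
  best_loss <- Inf; best_params <- model$params; best_epoch <- 0L
  history <- list(); step <- 0L; stop_reason <- "max_epochs"
  for (epoch in seq_len(train$max_epochs)) {
    ord <- sample.int(tr$n)
    ep_loss <- 0; ep_correct <- 0
    for (s in seq(1, tr$n, by = train$batch_size)) {
      bi <- ord[s:min(s + train$batch_size - 1, tr$n)]
      nb <- length(bi)
      idx <- as.vector(outer(bi, (0:(W - 1)) * tr$n, "+"))
      xb <- tr$xs[idx, , drop = FALSE]
      yb <- tr$y[bi]
      st <- .tcn_step_cpp(xb, nb, yb, model$params, cfg)
      ep_loss <- ep_loss + st$loss_sum
      ep_correct <- ep_correct + st$n_correct
      step <- step + 1L
      up <- optim_step(model$params, st$grads, state, train, step)
      model$params <- up$params
      state <- up$state
    }
    vl <- tcn_evaluate_loss(model, va$xs, va$y, va$n)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss / tr$n, train_acc = ep_correct / tr$n,
      val_loss = vl$loss, val_acc = vl$acc
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f", epoch,
                      ep_loss / tr$n, ep_correct / tr$n, vl$loss, vl$acc))
    }
    if (vl$loss < best_loss) {
      best_loss <- vl$loss
      best_params <- model$params
      best_epoch <- epoch
    } else if (epoch - best_epoch >= train$patience) {
      stop_reason <- "early_stopping"
      break
    }
  }
  model$params <- best_params
  structure(
    list(model = model, config = config, train_config = train,
         history = dplyr::bind_rows(history), best_epoch = best_epoch,
         stop_reason = stop_reason, split = split, classes = tug_classes()),
    class = "tug_tcn_fit"
  )
}

#' @export
print.tug_tcn_fit <- function(x, ...) {
  h <- x$history[x$best_epoch, ]
  cat(sprintf(
    "<tug_tcn_fit> %d params | best epoch %d/%d (%s) | val loss %.4f acc %.3f\n",
    count_parameters(x), x$best_epoch, nrow(x$history), x$stop_reason,
    h$val_loss, h$val_acc
  ))
  invisible(x)
}

#' Per-frame class probabilities for a recording
#'
#' Builds one window per frame (stride 1, edge replication) and runs the
#' model; each frame's prediction depends only on the frames inside its
#' window.
#'
#' @param object A `tug_tcn_fit` or `tug_tcn`.
#' @param features Preprocessed T x d feature matrix.
#' @return A T x n_classes probability matrix (rows sum to 1) with class
#'   column names.
#' @export
predict_frames <- function(object, features) {
  model <- if (inherits(object, "tug_tcn_fit")) object$model else object
  stopifnot(inherits(model, "tug_tcn"))
  if (!is.matrix(features)) features <- matrix(features, ncol = 1)
  if (ncol(features) != model$config$input_dim) {
    abort("feature dimension does not match the model input",
          class = "tug_shape_error")
  }
  W <- model$config$window_size
  wn <- make_windows(features, window_spec(W))
  n <- wn$n
  probs <- matrix(NA_real_, n, model$config$n_classes,
                  dimnames = list(NULL, tug_classes()[seq_len(model$config$n_classes)]))
  chunk <- 8192
  cfg <- cfg_ints(model$config)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    nb <- e - s + 1
    xb <- wn$x[window_rows(s, e, n, W), , drop = FALSE]
    probs[s:e, ] <- .tcn_probs_cpp(xb, nb, model$params, cfg)
  }
  probs
}

#' Subject-wise data splits
#'
#' `holdout_split()` partitions subjects into train/validation/test sets with
#' the given fractions (sizes as balanced as integer division allows, largest
#' remainders first); `kfold_split()` partitions subjects into `k` folds of
#' near-equal size. No subject ever appears in two sets.
#'
#' @param subject_ids Character or integer vector of subject identifiers
#'   (duplicates collapsed).
#' @param fractions Length-3 positive fractions summing to 1.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return `holdout_split()`: a named list `train`/`val`/`test`;
#'   `kfold_split()`: a list of `k` subject vectors.
#' @export
#' @examples
#' lengths(holdout_split(sprintf("S%02d", 1:50)))
holdout_split <- function(subject_ids, fractions = c(0.6, 0.2, 0.2), seed = 1) {
  subjects <- unique(subject_ids)
  n <- length(subjects)
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("fractions must be 3 positive values summing to 1",
          class = "tug_parameter_error")
  }
  if (n < 3) abort("need at least 3 subjects", class = "tug_data_error")
  set.seed(seed)
  shuffled <- sample(subjects)
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(n * fractions - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  ends <- cumsum(sizes)
  list(train = shuffled[seq_len(ends[1])],
       val = shuffled[(ends[1] + 1):ends[2]],
       test = shuffled[(ends[2] + 1):ends[3]])
}

#' @rdname holdout_split
#' @export
kfold_split <- function(subject_ids, k = 5, seed = 1) {
  subjects <- unique(subject_ids)
  if (k > length(subjects)) {
    abort("more folds than subjects", class = "tug_parameter_error")
  }
  set.seed(seed)
  shuffled <- sample(subjects)
  unname(split(shuffled, sort(rep_len(seq_len(k), length(subjects)))))
}
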