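# Preprocessing: Butterworth low-pass filtering (zero-phase by default),
# per-trial min-max normalization, axis matching to the walking direction,
# and per-frame model-input windows. The filter design (bilinear transform of
# the analog prototype) and forward-backward filtering with odd-extension
# padding and steady-state initial conditions are written out here because no
# signal-processing package ships with the target environment.

#' Low-pass filter specification
#'
#' Defaults follow the pipeline's tuned values: 4th-order Butterworth at
#' 0.3 Hz cutoff for 30 Hz skeleton data. `zero_phase` applies the filter
#' forward and backward (squared magnitude response, no group delay);
#' `causal` is a single forward pass, retained for ablation.
#'
#' @param order Filter order (>= 1).
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist.
#' @param fs_hz Sampling rate in Hz.
#' @param mode `"zero_phase"` or `"causal"`.
#' @return A `tug_filter_spec` list.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 0.3, fs_hz = 30,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (order < 1) abort("order must be >= 1", class = "tug_parameter_error")
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    abort("cutoff must lie in (0, fs/2)", class = "tug_parameter_error")
  }
  structure(list(order = order, cutoff_hz = cutoff_hz, fs_hz = fs_hz,
                 mode = mode), class = "tug_filter_spec")
}

# real polynomial coefficients from complex roots (descending powers)
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  Re(p)
}

#' Digital Butterworth low-pass coefficients
#'
#' Designs the discrete filter by bilinear transform of the analog Butterworth
#' prototype with frequency prewarping, the standard digital design.
#'
#' @param order Filter order.
#' @param cutoff_hz,fs_hz Cutoff and sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` (both length
#'   `order + 1`, `a[1] = 1`, unit DC gain).
#' @export
butter_coefficients <- function(order, cutoff_hz, fs_hz) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2) {
    abort("cutoff must lie in (0, fs/2)", class = "tug_parameter_error")
  }
  warped <- 2 * fs_hz * tan(pi * cutoff_hz / fs_hz)
  k <- seq_len(order)
  p <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * fs_hz
  pd <- (fs2 + p) / (fs2 - p)
  a <- poly_from_roots(pd)
  b <- poly_from_roots(rep(-1 + 0i, order))
  b <- b * Re(warped^order / prod(fs2 - p))
  b <- b * (sum(a) / sum(b))   # pin DC gain to exactly 1
  list(b = b, a = a / a[1])
}

#' Filter magnitude response
#'
#' Single-pass gain of the designed filter at the given frequencies; the
#' zero-phase (forward-backward) gain is this magnitude squared.
#'
#' @param spec A [filter_spec()].
#' @param f_hz Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of single-pass magnitude gains.
#' @export
butter_gain <- function(spec, f_hz) {
  co <- butter_coefficients(spec$order, spec$cutoff_hz, spec$fs_hz)
  w <- 2 * pi * f_hz / spec$fs_hz
  ez <- exp(-1i * w)
  pv <- function(coef) {
    acc <- rep(0 + 0i, length(ez))
    for (c0 in coef) acc <- acc * ez + c0
    acc
  }
  Mod(pv(co$b) / pv(co$a))
}

# steady-state initial filter state (direct form II transposed), so a constant
# input yields a constant output from the first sample
lfilter_zi <- function(b, a) {
  n <- length(a)
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[-1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(A), b[-1] - a[-1] * b[1])
}

# direct form II transposed IIR filter with initial state zi
lfilter <- function(b, a, x, zi) {
  n <- length(b)
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) for (j in 1:(n - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

#' Butterworth low-pass filter a signal
#'
#' Zero-phase mode filters forward and backward with odd-extension edge
#' padding and steady-state initial conditions (so a constant signal passes
#' through unchanged and there is no phase lag); causal mode is one forward
#' pass.
#'
#' @param signal Numeric vector (one channel) or a T x d matrix filtered
#'   column-wise.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same shape.
#' @export
#' @examples
#' butterworth_lowpass(rep(2, 50), filter_spec())[1:3]
butterworth_lowpass <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(spec, "tug_filter_spec"))
  if (is.matrix(signal)) {
    return(apply(signal, 2, butterworth_lowpass, spec = spec))
  }
  x <- as.numeric(signal)
  if (length(x) <= 3 * spec$order) {
    abort("signal too short for the filter order", class = "tug_parameter_error")
  }
  co <- butter_coefficients(spec$order, spec$cutoff_hz, spec$fs_hz)
  b <- co$b; a <- co$a
  zi <- lfilter_zi(b, a)
  if (spec$mode == "causal") {
    return(lfilter(b, a, x, zi * x[1]))
  }
  T0 <- length(x)
  padlen <- min(3 * length(a), T0 - 1)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[T0] - x[(T0 - 1):(T0 - padlen)])
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + T0)]
}

#' Min-max normalize a feature matrix
#'
#' Per-column linear map to `[0, 1]`. Constant columns cannot be scaled and
#' are mapped to all zeros with a warning.
#'
#' @param series Numeric vector or T x d matrix.
#' @return Same shape, each non-constant column spanning exactly `[0, 1]`.
#' @export
minmax_normalize <- function(series) {
  vec <- !is.matrix(series)
  m <- if (vec) matrix(series, ncol = 1) else series
  if (!all(is.finite(m))) abort("non-finite values", class = "tug_validation_error")
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warn(paste0(sum(flat), " constant column(s) mapped to zeros"),
         class = "tug_degenerate_warning")
    rng[flat] <- 1
  }
  out <- sweep(sweep(m, 2, lo), 2, rng, "/")
  out[, flat] <- 0
  if (vec) drop(out) else out
}

#' Align a recording to the subject's walking direction
#'
#' Rotates the recording about the vertical (y) axis so that the dominant
#' horizontal direction of pelvis displacement (first principal direction of
#' the centered horizontal pelvis track) becomes +x, with the outbound walk
#' positive. Vertical coordinates are untouched; the transform is rigid.
#'
#' @param recording A [tug_trial()] containing the PELVIS joint.
#' @return The rotated `tug_trial`.
#' @export
align_axes <- function(recording) {
  if (!"PELVIS" %in% trial_joints(recording)) {
    abort("PELVIS joint required for axis alignment", class = "tug_lookup_error")
  }
  h <- cbind(recording$PELVIS_x, recording$PELVIS_z)
  hc <- sweep(h, 2, colMeans(h))
  ev <- eigen(crossprod(hc) / nrow(hc), symmetric = TRUE)
  e <- ev$vectors[, 1]
  proj <- hc %*% e
  if (diff(range(proj)) < 0.5) {
    abort("horizontal pelvis displacement too small to define a walking axis",
          class = "tug_alignment_error")
  }
  q <- proj - proj[1]
  if (q[which.max(abs(q))] < 0) e <- -e
  out <- recording
  for (j in trial_joints(recording)) {
    cx <- paste0(j, "_x"); cz <- paste0(j, "_z")
    x <- out[[cx]]; z <- out[[cz]]
    out[[cx]] <- e[1] * x + e[2] * z
    out[[cz]] <- -e[2] * x + e[1] * z
  }
  out
}

#' Window specification for the frame classifier
#'
#' @param window_size Frames per model input window (default 8).
#' @param stride Window stride in frames; the classifier uses stride 1 (one
#'   window centered on every frame).
#' @return A `tug_window_spec` list.
#' @export
window_spec <- function(window_size = 8, stride = 1) {
  if (window_size < 1 || stride < 1) {
    abort("window_size and stride must be >= 1", class = "tug_parameter_error")
  }
  structure(list(window_size = window_size, stride = stride),
            class = "tug_window_spec")
}

#' Build per-frame input windows
#'
#' One window per frame (stride 1), centered with offsets
#' `-floor(W/2) ... ceiling(W/2) - 1`, edges replicated. Windows are stacked
#' position-major into a `(N * W) x d` matrix: rows `(t-1)*N + (1:N)` hold
#' window position `t` of every window, so each dilated kernel tap in the
#' classifier is a single contiguous-block matrix product. Use
#' [window_at()] to view one window in frame order.
#'
#' @param features T x d feature matrix.
#' @param spec A [window_spec()].
#' @return A `tug_windows` list: `x` the stacked matrix, `n` windows, `window`
#'   frames each, `d` channels, and `centers` the 0-based frame each window
#'   predicts.
#' @export
make_windows <- function(features, spec = window_spec()) {
  stopifnot(inherits(spec, "tug_window_spec"))
  if (!is.matrix(features)) features <- matrix(features, ncol = 1)
  T0 <- nrow(features)
  W <- spec$window_size
  off <- -floor(W / 2) + 0:(W - 1)
  centers <- seq(1, T0, by = spec$stride)
  idx <- pmin(pmax(rep(off, each = length(centers)) + centers, 1), T0)
  structure(
    list(x = features[idx, , drop = FALSE], n = length(centers), window = W,
         d = ncol(features), centers = centers - 1L),
    class = "tug_windows"
  )
}

#' @rdname make_windows
#' @param windows A `tug_windows` object.
#' @param i Window number (1-based).
#' @return `window_at()`: the `window_size` x d matrix of window `i` in frame
#'   order.
#' @export
window_at <- function(windows, i) {
  stopifnot(inherits(windows, "tug_windows"), i >= 1, i <= windows$n)
  windows$x[(0:(windows$window - 1)) * windows$n + i, , drop = FALSE]
}

#' Preprocess a trial into classifier features
#'
#' The full preprocessing chain: axis alignment (optional), joint selection,
#' low-pass filtering, then min-max normalization, in that order.
#'
#' @param trial A [tug_trial()].
#' @param joints Joint selection (see [select_features()]).
#' @param filter A [filter_spec()], or `NULL` to skip filtering.
#' @param align Whether to run [align_axes()] first.
#' @return A T x 3k feature matrix in `[0, 1]`.
#' @export
preprocess_trial <- function(trial, joints = "PELVIS", filter = filter_spec(),
                             align = TRUE) {
  if (align) trial <- align_axes(trial)
  f <- select_features(trial, joints)
  if (!is.null(filter)) f <- butterworth_lowpass(f, filter)
  minmax_normalize(f)
}
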