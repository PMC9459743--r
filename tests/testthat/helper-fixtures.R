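# Shared fixtures and independent oracles, all built in code.

# tiny hand-built recording: `joints` positions as T x 3 matrices
toy_trial <- function(positions, fps = 30, ...) {
  T0 <- nrow(positions[[1]])
  cols <- list(frame = 0:(T0 - 1), timestamp = (0:(T0 - 1)) / fps)
  for (j in names(positions)) {
    p <- positions[[j]]
    cols[[paste0(j, "_x")]] <- p[, 1]
    cols[[paste0(j, "_y")]] <- p[, 2]
    cols[[paste0(j, "_z")]] <- p[, 3]
  }
  tug_trial(tibble::as_tibble(cols), ...)
}

# one noiseless synthetic trial of a given group, fixed walking azimuth
noiseless_trial <- function(group = "older_adult", seed = 3, azimuth = 0,
                            total_sd = 0) {
  preset <- group_preset(group, noise_sd = 0, total_sd = total_sd)
  plan <- sample_phase_plan(preset, seed = seed)
  synthesize_trial(plan, preset, seed = seed + 1, azimuth = azimuth,
                   origin = c(0, 0))
}

# brute-force oracle for the order-constrained alignment: enumerates every
# placement of the six boundaries (leading/trailing sit may be empty, active
# segments may not) and returns the minimal total 1-p cost with the
# lexicographically earliest optimal boundaries
bf_align <- local({
  comb_cache <- new.env(parent = emptyenv())
  function(p) {
    T0 <- nrow(p)
    key <- as.character(T0)
    if (is.null(comb_cache[[key]])) {
      comb_cache[[key]] <- utils::combn(T0 + 1, 6)
    }
    combs <- comb_cache[[key]]
    C <- 1 - p[, match(tug_template(), tug_classes()), drop = FALSE]
    CC <- rbind(0, apply(C, 2, cumsum))
    dimnames(CC) <- NULL
    S <- rbind(1, combs, T0 + 1)
    cost <- numeric(ncol(combs))
    for (j in 1:7) cost <- cost + CC[S[j + 1, ], j] - CC[S[j, ], j]
    best <- which.min(cost)   # combn enumerates lexicographically
    list(cost = cost[best], boundaries = combs[, best] - 1L)
  }
})

# independent ICC(2,1) oracle: mean squares from an explicit two-way ANOVA fit
icc_oracle <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   target = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# random hard-label probability input for fuzzing
random_labels <- function(T0) sample(tug_classes(), T0, replace = TRUE)
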