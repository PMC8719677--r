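# Shared fixtures built in code. All fixtures are deterministic given the
# seeds fixed here.

# Small ground truth whose events fit comfortably in memory.
tiny_truth <- function(P = 60L, R = 6L, C = 4L, n_events = 300L,
                       seed = 7L, ...) {
  simulate_noise_study(P = P, R = R, C = C, n_condition_specific = 2L,
                       n_global = 2L, n_events = n_events, seed = seed, ...)
}

# Noise matrix built directly from ground truth plus Gaussian measurement
# jitter, bypassing event generation and EM; for propagation tests where
# the cytometry stage is not under test.
direct_noise <- function(truth, meas_sd = 6e-4, seed = 1L) {
  N <- true_noise(truth)
  set.seed(seed)
  N + matrix(rnorm(length(N), 0, meas_sd), nrow = nrow(N))
}

# Brute-force minimizer of the penalized least-squares objective
# ||y - X a||^2 + lambda ||a||^2, independent of the closed-form ridge
# path: cyclic coordinate descent iterated to stationarity.
brute_force_ridge <- function(X, y, lambda) {
  a <- rep(0, ncol(X))
  for (it in 1:100000) {
    delta <- 0
    for (j in seq_along(a)) {
      r_j <- y - X[, -j, drop = FALSE] %*% a[-j]
      new_j <- sum(X[, j] * r_j) / (sum(X[, j]^2) + lambda)
      delta <- max(delta, abs(new_j - a[j]))
      a[j] <- new_j
    }
    if (delta < 1e-13) break
  }
  a
}

# Textbook Welch statistic for cross-checking.
welch_oracle <- function(x, y) {
  sx <- var(x) / length(x)
  sy <- var(y) / length(y)
  (mean(x) - mean(y)) / sqrt(sx + sy)
}
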