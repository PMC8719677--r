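# Minimal-variance envelope, noise levels, growth-rate regression, and
# distribution comparisons.

test_that("minimal variance has the stated form, monotonicity and asymptote", {
  fit <- list(a = 0.01, b = 1)
  expect_equal(minimal_variance(0, fit), 1.01)
  expect_lt(abs(minimal_variance(20, fit) - 0.01), 1e-6)
  m <- seq(0, 10, by = 0.1)
  expect_true(all(diff(minimal_variance(m, fit)) < 0))
  flat <- list(a = 0.03, b = 0)
  expect_true(all(minimal_variance(m, flat) == 0.03))
})

test_that("noiseless summaries on the curve are recovered exactly", {
  m <- seq(2, 9, length.out = 200)
  s <- data.frame(condition_id = "c1", mean = m,
                  variance = 0.02 + 0.8 * exp(-m))
  fit <- fit_noise_floor(s, q = 0.05, n_bins = 20)
  expect_equal(fit$a, 0.02, tolerance = 1e-6)
  expect_equal(fit$b, 0.8, tolerance = 1e-5)
  expect_equal(noise_level(s, fit), rep(0, 200), tolerance = 1e-8)
})

test_that("floor is recovered from generator events within tolerance", {
  meta <- generate_condition_metadata(C = 2, rate_range = c(0.5, 1.5))
  truth <- simulate_noise_study(P = 600L, R = 8L, C = 2L,
                                n_condition_specific = 1L, n_global = 1L,
                                n_events = 2000L, metadata = meta,
                                seed = 21L)
  s <- summarize_replicates(summarize_study(truth))
  nl <- noise_level_matrix(s)
  for (k in 1:2) {
    expect_lt(abs(nl$fits[[k]]$a - meta$a[k]) / meta$a[k], 0.10)
    expect_lt(abs(nl$fits[[k]]$b - meta$b[k]) / meta$b[k], 0.20)
  }
})

test_that("higher envelope quantiles give higher floors on symmetric scatter", {
  set.seed(22)
  m <- runif(1000, 3, 8)
  s <- data.frame(condition_id = "c1", mean = m,
                  variance = 0.05 + rnorm(1000, 0, 0.01))
  a_low <- fit_noise_floor(s, q = 0.05)$a
  a_med <- fit_noise_floor(s, q = 0.5)$a
  expect_gt(a_med, a_low)
  expect_equal(a_med, 0.05, tolerance = 0.05)
})

test_that("about a fraction q of promoters fall below the fitted envelope", {
  set.seed(23)
  n <- 2000
  m <- runif(n, 3, 8)
  v <- 0.03 + 0.8 * exp(-m) + abs(rnorm(n, 0, 0.02)) + rnorm(n, 0, 0.004)
  s <- data.frame(condition_id = "c1", mean = m, variance = v)
  q <- 0.05
  fit <- fit_noise_floor(s, q = q)
  below <- mean(v < minimal_variance(m, fit))
  expect_lt(abs(below - q), 2 * sqrt(q * (1 - q) / n) + 0.02)
})

test_that("noise level is the variance above the floor", {
  fit <- list(a = 0.05, b = 0)
  s <- data.frame(mean = c(5, 6), variance = c(0.3, 0.05))
  expect_equal(noise_level(s, fit), c(0.25, 0))
})

test_that("floor-vs-growth regression recovers an exact linear law", {
  meta <- generate_condition_metadata(C = 8)
  fits <- lapply(seq_len(8), function(k) list(a = meta$a[k]))
  res <- floor_vs_growth_rate(fits, meta$growth_rate)
  expect_equal(res$slope, -0.02, tolerance = 1e-6)
  expect_equal(res$intercept, 0.055, tolerance = 1e-6)
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
})

test_that("floor-vs-growth regression flags degenerate designs", {
  expect_error(floor_vs_growth_rate(list(list(a = 1), list(a = 2)),
                                    c(1, 1)), "constant")
  expect_warning(res <- floor_vs_growth_rate(list(list(a = 0.05),
                                                  list(a = 0.03)),
                                             c(0.5, 1.5)), "R\\^2 = 1")
  expect_equal(res$r_squared, 1)
})

test_that("jittered floor slopes fall within 2 analytic SEs at the nominal rate", {
  hits <- 0L
  n_seeds <- 100L
  for (sd_i in seq_len(n_seeds)) {
    meta <- generate_condition_metadata(C = 8, jitter_sd = 0.002,
                                        seed = sd_i)
    fits <- lapply(seq_len(8), function(k) list(a = meta$a[k]))
    res <- floor_vs_growth_rate(fits, meta$growth_rate)
    if (abs(res$slope - (-0.02)) <= 2 * res$se_slope) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.88)  # nominal 95.4% coverage
})

test_that("rank-sum comparison of noise distributions behaves as expected", {
  set.seed(24)
  a <- rexp(1500, 1 / 0.005)
  same <- noise_distribution_tests(a, a)
  expect_gt(same$p_value, 0.9)
  shifted <- noise_distribution_tests(a, a + 0.05)
  expect_lt(shifted$p_value, 1e-10)
  expect_equal(shifted$median_b - shifted$median_a, 0.05)
  sym <- rnorm(2001, 0.1, 0.02)
  expect_equal(noise_distribution_tests(sym, sym)$median_a, 0.1,
               tolerance = 0.02)
  expect_error(noise_distribution_tests(a[1:5], a), ">= 10")
})

test_that("noise levels of constitutive promoters are mean-independent", {
  truth <- simulate_noise_study(P = 500L, R = 8L, C = 2L,
                                mean_in_degree = 0,
                                n_condition_specific = 0L, n_global = 0L,
                                n_events = 2000L, seed = 25L)
  s <- summarize_replicates(summarize_study(truth))
  nl <- noise_level_matrix(s)
  r <- cor(as.vector(nl$noise), as.vector(nl$mean))
  expect_lt(abs(r), 0.05)
})
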