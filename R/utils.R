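# Internal helpers shared across modules.

# Deterministic child seed derived from a master seed and one or two integer
# offsets. Keeps every derived seed in [1, 2^31 - 2] so it is a valid R seed.
# Stage-level fan-out means a stage can be rerun in isolation and still see
# the same random stream as inside the full pipeline.
child_seed <- function(seed, i, j = 0L) {
  s <- (as.double(seed) %% 2147483647) * 69069 + as.double(i) * 1000003 +
    as.double(j) * 7919 + 12345
  as.integer(s %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Ordinary least squares of y on x with slope/intercept standard errors and
# R^2; used for the floor-vs-growth-rate regression.
ols_line <- function(x, y) {
  fit <- lm(y ~ x)
  # summary.lm warns on numerically perfect fits; exact linearity is a
  # legitimate input here (e.g. jitter-free synthetic metadata)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  r2 <- if (length(x) == 2L) 1 else sm$r.squared
  list(
    intercept = unname(cf[1L, 1L]), slope = unname(cf[2L, 1L]),
    se_intercept = unname(cf[1L, 2L]), se_slope = unname(cf[2L, 2L]),
    r_squared = r2
  )
}
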