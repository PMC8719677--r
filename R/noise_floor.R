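#' Minimal variance of log-fluorescence at a given mean
#'
#' The minimal-variance envelope combines a multiplicative (extrinsic)
#' floor `a_c`, independent of expression level, with a Poissonian term
#' `b_c exp(-m)` whose contribution decays with mean log-expression `m`
#' (dominated by measurement shot noise at these expression levels):
#' `v_min(m) = a_c + b_c exp(-m)`. It is strictly decreasing in `m` when
#' `b_c > 0` and asymptotes to `a_c` at high expression.
#'
#' @param m mean log-fluorescence (vectorized).
#' @param fit a `noise_floor_fit`, or a list with elements `a` and `b`.
#' @return variance of log-fluorescence at each `m`.
#' @export
minimal_variance <- function(m, fit) {
  fit$a + fit$b * exp(-m)
}

#' Fit the per-condition noise floor from expression summaries
#'
#' Estimates the minimal-variance envelope for one condition by binning
#' promoters into `n_bins` equal-count bins of mean expression, selecting
#' in each bin the promoter at the `q`-th quantile of variance (its
#' observed mean/variance pair becomes an envelope point), and fitting
#' `v_min(m) = a + b exp(-m)` to the envelope points by least squares under
#' positivity constraints (`a > 0`, `b >= 0`).
#'
#' Bins with fewer than 5 promoters trigger a warning and a coarser
#' binning. The model is linear in `(a, b)` given `exp(-m)`, so the
#' unconstrained solution is exact; the constrained fall-back uses
#' box-constrained quasi-Newton minimization of the same sum of squares.
#'
#' @param summaries data.frame for one condition with columns `mean` and
#'   `variance` (one row per promoter, above background).
#' @param q lower quantile defining the envelope (default 0.05).
#' @param n_bins number of equal-count bins of mean expression.
#' @param condition_id optional label stored in the fit.
#' @return object of class `noise_floor_fit` with elements `a`, `b`,
#'   `condition_id`, `q`, `n_bins`, `n_points`, `envelope`.
#' @export
fit_noise_floor <- function(summaries, q = 0.05, n_bins = 20L,
                            condition_id = NULL) {
  m <- summaries$mean
  v <- summaries$variance
  n <- length(m)
  if (n < 50L) stopf("need >= 50 promoters to fit a noise floor (got %d)", n)
  n_bins <- as.integer(n_bins)
  if (n %/% n_bins < 5L) {
    n_bins <- max(1L, n %/% 5L)
    warnf("bins with < 5 points; merged to %d bins", n_bins)
  }
  bin <- rep(seq_len(n_bins), each = ceiling(n / n_bins))[rank(m, ties.method = "first")]
  env <- t(vapply(split(seq_len(n), bin), function(idx) {
    k <- max(1L, ceiling(q * length(idx)))
    pick <- idx[order(v[idx])[k]]
    c(m[pick], v[pick])
  }, numeric(2L)))
  em <- exp(-env[, 1L])
  fit0 <- lm(env[, 2L] ~ em)
  a0 <- unname(coef(fit0)[1L])
  b0 <- unname(coef(fit0)[2L])
  if (is.na(b0)) b0 <- 0
  if (a0 > 0 && b0 >= 0) {
    a <- a0
    b <- b0
  } else {
    sse <- function(p) sum((env[, 2L] - p[1L] - p[2L] * em)^2)
    opt <- optim(c(max(a0, 1e-4), max(b0, 0)), sse, method = "L-BFGS-B",
                 lower = c(1e-10, 0))
    if (opt$convergence != 0) stopf("noise-floor fit did not converge")
    a <- opt$par[1L]
    b <- opt$par[2L]
  }
  structure(
    list(a = a, b = b, condition_id = condition_id %||%
           (summaries$condition_id[1L] %||% NA_character_),
         q = q, n_bins = n_bins, n_points = n,
         envelope = data.frame(mean = env[, 1L], variance = env[, 2L])),
    class = "noise_floor_fit"
  )
}

#' @export
print.noise_floor_fit <- function(x, ...) {
  cat(sprintf("Noise floor [%s]: a = %.4g, b = %.4g (q = %g, %d promoters)\n",
              x$condition_id, x$a, x$b, x$q, x$n_points))
  invisible(x)
}

#' Noise level of each summary relative to a fitted floor
#'
#' `N_pc = v_pc - v_min(m_pc)`: the variance of log-fluorescence above the
#' minimal variance at the promoter's mean expression. Values are *not*
#' clipped at zero — measurement scatter places some promoters slightly
#' below the fitted envelope, and clipping would bias the downstream
#' linear propagation model.
#'
#' @param summaries data.frame with `mean` and `variance` columns.
#' @param fit a `noise_floor_fit` for the matching condition.
#' @return numeric vector of noise levels.
#' @export
noise_level <- function(summaries, fit) {
  summaries$variance - minimal_variance(summaries$mean, fit)
}

#' Fit all per-condition floors and assemble the noise matrix
#'
#' Splits a pooled summary table by condition, fits the noise floor in each
#' condition, and returns the promoters-by-conditions matrices of means and
#' noise levels.
#'
#' @param summaries pooled summary data.frame (`promoter_id`,
#'   `condition_id`, `mean`, `variance`, optionally `se_variance`).
#' @param q,n_bins envelope settings, see [fit_noise_floor()].
#' @return list with `noise` (promoters x conditions matrix of `N_pc`),
#'   `mean` (matrix of `m_pc`), `se` (matrix of `se_variance` or `NA`), and
#'   `fits` (named list of `noise_floor_fit`).
#' @export
noise_level_matrix <- function(summaries, q = 0.05, n_bins = 20L) {
  conds <- unique(summaries$condition_id)
  proms <- unique(summaries$promoter_id)
  N <- M <- SE <- matrix(NA_real_, nrow = length(proms), ncol = length(conds),
                         dimnames = list(proms, conds))
  fits <- list()
  for (cc in conds) {
    g <- summaries[summaries$condition_id == cc, , drop = FALSE]
    fit <- fit_noise_floor(g, q = q, n_bins = n_bins, condition_id = cc)
    fits[[cc]] <- fit
    i <- match(g$promoter_id, proms)
    N[i, cc] <- noise_level(g, fit)
    M[i, cc] <- g$mean
    SE[i, cc] <- g$se_variance %||% rep(NA_real_, nrow(g))
  }
  list(noise = N, mean = M, se = SE, fits = fits)
}

#' Linear regression of the noise floor on growth rate
#'
#' Ordinary least squares of the per-condition floor `a_c` on the
#' condition's growth rate. With only two conditions the fit is exact and
#' `R^2 = 1` by construction (a warning notes this).
#'
#' @param fits list of `noise_floor_fit` (one per condition).
#' @param growth_rates numeric vector of growth rates (1/h), same order.
#' @return list with `slope`, `intercept`, `se_slope`, `se_intercept`,
#'   `r_squared`.
#' @export
floor_vs_growth_rate <- function(fits, growth_rates) {
  a <- vapply(fits, function(f) f$a, numeric(1L))
  if (length(a) < 2L) stopf("need >= 2 conditions")
  if (sd(growth_rates) < 1e-15) stopf("growth rates are constant")
  if (length(a) == 2L) warnf("only 2 conditions: R^2 = 1 by construction")
  ols_line(growth_rates, a)
}

#' Compare noise-level distributions between two conditions
#'
#' Two-sided Wilcoxon rank-sum test on the promoter noise levels of two
#' conditions, plus the medians the comparison is about.
#'
#' @param noise_a,noise_b numeric vectors of noise levels (>= 10 each).
#' @return list with `p_value`, `statistic`, `median_a`, `median_b`.
#' @export
noise_distribution_tests <- function(noise_a, noise_b) {
  noise_a <- noise_a[is.finite(noise_a)]
  noise_b <- noise_b[is.finite(noise_b)]
  if (length(noise_a) < 10L || length(noise_b) < 10L) {
    stopf("need >= 10 promoters per condition")
  }
  wt <- suppressWarnings(wilcox.test(noise_a, noise_b, exact = FALSE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_a = median(noise_a), median_b = median(noise_b))
}
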