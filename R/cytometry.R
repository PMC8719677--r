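#' Robust mean/variance of log-fluorescence via a Gaussian + uniform mixture
#'
#' Fits the distribution of single-cell log-fluorescence values with a
#' two-component mixture of a Gaussian (the cell population) and a uniform
#' density (outliers: contaminants, non-growing cells) by
#' expectation-maximization, and returns the Gaussian component's mean and
#' variance together with the uniform mixing weight. The uniform support is
#' fixed to the observed data range, which keeps the likelihood bounded; it
#' is not re-estimated. The EM starts from robust estimates (median and
#' MAD-based variance) so that outliers are not captured by the Gaussian
#' component at initialization.
#'
#' @param values numeric vector of log-fluorescence values (natural log),
#'   length >= 10.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on successive log-likelihoods.
#' @param outlier_weight_init initial uniform mixing weight.
#' @param trace if `TRUE`, keep the per-iteration log-likelihood trace
#'   (non-decreasing by EM theory).
#' @return list with `mean`, `variance`, `outlier_weight`, `loglik`,
#'   `n_iter`, `converged`, and (if `trace`) `loglik_trace`.
#' @export
fit_gaussian_uniform_mixture <- function(values, max_iter = 500L,
                                         tol = 1e-8,
                                         outlier_weight_init = 0.05,
                                         trace = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 10L) stopf("need at least 10 events")
  if (!all(is.finite(values))) stopf("values must be finite")
  lo <- min(values)
  hi <- max(values)
  if (hi - lo < 1e-12) stopf("all values identical: mixture fit undefined")
  mu0 <- median(values)
  var0 <- mad(values)^2  # mad() includes the 1.4826 normal-consistency factor
  if (var0 < 1e-12) var0 <- var(values)
  fit <- em_gaussian_uniform_cpp(values, lo, hi, mu0, var0,
                                 outlier_weight_init,
                                 as.integer(max_iter), tol, trace)
  if (isTRUE(fit$degenerate) || fit$variance < 1e-12) {
    stop(structure(
      class = c("noisenet_degenerate_fit", "error", "condition"),
      list(message = "mixture fit degenerated: Gaussian variance collapsed",
           call = sys.call())
    ))
  }
  fit[c("mean", "variance", "outlier_weight", "loglik", "n_iter",
        "converged", if (trace) "loglik_trace")]
}

#' Summarize an event table into per-cell expression summaries
#'
#' Applies [fit_gaussian_uniform_mixture()] to every
#' promoter x condition (x replicate) group of a long event table.
#'
#' @param events data.frame with columns `promoter_id`, `condition_id`,
#'   `log_fluorescence`, and optionally `replicate_id`.
#' @param max_iter,tol EM settings, see [fit_gaussian_uniform_mixture()].
#' @return data.frame of expression summaries with columns `promoter_id`,
#'   `condition_id`, `replicate_id`, `mean`, `variance`, `outlier_weight`,
#'   `n_used`, `converged`.
#' @export
summarize_events <- function(events, max_iter = 500L, tol = 1e-8) {
  req <- c("promoter_id", "condition_id", "log_fluorescence")
  if (!all(req %in% names(events))) {
    stopf("events must have columns %s", paste(req, collapse = ", "))
  }
  rep_id <- events$replicate_id %||% rep("r1", nrow(events))
  key <- interaction(events$promoter_id, events$condition_id, rep_id,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(events$log_fluorescence, key)
  info <- do.call(rbind, strsplit(names(groups), ".", fixed = TRUE))
  rows <- lapply(groups, function(x) {
    f <- fit_gaussian_uniform_mixture(x, max_iter = max_iter, tol = tol)
    data.frame(mean = f$mean, variance = f$variance,
               outlier_weight = f$outlier_weight, n_used = length(x),
               converged = f$converged)
  })
  out <- do.call(rbind, rows)
  out <- cbind(
    data.frame(promoter_id = info[, 1L], condition_id = info[, 2L],
               replicate_id = info[, 3L], stringsAsFactors = FALSE),
    out
  )
  rownames(out) <- NULL
  out
}

#' Summarize a synthetic study without materializing all events
#'
#' Streams every promoter x condition cell of a ground truth through event
#' generation and the mixture EM, returning the summary table the real
#' pipeline would produce from cytometry data. Memory use is one cell's
#' events at a time.
#'
#' @param truth a `noise_ground_truth` from [simulate_noise_study()].
#' @param max_iter,tol EM settings.
#' @return summary data.frame as from [summarize_events()].
#' @export
summarize_study <- function(truth, max_iter = 500L, tol = 1e-8) {
  stopifnot(inherits(truth, "noise_ground_truth"))
  pn <- rownames(truth$network)
  cn <- truth$metadata$condition_id
  vtot <- true_variance(truth)
  P <- length(pn)
  C <- length(cn)
  n <- P * C
  mean_v <- variance_v <- weight_v <- numeric(n)
  conv_v <- logical(n)
  k <- 1L
  for (ci in seq_len(C)) {
    for (pi in seq_len(P)) {
      x <- cell_events(truth, pi, ci, vtot)
      f <- fit_gaussian_uniform_mixture(x, max_iter = max_iter, tol = tol)
      mean_v[k] <- f$mean
      variance_v[k] <- f$variance
      weight_v[k] <- f$outlier_weight
      conv_v[k] <- f$converged
      k <- k + 1L
    }
  }
  data.frame(
    promoter_id = rep(pn, C), condition_id = rep(cn, each = P),
    replicate_id = "r1", mean = mean_v, variance = variance_v,
    outlier_weight = weight_v, n_used = truth$n_events, converged = conv_v,
    stringsAsFactors = FALSE
  )
}

#' Pool replicate summaries and attach standard errors
#'
#' Averages per-replicate expression summaries for each
#' promoter x condition and reports the standard error of the mean across
#' replicates (`sd / sqrt(k)`). With a single replicate the values pass
#' through and the standard errors are `NA` (unavailable, not zero).
#'
#' @param summaries data.frame as from [summarize_events()], with
#'   `replicate_id`.
#' @return data.frame with one row per promoter x condition and columns
#'   `mean`, `variance`, `se_mean`, `se_variance`, `n_replicates`,
#'   `outlier_weight` (averaged), `n_used` (summed).
#' @export
summarize_replicates <- function(summaries) {
  key <- interaction(summaries$promoter_id, summaries$condition_id,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(summaries, key), function(g) {
    k <- nrow(g)
    data.frame(
      promoter_id = g$promoter_id[1L], condition_id = g$condition_id[1L],
      mean = mean(g$mean), variance = mean(g$variance),
      se_mean = if (k >= 2L) sd(g$mean) / sqrt(k) else NA_real_,
      se_variance = if (k >= 2L) sd(g$variance) / sqrt(k) else NA_real_,
      n_replicates = k, outlier_weight = mean(g$outlier_weight),
      n_used = sum(g$n_used), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Squared Pearson correlation between replicate summaries
#'
#' Reproducibility of mean (or variance) estimates between two biological
#' replicates, over the promoters shared by both.
#'
#' @param a,b summary data.frames (single condition, single replicate each).
#' @param field `"mean"` or `"variance"`.
#' @return squared Pearson correlation.
#' @export
replicate_r2 <- function(a, b, field = c("mean", "variance")) {
  field <- match.arg(field)
  shared <- intersect(a$promoter_id, b$promoter_id)
  if (length(shared) < 3L) stopf("need >= 3 shared promoters")
  xa <- a[[field]][match(shared, a$promoter_id)]
  xb <- b[[field]][match(shared, b$promoter_id)]
  if (sd(xa) < 1e-15 || sd(xb) < 1e-15) stopf("zero-variance input")
  cor(xa, xb)^2
}

#' Background threshold from a control event set
#'
#' @param control_values log-fluorescence values of a designated
#'   negative-control (promoterless) reporter.
#' @param q quantile used as the background threshold.
#' @return scalar threshold in log-fluorescence units.
#' @export
estimate_background <- function(control_values, q = 0.975) {
  unname(quantile(as.numeric(control_values), q))
}

#' Drop summaries at or below background expression
#'
#' Retains summaries with mean log-fluorescence strictly above
#' `background_mean`; the number removed is reported via `message()`.
#'
#' @param summaries summary data.frame with a `mean` column.
#' @param background_mean scalar threshold (`-Inf` keeps everything).
#' @return filtered data.frame.
#' @export
filter_above_background <- function(summaries, background_mean) {
  keep <- summaries$mean > background_mean
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_above_background: removed %d of %d summaries",
                    n_removed, length(keep)))
  }
  summaries[keep, , drop = FALSE]
}
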