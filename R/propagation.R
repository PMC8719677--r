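#' Center noise matrix and network for the linear propagation model
#'
#' The propagation model relates centered noise levels to centered
#' regulatory inputs: `N_pc - Nbar_c = sum_r (S_pr - Sbar_r) A_rc + eps`,
#' where `Nbar_c` is the average noise level over promoters in condition
#' `c` and `Sbar_r` the average of `S_pr` over promoters. This helper
#' aligns the two matrices on shared promoter ids (inner join; mismatches
#' are reported) and returns the centered response and design.
#'
#' Promoters measured but absent from the network annotation can instead be
#' retained as all-zero network rows (unregulated as far as known) with
#' `unannotated = "zero"`.
#'
#' @param N promoters x conditions noise matrix (rownames = promoter ids).
#' @param S promoters x regulators binary network (rownames = promoter
#'   ids).
#' @param unannotated `"drop"` (inner join, default) or `"zero"` (keep all
#'   promoters of `N`, filling missing network rows with zeros).
#' @return list with `Y` (centered response, promoters x conditions), `X`
#'   (centered design, promoters x regulators), `N_bar` (condition means),
#'   `S_bar` (regulator means), `n_dropped`.
#' @export
center_model_inputs <- function(N, S, unannotated = c("drop", "zero")) {
  unannotated <- match.arg(unannotated)
  if (is.null(rownames(N)) || is.null(rownames(S))) {
    stopf("N and S must have promoter rownames")
  }
  if (unannotated == "zero") {
    missing <- setdiff(rownames(N), rownames(S))
    if (length(missing) > 0) {
      S <- rbind(S, matrix(0, nrow = length(missing), ncol = ncol(S),
                           dimnames = list(missing, colnames(S))))
    }
  }
  shared <- intersect(rownames(N), rownames(S))
  if (length(shared) == 0L) stopf("no shared promoter ids between N and S")
  n_dropped <- nrow(N) - length(shared)
  if (n_dropped > 0) {
    message(sprintf("center_model_inputs: %d of %d promoters dropped (no network row)",
                    n_dropped, nrow(N)))
  }
  N <- N[shared, , drop = FALSE]
  S <- S[shared, , drop = FALSE]
  N_bar <- colMeans(N)
  S_bar <- colMeans(S)
  list(Y = sweep(N, 2L, N_bar), X = sweep(S, 2L, S_bar),
       N_bar = N_bar, S_bar = S_bar, n_dropped = n_dropped)
}

# Ridge solution for one condition: posterior mean and standard deviations
# under a Gaussian prior with precision lambda and plug-in residual
# variance.
ridge_activities <- function(X, y, lambda) {
  if (lambda <= 0) {
    stopf("lambda must be > 0 (the unpenalized system may be singular)")
  }
  R <- ncol(X)
  G <- crossprod(X) + diag(lambda, R)
  Ginv <- chol2inv(chol(G))
  A <- drop(Ginv %*% crossprod(X, y))
  resid <- y - drop(X %*% A)
  sigma2 <- sum(resid^2) / max(1L, length(y) - 1L)
  delta <- sqrt(sigma2 * diag(Ginv))
  fov <- if (var(y) < 1e-30) NA_real_ else 1 - var(resid) / var(y)
  list(A = A, delta = delta, sigma2 = sigma2, fov = fov)
}

#' Infer TF noise-propagation activities by ridge regression
#'
#' Fits, per condition, the centered linear model
#' `N_pc - Nbar_c = sum_r (S_pr - Sbar_r) A_rc + eps` with a Gaussian prior
#' on the activities (ridge penalty `lambda`), yielding the posterior mean
#' activities `A_rc`, their posterior standard deviations `delta_A_rc`
#' (error bars, from the posterior covariance with plug-in residual
#' variance), per-condition residual variance, and the in-sample fraction
#' of explained variance (FOV).
#'
#' @param N promoters x conditions noise matrix.
#' @param S promoters x regulators binary network.
#' @param lambda positive ridge penalty, or `"auto"` to select it by
#'   promoter-wise cross-validation ([select_prior_strength()]).
#' @param lambda_grid grid searched when `lambda = "auto"`.
#' @param k_folds,seed cross-validation settings for `"auto"`.
#' @param unannotated see [center_model_inputs()].
#' @return object of class `activity_estimates`: list with `A` and `delta`
#'   (regulators x conditions), `fov`, `sigma2`, `N_bar` (per condition),
#'   `S_bar`, `lambda`, `n_promoters`.
#' @export
infer_activities <- function(N, S, lambda = "auto",
                             lambda_grid = 10^seq(-2, 4),
                             k_folds = 10L, seed = 1L,
                             unannotated = c("drop", "zero")) {
  ci <- center_model_inputs(N, S, unannotated = match.arg(unannotated))
  if (identical(lambda, "auto")) {
    lambda <- select_prior_strength(N, S, lambda_grid = lambda_grid,
                                    k_folds = k_folds, seed = seed,
                                    unannotated = match.arg(unannotated))$lambda
  }
  C <- ncol(ci$Y)
  R <- ncol(ci$X)
  A <- delta <- matrix(NA_real_, nrow = R, ncol = C,
                       dimnames = list(colnames(ci$X), colnames(ci$Y)))
  fov <- sigma2 <- setNames(numeric(C), colnames(ci$Y))
  for (k in seq_len(C)) {
    f <- ridge_activities(ci$X, ci$Y[, k], lambda)
    A[, k] <- f$A
    delta[, k] <- f$delta
    fov[k] <- f$fov
    sigma2[k] <- f$sigma2
  }
  structure(
    list(A = A, delta = delta, fov = fov, sigma2 = sigma2,
         N_bar = ci$N_bar, S_bar = ci$S_bar, lambda = lambda,
         n_promoters = nrow(ci$X)),
    class = "activity_estimates"
  )
}

#' @export
print.activity_estimates <- function(x, ...) {
  cat(sprintf("Activity estimates: %d regulators x %d conditions (%d promoters, lambda = %.4g)\n",
              nrow(x$A), ncol(x$A), x$n_promoters, x$lambda))
  cat(sprintf("  in-sample FOV: %s\n",
              paste(sprintf("%.1f%%", 100 * x$fov), collapse = ", ")))
  invisible(x)
}

#' Select the ridge prior strength by cross-validation
#'
#' Promoter-wise k-fold cross-validation: for each candidate `lambda` the
#' model is fitted on the training promoters of each fold and the fraction
#' of out-of-fold explained variance is recorded, averaged over folds and
#' conditions. The `lambda` maximizing the mean out-of-fold FOV wins; ties
#' go to the smallest `lambda`. A single prior strength is shared across
#' conditions, mirroring one Gaussian prior for all activities.
#'
#' @param N,S noise matrix and network, as in [infer_activities()].
#' @param lambda_grid positive candidate penalties.
#' @param k_folds number of promoter folds.
#' @param seed integer seed for the fold assignment.
#' @param unannotated see [center_model_inputs()].
#' @return list with `lambda` (the winner), `oof_fov` (mean out-of-fold
#'   FOV per candidate), `lambda_grid`.
#' @export
select_prior_strength <- function(N, S, lambda_grid = 10^seq(-2, 4),
                                  k_folds = 10L, seed = 1L,
                                  unannotated = c("drop", "zero")) {
  if (length(lambda_grid) == 0L || any(lambda_grid <= 0)) {
    stopf("lambda_grid must be non-empty and positive")
  }
  ci <- center_model_inputs(N, S, unannotated = match.arg(unannotated))
  P <- nrow(ci$X)
  C <- ncol(ci$Y)
  set.seed(child_seed(seed, 301L))
  fold <- sample(rep_len(seq_len(k_folds), P))
  oof <- matrix(NA_real_, nrow = length(lambda_grid), ncol = C)
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    pred <- matrix(NA_real_, nrow = P, ncol = C)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      Xt <- ci$X[tr, , drop = FALSE]
      G <- crossprod(Xt) + diag(lam, ncol(Xt))
      Ahat <- chol2inv(chol(G)) %*% crossprod(Xt, ci$Y[tr, , drop = FALSE])
      pred[!tr, ] <- ci$X[!tr, , drop = FALSE] %*% Ahat
    }
    for (k in seq_len(C)) {
      oof[li, k] <- 1 - mean((ci$Y[, k] - pred[, k])^2) / var(ci$Y[, k])
    }
  }
  mean_oof <- rowMeans(oof)
  best <- which(mean_oof >= max(mean_oof) - 1e-12)[1L]
  list(lambda = lambda_grid[best], oof_fov = mean_oof,
       lambda_grid = lambda_grid)
}

#' Fraction of explained variance of centered noise levels
#'
#' `fov_c = 1 - Var(residual_c) / Var(N_.c - Nbar_c)` for a given activity
#' matrix (inferred or plugged-in truth).
#'
#' @param N,S noise matrix and network.
#' @param A regulators x conditions activity matrix.
#' @param unannotated see [center_model_inputs()].
#' @return named vector of FOV per condition (`NA` where the response has
#'   zero variance).
#' @export
explained_variance <- function(N, S, A, unannotated = c("drop", "zero")) {
  ci <- center_model_inputs(N, S, unannotated = match.arg(unannotated))
  A <- A[colnames(ci$X), , drop = FALSE]
  fitted <- ci$X %*% A
  vapply(seq_len(ncol(ci$Y)), function(k) {
    vy <- var(ci$Y[, k])
    if (vy < 1e-30) return(NA_real_)
    1 - var(ci$Y[, k] - fitted[, k]) / vy
  }, numeric(1L)) |> setNames(colnames(ci$Y))
}

#' Permutation null for the explained variance
#'
#' Breaks the association between regulatory inputs and noise levels by
#' randomly permuting whole promoter rows of the noise matrix (jointly
#' across conditions, preserving each promoter's cross-condition noise
#' profile), refits the ridge model at the same `lambda`, and records the
#' in-sample FOV of each shuffle. Because the design matrix is unchanged by
#' the permutation, the ridge projector is precomputed once.
#'
#' @param N,S noise matrix and network.
#' @param lambda positive ridge penalty (use the value selected on the
#'   observed data).
#' @param n_shuffles number of row permutations (>= 2).
#' @param seed integer seed.
#' @param unannotated see [center_model_inputs()].
#' @return list with per-condition `mean`, `sd` (standard error of a
#'   single null FOV), `sem` (standard error of the null mean), and the
#'   `n_shuffles x C` matrix `fov` of all shuffle FOVs.
#' @export
randomized_fov <- function(N, S, lambda, n_shuffles = 100L, seed = 1L,
                           unannotated = c("drop", "zero")) {
  if (n_shuffles < 2L) stopf("n_shuffles must be >= 2")
  ci <- center_model_inputs(N, S, unannotated = match.arg(unannotated))
  P <- nrow(ci$X)
  C <- ncol(ci$Y)
  G <- crossprod(ci$X) + diag(lambda, ncol(ci$X))
  proj <- chol2inv(chol(G)) %*% t(ci$X)  # A = proj %*% y for any response
  set.seed(child_seed(seed, 302L))
  fov <- matrix(NA_real_, nrow = n_shuffles, ncol = C,
                dimnames = list(NULL, colnames(ci$Y)))
  for (s in seq_len(n_shuffles)) {
    Yp <- ci$Y[sample.int(P), , drop = FALSE]
    Ahat <- proj %*% Yp
    fitted <- ci$X %*% Ahat
    for (k in seq_len(C)) {
      fov[s, k] <- 1 - var(Yp[, k] - fitted[, k]) / var(Yp[, k])
    }
  }
  list(mean = colMeans(fov), sd = apply(fov, 2L, sd),
       sem = apply(fov, 2L, sd) / sqrt(n_shuffles), fov = fov)
}

#' Condition-specific noise propagators
#'
#' A regulator significantly propagates noise in condition `c` when its
#' activity exceeds its error bar, `A_rc > delta_A_rc`. Condition-specific
#' propagators are the regulators significant in exactly one condition.
#'
#' @param estimates an `activity_estimates`.
#' @return list with `specific` (data.frame: regulator, condition,
#'   activity, error) and `per_condition` (named list of significant
#'   regulators per condition).
#' @export
condition_specific_propagators <- function(estimates) {
  sig <- estimates$A > estimates$delta
  per_condition <- lapply(seq_len(ncol(sig)), function(k) {
    rownames(sig)[sig[, k]]
  })
  names(per_condition) <- colnames(sig)
  n_sig <- rowSums(sig)
  idx <- which(n_sig == 1L)
  specific <- do.call(rbind, lapply(idx, function(r) {
    k <- which(sig[r, ])
    data.frame(regulator = rownames(sig)[r], condition = colnames(sig)[k],
               activity = estimates$A[r, k], error = estimates$delta[r, k],
               stringsAsFactors = FALSE)
  }))
  if (is.null(specific)) {
    specific <- data.frame(regulator = character(), condition = character(),
                           activity = numeric(), error = numeric())
  }
  rownames(specific) <- NULL
  list(specific = specific, per_condition = per_condition)
}

#' Condition-averaged noise-propagation activities and top propagators
#'
#' For each regulator, averages its activity over conditions
#' (`Abar_r = mean_c A_rc`) with combined error
#' `delta_Abar_r = sqrt(sum_c delta_A_rc^2) / C` (per-condition errors
#' treated as independent). Regulators with `Abar_r > delta_Abar_r` are
#' ranked by significance `|Abar_r / delta_Abar_r|`, and the strongest
#' `top_k` are reported as the consistent propagators.
#'
#' @param estimates an `activity_estimates`.
#' @param top_k number of top propagators to report (default 6).
#' @return list with `table` (data.frame: regulator, A_bar, delta_A_bar,
#'   significance, sorted by significance among `A_bar > delta_A_bar`) and
#'   `top` (character vector of the strongest `top_k` regulators).
#' @export
average_activities <- function(estimates, top_k = 6L) {
  C <- ncol(estimates$A)
  A_bar <- rowMeans(estimates$A)
  delta_bar <- sqrt(rowSums(estimates$delta^2)) / C
  tab <- data.frame(regulator = rownames(estimates$A), A_bar = A_bar,
                    delta_A_bar = delta_bar,
                    significance = abs(A_bar / delta_bar),
                    stringsAsFactors = FALSE, row.names = NULL)
  sig <- tab[tab$A_bar > tab$delta_A_bar, , drop = FALSE]
  sig <- sig[order(-sig$significance), , drop = FALSE]
  rownames(sig) <- NULL
  list(table = sig, top = head(sig$regulator, top_k), all = tab)
}
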