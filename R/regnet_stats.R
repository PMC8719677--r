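#' Per-promoter plasticities, average noise, and input counts
#'
#' Expression plasticity is the variance of a promoter's mean
#' log-expression across conditions; noise plasticity the variance of its
#' noise level across conditions (denominator `C - 1` in both); mean noise
#' the average noise level; `n_inputs` the number of known regulators (row
#' sum of the binary network, 0 for promoters without a network row).
#'
#' @param mean_matrix promoters x conditions matrix of mean log-expression.
#' @param noise_matrix promoters x conditions matrix of noise levels.
#' @param network promoters x regulators binary matrix (optional).
#' @return data.frame (`promoter_id`, `expression_plasticity`,
#'   `noise_plasticity`, `mean_noise`, `n_inputs`).
#' @export
compute_plasticities <- function(mean_matrix, noise_matrix, network = NULL) {
  if (ncol(mean_matrix) < 2L) stopf("need >= 2 conditions")
  stopifnot(identical(rownames(mean_matrix), rownames(noise_matrix)))
  n_inputs <- rep(0L, nrow(mean_matrix))
  if (!is.null(network)) {
    i <- match(rownames(mean_matrix), rownames(network))
    n_inputs <- ifelse(is.na(i), 0L, rowSums(network)[i])
  }
  data.frame(
    promoter_id = rownames(mean_matrix),
    expression_plasticity = apply(mean_matrix, 1L, var),
    noise_plasticity = apply(noise_matrix, 1L, var),
    mean_noise = rowMeans(noise_matrix),
    n_inputs = as.integer(n_inputs),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Shared machinery for the cutoff curves: for every distinct observed
# cutoff value, a statistic of the promoters with `value > = cutoff`,
# truncated where fewer than `min_group` promoters remain.
cutoff_curve <- function(values, stat_fun, min_group = 10L) {
  cutoffs <- sort(unique(values))
  rows <- lapply(cutoffs, function(ct) {
    idx <- which(values >= ct)
    if (length(idx) < min_group) return(NULL)
    cbind(cutoff = ct, stat_fun(idx), n = length(idx))
  })
  out <- do.call(rbind, rows)
  as.data.frame(out)
}

#' Mean number of regulatory inputs above a noise cutoff
#'
#' For each cutoff on the grid of observed average noise values, the mean
#' and standard error of the number of known regulatory inputs among
#' promoters with average noise at or above the cutoff. The curve is
#' truncated where fewer than `min_group` promoters remain.
#'
#' @param table plasticity table from [compute_plasticities()].
#' @param value column to threshold on (default `"mean_noise"`; pass a
#'   numeric vector to threshold per-condition noise instead).
#' @param min_group minimum group size for a curve point.
#' @return data.frame (`cutoff`, `mean_inputs`, `se`, `n`).
#' @export
inputs_above_cutoff_curve <- function(table, value = "mean_noise",
                                      min_group = 10L) {
  if (nrow(table) < 20L) stopf("need >= 20 promoters")
  v <- if (is.character(value)) table[[value]] else value
  cutoff_curve(v, function(idx) {
    x <- table$n_inputs[idx]
    data.frame(mean_inputs = mean(x), se = sd(x) / sqrt(length(x)))
  }, min_group = min_group)
}

#' Fraction of regulated promoters above a noise cutoff
#'
#' As [inputs_above_cutoff_curve()], but the statistic is the fraction of
#' promoters with at least one known regulatory input, with a binomial
#' standard error `sqrt(f (1 - f) / n)`.
#'
#' @inheritParams inputs_above_cutoff_curve
#' @return data.frame (`cutoff`, `fraction_regulated`, `se`, `n`).
#' @export
fraction_regulated_curve <- function(table, value = "mean_noise",
                                     min_group = 10L) {
  if (nrow(table) < 20L) stopf("need >= 20 promoters")
  v <- if (is.character(value)) table[[value]] else value
  cutoff_curve(v, function(idx) {
    f <- mean(table$n_inputs[idx] >= 1L)
    data.frame(fraction_regulated = f,
               se = sqrt(f * (1 - f) / length(idx)))
  }, min_group = min_group)
}

# Welch's two-sample t statistic (and two-sided p) from first principles;
# used as the shared backend so the cutoff scan does not pay t.test()
# overhead per cutoff.
welch_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vx <- var(x) / nx
  vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

#' Welch t-statistics of input counts above versus below noise cutoffs
#'
#' For each cutoff over a condition's noise levels, Welch's two-sample t
#' statistic for the difference in number of known regulatory inputs
#' between promoters above and below the cutoff. Cutoffs where either
#' group has fewer than `min_group` promoters are omitted.
#'
#' @param n_inputs integer vector of regulatory-input counts per promoter.
#' @param noise numeric vector of noise levels (same promoters).
#' @param min_group minimum size of both groups.
#' @return data.frame (`cutoff`, `t`, `df`, `p`, `n_above`, `n_below`).
#' @export
cutoff_t_statistics <- function(n_inputs, noise, min_group = 10L) {
  stopifnot(length(n_inputs) == length(noise))
  cutoffs <- sort(unique(noise))
  rows <- lapply(cutoffs, function(ct) {
    above <- noise >= ct
    if (sum(above) < min_group || sum(!above) < min_group) return(NULL)
    w <- welch_t(n_inputs[above], n_inputs[!above])
    data.frame(cutoff = ct, t = unname(w["t"]), df = unname(w["df"]),
               p = unname(w["p"]), n_above = sum(above),
               n_below = sum(!above))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cutoff = numeric(), t = numeric(), df = numeric(),
                      p = numeric(), n_above = integer(),
                      n_below = integer())
  }
  out
}

#' Noise plasticity by number of regulatory inputs
#'
#' Splits promoters into the groups "no known input" (`0`), "1 or 2
#' inputs", and "3 or more inputs", returns the empirical cumulative
#' distribution of noise plasticity per group, and all pairwise two-sided
#' Welch t tests between groups with at least `min_group` members.
#'
#' @param table plasticity table from [compute_plasticities()].
#' @param min_group minimum group size for a pairwise test.
#' @return list with `groups` (named list of noise-plasticity vectors),
#'   `ecdf` (named list of ECDF functions), `tests` (data.frame of
#'   pairwise Welch tests; zero rows if fewer than two groups qualify).
#' @export
plasticity_by_input_group <- function(table, min_group = 5L) {
  grp <- cut(table$n_inputs, breaks = c(-Inf, 0, 2, Inf),
             labels = c("0", "1-2", ">=3"))
  groups <- split(table$noise_plasticity, grp, drop = FALSE)
  groups <- groups[vapply(groups, length, 1L) > 0L]
  ec <- lapply(groups, ecdf)
  eligible <- names(groups)[vapply(groups, length, 1L) >= min_group]
  tests <- NULL
  if (length(eligible) >= 2L) {
    pairs <- utils::combn(eligible, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]
      b <- pairs[2L, j]
      w <- welch_t(groups[[a]], groups[[b]])
      data.frame(group_a = a, group_b = b, t = unname(w["t"]),
                 p = unname(w["p"]), mean_a = mean(groups[[a]]),
                 mean_b = mean(groups[[b]]), stringsAsFactors = FALSE)
    }))
  }
  if (is.null(tests)) {
    tests <- data.frame(group_a = character(), group_b = character(),
                        t = numeric(), p = numeric(), mean_a = numeric(),
                        mean_b = numeric())
  }
  list(groups = groups, ecdf = ec, tests = tests)
}

#' Compare constitutive-like and regulated promoter sets
#'
#' Three two-sided Welch t tests — expression plasticity, mean noise, and
#' noise plasticity — between a constitutive-like promoter set and a
#' regulated set, with group means so the direction of each effect is
#' checkable.
#'
#' @param constitutive,regulated plasticity tables (as from
#'   [compute_plasticities()]) for the two sets, each with >= 5 rows.
#' @return data.frame with one row per quantity: `quantity`, `p`, `t`,
#'   `mean_constitutive`, `mean_regulated`.
#' @export
constitutive_vs_regulated_comparison <- function(constitutive, regulated) {
  if (nrow(constitutive) < 5L || nrow(regulated) < 5L) {
    stopf("both sets need >= 5 promoters")
  }
  quantities <- c("expression_plasticity", "mean_noise", "noise_plasticity")
  do.call(rbind, lapply(quantities, function(q) {
    w <- welch_t(constitutive[[q]], regulated[[q]])
    data.frame(quantity = q, p = unname(w["p"]), t = unname(w["t"]),
               mean_constitutive = mean(constitutive[[q]]),
               mean_regulated = mean(regulated[[q]]),
               stringsAsFactors = FALSE)
  }))
}
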