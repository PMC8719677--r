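#' Generate a sparse binary regulatory network
#'
#' Draws a binary promoter-by-regulator matrix `S_pr` in which the number of
#' regulatory inputs of each promoter follows a Poisson law. A fraction
#' `exp(-mean_in_degree)` of promoters therefore has no input at all
#' (constitutive promoters), emulating the sparsity of curated regulatory
#' annotations such as RegulonDB, where the majority of promoters have no
#' known regulator.
#'
#' @param P number of promoters (rows).
#' @param R number of regulators (columns).
#' @param mean_in_degree mean number of regulatory inputs per promoter
#'   (Poisson mean, capped at `R`); 0 yields an all-zero network.
#' @param seed integer seed.
#' @return binary matrix with promoter row names and regulator column names.
#' @export
generate_network <- function(P, R, mean_in_degree, seed = 1L) {
  if (P < 1 || R < 1) stopf("P and R must be >= 1")
  if (mean_in_degree < 0) stopf("mean_in_degree must be non-negative")
  if (mean_in_degree >= R) stopf("mean_in_degree must be < R")
  set.seed(child_seed(seed, 101L))
  S <- matrix(0L, nrow = P, ncol = R,
              dimnames = list(sprintf("p%04d", seq_len(P)),
                              sprintf("TF%02d", seq_len(R))))
  if (mean_in_degree > 0) {
    deg <- pmin(rpois(P, mean_in_degree), R)
    for (p in which(deg > 0L)) {
      S[p, sample.int(R, deg[p])] <- 1L
    }
  }
  S
}

#' Generate ground-truth noise-propagation activities
#'
#' Builds a regulator-by-condition activity matrix with two planted classes
#' of noise propagators: `n_global` regulators active at `scale` in every
#' condition, and `n_condition_specific` regulators active at `scale` in
#' exactly one (randomly chosen) condition each. All remaining regulators
#' are inactive everywhere. Activities are variances of log-fluorescence
#' injected per target and are therefore non-negative at truth level, even
#' though the downstream inference model permits signed centered estimates.
#'
#' @param R number of regulators.
#' @param C number of conditions.
#' @param n_condition_specific regulators active in exactly one condition.
#' @param n_global regulators active in all conditions.
#' @param scale activity magnitude (variance of log-fluorescence per target).
#' @param seed integer seed.
#' @return `R x C` matrix with attributes `global_regulators`,
#'   `specific_regulators` (named integer vector of active conditions).
#' @export
generate_activities <- function(R, C, n_condition_specific = 5L,
                                n_global = 6L, scale = 0.01, seed = 1L) {
  if (scale < 0) stopf("scale must be non-negative")
  if (n_condition_specific + n_global > R) {
    stopf("n_condition_specific + n_global must be <= R")
  }
  set.seed(child_seed(seed, 102L))
  A <- matrix(0, nrow = R, ncol = C,
              dimnames = list(sprintf("TF%02d", seq_len(R)),
                              sprintf("cond%d", seq_len(C))))
  chosen <- sample.int(R, n_condition_specific + n_global)
  glob <- chosen[seq_len(n_global)]
  spec <- chosen[n_global + seq_len(n_condition_specific)]
  A[glob, ] <- scale
  spec_cond <- integer(0)
  if (n_condition_specific > 0) {
    spec_cond <- sample.int(C, n_condition_specific, replace = TRUE)
    A[cbind(spec, spec_cond)] <- scale
  }
  attr(A, "global_regulators") <- rownames(A)[glob]
  attr(A, "specific_regulators") <- setNames(spec_cond, rownames(A)[spec])
  A
}

#' Generate per-condition growth rates and noise-floor parameters
#'
#' Growth rates are evenly spaced over `rate_range` (a designed set of
#' conditions, not random) and the extrinsic noise floor follows a linear
#' law `a_c = intercept + slope * rate`, optionally with Gaussian jitter.
#' The Poissonian measurement-noise magnitude `b_c` is constant by default.
#'
#' @param C number of conditions.
#' @param slope change in floor variance per unit growth rate (1/h);
#'   negative for the empirically observed decrease of noise with growth.
#' @param intercept floor variance at zero growth.
#' @param rate_range numeric length-2, growth-rate range in 1/h.
#' @param b Poissonian term magnitude per condition (recycled).
#' @param jitter_sd Gaussian jitter SD added to each `a_c` (0 = exact law).
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @return data.frame with columns `condition_id`, `growth_rate`, `a`, `b`.
#' @export
generate_condition_metadata <- function(C = 8L, slope = -0.02,
                                        intercept = 0.055,
                                        rate_range = c(0.1, 1.7),
                                        b = 0.8, jitter_sd = 0,
                                        seed = 1L) {
  if (C < 1) stopf("C must be >= 1")
  rate <- if (C == 1L) mean(rate_range) else {
    seq(rate_range[2L], rate_range[1L], length.out = C)
  }
  a <- intercept + slope * rate
  if (jitter_sd > 0) {
    set.seed(child_seed(seed, 103L))
    a <- a + rnorm(C, 0, jitter_sd)
  }
  if (any(a <= 0)) {
    stopf("parameters yield non-positive noise floor a_c (min %.4g)", min(a))
  }
  data.frame(
    condition_id = sprintf("cond%d", seq_len(C)),
    growth_rate = rate, a = a, b = rep_len(b, C),
    stringsAsFactors = FALSE
  )
}

#' Assemble a ground-truth object for a synthetic noise study
#'
#' Bundles a network, planted activities, condition metadata, per-promoter
#' baseline noise and per-promoter/condition mean expression into a single
#' ground-truth object from which single-cell events can be generated and
#' against which every downstream stage can be checked.
#'
#' Baseline noise (noise of a promoter above the floor not attributable to
#' any modeled regulator) is exponentially distributed with a small mean and
#' is a *per-promoter* constant shared across conditions, so constitutive
#' promoters sit just above the floor with reproducible cross-condition
#' structure. Mean log-fluorescence is uniform over `mean_range` per
#' promoter, with per-condition Gaussian shifts whose SD grows as
#' `mean_shift_sd * sqrt(n_inputs)` — regulated promoters are the plastic
#' ones, constitutive promoters are not.
#'
#' @param P,R,C numbers of promoters, regulators, conditions.
#' @param mean_in_degree Poisson mean of regulatory inputs per promoter.
#' @param n_condition_specific,n_global planted propagator counts.
#' @param activity_scale planted activity magnitude (variance units).
#' @param baseline_mean mean of the exponential per-promoter baseline noise.
#' @param mean_range range of per-promoter mean log-fluorescence.
#' @param mean_shift_sd per-condition mean-shift SD per sqrt(regulatory
#'   input); creates expression plasticity for regulated promoters.
#' @param outlier_fraction fraction of events replaced by uniform outliers.
#' @param n_events single-cell events per promoter and condition.
#' @param metadata optional condition metadata (as from
#'   [generate_condition_metadata()]); generated at defaults if `NULL`.
#' @param seed integer master seed; all randomness fans out from it.
#' @return object of class `noise_ground_truth`.
#' @export
simulate_noise_study <- function(P = 1810L, R = 40L, C = 8L,
                                 mean_in_degree = 0.9,
                                 n_condition_specific = 5L, n_global = 6L,
                                 activity_scale = 0.01,
                                 baseline_mean = 0.005,
                                 mean_range = c(3, 8), mean_shift_sd = 0.15,
                                 outlier_fraction = 0.02,
                                 n_events = 5000L, metadata = NULL,
                                 seed = 1L) {
  if (n_events < 2) stopf("n_events must be >= 2")
  if (outlier_fraction < 0 || outlier_fraction >= 1) {
    stopf("outlier_fraction must be in [0, 1)")
  }
  S <- generate_network(P, R, mean_in_degree, seed = seed)
  A <- generate_activities(R, C, n_condition_specific, n_global,
                           scale = activity_scale, seed = seed)
  meta <- metadata %||% generate_condition_metadata(C, seed = seed)
  if (nrow(meta) != C) stopf("metadata must have C rows")

  set.seed(child_seed(seed, 104L))
  baseline <- if (baseline_mean > 0) rexp(P, rate = 1 / baseline_mean)
              else rep(0, P)
  m0 <- runif(P, mean_range[1L], mean_range[2L])
  n_inputs <- rowSums(S)
  shift_sd <- mean_shift_sd * sqrt(n_inputs)
  shifts <- matrix(rnorm(P * C, 0, rep(shift_sd, C)), nrow = P, ncol = C)
  M <- m0 + shifts
  dimnames(M) <- list(rownames(S), meta$condition_id)
  colnames(A) <- meta$condition_id

  truth <- list(
    network = S, activities = A, baseline = setNames(baseline, rownames(S)),
    metadata = meta, base_means = M,
    outlier_fraction = outlier_fraction, n_events = as.integer(n_events),
    outlier_range = c(mean_range[1L] - 2, mean_range[2L] + 2),
    seed = as.integer(seed)
  )
  class(truth) <- "noise_ground_truth"
  truth
}

#' @export
print.noise_ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d promoters x %d regulators x %d conditions, %d events/cell\n",
    nrow(x$network), ncol(x$network), nrow(x$metadata), x$n_events))
  cat(sprintf("  planted propagators: %d global, %d condition-specific\n",
              length(attr(x$activities, "global_regulators")),
              length(attr(x$activities, "specific_regulators"))))
  invisible(x)
}

#' True injected noise levels of a ground truth
#'
#' `N_pc^true = baseline_p + sum_r S_pr A_rc^true`: the per-promoter noise
#' above the floor that the generator injected.
#'
#' @param truth a `noise_ground_truth`.
#' @return promoters-by-conditions matrix.
#' @export
true_noise <- function(truth) {
  N <- truth$network %*% truth$activities + truth$baseline
  dimnames(N) <- dimnames(truth$base_means)
  N
}

#' True total variance of log-fluorescence of a ground truth
#'
#' `v_pc = v_min(m_pc) + N_pc^true`, with the minimal variance
#' `v_min(m) = a_c + b_c exp(-m)` evaluated at the true mean. This is the
#' Gaussian variance events are drawn with (measurement noise folded in).
#'
#' @param truth a `noise_ground_truth`.
#' @return promoters-by-conditions matrix.
#' @export
true_variance <- function(truth) {
  a <- truth$metadata$a
  b <- truth$metadata$b
  vmin <- sweep(exp(-truth$base_means), 2L, b, `*`)
  vmin <- sweep(vmin, 2L, a, `+`)
  vmin + true_noise(truth)
}

# Events for one promoter x condition cell, deterministic in
# (truth$seed, p, c) regardless of generation order.
cell_events <- function(truth, p, c, vtot = NULL) {
  v <- if (is.null(vtot)) true_variance(truth)[p, c] else vtot[p, c]
  set.seed(child_seed(truth$seed, 200L + p, c))
  x <- rnorm(truth$n_events, truth$base_means[p, c], sqrt(v))
  if (truth$outlier_fraction > 0) {
    is_out <- runif(truth$n_events) < truth$outlier_fraction
    n_out <- sum(is_out)
    if (n_out > 0) {
      x[is_out] <- runif(n_out, truth$outlier_range[1L],
                         truth$outlier_range[2L])
    }
  }
  x
}

#' Generate single-cell log-fluorescence events
#'
#' Draws `n_events` events per promoter and condition from
#' `Normal(m_pc, v_min(m_pc) + N_pc^true)` in log-space, then replaces a
#' fraction `outlier_fraction` of events with draws from a uniform law over
#' the generator's outlier range (the mean range widened by 2 log units on
#' each side). Events are deterministic given the master seed, per cell,
#' independent of the order or subset in which cells are generated.
#'
#' For a full-size study this table is large; restrict via `promoters` /
#' `conditions`, or use [summarize_study()] which streams cells through the
#' mixture EM without materializing all events.
#'
#' @param truth a `noise_ground_truth`.
#' @param promoters,conditions optional subsets (names or indices).
#' @return data.frame with columns `promoter_id`, `condition_id`,
#'   `log_fluorescence`.
#' @export
generate_events <- function(truth, promoters = NULL, conditions = NULL) {
  stopifnot(inherits(truth, "noise_ground_truth"))
  pn <- rownames(truth$network)
  cn <- truth$metadata$condition_id
  pidx <- if (is.null(promoters)) seq_along(pn) else {
    if (is.character(promoters)) match(promoters, pn) else as.integer(promoters)
  }
  cidx <- if (is.null(conditions)) seq_along(cn) else {
    if (is.character(conditions)) match(conditions, cn) else as.integer(conditions)
  }
  if (anyNA(pidx) || anyNA(cidx)) stopf("unknown promoter or condition id")
  vtot <- true_variance(truth)
  n <- truth$n_events
  out <- vector("list", length(pidx) * length(cidx))
  k <- 1L
  for (ci in cidx) {
    for (pi in pidx) {
      out[[k]] <- data.frame(
        promoter_id = rep(pn[pi], n), condition_id = rep(cn[ci], n),
        log_fluorescence = cell_events(truth, pi, ci, vtot),
        stringsAsFactors = FALSE
      )
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}

#' Simulate a two-block gene-feature table
#'
#' Generates the 10 canonical gene features under a latent factor model:
#' five "expression" features (RNA level, protein level, codon bias, dN,
#' dS) load on one factor (evolutionary rates with negative sign), four
#' "regulation" features (number of inputs, expression plasticity, mean
#' noise, noise plasticity) load on an orthogonal factor, and one feature
#' (mean expression in this pipeline) is independent. Used to check that
#' the feature PCA recovers the two-axis organization.
#'
#' @param n_genes number of genes (rows).
#' @param loading factor loading of each block feature (0..1).
#' @param seed integer seed.
#' @return data.frame with `gene_id` plus the 10 feature columns.
#' @export
simulate_gene_features <- function(n_genes = 2000L, loading = 0.9,
                                   seed = 1L) {
  if (loading < 0 || loading > 1) stopf("loading must be in [0, 1]")
  set.seed(child_seed(seed, 105L))
  f1 <- rnorm(n_genes)
  f2 <- rnorm(n_genes)
  # the two latent axes are orthogonal by construction; remove the
  # O(1/sqrt(n)) sampling correlation of the scores so the factor
  # structure is exact in-sample
  f1 <- scale(f1)[, 1L]
  f2 <- residuals(lm(f2 ~ f1))
  f2 <- f2 / sd(f2)
  res <- sqrt(1 - loading^2)
  blk <- function(f, sign = 1) sign * loading * f + res * rnorm(n_genes)
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    rna_level = blk(f1), protein_level = blk(f1), codon_bias = blk(f1),
    dN = blk(f1, -1), dS = blk(f1, -1),
    n_inputs = blk(f2), expression_plasticity = blk(f2),
    mean_noise = blk(f2), noise_plasticity = blk(f2),
    mean_expression = rnorm(n_genes),
    stringsAsFactors = FALSE
  )
}
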