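# Plasticities, cutoff curves, and Welch group comparisons.

make_plasticity_table <- function(n, n_inputs, noise_plasticity,
                                  mean_noise = noise_plasticity,
                                  expression_plasticity = noise_plasticity) {
  data.frame(promoter_id = sprintf("p%04d", seq_len(n)),
             expression_plasticity = expression_plasticity,
             noise_plasticity = noise_plasticity, mean_noise = mean_noise,
             n_inputs = as.integer(n_inputs), stringsAsFactors = FALSE)
}

test_that("plasticities are row variances with denominator C - 1", {
  M <- matrix(c(5, 5, 0, 0.2), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("c1", "c2")))
  N <- M
  S <- matrix(c(1, 1, 0, 0, 0, 1), nrow = 2,
              dimnames = list(c("p1", "p2"), c("TF1", "TF2", "TF3")))
  tab <- compute_plasticities(M, N, S)
  expect_equal(tab$expression_plasticity, c(0, 0.02))
  expect_equal(tab$noise_plasticity, c(0, 0.02))
  expect_equal(tab$mean_noise, c(5, 0.1))
  expect_identical(tab$n_inputs, c(1L, 2L))
  expect_error(compute_plasticities(M[, 1, drop = FALSE],
                                    N[, 1, drop = FALSE]), ">= 2")
  # promoters without a network row count zero inputs
  tab2 <- compute_plasticities(M, N, S[1, , drop = FALSE])
  expect_identical(tab2$n_inputs, c(1L, 0L))
})

test_that("input-count cutoff curve is flat for constant inputs and dense otherwise", {
  tab <- make_plasticity_table(50, n_inputs = 2,
                               noise_plasticity = runif(50))
  cur <- inputs_above_cutoff_curve(tab)
  expect_true(all(cur$mean_inputs == 2))
  expect_true(all(cur$se == 0))
  # lowest cutoff covers all promoters
  expect_equal(cur$n[1], 50)
  expect_equal(cur$cutoff, sort(cur$cutoff))
  # truncation: fewer than min_group promoters above -> no point
  expect_true(all(cur$n >= 10))
  expect_error(inputs_above_cutoff_curve(tab[1:10, ]), ">= 20")
})

test_that("regulated fraction curve hits its trivial bounds", {
  all_reg <- make_plasticity_table(40, n_inputs = 1,
                                   noise_plasticity = runif(40))
  expect_true(all(fraction_regulated_curve(all_reg)$fraction_regulated == 1))
  none <- make_plasticity_table(40, n_inputs = 0,
                                noise_plasticity = runif(40))
  expect_true(all(fraction_regulated_curve(none)$fraction_regulated == 0))
})

test_that("noise-linked inputs produce rising curves and large t statistics", {
  set.seed(41)
  n <- 800
  n_inputs <- rpois(n, 0.9)
  noise <- 0.005 + 0.01 * n_inputs + rexp(n, 1 / 0.005)
  tab <- make_plasticity_table(n, n_inputs, noise_plasticity = noise,
                               mean_noise = noise)
  cur <- inputs_above_cutoff_curve(tab)
  trend <- cor.test(cur$cutoff, cur$mean_inputs, method = "spearman",
                    exact = FALSE)
  expect_gt(trend$estimate, 0)
  expect_lt(trend$p.value, 0.05)

  frac <- fraction_regulated_curve(tab)
  overall <- mean(tab$n_inputs >= 1)
  expect_gt(frac$fraction_regulated[nrow(frac)], overall)

  ts <- cutoff_t_statistics(tab$n_inputs, noise)
  expect_gt(max(abs(ts$t)), 4)
})

test_that("Welch statistics match a hand-computed oracle", {
  x <- c(0, 0, 1)
  y <- c(2, 3, 4)
  ts <- cutoff_t_statistics(c(x, y), c(rep(0, 3), rep(1, 3)), min_group = 3)
  expect_equal(ts$t[ts$cutoff == 1], welch_oracle(y, x), tolerance = 1e-12)
  # identical groups: t = 0
  ts0 <- cutoff_t_statistics(rep(c(0, 1, 2), 10), rep(c(0, 1), each = 15),
                             min_group = 3)
  expect_equal(ts0$t[ts0$cutoff == 1], 0)
  # undersized groups are omitted
  expect_identical(nrow(cutoff_t_statistics(1:5, 1:5, min_group = 3)), 0L)
})

test_that("noise plasticity grows with regulatory inputs across groups", {
  set.seed(42)
  n <- 600
  n_inputs <- rpois(n, 1.2)
  plast <- 1e-4 + 5e-4 * n_inputs + rexp(n, 1 / 2e-4)
  tab <- make_plasticity_table(n, n_inputs, noise_plasticity = plast)
  res <- plasticity_by_input_group(tab)
  expect_setequal(names(res$groups), c("0", "1-2", ">=3"))
  # ECDFs are proper distribution functions
  for (f in res$ecdf) {
    expect_equal(f(max(plast)), 1)
    xs <- seq(min(plast), max(plast), length.out = 50)
    expect_true(all(diff(f(xs)) >= 0))
  }
  row <- res$tests[res$tests$group_a == "0" & res$tests$group_b == ">=3", ]
  expect_lt(row$p, 0.01)
  expect_lt(row$mean_a, row$mean_b)  # stochastic dominance direction

  solo <- plasticity_by_input_group(make_plasticity_table(
    30, n_inputs = 0, noise_plasticity = runif(30)))
  expect_identical(nrow(solo$tests), 0L)
  expect_length(solo$groups, 1L)
})

test_that("constitutive and regulated sets separate on all three quantities", {
  set.seed(43)
  const <- make_plasticity_table(
    200, 0, noise_plasticity = rexp(200, 1 / 1e-4),
    mean_noise = rexp(200, 1 / 0.005),
    expression_plasticity = rexp(200, 1 / 0.001))
  reg <- make_plasticity_table(
    200, 2, noise_plasticity = rexp(200, 1 / 5e-4),
    mean_noise = rexp(200, 1 / 0.02),
    expression_plasticity = rexp(200, 1 / 0.02))
  res <- constitutive_vs_regulated_comparison(const, reg)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$p < 0.01))
  expect_true(all(res$mean_constitutive < res$mean_regulated))

  same <- constitutive_vs_regulated_comparison(const, const)
  expect_true(all(same$p > 0.999))
  expect_error(constitutive_vs_regulated_comparison(const[1:3, ], reg),
               ">= 5")
})

test_that("generator-linked noise statistics behave as in a propagation scenario", {
  truth <- simulate_noise_study(P = 600L, R = 15L, C = 4L,
                                n_condition_specific = 2L, n_global = 3L,
                                seed = 44L)
  N <- direct_noise(truth, seed = 44L)
  M <- truth$base_means
  tab <- compute_plasticities(M, N, truth$network)
  targets <- rowSums(truth$network[, attr(truth$activities,
                                          "global_regulators")]) > 0
  w <- wilcox.test(tab$mean_noise[targets], tab$mean_noise[tab$n_inputs == 0],
                   alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})
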