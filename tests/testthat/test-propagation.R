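# Ridge activity inference: closed form vs brute force, centering,
# prior-strength selection, explained variance, permutation null, and
# propagator calling.

test_that("centering produces zero-mean response and design with an inner join", {
  truth <- tiny_truth()
  N <- direct_noise(truth)
  ci <- center_model_inputs(N, truth$network)
  expect_lt(max(abs(colMeans(ci$Y))), 1e-12)
  expect_lt(max(abs(colMeans(ci$X))), 1e-12)
  expect_identical(ci$n_dropped, 0L)

  expect_message(
    ci2 <- center_model_inputs(N, truth$network[1:40, , drop = FALSE]),
    "20 of 60 promoters dropped")
  expect_identical(nrow(ci2$X), 40L)
  expect_identical(ci2$n_dropped, 20L)

  ci3 <- center_model_inputs(N, truth$network[1:40, , drop = FALSE],
                             unannotated = "zero")
  expect_identical(nrow(ci3$X), 60L)

  S_alien <- truth$network
  rownames(S_alien) <- paste0("x", rownames(S_alien))
  expect_error(center_model_inputs(N, S_alien), "no shared")
})

test_that("ridge solution matches a brute-force penalized minimizer", {
  # 3-promoter, 2-TF toy
  S <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 3,
              dimnames = list(paste0("p", 1:3), c("TF1", "TF2")))
  y <- c(0.1, 0.2, 0.3)
  X <- sweep(S, 2, colMeans(S))
  yc <- y - mean(y)
  A1 <- noisenet:::ridge_activities(X, yc, lambda = 1)$A
  expect_equal(unname(A1), brute_force_ridge(X, yc, 1), tolerance = 1e-8)

  # a batch of random instances up to 5 x 5
  set.seed(31)
  for (i in 1:8) {
    P <- sample(3:5, 1)
    R <- sample(2:5, 1)
    X <- matrix(rnorm(P * R), P, R)
    y <- rnorm(P)
    lam <- runif(1, 0.1, 5)
    expect_equal(unname(noisenet:::ridge_activities(X, y, lam)$A),
                 brute_force_ridge(X, y, lam), tolerance = 1e-8)
  }
})

test_that("ridge limiting cases behave as the prior dictates", {
  set.seed(32)
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(unname(noisenet:::ridge_activities(X, rep(0, 10), 1)$A),
               rep(0, 4))
  strong <- noisenet:::ridge_activities(X, rnorm(10), 1e12)$A
  expect_lt(max(abs(strong)), 1e-6)
  expect_error(noisenet:::ridge_activities(X, rnorm(10), 0), "lambda")
  expect_true(all(noisenet:::ridge_activities(X, rnorm(10), 1)$delta > 0))
})

test_that("explained variance is 1 for perfect fits, 0 for null activities", {
  truth <- tiny_truth()
  N <- true_noise(truth) - truth$baseline  # exactly X-spanned signal
  fov0 <- explained_variance(N, truth$network,
                             matrix(0, ncol(truth$network),
                                    ncol(N), dimnames = list(colnames(truth$network), colnames(N))))
  expect_equal(unname(fov0), rep(0, ncol(N)))
  fov1 <- explained_variance(N, truth$network, truth$activities)
  expect_equal(unname(fov1), rep(1, ncol(N)), tolerance = 1e-10)
})

test_that("in-sample FOV is non-increasing in the prior strength", {
  truth <- tiny_truth(P = 120L)
  N <- direct_noise(truth, meas_sd = 2e-3)
  fovs <- vapply(10^seq(-2, 3), function(lam) {
    mean(infer_activities(N, truth$network, lambda = lam)$fov)
  }, numeric(1))
  expect_true(all(diff(fovs) <= 1e-12))
})

test_that("cross-validation picks small penalties for strong signal and nothing spurious for noise", {
  truth <- simulate_noise_study(P = 500L, R = 12L, C = 4L,
                                n_condition_specific = 2L, n_global = 3L,
                                activity_scale = 0.05,
                                baseline_mean = 0.002, seed = 33L)
  N <- direct_noise(truth, seed = 33L)
  sel <- select_prior_strength(N, truth$network, lambda_grid = 10^seq(-2, 4),
                               seed = 1)
  expect_lte(sel$lambda, 1)  # strong signal: little shrinkage wanted

  single <- select_prior_strength(N, truth$network, lambda_grid = 7)
  expect_identical(single$lambda, 7)

  # pure-noise response: no lambda earns positive out-of-fold FOV
  set.seed(34)
  N_null <- matrix(rnorm(length(N), 0, 0.005), nrow = nrow(N),
                   dimnames = dimnames(N))
  sel_null <- select_prior_strength(N_null, truth$network,
                                    lambda_grid = 10^seq(-2, 4), seed = 1)
  expect_true(all(sel_null$oof_fov <= 0.01))
})

test_that("activities are recovered from a direct noise matrix", {
  truth <- simulate_noise_study(P = 500L, R = 20L, C = 6L,
                                n_condition_specific = 3L, n_global = 4L,
                                seed = 35L)
  N <- direct_noise(truth, seed = 35L)
  est <- infer_activities(N, truth$network, lambda = "auto", seed = 1)
  r <- cor(as.vector(truth$activities), as.vector(est$A))
  expect_gt(r, 0.8)
  # in-sample FOV close to the plug-in-truth band
  fov_truth <- explained_variance(N, truth$network, truth$activities)
  expect_lt(max(abs(est$fov - fov_truth)), 0.05)
})

test_that("row-shuffle null is reproducible and well below a real signal", {
  truth <- tiny_truth(P = 150L)
  N <- direct_noise(truth, meas_sd = 2e-3)
  sh1 <- randomized_fov(N, truth$network, lambda = 1, n_shuffles = 20,
                        seed = 9)
  sh2 <- randomized_fov(N, truth$network, lambda = 1, n_shuffles = 20,
                        seed = 9)
  expect_identical(sh1, sh2)
  est <- infer_activities(N, truth$network, lambda = 1)
  expect_true(all(est$fov > sh1$mean + 5 * sh1$sd))
  expect_error(randomized_fov(N, truth$network, 1, n_shuffles = 1), ">= 2")
})

test_that("condition-specific propagator calling follows its definition", {
  A <- matrix(0, 4, 3, dimnames = list(paste0("TF", 1:4), paste0("c", 1:3)))
  delta <- matrix(0.01, 4, 3, dimnames = dimnames(A))
  est <- structure(list(A = A, delta = delta), class = "activity_estimates")
  expect_identical(nrow(condition_specific_propagators(est)$specific), 0L)

  A["TF1", "c2"] <- 0.05           # specific to c2
  A["TF2", c("c1", "c3")] <- 0.05  # significant twice -> excluded
  est$A <- A
  cs <- condition_specific_propagators(est)
  expect_identical(cs$specific$regulator, "TF1")
  expect_identical(cs$specific$condition, "c2")
  expect_true(all(c("TF2") %in% cs$per_condition$c1))
  expect_true(all(c("TF2") %in% cs$per_condition$c3))
  expect_false("TF2" %in% cs$specific$regulator)
})

test_that("condition-averaged activities combine errors and rank by significance", {
  A <- matrix(c(0.02, 0.001), 2, 1,
              dimnames = list(c("TFa", "TFb"), "c1"))
  delta <- matrix(c(0.002, 0.002), 2, 1, dimnames = dimnames(A))
  est <- structure(list(A = A, delta = delta), class = "activity_estimates")
  av <- average_activities(est, top_k = 6)
  expect_equal(av$all$A_bar, as.vector(A))       # single condition: passthrough
  expect_equal(av$all$delta_A_bar, as.vector(delta))
  expect_identical(av$top, "TFa")                # TFb below its error bar

  A2 <- matrix(0.01, 2, 4, dimnames = list(c("TFa", "TFb"), paste0("c", 1:4)))
  delta2 <- matrix(0.002, 2, 4, dimnames = dimnames(A2))
  est2 <- structure(list(A = A2, delta = delta2),
                    class = "activity_estimates")
  av2 <- average_activities(est2)
  expect_equal(av2$all$delta_A_bar,
               rep(sqrt(4 * 0.002^2) / 4, 2))    # sqrt(sum d^2)/C
})
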