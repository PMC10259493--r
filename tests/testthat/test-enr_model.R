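test_that("min-max scaling maps training columns to [0,1] without clipping test data", {
  X <- cbind(a = c(1, 3, 5), b = c(0, 0.5, 1))
  sc <- minmax_scale(X)
  expect_equal(unname(sc$X[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(sc$X[, "b"]), c(0, 0.5, 1))
  te <- apply_minmax(cbind(a = 7, b = 0.5), sc)
  expect_equal(unname(te[1, "a"]), 1.5)       # beyond training max, no clip
  expect_warning(minmax_scale(cbind(c = c(2, 2, 2))), "constant")
})

test_that("the penalized objective reduces to OLS when unregularized", {
  set.seed(2)
  x <- rnorm(50)
  y <- 2 * x
  f <- elastic_net_fit(matrix(x, ncol = 1), y, 0, 0)
  expect_equal(unname(f$weights), 2, tolerance = 1e-8)
  expect_equal(f$intercept, 0, tolerance = 1e-8)
  X <- matrix(rnorm(200), 50, 4)
  yy <- X %*% c(1, -2, 0.5, 0) + rnorm(50, 0, 0.1)
  f2 <- elastic_net_fit(X, as.vector(yy), 0, 0)
  ols <- stats::lm.fit(cbind(1, X), as.vector(yy))$coefficients
  expect_equal(unname(f2$weights), unname(ols[-1]), tolerance = 1e-6)
})

test_that("the single-feature soft-threshold closed form is reproduced", {
  # centered x with (1/n) x'x = 1 and (1/n) x'y = 1
  x <- c(1, -1); y <- c(1, -1)
  f <- elastic_net_fit(matrix(x, ncol = 1), y, lambda1 = 0.3, lambda2 = 0.25)
  expect_equal(unname(f$weights), (1 - 0.3) / (1 + 0.5), tolerance = 1e-9)
  f0 <- elastic_net_fit(matrix(x, ncol = 1), rep(0, 2), 0.3, 0.25)
  expect_equal(unname(f0$weights), 0)
})

test_that("orthonormal designs match the soft-threshold solution to 1e-4", {
  set.seed(9)
  for (i in 1:5) {
    n <- 40; p <- 5
    M <- matrix(rnorm(n * p), n, p)
    M <- sweep(M, 2, colMeans(M))        # center, then orthonormalize:
    X <- qr.Q(qr(M)) * sqrt(n)           # columns stay centered, (1/n) X'X = I
    y <- rnorm(n)
    l1 <- runif(1, 0, 0.2); l2 <- runif(1, 0, 0.2)
    f <- elastic_net_fit(X, y, l1, l2)
    rho <- as.vector(crossprod(X, y - mean(y))) / n
    closed <- sign(rho) * pmax(abs(rho) - l1, 0) / (1 + 2 * l2)
    expect_equal(unname(f$weights), closed, tolerance = 1e-4)
  }
})

test_that("the solver agrees with glmnet under the lambda mapping", {
  skip_if_not_installed("glmnet")
  set.seed(33)
  n <- 200; p <- 8
  X <- matrix(runif(n * p), n, p)
  y <- as.vector(X %*% rnorm(p) + rnorm(n, 0, 0.3))
  # glmnet internally standardizes y by its 1/n-denominator SD; supply a
  # pre-standardized response so both solvers face the identical objective
  # (1/2n)RSS + lambda*(l1_ratio*|w| + (1-l1_ratio)/2 * w^2)
  y <- y / (stats::sd(y) * sqrt((n - 1) / n))
  alpha <- 0.05; l1_ratio <- 0.5
  f <- elastic_net_fit(X, y, alpha * l1_ratio, 0.5 * alpha * (1 - l1_ratio))
  g <- glmnet::glmnet(X, y, alpha = l1_ratio, lambda = alpha,
                      standardize = FALSE, thresh = 1e-14)
  gw <- as.vector(stats::coef(g))[-1]
  expect_equal(unname(f$weights), gw, tolerance = 1e-4)
})

test_that("solver objective never exceeds the objective at zero", {
  set.seed(8)
  for (i in 1:10) {
    X <- matrix(rnorm(60), 20, 3)
    y <- rnorm(20)
    l1 <- runif(1, 0, 0.5); l2 <- runif(1, 0, 0.5)
    f <- elastic_net_fit(X, y, l1, l2)
    obj0 <- sum((y - mean(y))^2) / (2 * length(y))
    expect_lte(f$objective, obj0 + 1e-12)
  }
})

test_that("trials are reproducible and pure-noise responses score near zero", {
  sim <- simulate_feature_matrix(300, c(kozak_score = -1), snr = 5, seed = 5)
  cfg <- enr_config(n_trials = 1, seed = 10)
  t1 <- run_trials(sim$X, sim$y, cfg)
  t2 <- run_trials(sim$X, sim$y, cfg)
  expect_identical(t1$trials, t2$trials)
  set.seed(77)
  ynoise <- rnorm(300)
  tn <- run_trials(sim$X, ynoise, enr_config(n_trials = 100, seed = 3))
  expect_lt(abs(mean(tn$trials$r2_test)), 0.1)
})

test_that("planted signals are selected and beat the Kozak-only baseline", {
  sim <- simulate_feature_matrix(
    400, c(kozak_score = -1.5, dist_cap_start = 0.01), snr = 10, seed = 6)
  tr <- run_trials(sim$X, sim$y, enr_config(n_trials = 40, seed = 2))
  expect_gte(mean(tr$selected[, "kozak_score"]), 0.95)
  expect_gte(mean(tr$selected[, "dist_cap_start"]), 0.95)
  expect_true(all(tr$weights[, "kozak_score"] < 0))
  bl <- kozak_only_baseline(tr)
  expect_gte(bl$n_full_better, 38)
  expect_lt(bl$wrt_p, 0.05)
  # a response driven by Kozak alone leaves no baseline gap
  simk <- simulate_feature_matrix(400, c(kozak_score = -1.5), snr = 50, seed = 7)
  trk <- run_trials(simk$X, simk$y, enr_config(n_trials = 20, seed = 2))
  blk <- kozak_only_baseline(trk)
  expect_lt(abs(blk$r2_full_mean - blk$r2_kozak_mean), 0.05)
})

test_that("feature significance summarizes weights across trials", {
  sim <- simulate_feature_matrix(300, c(kozak_score = -1.5), snr = 20, seed = 8)
  tr <- run_trials(sim$X, sim$y, enr_config(n_trials = 30, seed = 4))
  fs <- feature_significance(tr)
  expect_equal(fs$feature, uorf_feature_names())
  k <- fs[fs$feature == "kozak_score", ]
  expect_lt(k$p, 0.001)
  expect_equal(k$selection_freq, 1)
  # a never-selected feature gets p = 1
  tr0 <- tr; tr0$weights[, "is_oorf"] <- 0
  fs0 <- feature_significance(tr0)
  expect_equal(fs0$p[fs0$feature == "is_oorf"], 1)
  expect_true(all(fs0$fdr >= fs0$p - 1e-12))
})
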