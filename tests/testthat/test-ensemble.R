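test_that("init_ensemble with zero spread collapses onto theta0", {
  th <- stable_theta()
  ens <- init_ensemble(th, diag(0, 5), M = 50)
  expect_equal(nrow(ens$particles), 50)
  expect_true(all(apply(ens$particles, 1, function(p) all(p == theta_flat(th)))))
  expect_equal(sum(ens$weights), 1)
  expect_equal(ens$weights, rep(1 / 50, 50))
})

test_that("init_ensemble samples centred on theta0 (law of large numbers)", {
  th <- stable_theta()
  M <- 10000
  ens <- init_ensemble(th, diag(1, 5), M = M, seed = 101)
  dev <- abs(colMeans(ens$particles) - theta_flat(th))
  expect_true(all(dev < 3 / sqrt(M)))
})

test_that("init_ensemble rejects a non-PSD spread", {
  A <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(init_ensemble(theta(1, 0), A, 10), "positive semi-definite")
  expect_error(init_ensemble(theta(1, 0), matrix(c(1, 0.5, 0.2, 1), 2), 10),
               "symmetric")
})

test_that("predict_step with zero process noise is the identity", {
  ens <- init_ensemble(stable_theta(), diag(1, 5), 30, seed = 5)
  out <- predict_step(ens, diag(0, 5))
  expect_identical(out$particles, ens$particles)
  expect_identical(out$weights, ens$weights)
})

test_that("predict_step jitter matches the prescribed covariance", {
  M <- 20000
  ens <- make_ensemble(matrix(2, M, 1))
  set.seed(7)
  out <- predict_step(ens, matrix(0.25, 1, 1))
  expect_equal(var(out$particles[, 1]), 0.25, tolerance = 0.05)
  expect_equal(mean(out$particles[, 1]), 2, tolerance = 3 * 0.5 / sqrt(M))
  expect_identical(out$weights, ens$weights)
})

test_that("jitter covariance is additive across steps", {
  M <- 40000
  ens <- make_ensemble(matrix(0, M, 1))
  set.seed(8)
  twice <- predict_step(predict_step(ens, matrix(0.1, 1, 1)), matrix(0.1, 1, 1))
  once <- predict_step(ens, matrix(0.2, 1, 1))
  expect_equal(var(twice$particles[, 1]), var(once$particles[, 1]),
               tolerance = 0.02)
})

test_that("likelihood follows the Gaussian squared-error form", {
  expect_equal(likelihood(1, 1, 0.1), 1)
  expect_equal(likelihood(1, 0.5, 0.1), 0.28650479686, tolerance = 1e-10)
  expect_equal(likelihood(0, 0.5, 0.1), likelihood(1, 0.5, 0.1))
  expect_true(all(likelihood(1, seq(0, 1, 0.1), 0.2) <= 1))
  expect_error(likelihood(1, 0.5, 0), "positive")
  expect_error(likelihood(1, 0.5, -1), "positive")
})

test_that("weight_step leaves identical particles uniform", {
  ens <- make_ensemble(matrix(rep(c(1, -0.5), 10), 10, 2, byrow = TRUE))
  out <- weight_step(ens, 1, 1, R = 0.1)
  expect_equal(out$weights, rep(0.1, 10))
})

test_that("weight_step matches the brute-force Bayes update on three atoms", {
  # intercept-only particles engineered to predict 0.2, 0.5, 0.9
  ens <- make_ensemble(matrix(qlogis(c(0.2, 0.5, 0.9)), ncol = 1))
  out <- weight_step(ens, numeric(0), y = 1, R = 0.1)
  expect_equal(out$weights,
               c(0.0318829236989, 0.2240951098351, 0.7440219664660),
               tolerance = 1e-10)
  # two-atom normalization identity
  ens2 <- make_ensemble(matrix(qlogis(c(0.3, 0.8)), ncol = 1))
  out2 <- weight_step(ens2, numeric(0), y = 1, R = 0.05)
  L <- likelihood(1, c(0.3, 0.8), 0.05)
  expect_equal(out2$weights, L / sum(L))
})

test_that("weights renormalize to one after every update", {
  set.seed(21)
  ens <- init_ensemble(stable_theta(), diag(1, 5), 200, seed = 21)
  for (i in 1:25) {
    x <- rbinom(4, 1, 0.4)
    ens <- weight_step(ens, x, rbinom(1, 1, 0.2), R = 0.1)
    expect_lt(abs(sum(ens$weights) - 1), 1e-12)
    ens <- resample_step(ens)
    expect_equal(nrow(ens$particles), 200)
  }
})

test_that("resample_step with a degenerate weight copies that particle", {
  ens <- make_ensemble(matrix(1:6, 3, 2), weights = c(0, 1, 0))
  set.seed(3)
  out <- resample_step(ens)
  expect_true(all(out$particles[, 1] == 2 & out$particles[, 2] == 5))
  expect_equal(out$weights, rep(1 / 3, 3))
})

test_that("multinomial resampling copy counts pass a goodness-of-fit check", {
  M <- 400
  ens <- make_ensemble(matrix(seq_len(M), ncol = 1))
  for (s in 1:5) {
    set.seed(30 + s)
    out <- resample_step(ens)
    counts <- tabulate(match(out$particles[, 1], ens$particles[, 1]), M)
    expect_equal(mean(counts), 1)
    expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
  }
})

test_that("resampling is unbiased for the weighted mean", {
  set.seed(44)
  w <- runif(50); w <- w / sum(w)
  ens <- make_ensemble(matrix(rnorm(50), ncol = 1), weights = w)
  target <- sum(w * ens$particles[, 1])
  draws <- replicate(1000, theta_flat(posterior_mean(resample_step(ens)))[1])
  se <- sd(draws) / sqrt(1000)
  expect_lt(abs(mean(draws) - target), 3 * se)
})

test_that("systematic resampling preserves counts and weights too", {
  set.seed(45)
  w <- runif(30); w <- w / sum(w)
  ens <- make_ensemble(matrix(rnorm(30), ncol = 1), weights = w)
  out <- resample_step(ens, method = "systematic")
  expect_equal(nrow(out$particles), 30)
  expect_equal(out$weights, rep(1 / 30, 30))
  expect_true(all(out$particles[, 1] %in% ens$particles[, 1]))
})

test_that("posterior_mean equals the explicit weighted sum", {
  # symmetric cloud about a centre
  ens <- make_ensemble(matrix(c(1, 3, 2, 0, 4, 2), 3, 2))
  expect_equal(theta_flat(posterior_mean(ens)), c(2, 2))
  # two-atom arithmetic
  ens2 <- make_ensemble(matrix(c(0, 4), ncol = 1), weights = c(0.25, 0.75))
  expect_equal(theta_flat(posterior_mean(ens2)), 3)
  # loop oracle on random ensembles
  set.seed(50)
  for (i in 1:10) {
    P <- matrix(rnorm(60), 20, 3)
    w <- runif(20); w <- w / sum(w)
    manual <- rep(0, 3)
    for (m in 1:20) manual <- manual + w[m] * P[m, ]
    expect_equal(theta_flat(posterior_mean(make_ensemble(P, w))), manual)
  }
})

test_that("effective sample size spans [1, M]", {
  M <- 40
  uni <- make_ensemble(matrix(rnorm(M), ncol = 1))
  expect_equal(ess(uni), M)
  degen <- make_ensemble(matrix(rnorm(M), ncol = 1),
                         weights = c(1, rep(0, M - 1)))
  expect_equal(ess(degen), 1)
})
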