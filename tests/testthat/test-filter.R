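test_that("degenerate filter (Q = 0, A = 0) stays pinned at theta0", {
  th <- stable_theta()
  stream <- make_stream(th, 50, seed = 60)
  tr <- run_filter(stream, th, noise_spec(0, 0.1, 0),
                   filter_config(100, 50, 10, seed = 61))
  dev <- max(abs(sweep(tr$means, 2, theta_flat(th))))
  expect_lt(dev, 1e-12)
  expect_equal(as.numeric(stability_metric(tr, 50)), 0, tolerance = 1e-12)
})

test_that("final estimate is the mean of the trailing window of means", {
  th <- stable_theta()
  stream <- make_stream(th, 80, seed = 62)
  tr <- run_filter(stream, th, noise_spec(diag(0.01, 5), 0.1, diag(0.2, 5)),
                   filter_config(60, 80, 25, seed = 63))
  expect_identical(theta_flat(tr$final_estimate),
                   colMeans(tr$means[56:80, , drop = FALSE]))
})

test_that("a run is bit-reproducible from its seed", {
  th <- stable_theta()
  stream <- make_stream(th, 40, seed = 64)
  cfg <- filter_config(80, 40, 10, seed = 65)
  ns <- noise_spec(diag(0.02, 5), 0.1, diag(0.5, 5))
  t1 <- run_filter(stream, th, ns, cfg)
  t2 <- run_filter(stream, th, ns, cfg)
  expect_identical(t1$means, t2$means)
  expect_identical(theta_flat(t1$final_estimate), theta_flat(t2$final_estimate))
})

test_that("filter rejects short, empty or NA-bearing streams", {
  th <- stable_theta()
  stream <- make_stream(th, 10, seed = 66)
  expect_error(run_filter(list(X = stream$X, y = integer(0)), th,
                          noise_spec(0, 0.1, 0), filter_config(10, 5, 1)),
               "empty")
  expect_error(run_filter(stream, th, noise_spec(0, 0.1, 0),
                          filter_config(10, 99, 1)), "n_cycles")
  bad <- stream; bad$X[3, 2] <- NA
  expect_error(run_filter(bad, th, noise_spec(0, 0.1, 0),
                          filter_config(10, 10, 1)), "NaN/NA")
})

test_that("huge observation noise reduces the filter to an unweighted walk", {
  th <- stable_theta()
  stream <- make_stream(th, 20, seed = 67)
  set.seed(68)
  ens <- init_ensemble(th, diag(0.5, 5), 100)
  for (k in 1:20) {
    ens <- predict_step(ens, diag(0.01, 5))
    ens <- weight_step(ens, stream$X[k, ], stream$y[k], R = 1e6)
    expect_lt(max(abs(ens$weights - 1 / 100)), 1e-6)
    ens <- resample_step(ens)
  }
})

test_that("particle filter tracks the dense-grid Bayes filter", {
  # per-step discrepancy scaled by sd/sqrt(M): one resampling pass injects
  # about one SE of noise, so a correct filter drifts within a sqrt(k)
  # envelope of the exact posterior mean and stays well inside the
  # posterior sd itself
  res <- oracle_comparison(n_steps = 60, n_particles = 1000, n_seeds = 5,
                           seed = 70)
  expect_lt(res$max_envelope, 6)
  expect_lt(res$max_ratio / sqrt(1000), 1)  # i.e. always below one posterior sd
})

test_that("filter concentrates near the truth on an informative 1-d problem", {
  # strong repeated signal: posterior should move from 0 toward theta_true
  set.seed(71)
  y <- rbinom(200, 1, plogis(2))
  tr <- run_filter(list(X = matrix(nrow = 200, ncol = 0), y = y),
                   theta(numeric(0), 0),
                   noise_spec(matrix(0.005, 1, 1), 0.1, matrix(0.25, 1, 1)),
                   filter_config(500, 200, 50, seed = 72))
  expect_gt(theta_flat(tr$final_estimate), 0.5)
})

test_that("stability metric is the worst trailing parameter range", {
  th <- stable_theta()
  stream <- make_stream(th, 30, seed = 73)
  tr <- run_filter(stream, th, noise_spec(0, 0.1, 0),
                   filter_config(20, 30, 5, seed = 74))
  # graft a synthetic oscillation onto the trace
  tr$means[, 2] <- rep(c(1.0, 1.4), 15)
  expect_equal(as.numeric(stability_metric(tr, 30)), 0.4)
  expect_true(attr(stability_metric(tr, 30), "stable"))
  tr$means[, 3] <- seq(0, 2.9, length.out = 30)
  expect_false(attr(stability_metric(tr, 10), "stable"))
  expect_error(stability_metric(tr, 31), "longer than the trace")
})

test_that("build_q normalizes absolute parameter shares on the diagonal", {
  th <- stable_theta()
  Q <- build_q(th, diag(1, 4), scale = 0.1)
  expect_equal(diag(Q), c(2.79, 2.39, 2.4, 1.3, 0.9) / 9.78 * 0.1)
  expect_equal(diag(Q)[1], 0.028527607362, tolerance = 1e-10)
  # identity feature correlation leaves Q diagonal
  expect_true(all(Q[upper.tri(Q)] == 0))
})

test_that("build_q off-diagonals are normalized absolute correlations", {
  th <- theta(c(1, 1, 2), 0.5)
  fc <- diag(1, 3)
  fc[1, 2] <- fc[2, 1] <- 0.6
  fc[1, 3] <- fc[3, 1] <- -0.3
  fc[2, 3] <- fc[3, 2] <- 0.1
  raw_off <- c(0.6, 0.3, 0.1) / 1.0  # |r| / sum of pairwise |r|
  Q <- build_q(th, fc, scale = 1)
  # compare against the pre-repair construction on its PSD-projected form
  base <- diag(c(1, 1, 2, 0.5) / 4.5)
  base[1, 2] <- base[2, 1] <- raw_off[1]
  base[1, 3] <- base[3, 1] <- raw_off[2]
  base[2, 3] <- base[3, 2] <- raw_off[3]
  ev <- eigen(base, symmetric = TRUE)
  expected <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  expect_equal(Q, (expected + t(expected)) / 2, tolerance = 1e-10)
  # intercept row/column has zero off-diagonals
  expect_equal(Q[4, 1:3], c(0, 0, 0))
})

test_that("build_q output is symmetric PSD over random inputs", {
  set.seed(80)
  for (i in 1:25) {
    d <- sample(2:6, 1)
    th <- theta(rnorm(d), rnorm(1))
    Z <- matrix(rnorm(40 * d), 40, d)
    Q <- suppressMessages(build_q(th, cor(Z), scale = 0.1))
    expect_equal(Q, t(Q))
    expect_gte(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  expect_error(build_q(theta(c(0, 0), 0), diag(1, 2)), "nonzero")
})

test_that("protocol grid is deterministic and one row per protocol", {
  th <- stable_theta()
  stream <- make_stream(th, 60, seed = 81)
  test <- make_stream(th, 40, seed = 82)
  protos <- list(
    base = list(Q = diag(0.01, 5), R = 0.1, A = diag(1, 5)),
    base_again = list(Q = diag(0.01, 5), R = 0.1, A = diag(1, 5)),
    tight = list(Q = diag(0.001, 5), R = 0.05, A = diag(0.1, 5))
  )
  tab <- run_protocol_grid(stream, th, protos, test, n_particles = 50,
                           seed = 83, stability_window = 30)
  expect_equal(nrow(tab), 3)
  expect_true(all(is.finite(tab$accuracy)) && all(is.finite(tab$stability)))
  expect_equal(tab$accuracy[1], tab$accuracy[2])
  expect_equal(tab$stability[1], tab$stability[2])
})
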