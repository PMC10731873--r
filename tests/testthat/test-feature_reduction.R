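make_toy_cohort <- function(n = 300, seed = 1) {
  set.seed(seed)
  cohort(data.frame(
    a = rbinom(n, 1, 0.4),
    b = rnorm(n),
    g = factor(sample(c("x", "y", "z"), n, TRUE, prob = c(0.5, 0.3, 0.2)))
  ), rbinom(n, 1, 0.3))
}

test_that("variance filter drops exactly the planted near-constant columns", {
  set.seed(90)
  n <- 500
  df <- data.frame(matrix(rnorm(n * 6), n, 6))
  for (j in 1:5) df[[paste0("flat", j)]] <- rbinom(n, 1, 0.004)
  co <- cohort(df, rbinom(n, 1, 0.3))
  out <- variance_filter(co, min_variance = 0.01)
  expect_setequal(out$report$dropped, paste0("flat", 1:5))
  expect_equal(ncol(out$cohort$features), 6)
  # min_variance = 0 drops nothing
  expect_equal(variance_filter(co, 0)$report$dropped, character(0))
  # a truly constant column always goes for any positive threshold
  co2 <- cohort(data.frame(k = rep(1, 50), z = rnorm(50)), rbinom(50, 1, 0.5))
  expect_equal(variance_filter(co2, 1e-9)$report$dropped, "k")
  expect_error(variance_filter(co2, 10), "every column")
})

test_that("correlation filter keeps the earlier member of a correlated pair", {
  set.seed(91)
  n <- 400
  a <- rnorm(n)
  co <- cohort(data.frame(a = a, b = rnorm(n), a_dup = a), rbinom(n, 1, 0.4))
  out <- correlation_filter(co, 0.6)
  expect_equal(out$report$dropped, "a_dup")
  expect_equal(out$report$correlated_with, "a")
  expect_true("a" %in% names(out$cohort$features))
})

test_that("independent columns survive; a planted block keeps one survivor", {
  set.seed(92)
  n <- 10000
  ind <- cohort(data.frame(u = rnorm(n), v = rnorm(n)), rbinom(n, 1, 0.5))
  expect_equal(correlation_filter(ind, 0.6)$report$dropped, character(0))
  S <- matrix(0.9, 3, 3); diag(S) <- 1
  Z <- MASS::mvrnorm(1288, rep(0, 3), S)
  blk <- cohort(data.frame(p = Z[, 1], q = Z[, 2], r = Z[, 3], w = rnorm(1288)),
                rbinom(1288, 1, 0.3))
  out <- correlation_filter(blk, 0.6)
  expect_setequal(out$report$dropped, c("q", "r"))
})

test_that("lasso selection recovers planted informative features", {
  set.seed(93)
  n <- 1000
  X <- matrix(rnorm(n * 45), n, 45,
              dimnames = list(NULL, sprintf("c%02d", 1:45)))
  beta <- c(rep(1.2, 5), rep(0, 40))
  y <- rbinom(n, 1, plogis(X %*% beta))
  co <- cohort(as.data.frame(X), y)
  for (s in 1:3) {
    sel <- lasso_select(co, n_folds = 10, seed = s)
    expect_true(all(sprintf("c%02d", 1:5) %in% sel$selected))
  }
})

test_that("lasso penalty limits behave as expected", {
  set.seed(94)
  n <- 200
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, letters[1:8]))
  y <- rbinom(n, 1, plogis(X[, 1]))
  co <- cohort(as.data.frame(X), y)
  expect_length(lasso_select(co, lambda = 50)$selected, 0)
  expect_length(lasso_select(co, lambda = 1e-8)$selected, 8)
  expect_error(lasso_select(cohort(as.data.frame(X), rep(0, n))),
               "single class")
})

test_that("forest screen ranks a lone informative feature first", {
  for (s in 1:2) {
    set.seed(95 + s)
    n <- 600
    X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    names(X) <- sprintf("n%02d", 1:10)
    X$signal <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, plogis(2.5 * X$signal - 1.5))
    out <- rf_screen(cohort(X, y), threshold = 0.05, seed = s)
    expect_equal(names(out$importance)[1], "signal")
    expect_equal(sum(out$importance), 1, tolerance = 1e-9)
  }
})

test_that("forest screen threshold zero keeps every column", {
  set.seed(96)
  n <- 300
  df <- data.frame(s = rbinom(n, 1, 0.5), u = rnorm(n), v = rnorm(n))
  co <- cohort(df, rbinom(n, 1, plogis(2 * df$s - 1)))
  out <- rf_screen(co, threshold = 0, seed = 1, ntree = 200)
  expect_setequal(out$selected, names(co$features))
})

test_that("dummy encoding applies the c-1 rule with a frequency reference", {
  co <- make_toy_cohort(seed = 97)
  enc <- encode_dummies(co)
  expect_true(all(c("a", "b") %in% colnames(enc$design)))
  expect_identical(enc$design[, "a"], as.numeric(co$features$a))
  # 3 levels -> 2 indicators, most frequent level is the absent reference
  gcols <- grep("^g\\.", colnames(enc$design), value = TRUE)
  expect_length(gcols, 2)
  expect_equal(enc$map$g$reference, "x")
  expect_false("g.x" %in% colnames(enc$design))
  # round trip is lossless
  dec <- decode_dummies(enc$design, enc$map)
  expect_equal(as.character(dec$g), as.character(co$features$g))
  expect_equal(dec$a, as.numeric(co$features$a))
  expect_equal(dec$b, co$features$b)
})

test_that("applying an encoding to data with unseen levels fails loudly", {
  co <- make_toy_cohort(seed = 98)
  enc <- encode_dummies(co)
  nd <- co$features[1:5, ]
  nd$g <- as.character(nd$g); nd$g[2] <- "mystery"
  expect_error(apply_encoding(enc$map, nd), "unseen level.*mystery")
  # and matches the training design on the training rows
  expect_equal(apply_encoding(enc$map, co$features), enc$design)
})

test_that("initial model fit recovers known parameters within 3 SE", {
  set.seed(99)
  n <- 4000
  X <- matrix(rbinom(n * 3, 1, 0.4), n, 3,
              dimnames = list(NULL, c("u", "v", "w")))
  th_true <- c(1.5, -2, 1, -0.8)  # u, v, w, intercept
  y <- rbinom(n, 1, plogis(X %*% th_true[1:3] + th_true[4]))
  fit <- fit_initial_model(X, y, seed = 1)
  expect_setequal(fit$kept, c("u", "v", "w"))
  se <- summary(fit$fit)$coefficients[, "Std. Error"]
  est <- theta_flat(fit$theta)
  expect_true(all(abs(est - c(th_true[1:3], th_true[4])) <
                    3 * se[c("u", "v", "w", "(Intercept)")]))
  expect_gt(fit$cv_accuracy, 0.5)
})

test_that("refitting after dropping nothing reproduces the original fit", {
  set.seed(100)
  n <- 2000
  X <- matrix(rbinom(n * 2, 1, 0.5), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- rbinom(n, 1, plogis(2 * X[, 1] - 2 * X[, 2]))
  fit <- fit_initial_model(X, y, seed = 2)
  expect_setequal(fit$kept, c("u", "v"))
  direct <- glm(y ~ X, family = binomial())
  expect_equal(unname(theta_flat(fit$theta)),
               unname(coef(direct)[c(2, 3, 1)]), tolerance = 1e-8)
})

test_that("noise columns are kept at roughly the Wald type-I rate", {
  set.seed(101)
  n <- 1000
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, sprintf("z%02d", 1:12)))
  y <- rbinom(n, 1, 0.3)
  fit <- fit_initial_model(X, y, alpha = 0.05, seed = 3)
  expect_lte(length(fit$kept), 3)  # expected 0.6 of 12 at the 5% level
})

test_that("the full reduction chain yields nested shrinking column sets", {
  sim <- generate_cohort(generator_spec(n_patients = 600, n_features = 30,
                                        seed = 102))
  s1 <- variance_filter(sim$cohort, 0.01)
  s2 <- correlation_filter(s1$cohort, 0.6)
  expect_true(all(names(s2$cohort$features) %in% names(s1$cohort$features)))
  expect_true(all(names(s1$cohort$features) %in% names(sim$cohort$features)))
  red <- reduce_features(sim$cohort, seed = 103)
  expect_true(all(red$selected %in% names(sim$cohort$features)))
  expect_lt(length(red$selected), ncol(sim$cohort$features))
})
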