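#' Validation experiments for the direct filter
#'
#' Pre-packaged, seed-reproducible experiments that probe the filter's core
#' claims on synthetic data with known ground truth.  Tests and the
#' acceptance script run these rather than re-wiring the pipeline by hand,
#' so the study conditions are defined in exactly one place.
#'
#' @name experiments
NULL

#' Particle filter vs dense-grid Bayes filter
#'
#' Runs the particle filter and [grid_bayes_filter()] side by side on a
#' one-parameter (intercept-only) logistic model with the same jitter
#' kernel and Gaussian squared-error likelihood, over several independently
#' seeded replicates, and reports the per-step discrepancy of the posterior
#' means scaled by the naive particle standard error `sd_k / sqrt(M)`.
#'
#' Note on scales: one multinomial resampling pass adds Monte Carlo noise of
#' about one standard error to the ensemble mean, and with a weakly
#' informative per-observation likelihood these perturbations accumulate
#' like a random walk, so the discrepancy after `k` steps is expected to
#' grow like `sqrt(k)` standard errors even for a correct filter.  The
#' returned `ratio` matrix lets callers assess either the per-step ratio or
#' the accumulation-corrected `ratio / sqrt(k)` envelope.
#'
#' @param n_steps Observations per replicate (default 100).
#' @param n_particles Ensemble size `M` (default 1000).
#' @param n_seeds Number of replicates (default 20).
#' @param theta_true True intercept generating the Bernoulli outcomes.
#' @param A,Q,R Initial-spread variance, jitter variance, observation-noise
#'   variance (scalars; the model is one-dimensional).
#' @param grid_size Grid resolution of the reference filter.
#' @param seed Master seed; replicate seeds are derived from it.
#' @return List with `ratio` (`n_seeds x n_steps` matrix of
#'   `|pf - grid| / (sd/sqrt(M))`), `max_ratio`, and
#'   `max_envelope` (max over steps/seeds of `ratio / sqrt(k)`).
#' @export
oracle_comparison <- function(n_steps = 100, n_particles = 1000, n_seeds = 20,
                              theta_true = 0.5, A = 0.25, Q = 0.01, R = 0.1,
                              grid_size = 10000, seed = 1) {
  ratio <- matrix(NA_real_, n_seeds, n_steps)
  for (s in seq_len(n_seeds)) {
    set.seed(derive_seed(seed, s))
    y <- stats::rbinom(n_steps, 1, stats::plogis(theta_true))
    g <- grid_bayes_filter(y, x = 1, theta0 = 0, A = A, Q = Q, R = R,
                           grid_size = grid_size)
    cfg <- filter_config(n_particles = n_particles, n_cycles = n_steps,
                         estimate_window = 1,
                         seed = derive_seed(seed, 1000 + s))
    tr <- run_filter(list(X = matrix(nrow = n_steps, ncol = 0), y = y),
                     theta(numeric(0), 0),
                     noise_spec(matrix(Q, 1, 1), R, matrix(A, 1, 1)), cfg)
    ratio[s, ] <- abs(tr$means[, 1] - g$means) /
      (tr$sds[, 1] / sqrt(n_particles))
  }
  env <- sweep(ratio, 2, sqrt(seq_len(n_steps)), "/")
  list(ratio = ratio, max_ratio = max(ratio), max_envelope = max(env))
}

#' Parameter recovery on a static synthetic stream
#'
#' For each replicate: generate a default synthetic cohort, split it
#' (250 initialisation + 608 filtering + test), fit the initial parameters
#' by plain logistic regression on the 250 initialisation rows, build the
#' process noise with [build_q()] from those rows, assimilate the filtering
#' stream, and compare both parameter RMSE against the generating truth and
#' held-out classification accuracy for the initial vs the filtered model.
#'
#' @param n_seeds Number of replicates (default 10).
#' @param n_particles,R,A,scale Filter settings (defaults 100, 0.1, 1, 0.1).
#' @param estimate_window Trailing means averaged into the final estimate.
#' @param seed Master seed.
#' @return A `data.frame` with one row per replicate: `rmse_theta0`,
#'   `rmse_filtered`, `stability`, `acc_theta0`, `acc_filtered`,
#'   `auc_theta0`, `auc_filtered`.
#' @export
recovery_experiment <- function(n_seeds = 10, n_particles = 100, R = 0.1,
                                A = 1, scale = 0.1, estimate_window = 100,
                                seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    parts <- recovery_setup(seed, s)
    Q <- suppressMessages(build_q(parts$theta0, safe_cor(parts$init$X), scale))
    cfg <- filter_config(n_particles = n_particles,
                         n_cycles = length(parts$filtering$y),
                         estimate_window = estimate_window,
                         seed = derive_seed(seed, 3000 + s))
    tr <- run_filter(parts$filtering, parts$theta0, noise_spec(Q, R, A), cfg)
    cmp <- compare_models(parts$theta0, tr$final_estimate, parts$test)
    rmse <- function(th) sqrt(mean((theta_flat(th) - parts$truth)^2))
    data.frame(rmse_theta0 = rmse(parts$theta0),
               rmse_filtered = rmse(tr$final_estimate),
               stability = as.numeric(stability_metric(tr, 100)),
               acc_theta0 = cmp$batch$accuracy,
               acc_filtered = cmp$filtered$accuracy,
               auc_theta0 = cmp$batch$auc,
               auc_filtered = cmp$filtered$auc)
  })
  do.call(rbind, rows)
}

# shared set-up: default cohort, split, batch theta0 from the init segment
recovery_setup <- function(seed, s) {
  sim <- generate_cohort(generator_spec(seed = derive_seed(seed, 100 + s)))
  sp <- split_stream(sim$cohort, seed = derive_seed(seed, 2000 + s))
  inf <- sim$truth$informative
  init <- as_stream(sp$init, inf)
  df <- as.data.frame(init$X)
  df$.y <- init$y
  cf <- stats::coef(suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial())))
  list(theta0 = theta(unname(cf[-1]), unname(cf[1])),
       truth = c(sim$truth$theta_star, sim$truth$intercept),
       truth_theta = theta(sim$truth$theta_star, sim$truth$intercept),
       init = init,
       filtering = as_stream(sp$filtering, inf),
       test = as_stream(sp$test, inf))
}

#' Drift adaptation: assimilated vs frozen model after a coefficient flip
#'
#' Injects an abrupt concept drift — the sign of the first risk coefficient
#' flips midway through the filtering stream — re-draws post-drift outcomes
#' (stream and test set) from the flipped parameters, and compares the
#' frozen initial model with the assimilated model on the post-drift test
#' set.  This is the scenario the online filter exists for: a deployed model
#' decaying as the data-generating process changes.
#'
#' @param n_seeds Number of replicates (default 10).
#' @param flip_at Stream position at which the drift begins (default 305,
#'   midway through the 608-observation filtering stream).
#' @param n_particles,R,A,scale,estimate_window Filter settings as in
#'   [recovery_experiment()].
#' @param seed Master seed.
#' @return A `data.frame` with one row per replicate: `acc_frozen`,
#'   `acc_filtered`.
#' @export
drift_experiment <- function(n_seeds = 10, flip_at = 305, n_particles = 100,
                             R = 0.1, A = 1, scale = 0.1,
                             estimate_window = 100, seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    parts <- recovery_setup(seed, s)
    flipped <- parts$truth_theta
    flipped$coefficients[1] <- -flipped$coefficients[1]
    stream <- inject_drift(parts$filtering,
                           list(list(at = flip_at, theta = flipped)),
                           seed = derive_seed(seed, 4000 + s))
    set.seed(derive_seed(seed, 5000 + s))
    test <- list(X = parts$test$X,
                 y = stats::rbinom(nrow(parts$test$X), 1,
                                   predict_proba(flipped, parts$test$X)))
    Q <- suppressMessages(build_q(parts$theta0, safe_cor(parts$init$X), scale))
    cfg <- filter_config(n_particles = n_particles,
                         n_cycles = length(stream$y),
                         estimate_window = estimate_window,
                         seed = derive_seed(seed, 3000 + s))
    tr <- run_filter(stream, parts$theta0, noise_spec(Q, R, A), cfg)
    cmp <- compare_models(parts$theta0, tr$final_estimate, test)
    data.frame(acc_frozen = cmp$batch$accuracy,
               acc_filtered = cmp$filtered$accuracy)
  })
  do.call(rbind, rows)
}

#' Planted-feature recovery of the reduction chain
#'
#' Generates cohorts with five planted informative binary risk factors among
#' noise, correlated and near-constant columns, runs the full
#' [reduce_features()] chain, and records whether all five survive it.
#'
#' @param n_seeds Number of replicates (default 20).
#' @param theta_star Coefficients of the five planted features.
#' @param seed Master seed.
#' @return Logical vector (length `n_seeds`): all five retained?
#' @export
reduction_recovery_experiment <- function(n_seeds = 20,
                                          theta_star = c(2.79, -2.39, 2.4,
                                                         1.3, -1.8),
                                          seed = 1) {
  vapply(seq_len(n_seeds), function(s) {
    ss <- derive_seed(seed, 6000 + s)
    sim <- generate_cohort(generator_spec(theta_star = theta_star, seed = ss))
    red <- reduce_features(sim$cohort, seed = ss)
    all(sim$truth$informative %in% red$selected)
  }, logical(1))
}
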