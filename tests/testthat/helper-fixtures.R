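# shared fixtures: the stabilized four-feature risk model and small builders

stable_theta <- function() theta(c(2.79, -2.39, 2.4, 1.3), -0.9)

# ensemble with explicit particles/weights, bypassing the random initialiser
make_ensemble <- function(particles, weights = NULL) {
  if (!is.matrix(particles)) particles <- matrix(particles, ncol = 1)
  M <- nrow(particles)
  if (is.null(weights)) weights <- rep(1 / M, M)
  ens <- init_ensemble(as_theta(rep(0, ncol(particles))),
                       diag(0, ncol(particles)), M)
  ens$particles <- particles
  ens$weights <- weights
  ens
}

# tiny Bernoulli stream from a known theta
make_stream <- function(th, n, seed, feature_rate = 0.3) {
  set.seed(seed)
  d <- length(th$coefficients)
  X <- matrix(rbinom(n * d, 1, feature_rate), n, d)
  list(X = X, y = rbinom(n, 1, predict_proba(th, X)))
}
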