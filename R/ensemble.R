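#' Particle ensembles over risk-model parameters
#'
#' The filter represents the posterior distribution of the parameter vector
#' as a cloud of `M` weighted particles, each a flat parameter vector
#' (coefficients then intercept).  These functions implement the four
#' elementary moves: initialisation, Gaussian jitter (prediction), Bayesian
#' reweighting against one observed patient, and resampling.
#'
#' @name particle_ensemble
NULL

new_ensemble <- function(particles, weights) {
  structure(list(particles = particles, weights = weights),
            class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat("<particle_ensemble> M =", nrow(x$particles),
      " params =", ncol(x$particles),
      " ESS =", signif(ess(x), 4), "\n")
  invisible(x)
}

#' Initialise a particle ensemble around an initial parameter estimate
#'
#' Draws `M` particles from `N(theta0, A)` with uniform weights `1/M`.
#' `A` controls the initial spread of the search around the batch-fitted
#' parameters; `A = 0` collapses all particles onto `theta0` exactly.
#'
#' @param theta0 A [theta()] object, typically a batch logistic fit on the
#'   initialisation segment of the training data.
#' @param A `(d+1) x (d+1)` symmetric PSD covariance of the initial spread,
#'   or a single scalar (interpreted as `scalar * I`).
#' @param M Number of particles (>= 2).
#' @param seed Optional integer seed; if supplied, `set.seed()` is called.
#' @return A `particle_ensemble`.
#' @export
init_ensemble <- function(theta0, A, M, seed = NULL) {
  stopifnot(inherits(theta0, "theta"), M >= 2)
  mu <- theta_flat(theta0)
  p <- length(mu)
  if (length(A) == 1L && !is.matrix(A)) A <- diag(as.numeric(A), p)
  check_psd(A, "A")
  if (!is.null(seed)) set.seed(seed)
  particles <- draw_mvn(M, mu, A)
  new_ensemble(particles, rep(1 / M, M))
}

# N(mu, Sigma) draws as an M x p matrix; exact for Sigma = 0
draw_mvn <- function(M, mu, Sigma) {
  p <- length(mu)
  if (all(Sigma == 0)) {
    return(matrix(mu, nrow = M, ncol = p, byrow = TRUE))
  }
  out <- MASS::mvrnorm(M, mu = mu, Sigma = Sigma)
  if (!is.matrix(out)) out <- matrix(out, nrow = M)
  out
}

#' Prediction step: pseudo-dynamic jitter
#'
#' The parameters have no true dynamics; an artificial Gaussian perturbation
#' `N(0, Q)` is added to every particle so the cloud keeps exploring parameter
#' space instead of collapsing.  Weights are unchanged.
#'
#' @param ensemble A `particle_ensemble`.
#' @param Q `(d+1) x (d+1)` symmetric PSD process-noise covariance (or scalar
#'   for `scalar * I`).
#' @return The jittered `particle_ensemble`.
#' @export
predict_step <- function(ensemble, Q) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  p <- ncol(ensemble$particles)
  if (length(Q) == 1L && !is.matrix(Q)) Q <- diag(as.numeric(Q), p)
  check_psd(Q, "Q")
  if (all(Q == 0)) return(ensemble)
  eps <- draw_mvn(nrow(ensemble$particles), rep(0, p), Q)
  new_ensemble(ensemble$particles + eps, ensemble$weights)
}

#' Gaussian squared-error observation likelihood
#'
#' The (unnormalised) likelihood of observing outcome `y` when the model
#' predicts probability `y_hat`: `exp(-(y - y_hat)^2 / (2 R))`.  The binary
#' outcome is compared with the predicted probability through a Gaussian
#' error model with variance `R`; smaller `R` trusts each new patient more.
#'
#' @param y Observed outcome(s) in \{0, 1\}.
#' @param y_hat Predicted probability(ies).
#' @param R Positive observation-noise variance.
#' @return Likelihood value(s) in (0, 1].
#' @export
likelihood <- function(y, y_hat, R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("`R` must be a positive scalar", call. = FALSE)
  }
  exp(-(y - y_hat)^2 / (2 * R))
}

#' Update step: reweight particles against one observed patient
#'
#' Each particle's weight is multiplied by the likelihood of the observed
#' outcome under that particle's parameters and the weights are renormalised
#' to sum to one (computed in log space).  If every raw weight underflows to
#' zero the weights fall back to uniform with a warning, so a single extreme
#' patient cannot abort a run.
#'
#' @param ensemble A `particle_ensemble` with `d + 1` parameter columns.
#' @param x Feature vector of length `d` for the new patient.
#' @param y Observed outcome (0/1).
#' @param R Positive observation-noise variance.
#' @return The reweighted `particle_ensemble`.
#' @export
weight_step <- function(ensemble, x, y, R) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("`R` must be a positive scalar", call. = FALSE)
  }
  p <- ncol(ensemble$particles)
  x <- as.numeric(x)
  if (length(x) != p - 1L) {
    stop(sprintf("feature vector has length %d but particles carry %d coefficients",
                 length(x), p - 1L), call. = FALSE)
  }
  eta <- drop(ensemble$particles %*% c(x, 1))
  y_hat <- stats::plogis(eta)
  logw <- log(ensemble$weights) - (y - y_hat)^2 / (2 * R)
  m <- max(logw)
  if (!is.finite(m)) {
    warning("all particle weights underflowed; falling back to uniform weights")
    w <- rep(1 / nrow(ensemble$particles), nrow(ensemble$particles))
  } else {
    w <- exp(logw - m)
    w <- w / sum(w)
  }
  new_ensemble(ensemble$particles, w)
}

#' Resampling step
#'
#' Draws `M` particles with replacement proportional to the weights and resets
#' the weights to uniform, combating weight degeneracy.  `"multinomial"`
#' (independent random draws) is the default;
#' `"systematic"` (one uniform offset, stratified thresholds) is available as
#' a lower-variance alternative.
#'
#' @param ensemble A `particle_ensemble` with normalised weights.
#' @param method `"multinomial"` or `"systematic"`.
#' @return A `particle_ensemble` with uniform weights whose particles form a
#'   sub-multiset of the input particles.
#' @export
resample_step <- function(ensemble, method = c("multinomial", "systematic")) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  method <- match.arg(method)
  w <- ensemble$weights
  if (all(w == 0)) stop("cannot resample from all-zero weights", call. = FALSE)
  M <- nrow(ensemble$particles)
  idx <- if (method == "multinomial") {
    sample.int(M, M, replace = TRUE, prob = w)
  } else {
    u <- (stats::runif(1) + seq_len(M) - 1) / M
    findInterval(u, cumsum(w / sum(w))) + 1L
  }
  new_ensemble(ensemble$particles[idx, , drop = FALSE], rep(1 / M, M))
}

#' Weighted posterior mean of the ensemble
#'
#' The conditional-expectation estimate of the parameters given the data
#' assimilated so far: the weight-averaged particle.
#'
#' @param ensemble A `particle_ensemble`.
#' @return A [theta()] object.
#' @export
posterior_mean <- function(ensemble) {
  stopifnot(inherits(ensemble, "particle_ensemble"))
  w <- ensemble$weights / sum(ensemble$weights)
  as_theta(drop(crossprod(ensemble$particles, w)))
}

#' Effective sample size of the weights
#'
#' `1 / sum(w^2)`: ranges from 1 (all weight on one particle) to `M`
#' (uniform weights); a standard degeneracy diagnostic.
#'
#' @param ensemble A `particle_ensemble`.
#' @return Scalar in `[1, M]`.
#' @export
ess <- function(ensemble) {
  w <- ensemble$weights / sum(ensemble$weights)
  1 / sum(w^2)
}
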