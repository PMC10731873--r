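#' Dense-grid Bayes filter for a one-parameter logistic model
#'
#' Deterministic reference filter used to validate the particle filter on a
#' scalar parameter.  The posterior density over the parameter is carried on
#' a fine uniform grid; each cycle performs the same two moves as the particle
#' filter — convolution with the Gaussian jitter kernel `N(0, Q)` (prediction)
#' and multiplication by the Gaussian squared-error likelihood
#' `exp(-(y - sigmoid(theta * x))^2 / (2R))` (update) — followed by
#' renormalisation.  With a fine grid and a wide span this is exact up to
#' discretisation, providing an independent yardstick: the particle filter's
#' per-step posterior mean should match the grid filter's within Monte Carlo
#' error.
#'
#' The observation model is `y ~ sigmoid(theta * x)`; pass `x = 1` for an
#' intercept-only model (then the particle-filter counterpart is a run with
#' `theta0 = theta(numeric(0), b)`).
#'
#' @param y Length-`K` vector of 0/1 outcomes.
#' @param x Scalar covariate or length-`K` vector (default 1, intercept-only).
#' @param theta0 Scalar prior mean.
#' @param A Positive prior variance of the parameter.
#' @param Q Non-negative per-step jitter variance.
#' @param R Positive observation-noise variance.
#' @param grid_size Number of grid points (default 10000).
#' @param span Half-width of the grid around `theta0`; default
#'   `8 * sqrt(A + K * Q) + 2`, wide enough that boundary mass is negligible.
#' @return List with `means` (length-`K` posterior means), `grid`, and the
#'   final posterior `density` on the grid.
#' @export
grid_bayes_filter <- function(y, x = 1, theta0, A, Q, R,
                              grid_size = 10000, span = NULL) {
  stopifnot(A > 0, Q >= 0, R > 0, grid_size >= 100)
  K <- length(y)
  if (length(x) == 1L) x <- rep(x, K)
  stopifnot(length(x) == K)
  if (is.null(span)) span <- 8 * sqrt(A + K * Q) + 2
  grid <- seq(theta0 - span, theta0 + span, length.out = grid_size)
  dx <- grid[2] - grid[1]

  dens <- stats::dnorm(grid, theta0, sqrt(A))
  dens <- dens / sum(dens)

  # precompute the discretised jitter kernel (truncated at 6 sd)
  kern <- NULL
  if (Q > 0) {
    J <- min(grid_size - 1L, ceiling(6 * sqrt(Q) / dx))
    kern <- stats::dnorm(seq(-J, J) * dx, 0, sqrt(Q))
    kern <- kern / sum(kern)
  }

  means <- numeric(K)
  for (k in seq_len(K)) {
    if (!is.null(kern)) dens <- conv_same(dens, kern)
    lik <- exp(-(y[k] - stats::plogis(grid * x[k]))^2 / (2 * R))
    dens <- dens * lik
    s <- sum(dens)
    if (s == 0) stop("grid filter density vanished; widen the grid", call. = FALSE)
    dens <- dens / s
    means[k] <- sum(grid * dens)
  }
  list(means = means, grid = grid, density = dens)
}

# "same"-aligned convolution of a density with a symmetric kernel via FFT
conv_same <- function(p, kern) {
  L <- length(p)
  J <- (length(kern) - 1L) / 2L
  n <- L + length(kern) - 1L
  n2 <- stats::nextn(n, 2)
  fp <- stats::fft(c(p, rep(0, n2 - L)))
  fk <- stats::fft(c(kern, rep(0, n2 - length(kern))))
  full <- Re(stats::fft(fp * fk, inverse = TRUE)) / n2
  out <- full[(J + 1):(J + L)]
  pmax(out, 0)
}
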