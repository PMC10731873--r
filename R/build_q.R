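#' Build the process-noise covariance by differentiation and standardisation
#'
#' Constructs the `(d+1) x (d+1)` process-noise covariance `Q` from the
#' initial parameter estimate and the pairwise correlations of the model
#' features, then shrinks it by `scale` so per-step jitter stays small enough
#' for the parameter estimates to reach a steady state:
#'
#' * diagonal entry `i`: `|theta0_i| / sum_j |theta0_j|` — each parameter's
#'   share of the total parameter magnitude ("differentiation"), so larger
#'   coefficients are allowed to wander proportionally more.  Absolute values
#'   are used throughout: a share of a negative coefficient cannot serve as a
#'   variance.
#' * off-diagonal `(i, j)` for two feature coefficients: the features'
#'   absolute Pearson correlation normalised by the sum of all pairwise
#'   absolute correlations ("standardisation").
#' * the intercept corresponds to no feature, so its off-diagonals are 0 and
#'   its diagonal follows the same normalised-magnitude rule.
#'
#' The normalised-correlation construction does not guarantee positive
#' semi-definiteness; if the result is indefinite its eigenvalues are clipped
#' at zero and the matrix resymmetrised (a message is emitted whenever the
#' repair is material).
#'
#' @param theta0 A [theta()] with at least one nonzero entry.
#' @param feature_corr `d x d` symmetric correlation matrix of the model
#'   features with unit diagonal (e.g. `cor()` of the design matrix on the
#'   initialisation data).
#' @param scale Overall shrink factor, default 0.1.
#' @return Symmetric PSD `(d+1) x (d+1)` matrix.
#' @export
build_q <- function(theta0, feature_corr, scale = 0.1) {
  stopifnot(inherits(theta0, "theta"), scale > 0)
  th <- theta_flat(theta0)
  d <- length(theta0$coefficients)
  if (all(th == 0)) stop("theta0 has no nonzero entry", call. = FALSE)
  if (d > 0) {
    feature_corr <- as.matrix(feature_corr)
    if (nrow(feature_corr) != d || ncol(feature_corr) != d) {
      stop(sprintf("feature_corr must be %d x %d", d, d), call. = FALSE)
    }
    if (max(abs(feature_corr - t(feature_corr))) > 1e-8 ||
        max(abs(diag(feature_corr) - 1)) > 1e-8) {
      stop("feature_corr must be symmetric with unit diagonal", call. = FALSE)
    }
  }
  p <- d + 1L
  Q <- diag(abs(th) / sum(abs(th)), p)
  if (d >= 2) {
    off <- abs(feature_corr)
    diag(off) <- 0
    denom <- sum(off[upper.tri(off)])
    if (denom > 0) Q[1:d, 1:d] <- Q[1:d, 1:d] + off / denom
  }
  psd_project(Q * scale)
}
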