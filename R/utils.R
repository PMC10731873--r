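# internal numerical helpers

# symmetry + PSD check with a relative eigenvalue tolerance
check_psd <- function(S, name = "matrix", tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    stop(sprintf("`%s` must be positive semi-definite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

# project a symmetric matrix to the PSD cone by clipping eigenvalues at zero
psd_project <- function(S, warn_tol = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 0) return(S)
  clipped <- pmax(e$values, 0)
  if (max(abs(clipped - e$values)) > warn_tol) {
    message(sprintf("PSD repair clipped eigenvalues (most negative %.3g)",
                    min(e$values)))
  }
  out <- e$vectors %*% (clipped * t(e$vectors))
  (out + t(out)) / 2
}

# deterministic per-stage sub-seed from one global seed; keeps results
# reproducible when a stage is re-run in isolation (value stays < 2^31)
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  as.integer((as.double(seed) %% 1e6) * 2017 + 100003 * stage) %% 2147483629L
}
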