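#' Logistic risk-model parameters
#'
#' A `theta` object holds the parameters of a logistic prognostic risk model:
#' one coefficient per model feature plus an intercept.  When parameters are
#' handled as a flat vector (e.g. inside the particle filter) the intercept
#' occupies the last slot, so a model with `d` features has `d + 1` parameters.
#'
#' @param coefficients Numeric vector of feature coefficients (length `d`;
#'   `d = 0` gives an intercept-only model).
#' @param intercept Single finite numeric intercept.
#' @return An object of class `theta`.
#' @examples
#' th <- theta(c(2.79, -2.39, 2.4, 1.3), -0.9)
#' log_odds(th, c(1, 0, 0, 0))
#' @export
theta <- function(coefficients, intercept) {
  coefficients <- as.numeric(coefficients)
  intercept <- as.numeric(intercept)
  if (length(intercept) != 1L || !is.finite(intercept)) {
    stop("`intercept` must be a single finite number", call. = FALSE)
  }
  if (anyNA(coefficients) || !all(is.finite(coefficients))) {
    stop("`coefficients` must be finite", call. = FALSE)
  }
  structure(list(coefficients = coefficients, intercept = intercept),
            class = "theta")
}

#' @export
print.theta <- function(x, ...) {
  cat("<theta> d =", length(x$coefficients), "\n")
  cat("  coefficients:", paste(signif(x$coefficients, 4), collapse = ", "), "\n")
  cat("  intercept:   ", signif(x$intercept, 4), "\n")
  invisible(x)
}

#' Flatten / rebuild theta as a plain parameter vector
#'
#' `theta_flat()` returns `c(coefficients, intercept)`; `as_theta()` is its
#' inverse (last slot read as the intercept).  This is the layout used for
#' particles.
#'
#' @param th A [theta()] object.
#' @param v Numeric vector of length `d + 1` (intercept last).
#' @return A numeric vector / a `theta`.
#' @export
theta_flat <- function(th) {
  stopifnot(inherits(th, "theta"))
  c(th$coefficients, th$intercept)
}

#' @rdname theta_flat
#' @export
as_theta <- function(v) {
  v <- as.numeric(v)
  if (length(v) < 1L) stop("parameter vector must have length >= 1", call. = FALSE)
  theta(v[-length(v)], v[length(v)])
}

#' Linear predictor of the logistic risk model
#'
#' Computes `theta . x + intercept` for a single feature vector or row-wise
#' for a feature matrix.  No clipping is applied.
#'
#' @param th A [theta()] object.
#' @param x Numeric feature vector of length `d`, or an `n x d` matrix.
#' @return Numeric scalar (vector input) or length-`n` vector (matrix input).
#' @export
log_odds <- function(th, x) {
  stopifnot(inherits(th, "theta"))
  d <- length(th$coefficients)
  if (is.matrix(x)) {
    if (ncol(x) != d) {
      stop(sprintf("feature matrix has %d columns but theta has %d coefficients",
                   ncol(x), d), call. = FALSE)
    }
    drop(x %*% th$coefficients) + th$intercept
  } else {
    x <- as.numeric(x)
    if (length(x) != d) {
      stop(sprintf("feature vector has length %d but theta has %d coefficients",
                   length(x), d), call. = FALSE)
    }
    sum(th$coefficients * x) + th$intercept
  }
}

#' Predicted death probability
#'
#' The logistic observation function: `sigmoid(theta . x + intercept)`.
#' This is the model's predicted probability of the outcome `y = 1` (death)
#' and the quantity compared with the observed outcome inside the filter's
#' likelihood.
#'
#' @inheritParams log_odds
#' @return Probability in (0, 1), vectorised over matrix rows.
#' @export
predict_proba <- function(th, x) {
  stats::plogis(log_odds(th, x))
}

#' Threshold a predicted probability into a class label
#'
#' Ties at the threshold classify as 1 (death): a patient whose predicted risk
#' equals the cut-off is flagged, the conservative choice in a prognosis
#' setting.
#'
#' @param p Probabilities in `[0, 1]` (vectorised).
#' @param threshold Classification cut-off, default 0.5.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(p, threshold = 0.5) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  as.integer(p >= threshold)
}

#' Serialize / deserialize theta as JSON
#'
#' @param th A [theta()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param json JSON string or file path produced by `theta_to_json()`.
#' @return `theta_to_json()`: JSON string (invisibly, if written to file);
#'   `theta_from_json()`: a `theta`.
#' @export
theta_to_json <- function(th, path = NULL) {
  stopifnot(inherits(th, "theta"))
  txt <- jsonlite::toJSON(list(coefficients = th$coefficients,
                               intercept = th$intercept),
                          auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname theta_to_json
#' @export
theta_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  theta(obj$coefficients, obj$intercept)
}
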