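#' Specification for a synthetic patient cohort
#'
#' Describes a cohort generator with known ground truth, shaped like a
#' single-centre surgical-resection registry: on the order of a thousand
#' patients, tens of raw features of mixed type with correlated blocks and a
#' few near-constant columns, and a heavily imbalanced binary survival
#' outcome driven by a small set of informative binary features through a
#' logistic model.
#'
#' Defaults mirror the working case the package targets: 1288 patients,
#' 70 raw features, 4 informative binary risk factors with coefficients
#' (2.79, -2.39, 2.4, 1.3), death prevalence 0.12, two correlated continuous
#' blocks and five near-constant columns.
#'
#' @param n_patients Number of rows.
#' @param n_features Total raw feature columns (pre-encoding).
#' @param theta_star Coefficients of the informative binary features; its
#'   length sets `n_informative`.
#' @param prevalence Target death prevalence in (0, 1); the generator solves
#'   for the intercept that attains it in expectation.
#' @param blocks List of correlated continuous blocks, each
#'   `list(size =, r =)` (pairwise within-block correlation).
#' @param n_low_variance Number of near-constant binary columns
#'   (event rate `low_variance_rate`).
#' @param low_variance_rate Bernoulli rate of the near-constant columns.
#' @param drift_schedule Optional drift schedule recorded in the spec (see
#'   [inject_drift()]); the base generator itself is drift-free.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(n_patients = 1288,
                           n_features = 70,
                           theta_star = c(2.79, -2.39, 2.4, 1.3),
                           prevalence = 0.12,
                           blocks = list(list(size = 3, r = 0.9),
                                         list(size = 4, r = 0.8)),
                           n_low_variance = 5,
                           low_variance_rate = 0.005,
                           drift_schedule = list(),
                           seed = 1) {
  n_informative <- length(theta_star)
  n_block <- sum(vapply(blocks, function(b) b$size, numeric(1)))
  if (n_informative + n_block + n_low_variance > n_features) {
    stop("informative + block + low-variance columns exceed n_features",
         call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (length(drift_schedule)) {
    at <- vapply(drift_schedule, function(d) d$at, numeric(1))
    if (any(diff(at) <= 0)) stop("drift indices must be strictly increasing",
                                 call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_features = as.integer(n_features),
                 n_informative = n_informative,
                 theta_star = as.numeric(theta_star),
                 prevalence = prevalence,
                 blocks = blocks,
                 n_low_variance = as.integer(n_low_variance),
                 low_variance_rate = low_variance_rate,
                 drift_schedule = drift_schedule,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the feature table column-block by column-block — informative binary
#' risk factors, correlated continuous blocks (equicorrelated latent
#' Gaussian), near-constant binary columns, and independent binary /
#' categorical / continuous noise — then draws the outcome
#' `y ~ Bernoulli(sigmoid(theta_star . x_inf + b))` with the intercept `b`
#' solved numerically so the expected prevalence matches the target.
#'
#' @param spec A [generator_spec()].
#' @return List with `cohort` (a [cohort()]) and `truth` (list:
#'   `theta_star`, `intercept`, `informative` column names, `linpred`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  d <- spec$n_informative

  cols <- list()
  types <- character(0)

  # informative binary risk factors with moderate, varied prevalences
  inf_rates <- stats::runif(d, 0.2, 0.5)
  inf_names <- sprintf("risk%d", seq_len(d))
  for (j in seq_len(d)) {
    cols[[inf_names[j]]] <- stats::rbinom(n, 1, inf_rates[j])
    types[inf_names[j]] <- "binary"
  }

  # correlated continuous blocks via an equicorrelated latent Gaussian
  for (b in seq_along(spec$blocks)) {
    blk <- spec$blocks[[b]]
    S <- matrix(blk$r, blk$size, blk$size)
    diag(S) <- 1
    Z <- MASS::mvrnorm(n, mu = rep(0, blk$size), Sigma = S)
    for (j in seq_len(blk$size)) {
      nm <- sprintf("blk%d_%d", b, j)
      cols[[nm]] <- Z[, j]
      types[nm] <- "continuous"
    }
  }

  # near-constant binary columns
  for (j in seq_len(spec$n_low_variance)) {
    nm <- sprintf("rare%d", j)
    cols[[nm]] <- stats::rbinom(n, 1, spec$low_variance_rate)
    types[nm] <- "binary"
  }

  # remaining noise columns cycle through binary / categorical / continuous
  n_noise <- spec$n_features - length(cols)
  for (j in seq_len(n_noise)) {
    nm <- sprintf("noise%02d", j)
    kind <- c("binary", "categorical", "continuous")[(j - 1) %% 3 + 1]
    cols[[nm]] <- switch(kind,
      binary = stats::rbinom(n, 1, stats::runif(1, 0.15, 0.85)),
      categorical = factor(sample(c("a", "b", "c"), n, replace = TRUE,
                                  prob = c(0.5, 0.3, 0.2))),
      continuous = stats::rnorm(n))
    types[nm] <- kind
  }

  X_inf <- do.call(cbind, cols[inf_names])
  eta0 <- drop(X_inf %*% spec$theta_star)
  b <- solve_intercept(eta0, spec$prevalence)
  y <- stats::rbinom(n, 1, stats::plogis(eta0 + b))

  list(cohort = cohort(as.data.frame(cols, stringsAsFactors = FALSE), y, types),
       truth = list(theta_star = spec$theta_star,
                    intercept = b,
                    informative = inf_names,
                    linpred = eta0 + b,
                    spec = spec))
}

# intercept b with mean(sigmoid(eta + b)) == target, by monotone root finding
solve_intercept <- function(eta, target) {
  f <- function(b) mean(stats::plogis(eta + b)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target prevalence unattainable for the given theta_star", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Split a cohort into initialisation, filtering and test segments
#'
#' Random train/test split (`train_frac`, by row permutation), then within the
#' training rows the first `init_size` rows in stream order form the
#' initialisation set (used for the batch logistic fit of `theta0`) and the
#' remainder the filtering stream consumed one patient at a time.  With the
#' default settings on 1288 rows this yields 858 training rows = 250
#' initialisation + 608 filtering, and 430 test rows.
#'
#' @param x A [cohort()].
#' @param train_frac Training fraction (default 2/3; train size is
#'   `floor(train_frac * n)`).
#' @param init_size Rows of the training stream used for initialisation.
#' @param seed Integer seed for the permutation.
#' @return List with cohorts `init`, `filtering`, `test` and the integer row
#'   `indices` of each segment in the original cohort.
#' @export
split_stream <- function(x, train_frac = 2 / 3, init_size = 250, seed = 1) {
  stopifnot(inherits(x, "cohort"))
  n <- nrow(x$features)
  n_train <- floor(train_frac * n)
  if (init_size >= n_train) {
    stop("init_size must be smaller than the training-set size", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  idx_train <- perm[seq_len(n_train)]
  idx_test <- perm[(n_train + 1):n]
  idx_init <- idx_train[seq_len(init_size)]
  idx_filt <- idx_train[(init_size + 1):n_train]
  list(init = x[idx_init], filtering = x[idx_filt], test = x[idx_test],
       indices = list(init = idx_init, filtering = idx_filt, test = idx_test))
}

#' Inject concept drift into an observation stream
#'
#' Re-draws the outcomes of a stream from new parameter values beyond given
#' stream positions, leaving the features untouched: a piecewise-constant
#' change in the outcome-generating parameters, the simplest form of the
#' concept drift / model decay an online filter exists to track.
#'
#' @param stream List with `X` (matrix) and `y`, as from [as_stream()].
#' @param schedule List of `list(at = <1-based stream index>, theta = <theta>)`
#'   entries with strictly increasing `at`; outcomes at positions `>= at` are
#'   re-drawn from that `theta` (until the next entry takes over).
#' @param seed Integer seed for the re-draws.
#' @return The stream with modified `y` and a `truth_path` attribute recording
#'   the piecewise schedule.
#' @export
inject_drift <- function(stream, schedule, seed = 1) {
  if (!length(schedule)) return(stream)
  K <- length(stream$y)
  at <- vapply(schedule, function(d) d$at, numeric(1))
  if (any(diff(at) <= 0)) stop("drift indices must be strictly increasing",
                               call. = FALSE)
  if (any(at < 1 | at > K)) stop("drift index outside the stream", call. = FALSE)
  set.seed(seed)
  y <- stream$y
  bounds <- c(at, K + 1)
  for (s in seq_along(schedule)) {
    th <- schedule[[s]]$theta
    stopifnot(inherits(th, "theta"))
    rows <- seq(bounds[s], bounds[s + 1] - 1)
    p <- predict_proba(th, stream$X[rows, , drop = FALSE])
    y[rows] <- stats::rbinom(length(rows), 1, p)
  }
  out <- list(X = stream$X, y = y)
  attr(out, "truth_path") <- schedule
  out
}
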