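#' Drop low-variance features
#'
#' A near-constant column carries almost no information about the outcome and
#' is removed before modelling.  Numeric (binary or continuous) columns are
#' screened on their sample variance; for a categorical column the spread of
#' its level indicators is used instead — the largest variance
#' `p_l (1 - p_l)` over its levels — so a column is dropped only when every
#' one of its dummy indicators would be near-constant.
#'
#' @param x A [cohort()].
#' @param min_variance Columns with variance below this are dropped
#'   (default 0.01; `0` drops nothing).
#' @return List with `cohort` (survivors) and `report` (dropped names and the
#'   per-column variance measure, so near-threshold calls are auditable).
#' @export
variance_filter <- function(x, min_variance = 0.01) {
  stopifnot(inherits(x, "cohort"), min_variance >= 0)
  v <- vapply(names(x$features), function(nm) {
    col <- x$features[[nm]]
    if (x$types[[nm]] == "categorical") {
      p <- table(col) / length(col)
      max(p * (1 - p))
    } else {
      stats::var(as.numeric(col))
    }
  }, numeric(1))
  drop_cols <- names(v)[v < min_variance]
  keep <- setdiff(names(x$features), drop_cols)
  if (!length(keep)) stop("variance filter dropped every column", call. = FALSE)
  list(cohort = cohort(x$features[keep], x$outcome, x$types[keep]),
       report = list(dropped = drop_cols, variances = v,
                     min_variance = min_variance))
}

#' Deduplicate highly correlated feature pairs
#'
#' When two features correlate strongly they carry nearly the same
#' information and one is redundant.  Numeric columns are swept left to right
#' in their declared order: a column is dropped if its absolute Pearson
#' correlation with any already-kept column reaches `threshold`, so the
#' earlier column of a correlated pair always survives (deterministic).
#' Categorical columns pass through untouched; the filter runs on raw columns
#' before dummy encoding.
#'
#' @param x A [cohort()].
#' @param threshold Absolute-correlation cut-off (default 0.6).
#' @return List with `cohort` and `report` (dropped names and, for each, the
#'   kept column that triggered the drop).
#' @export
correlation_filter <- function(x, threshold = 0.6) {
  stopifnot(inherits(x, "cohort"))
  num_cols <- names(x$features)[x$types != "categorical"]
  kept <- character(0)
  dropped <- character(0)
  culprit <- character(0)
  if (length(num_cols) >= 2) {
    Xn <- as.matrix(as.data.frame(lapply(x$features[num_cols], as.numeric)))
    cm <- suppressWarnings(stats::cor(Xn))
    cm[is.na(cm)] <- 0
    for (j in seq_along(num_cols)) {
      nm <- num_cols[j]
      hits <- kept[abs(cm[nm, kept]) >= threshold]
      if (length(hits)) {
        dropped <- c(dropped, nm)
        culprit <- c(culprit, hits[1])
      } else {
        kept <- c(kept, nm)
      }
    }
  } else {
    kept <- num_cols
  }
  keep <- setdiff(names(x$features), dropped)
  list(cohort = cohort(x$features[keep], x$outcome, x$types[keep]),
       report = list(dropped = dropped, correlated_with = culprit,
                     threshold = threshold))
}

#' Cross-validated L1 (lasso) feature selection
#'
#' Fits an L1-penalised logistic regression over a log-spaced penalty grid,
#' picks the penalty by k-fold cross-validated deviance, and keeps the
#' features with nonzero coefficients at that penalty.  Categorical columns
#' are dummy-encoded for the fit; a raw column survives if any of its
#' indicators does.
#'
#' @param x A [cohort()].
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param lambda Optional fixed penalty; skips cross-validation when given.
#' @return List with `selected` (raw column names), `lambda` (chosen
#'   penalty), `nonzero` (selected design columns) and `foldid`.
#' @export
lasso_select <- function(x, n_folds = 10, seed = 1, lambda = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (length(unique(x$outcome)) < 2) {
    stop("outcome has a single class; lasso selection undefined", call. = FALSE)
  }
  enc <- encode_dummies(x)
  set.seed(seed)
  if (is.null(lambda)) {
    if (nrow(enc$design) < n_folds) {
      stop("fewer rows than CV folds", call. = FALSE)
    }
    foldid <- sample(rep_len(seq_len(n_folds), nrow(enc$design)))
    cvfit <- glmnet::cv.glmnet(enc$design, x$outcome, family = "binomial",
                               foldid = foldid, nlambda = 100)
    lambda <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    foldid <- NULL
    fit <- glmnet::glmnet(enc$design, x$outcome, family = "binomial")
  }
  beta <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))[-1, 1]
  nonzero <- names(beta)[beta != 0]
  selected <- unique(enc$origin[nonzero])
  list(selected = selected, lambda = lambda, nonzero = nonzero, foldid = foldid)
}

#' Random-forest importance screening
#'
#' Fits a random-forest classifier, ranks the raw columns by z-scored
#' permutation importance (mean decrease in out-of-bag accuracy divided by
#' its between-tree standard error, clipped at zero) normalised to sum to
#' one, and keeps those whose share meets the threshold
#' — concentrating the model on the few features that predict the outcome
#' strongly.  Permutation importance is used rather than Gini impurity
#' because impurity importance is biased toward continuous / many-valued
#' columns, which would crowd out genuinely informative binary risk factors
#' in a mixed-type table.
#'
#' @param x A [cohort()].
#' @param threshold Minimum normalised importance to keep (default 0.05;
#'   `0` keeps everything).
#' @param seed Integer seed (forest growth is randomised).
#' @param ntree Number of trees (default 500).
#' @return List with `selected`, `importance` (named, sorted decreasing,
#'   sums to 1) and `threshold`.
#' @export
rf_screen <- function(x, threshold = 0.05, seed = 1, ntree = 500) {
  stopifnot(inherits(x, "cohort"), threshold >= 0)
  df <- x$features
  for (nm in names(df)) {
    if (x$types[[nm]] == "categorical" && !is.factor(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
    }
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x = df, y = factor(x$outcome, levels = c(0, 1)),
                                   ntree = ntree, importance = TRUE)
  imp <- pmax(randomForest::importance(rf, type = 1, scale = TRUE)[, 1], 0)
  if (sum(imp) == 0) stop("no column has positive permutation importance",
                          call. = FALSE)
  imp <- imp / sum(imp)
  imp <- sort(imp, decreasing = TRUE)
  list(selected = names(imp)[imp >= threshold], importance = imp,
       threshold = threshold)
}

#' Dummy-encode categorical columns
#'
#' Each categorical column with `c` levels becomes `c - 1` 0/1 indicator
#' columns named `column.level`; the reference level (the most frequent,
#' ties broken by level order) is omitted and recorded in the map.  Binary
#' and continuous columns pass through unchanged.
#'
#' @param x A [cohort()].
#' @return List with `design` (numeric matrix), `map` (per-column encoding
#'   record, with `reference` for categorical columns) and `origin` (named
#'   vector mapping design columns back to raw columns).
#' @export
encode_dummies <- function(x) {
  stopifnot(inherits(x, "cohort"))
  map <- list()
  blocks <- list()
  origin <- character(0)
  for (nm in names(x$features)) {
    col <- x$features[[nm]]
    if (x$types[[nm]] == "categorical") {
      col <- as.character(col)
      tab <- table(col)
      ref <- names(tab)[which.max(tab)]
      others <- setdiff(names(tab), ref)
      ind <- vapply(others, function(lv) as.numeric(col == lv), numeric(length(col)))
      ind <- matrix(ind, ncol = length(others),
                    dimnames = list(NULL, paste(nm, others, sep = ".")))
      blocks[[nm]] <- ind
      origin[colnames(ind)] <- nm
      map[[nm]] <- list(type = "categorical", levels = names(tab), reference = ref)
    } else {
      blocks[[nm]] <- matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, nm))
      origin[nm] <- nm
      map[[nm]] <- list(type = x$types[[nm]])
    }
  }
  list(design = do.call(cbind, blocks), map = map, origin = origin)
}

#' Apply a stored dummy encoding to new data
#'
#' Transforms a new feature table with the encoding map learned by
#' [encode_dummies()]; a level not seen when the map was built is an error.
#'
#' @param map Encoding map from [encode_dummies()].
#' @param newdata A `data.frame` with the mapped columns.
#' @return Numeric design matrix with the same columns as the training design.
#' @export
apply_encoding <- function(map, newdata) {
  blocks <- list()
  for (nm in names(map)) {
    if (!nm %in% names(newdata)) stop("missing column: ", nm, call. = FALSE)
    col <- newdata[[nm]]
    rec <- map[[nm]]
    if (rec$type == "categorical") {
      col <- as.character(col)
      unseen <- setdiff(unique(col), rec$levels)
      if (length(unseen)) {
        stop(sprintf("unseen level(s) in `%s`: %s", nm,
                     paste(unseen, collapse = ", ")), call. = FALSE)
      }
      others <- setdiff(rec$levels, rec$reference)
      ind <- vapply(others, function(lv) as.numeric(col == lv), numeric(length(col)))
      blocks[[nm]] <- matrix(ind, ncol = length(others),
                             dimnames = list(NULL, paste(nm, others, sep = ".")))
    } else {
      blocks[[nm]] <- matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, nm))
    }
  }
  do.call(cbind, blocks)
}

#' Reconstruct raw columns from an encoded design matrix
#'
#' Inverse of [encode_dummies()] (exact for data encoded with the same map);
#' used to verify the encoding is lossless.
#'
#' @param design Encoded design matrix.
#' @param map Encoding map from [encode_dummies()].
#' @return A `data.frame` of raw columns.
#' @export
decode_dummies <- function(design, map) {
  out <- list()
  for (nm in names(map)) {
    rec <- map[[nm]]
    if (rec$type == "categorical") {
      others <- setdiff(rec$levels, rec$reference)
      cols <- design[, paste(nm, others, sep = "."), drop = FALSE]
      lev <- rep(rec$reference, nrow(design))
      for (j in seq_along(others)) lev[cols[, j] == 1] <- others[j]
      out[[nm]] <- factor(lev, levels = rec$levels)
    } else {
      out[[nm]] <- design[, nm]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Initial cross-validated logistic fit with coefficient screening
#'
#' Fits the batch logistic model that seeds the filter: a maximum-likelihood
#' logistic regression on the encoded design, a per-coefficient Wald z-test,
#' one pass dropping the columns that fail significance at `alpha`, and a
#' single refit on the survivors.  Cross-validated accuracy (threshold 0.5)
#' is reported alongside.
#'
#' @param design Numeric design matrix.
#' @param outcome 0/1 outcome vector.
#' @param n_folds CV folds for the accuracy estimate (default 3).
#' @param alpha Wald significance level for keeping a column (default 0.05).
#' @param seed Integer seed for the fold assignment.
#' @return List with `theta` (a [theta()] over the kept columns — this is the
#'   filter's starting point), `kept` column names, `p_values` from the first
#'   fit, `cv_accuracy`, and the final `fit`.
#' @export
fit_initial_model <- function(design, outcome, n_folds = 3, alpha = 0.05,
                              seed = 1) {
  design <- as.matrix(design)
  stopifnot(nrow(design) == length(outcome), nrow(design) >= n_folds)
  df <- as.data.frame(design)
  df$.y <- outcome

  fit1 <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  check_converged(fit1)
  coefs <- summary(fit1)$coefficients
  pv <- coefs[rownames(coefs) != "(Intercept)", "Pr(>|z|)"]
  names(pv) <- clean_term(names(pv), colnames(design))
  kept <- names(pv)[pv < alpha]

  if (length(kept) == length(pv)) {
    fit2 <- fit1
  } else if (length(kept) == 0L) {
    fit2 <- stats::glm(outcome ~ 1, family = stats::binomial())
  } else {
    df2 <- as.data.frame(design[, kept, drop = FALSE])
    df2$.y <- outcome
    fit2 <- stats::glm(.y ~ ., data = df2, family = stats::binomial())
    check_converged(fit2)
  }
  cf <- stats::coef(fit2)
  th <- theta(unname(cf[-1]), unname(cf[1]))

  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), nrow(design)))
  acc <- vapply(seq_len(n_folds), function(f) {
    tr <- foldid != f
    dtr <- as.data.frame(design[tr, kept, drop = FALSE]); dtr$.y <- outcome[tr]
    fml <- if (length(kept)) .y ~ . else .y ~ 1
    m <- suppressWarnings(stats::glm(fml, data = dtr, family = stats::binomial()))
    dte <- as.data.frame(design[!tr, kept, drop = FALSE])
    p <- stats::predict(m, newdata = dte, type = "response")
    mean(classify(p) == outcome[!tr])
  }, numeric(1))

  list(theta = th, kept = kept, p_values = pv, cv_accuracy = mean(acc),
       fit = fit2)
}

check_converged <- function(fit) {
  if (!fit$converged) {
    stop(paste("logistic fit did not converge; check for separation or",
               "collinearity (drop or merge sparse columns and refit)"),
         call. = FALSE)
  }
  if (any(abs(stats::coef(fit)) > 50, na.rm = TRUE)) {
    stop(paste("logistic fit shows signs of complete separation (huge",
               "coefficients); reduce features or pool sparse levels"),
         call. = FALSE)
  }
  invisible(TRUE)
}

# glm backtick-quotes non-syntactic term names; map back to design columns
clean_term <- function(terms, cols) {
  cleaned <- gsub("^`|`$", "", terms)
  ifelse(cleaned %in% cols, cleaned, terms)
}

#' Run the full pre-modelling reduction chain
#'
#' Convenience wrapper applying, in order, [variance_filter()],
#' [correlation_filter()], [lasso_select()] and [rf_screen()], keeping at
#' each stage only the survivors of the previous one (so the column sets are
#' nested) and collecting every stage report.
#'
#' @param x A [cohort()].
#' @param min_variance,cor_threshold,n_folds,rf_threshold Stage parameters,
#'   see the individual functions.
#' @param seed Integer seed; stage sub-seeds are derived from it.
#' @return List with `cohort` (final survivors), `selected` column names and
#'   `reports` (one entry per stage).
#' @export
reduce_features <- function(x, min_variance = 0.01, cor_threshold = 0.6,
                            n_folds = 10, rf_threshold = 0.05, seed = 1) {
  s1 <- variance_filter(x, min_variance)
  s2 <- correlation_filter(s1$cohort, cor_threshold)
  s3 <- lasso_select(s2$cohort, n_folds = n_folds, seed = derive_seed(seed, 1))
  if (!length(s3$selected)) {
    stop("lasso selected no features; lower the penalty or check the outcome",
         call. = FALSE)
  }
  c3 <- s2$cohort[["features"]][s3$selected]
  co3 <- cohort(c3, s2$cohort$outcome, s2$cohort$types[s3$selected])
  s4 <- rf_screen(co3, threshold = rf_threshold, seed = derive_seed(seed, 2))
  co4 <- cohort(co3$features[s4$selected], co3$outcome, co3$types[s4$selected])
  list(cohort = co4, selected = s4$selected,
       reports = list(variance = s1$report, correlation = s2$report,
                      lasso = s3[c("selected", "lambda")],
                      forest = s4[c("selected", "importance", "threshold")]))
}
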