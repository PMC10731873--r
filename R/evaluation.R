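#' Confusion metrics for a binary risk classifier
#'
#' Accuracy plus per-class precision, recall and F1 for the survival (0) and
#' death (1) classes.  With heavily imbalanced survival data the death-class
#' recall — the fraction of patients who died that the model flagged — is the
#' clinically salient number; overall accuracy alone can be inflated by the
#' majority class.  A zero-denominator cell (e.g. precision when a class is
#' never predicted) is reported as 0 and flagged.
#'
#' @param y_true Observed 0/1 labels.
#' @param y_pred Predicted 0/1 labels of the same length.
#' @return An `eval_report`: list with `accuracy`, `n`, per-class lists
#'   (`precision`, `recall`, `f1`, `n`) under `survival` and `death`, and
#'   `zero_denominator` flags.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!length(y_true)) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  flags <- character(0)
  per_class <- lapply(c(survival = 0L, death = 1L), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    if (tp + fp == 0 || tp + fn == 0 || prec + rec == 0) {
      flags <<- c(flags, as.character(cl))
    }
    list(precision = prec, recall = rec, f1 = f1, n = sum(y_true == cl))
  })
  structure(list(accuracy = mean(y_true == y_pred),
                 n = length(y_true),
                 survival = per_class$survival,
                 death = per_class$death,
                 zero_denominator = length(flags) > 0),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  (n = %d)\n", x$accuracy, x$n))
  cat(sprintf("            precision  recall      f1     n\n"))
  for (cl in c("survival", "death")) {
    cat(sprintf("%-10s  %9.4f %7.4f %7.4f %5d\n", cl,
                x[[cl]]$precision, x[[cl]]$recall, x[[cl]]$f1, x[[cl]]$n))
  }
  if (!is.null(x$auc)) cat(sprintf("AUC %.4f\n", x$auc))
  invisible(x)
}

#' Area under the ROC curve (rank formulation)
#'
#' Computed from the Mann-Whitney statistic: the probability that a randomly
#' chosen death scores above a randomly chosen survivor, with ties handled by
#' midranks.
#'
#' @param y_true Observed 0/1 labels; both classes must be present.
#' @param scores Numeric risk scores (higher = more death-like).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(scores))
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare a batch model with a filtered model on one test set
#'
#' Evaluates both parameter vectors on the same test set (confusion metrics
#' at the given threshold plus AUC) and reports per-metric differences
#' (filtered minus batch): the gain, if any, from assimilating the data
#' stream over freezing the initial batch fit.
#'
#' @param theta_batch,theta_filtered [theta()] objects over the same
#'   features.
#' @param test List with `X` (matrix) and `y` (0/1), e.g. from [as_stream()].
#' @param threshold Classification cut-off (default 0.5).
#' @return A `model_comparison`: `batch` and `filtered` eval reports (with
#'   `$auc`) and `delta`, a named vector of filtered - batch differences.
#' @export
compare_models <- function(theta_batch, theta_filtered, test, threshold = 0.5) {
  stopifnot(inherits(theta_batch, "theta"), inherits(theta_filtered, "theta"))
  evals <- lapply(list(batch = theta_batch, filtered = theta_filtered),
                  function(th) {
    p <- predict_proba(th, test$X)
    rep <- confusion_metrics(test$y, classify(p, threshold))
    rep$auc <- auc(test$y, p)
    rep
  })
  metric <- function(r) c(accuracy = r$accuracy, auc = r$auc,
                          survival_precision = r$survival$precision,
                          survival_recall = r$survival$recall,
                          survival_f1 = r$survival$f1,
                          death_precision = r$death$precision,
                          death_recall = r$death$recall,
                          death_f1 = r$death$f1)
  structure(list(batch = evals$batch, filtered = evals$filtered,
                 delta = metric(evals$filtered) - metric(evals$batch)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("== batch model ==\n"); print(x$batch)
  cat("== filtered model ==\n"); print(x$filtered)
  cat("== delta (filtered - batch) ==\n")
  print(round(x$delta, 4))
  invisible(x)
}

#' Serialize an evaluation report or model comparison to JSON
#'
#' Full float precision is retained in the JSON; round only for display.
#'
#' @param x An `eval_report` or `model_comparison`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "model_comparison")) {
    list(batch = unclass(x$batch), filtered = unclass(x$filtered),
         delta = as.list(x$delta))
  } else {
    unclass(x)
  }
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
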