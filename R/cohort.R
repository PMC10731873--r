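#' Patient cohort container
#'
#' A light container for a tabular cohort: an `n x p` feature table of mixed
#' binary / categorical / continuous columns, a binary outcome vector
#' (1 = death, 0 = survival), and a per-column type tag.  Types are inferred
#' when not supplied: factors and character columns are `"categorical"`,
#' numeric columns taking only values in \{0, 1\} are `"binary"`, all other
#' numeric columns `"continuous"`.
#'
#' @param features A `data.frame` of patient features.
#' @param outcome Vector of 0/1 outcomes, one per row, no missing values.
#' @param types Optional named character vector (`"binary"`, `"categorical"`,
#'   `"continuous"`) covering every feature column.
#' @return A `cohort` object.
#' @export
cohort <- function(features, outcome, types = NULL) {
  features <- as.data.frame(features)
  if (nrow(features) == 0L || ncol(features) == 0L) {
    stop("cohort needs at least one row and one column", call. = FALSE)
  }
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(features)) {
    stop("outcome length must match the number of rows", call. = FALSE)
  }
  if (anyNA(outcome) || !all(outcome %in% c(0L, 1L))) {
    stop("outcome must be 0/1 with no missing values", call. = FALSE)
  }
  if (is.null(types)) {
    types <- vapply(features, infer_type, character(1))
  } else {
    if (!all(names(features) %in% names(types))) {
      stop("`types` must cover every feature column", call. = FALSE)
    }
    types <- types[names(features)]
    bad <- setdiff(unique(types), c("binary", "categorical", "continuous"))
    if (length(bad)) stop("unknown column type(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  structure(list(features = features, outcome = outcome, types = types),
            class = "cohort")
}

infer_type <- function(col) {
  if (is.factor(col) || is.character(col)) return("categorical")
  u <- unique(col[!is.na(col)])
  if (all(u %in% c(0, 1))) "binary" else "continuous"
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$features), "patients,", ncol(x$features), "features (",
      sum(x$types == "binary"), "binary,",
      sum(x$types == "categorical"), "categorical,",
      sum(x$types == "continuous"), "continuous )\n")
  cat("deaths:", sum(x$outcome), sprintf("(%.1f%%)\n", 100 * mean(x$outcome)))
  invisible(x)
}

#' Subset a cohort by row index
#'
#' @param x A [cohort()].
#' @param i Row indices.
#' @param ... Unused.
#' @return A `cohort` with the selected rows.
#' @export
`[.cohort` <- function(x, i, ...) {
  cohort(x$features[i, , drop = FALSE], x$outcome[i], x$types)
}

#' Read / write a cohort as CSV plus a JSON metadata sidecar
#'
#' The CSV holds the feature columns and an `outcome` column; the sidecar
#' records each column's declared type so categorical levels survive the
#' round trip.
#'
#' @param x A [cohort()].
#' @param csv_path Path of the CSV file.
#' @param meta_path Path of the JSON sidecar (default: `csv_path` with a
#'   `.meta.json` suffix).
#' @return `write_cohort()`: `csv_path` invisibly; `read_cohort()`: a `cohort`.
#' @export
write_cohort <- function(x, csv_path, meta_path = paste0(csv_path, ".meta.json")) {
  stopifnot(inherits(x, "cohort"))
  df <- x$features
  df$outcome <- x$outcome
  utils::write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(list(types = as.list(x$types)), meta_path,
                       auto_unbox = TRUE)
  invisible(csv_path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(csv_path, meta_path = paste0(csv_path, ".meta.json")) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!"outcome" %in% names(df)) {
    stop("cohort CSV must contain an `outcome` column", call. = FALSE)
  }
  outcome <- df$outcome
  df$outcome <- NULL
  types <- NULL
  if (file.exists(meta_path)) {
    types <- unlist(jsonlite::fromJSON(meta_path)$types)
    for (nm in names(types)) {
      if (identical(types[[nm]], "categorical")) df[[nm]] <- factor(df[[nm]])
    }
  }
  cohort(df, outcome, types)
}

#' Extract a numeric observation stream from a cohort
#'
#' Selects the given (numeric) feature columns and returns them with the
#' outcome as the `list(X, y)` stream consumed by [run_filter()].
#'
#' @param x A [cohort()].
#' @param columns Feature column names to keep (default: all; must be numeric
#'   — encode categorical columns first, see [encode_dummies()]).
#' @return List with `X` (numeric matrix) and `y` (integer vector).
#' @export
as_stream <- function(x, columns = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(columns)) columns <- names(x$features)
  missing_cols <- setdiff(columns, names(x$features))
  if (length(missing_cols)) {
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sub <- x$features[columns]
  if (any(vapply(sub, function(c) is.factor(c) || is.character(c), logical(1)))) {
    stop("stream columns must be numeric; dummy-encode categorical columns first",
         call. = FALSE)
  }
  list(X = as.matrix(sub), y = x$outcome)
}
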