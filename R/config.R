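#' Default run configuration
#'
#' The full nested configuration driving an end-to-end run: cohort source (a
#' CSV path, or the synthetic generator when none is given), split sizes,
#' reduction thresholds, initial-fit settings, every filter tunable (particle
#' count, cycles, noise covariances, estimate window, resampling scheme) and
#' the evaluation threshold.  One global `seed` fans out to per-stage
#' sub-seeds through a fixed derivation, so any stage can be re-run in
#' isolation reproducibly.
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    paths = list(output_dir = "riskfilter_run", cohort_csv = NULL),
    generator = list(n_patients = 1288, n_features = 70,
                     theta_star = c(2.79, -2.39, 2.4, 1.3),
                     prevalence = 0.12, n_low_variance = 5),
    split = list(train_frac = 2 / 3, init_size = 250),
    reduction = list(min_variance = 0.01, cor_threshold = 0.6,
                     lasso_folds = 10, rf_threshold = 0.05),
    model = list(fit_folds = 3, alpha = 0.05),
    filter = list(n_particles = 100, n_cycles = NULL, estimate_window = 100,
                  resampling = "multinomial", R = 0.1, A = 1,
                  q_mode = "auto", q_scale = 0.1, Q = NULL),
    evaluation = list(threshold = 0.5)
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML file, rejects unknown keys (typos fail loudly instead of
#' silently using a default), and merges the result over
#' [default_run_config()].
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, prefix = "")
}

merge_config <- function(base, user, prefix) {
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      base[[key]] <- merge_config(base[[key]], as.list(user[[key]]), full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Simulate a cohort and write it to disk
#'
#' Generates a synthetic cohort from the `generator` section of the config
#' and writes `cohort.csv`, its metadata sidecar and `truth.json` (the
#' generating parameters) into the output directory.
#'
#' @param config Configuration list (see [read_run_config()]).
#' @param overwrite Refuse to clobber existing outputs unless `TRUE`.
#' @return Paths of the written files, invisibly.
#' @export
cmd_simulate <- function(config = default_run_config(), overwrite = FALSE) {
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "cohort.csv")
  truth_json <- file.path(out_dir, "truth.json")
  if (!overwrite && (file.exists(csv) || file.exists(truth_json))) {
    stop("output exists; pass overwrite = TRUE to replace it", call. = FALSE)
  }
  g <- config$generator
  spec <- generator_spec(n_patients = g$n_patients, n_features = g$n_features,
                         theta_star = g$theta_star, prevalence = g$prevalence,
                         n_low_variance = g$n_low_variance,
                         seed = derive_seed(config$seed, 10))
  sim <- generate_cohort(spec)
  write_cohort(sim$cohort, csv)
  jsonlite::write_json(list(theta_star = sim$truth$theta_star,
                            intercept = sim$truth$intercept,
                            informative = sim$truth$informative),
                       truth_json, auto_unbox = TRUE, digits = NA)
  log_stage("simulate", sprintf("wrote %d patients to %s",
                                nrow(sim$cohort$features), csv))
  invisible(list(cohort_csv = csv, truth_json = truth_json))
}

#' Run the full pipeline: reduce, fit, assimilate, evaluate
#'
#' Executes the whole workflow on one cohort: split into initialisation /
#' filtering / test segments, feature-reduction chain on the training rows,
#' dummy encoding, batch logistic fit on the initialisation segment (theta0),
#' process-noise construction, particle-filter assimilation of the filtering
#' stream, and a batch-vs-filtered comparison on the held-out test set.
#' Every artefact (reduction report, theta0, filter trace, comparison, and a
#' manifest with checksums and seeds) is written to the output directory.
#'
#' @param config Configuration list (see [read_run_config()]).  If
#'   `paths$cohort_csv` is `NULL` a synthetic cohort is generated first.
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return List with `theta0`, `trace`, `comparison`, `reduction`, and
#'   `files` (all written paths), invisibly.
#' @export
cmd_run_all <- function(config = default_run_config(), overwrite = FALSE) {
  out_dir <- config$paths$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!overwrite && file.exists(manifest_path)) {
    stop("output exists; pass overwrite = TRUE to replace it", call. = FALSE)
  }
  files <- list()

  ## stage: cohort
  if (is.null(config$paths$cohort_csv)) {
    sim <- cmd_simulate(config, overwrite = overwrite)
    cohort_csv <- sim$cohort_csv
    files <- c(files, sim)
  } else {
    cohort_csv <- config$paths$cohort_csv
  }
  full <- with_stage("load", read_cohort(cohort_csv))

  ## stage: split
  sp <- with_stage("split",
    split_stream(full, train_frac = config$split$train_frac,
                 init_size = config$split$init_size,
                 seed = derive_seed(config$seed, 20)))
  n_init <- length(sp$indices$init)
  train <- full[c(sp$indices$init, sp$indices$filtering)]

  ## stage: reduce
  red <- with_stage("reduce",
    reduce_features(train, min_variance = config$reduction$min_variance,
                    cor_threshold = config$reduction$cor_threshold,
                    n_folds = config$reduction$lasso_folds,
                    rf_threshold = config$reduction$rf_threshold,
                    seed = derive_seed(config$seed, 30)))
  log_stage("reduce", sprintf("%d -> %d features", ncol(full$features),
                              length(red$selected)))
  files$reduction_json <- file.path(out_dir, "reduction.json")
  jsonlite::write_json(red$reports, files$reduction_json,
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  ## stage: fit theta0 on the initialisation rows
  enc <- encode_dummies(red$cohort)
  init_rows <- seq_len(n_init)
  fit <- with_stage("fit",
    fit_initial_model(enc$design[init_rows, , drop = FALSE],
                      red$cohort$outcome[init_rows],
                      n_folds = config$model$fit_folds,
                      alpha = config$model$alpha,
                      seed = derive_seed(config$seed, 40)))
  if (!length(fit$kept)) {
    stop("stage `fit` failed: no column passed the significance screen",
         call. = FALSE)
  }
  theta0 <- fit$theta
  log_stage("fit", sprintf("theta0 over %d columns, cv accuracy %.4f",
                           length(fit$kept), fit$cv_accuracy))
  files$theta0_json <- file.path(out_dir, "theta0.json")
  theta_to_json(theta0, files$theta0_json)

  ## stage: assimilate the filtering stream
  filt_design <- enc$design[-init_rows, fit$kept, drop = FALSE]
  stream <- list(X = filt_design, y = red$cohort$outcome[-init_rows])
  Q <- if (identical(config$filter$q_mode, "auto")) {
    build_q(theta0, safe_cor(enc$design[init_rows, fit$kept, drop = FALSE]),
            scale = config$filter$q_scale)
  } else {
    config$filter$Q
  }
  n_cycles <- if (is.null(config$filter$n_cycles)) length(stream$y) else
    config$filter$n_cycles
  cfg <- filter_config(n_particles = config$filter$n_particles,
                       n_cycles = n_cycles,
                       estimate_window = config$filter$estimate_window,
                       seed = derive_seed(config$seed, 50),
                       resampling = config$filter$resampling)
  trace <- with_stage("assimilate",
    run_filter(stream, theta0, noise_spec(Q, config$filter$R, config$filter$A),
               cfg))
  sm <- stability_metric(trace, window = min(100, n_cycles))
  log_stage("assimilate", sprintf("%d cycles, stability %.3f (%s)",
                                  n_cycles, as.numeric(sm),
                                  if (attr(sm, "stable")) "stable" else "not stable"))
  files$trace_json <- file.path(out_dir, "trace.json")
  files$trace_csv <- file.path(out_dir, "trace.csv")
  write_trace(trace, files$trace_json, files$trace_csv)

  ## stage: evaluate on the held-out test set
  test_design <- apply_encoding(enc$map, sp$test$features)[, fit$kept,
                                                           drop = FALSE]
  cmp <- with_stage("evaluate",
    compare_models(theta0, trace$final_estimate,
                   list(X = test_design, y = sp$test$outcome),
                   threshold = config$evaluation$threshold))
  log_stage("evaluate", sprintf("accuracy batch %.4f -> filtered %.4f",
                                cmp$batch$accuracy, cmp$filtered$accuracy))
  files$comparison_json <- file.path(out_dir, "comparison.json")
  report_to_json(cmp, files$comparison_json)

  ## manifest
  paths <- unlist(files, use.names = FALSE)
  paths <- c(paths, paste0(cohort_csv, c("", ".meta.json")))
  paths <- unique(paths[file.exists(paths)])
  manifest <- list(
    package = "riskfilter",
    version = as.character(utils::packageVersion("riskfilter")),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 10),
                       split = derive_seed(config$seed, 20),
                       reduce = derive_seed(config$seed, 30),
                       fit = derive_seed(config$seed, 40),
                       assimilate = derive_seed(config$seed, 50)),
    config = config,
    files = lapply(stats::setNames(paths, basename(paths)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  files$manifest_json <- manifest_path

  invisible(list(theta0 = theta0, trace = trace, comparison = cmp,
                 reduction = red, stability = sm, files = files))
}

# correlation matrix that tolerates constant columns (treated as uncorrelated)
safe_cor <- function(X) {
  cm <- suppressWarnings(stats::cor(X))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  (cm + t(cm)) / 2
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}
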