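#' Pipeline configuration
#'
#' Bundles every stage's settings. Either a [cohort_config()] (synthetic
#' cohort) or a path to an existing cohort CSV must be given. All randomness
#' flows from `seed`, deterministically split per stage.
#'
#' @param cohort a [cohort_config()], or `NULL` when reading from `csv_in`.
#' @param csv_in optional path to a cohort CSV (see [read_cohort_csv()]).
#' @param train_fraction train share of the stratified split.
#' @param arch a [planner_arch()].
#' @param metric_mode `"truncate"` or `"round"` (see [compute_metrics()]).
#' @param kmeans_k number of candidate-treatment clusters.
#' @param seed root integer seed.
#' @param out_dir optional output directory; when set, all artifacts
#'   (cohort, planners, report, scatter, clusters) are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), csv_in = NULL,
                            train_fraction = 0.85, arch = planner_arch(),
                            metric_mode = "truncate", kmeans_k = 3L,
                            seed = 7L, out_dir = NULL) {
  if (is.null(cohort) && is.null(csv_in))
    stop("either a cohort config or an input CSV is required",
         call. = FALSE)
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, csv_in = csv_in,
                 train_fraction = train_fraction, arch = arch,
                 metric_mode = metric_mode, kmeans_k = as.integer(kmeans_k),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full dual-planner pipeline
#'
#' Generate (or ingest) the cohort, label it from the creatinine
#' trajectories, split 85/15 per stratum, fit the imputer on the training
#' partition, train the AKI- and AKI+ planners on their training strata, fit
#' the plan-space scaler on the pooled training plans, evaluate the y = x
#' classifier on both partitions, and cluster the training plans into
#' candidate treatments. Re-running with the same config reproduces
#' identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage progress to the console.
#' @return object of class `pipeline_result`: `cohort`, `split`,
#'   `model_minus`, `model_plus`, `scaler`, `eval_train`, `eval_test`,
#'   `clusters`, `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- if (!is.null(config$csv_in)) {
    log_msg(verbose, "ingest: reading %s", config$csv_in)
    read_cohort_csv(config$csv_in)
  } else {
    log_msg(verbose, "cohortgen: generating n = %d (seed %d)",
            config$cohort$n_patients, config$cohort$seed)
    generate_cohort(config$cohort)
  }
  if (nrow(cohort) < 2L)
    stop_stage("cohortgen", "cohort has %d rows", nrow(cohort))

  # label from the trajectories (authoritative even if a Group column came in)
  cohort$Group <- assign_group(cohort$Cr, cohort$Cr_day1, cohort$Cr_day7)
  log_msg(verbose, "labeling: %d AKI+ / %d AKI-",
          sum(cohort$Group == "AKI+"), sum(cohort$Group == "AKI-"))

  split <- stratified_split(cohort, config$train_fraction,
                            seed = derive_seed(config$seed, "split"))
  part <- split$partition[match(cohort$patient_id, split$patient_id)]
  train <- cohort[part == "train", , drop = FALSE]
  test <- cohort[part == "test", , drop = FALSE]
  log_msg(verbose, "split: %d train / %d test", nrow(train), nrow(test))

  imputer <- fit_imputer(train[, c(PREOP_FEATURES, PLAN_PARAMS)])
  train <- apply_imputer(imputer, train)
  test <- apply_imputer(imputer, test)

  tr_minus <- train[train$Group == "AKI-", , drop = FALSE]
  tr_plus <- train[train$Group == "AKI+", , drop = FALSE]
  log_msg(verbose, "planners: training AKI- on %d, AKI+ on %d records",
          nrow(tr_minus), nrow(tr_plus))
  model_minus <- train_planner(tr_minus, stratum = "AKI-",
                               arch = config$arch,
                               seed = derive_seed(config$seed, "planner-"))
  model_plus <- train_planner(tr_plus, stratum = "AKI+",
                              arch = config$arch,
                              seed = derive_seed(config$seed, "planner+"))

  scaler <- fit_plan_scaler(train[, PLAN_PARAMS])
  eval_train <- evaluate_planners(model_minus, model_plus, train, scaler,
                                  mode = config$metric_mode)
  eval_test <- evaluate_planners(model_minus, model_plus, test, scaler,
                                 mode = config$metric_mode)
  log_msg(verbose, "evaluate: train accuracy %.3f, test accuracy %.3f",
          eval_train$metrics$accuracy, eval_test$metrics$accuracy)

  clusters <- kmeans_treatments(train[, PLAN_PARAMS], train$Group,
                                k = config$kmeans_k,
                                seed = derive_seed(config$seed, "kmeans"))

  res <- structure(
    list(cohort = cohort, split = split, imputer = imputer,
         model_minus = model_minus, model_plus = model_plus,
         scaler = scaler, eval_train = eval_train, eval_test = eval_test,
         clusters = clusters, config = config),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) export_pipeline(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Dual-planner pipeline on %d patients (%d AKI+ / %d AKI-)\n",
              nrow(x$cohort), sum(x$cohort$Group == "AKI+"),
              sum(x$cohort$Group == "AKI-")))
  cat("-- train --\n"); print(x$eval_train)
  cat("-- test --\n"); print(x$eval_test)
  invisible(x)
}

export_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(res$cohort, file.path(out_dir, "cohort.csv"))
  save_planner(res$model_minus, file.path(out_dir, "planner_neg.json"))
  save_planner(res$model_plus, file.path(out_dir, "planner_pos.json"))
  write_report(res, file.path(out_dir, "report.json"))
  utils::write.csv(res$eval_test$scatter,
                   file.path(out_dir, "scatter_test.csv"),
                   row.names = FALSE)
  utils::write.csv(res$eval_train$scatter,
                   file.path(out_dir, "scatter_train.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(unclass(res$clusters), function(cl)
      list(center = as.list(cl$center), range_lo = as.list(cl$range_lo),
           range_hi = as.list(cl$range_hi),
           member_count = cl$member_count, label = cl$label)),
    file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

# config echo serializable into the report
config_echo <- function(config) {
  list(
    n_patients = if (!is.null(config$cohort)) config$cohort$n_patients,
    prevalence_target = if (!is.null(config$cohort))
      config$cohort$prevalence_target,
    plan_shift = if (!is.null(config$cohort)) config$cohort$plan_shift,
    csv_in = config$csv_in,
    train_fraction = config$train_fraction,
    arch = config$arch,
    metric_mode = config$metric_mode,
    kmeans_k = config$kmeans_k,
    seed = config$seed)
}

#' Write the evaluation report as JSON
#'
#' The report embeds the confusion matrices and metrics for both partitions
#' together with the exact configuration used, so a run is reproducible from
#' its report alone.
#'
#' @param result a [run_pipeline()] result.
#' @param path output path.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  rep_part <- function(ev)
    list(confusion = as.list(ev$confusion), metrics = ev$metrics,
         n = sum(ev$confusion))
  jsonlite::write_json(
    list(train = rep_part(result$eval_train),
         test = rep_part(result$eval_test),
         config = config_echo(result$config)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cohort CSV round trip
#'
#' `write_cohort_csv` writes one row per patient with the canonical header
#' (Age, BMI, CCB, Cr, Alb, BS, HbA1C, Hct, AnesthesiaTime, CPBTime,
#' DiureticDose, CrystalloidDose, PC, FFP, Cr_day1, Cr_day7, Group) and
#' empty cells for missing values. `read_cohort_csv` validates the schema:
#' unknown columns are an error listing them, a non-numeric cell in a
#' numeric column is an error naming the row and column, and an empty file
#' is a schema error rather than an empty cohort.
#'
#' @param cohort cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort_csv` returns the cohort `data.frame`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort[, intersect(COHORT_COLUMNS, names(cohort))],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop("not a readable cohort CSV: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (!nrow(raw) && !ncol(raw))
    stop("empty file: ", path, " has no cohort schema", call. = FALSE)
  unknown <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(unknown))
    stop("unknown column(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  required <- setdiff(COHORT_COLUMNS, c("Group"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("cohort CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  numeric_cols <- setdiff(COHORT_COLUMNS, c("patient_id", "Group"))
  for (nm in intersect(numeric_cols, names(raw))) {
    vals <- raw[[nm]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & nzchar(vals) & is.na(parsed))
    if (length(bad))
      stop(sprintf("non-numeric value %s in column '%s', row %d of %s",
                   dQuote(vals[bad[1]]), nm, bad[1], path), call. = FALSE)
    parsed[!nzchar(vals)] <- NA
    raw[[nm]] <- parsed
  }
  raw
}
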