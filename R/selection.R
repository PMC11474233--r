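#' Canonical selected feature sets
#'
#' The eight preoperative features (Cr, BS, Alb, HbA1C, Age, BMI, Hct, CCB)
#' and the six intraoperative anesthesia parameters used throughout the
#' pipeline. These are the defaults regardless of what a re-ranking on a
#' user's own cohort returns, so the pipeline schema is stable.
#'
#' @return character vector of column names.
#' @export
canonical_preop_features <- function() PREOP_FEATURES

#' @rdname canonical_preop_features
#' @export
canonical_plan_params <- function() PLAN_PARAMS

#' Rank features by gradient-boosted-tree importance
#'
#' Fits a gradient-boosted tree classifier (xgboost; fixed depth, number of
#' trees, learning rate, single thread) of the binary AKI label on the feature
#' table and returns gain-based importances sorted non-increasingly, ties
#' broken by column order. Missing cells are handled natively by
#' default-direction splits, so no imputation happens at this stage. Features
#' never used in a split (e.g. constant columns) score exactly 0.
#'
#' @param X `data.frame` or matrix of numeric features.
#' @param y binary labels: 0/1, logical, or `"AKI+"`/`"AKI-"`.
#' @param params list overriding `max_depth` (3), `nrounds` (200),
#'   `eta` (0.1).
#' @param seed integer seed.
#' @param selection_k number of top features the ranking selects.
#' @return object of class `feature_ranking`: `data.frame` of
#'   (`feature`, `importance`) plus attributes `selection_k`, `selected`.
#' @export
rank_features <- function(X, y, params = list(), seed = 7L,
                          selection_k = min(8L, ncol(X))) {
  X <- as.data.frame(X)
  if (any(vapply(X, function(col) all(is.na(col)), logical(1))))
    stop("all-missing feature column(s) present", call. = FALSE)
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "AKI+"
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  stopifnot(length(y) == nrow(X))

  p <- list(max_depth = 3L, nrounds = 200L, eta = 0.1)
  p[names(params)] <- params

  mx <- as.matrix(X)
  storage.mode(mx) <- "double"
  dtrain <- xgboost::xgb.DMatrix(mx, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = p$max_depth,
                  eta = p$eta, nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = p$nrounds, verbose = 0)

  imp <- xgboost::xgb.importance(model = booster)
  gain <- stats::setNames(rep(0, ncol(X)), colnames(X))
  gain[imp$Feature] <- imp$Gain
  # stable sort: ties keep column order
  ord <- order(-gain, seq_along(gain))
  ranking <- data.frame(feature = names(gain)[ord],
                        importance = unname(gain[ord]),
                        stringsAsFactors = FALSE)
  structure(ranking, class = c("feature_ranking", "data.frame"),
            selection_k = as.integer(selection_k),
            selected = ranking$feature[seq_len(selection_k)])
}

#' @export
print.feature_ranking <- function(x, ...) {
  k <- attr(x, "selection_k")
  cat(sprintf("Feature ranking (gain importance), top %d selected:\n", k))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Reduce a table to the selected feature columns
#'
#' Returns the top-k ranked columns, reordered into canonical column order
#' (the order the columns appear in the input table).
#'
#' @param cohort `data.frame` containing at least the selected columns.
#' @param ranking a [rank_features()] result, or a character vector of
#'   selected column names.
#' @return the reduced `data.frame`, preserving row names.
#' @export
select_columns <- function(cohort, ranking) {
  selected <- if (is.character(ranking)) ranking else attr(ranking, "selected")
  missing_cols <- setdiff(selected, names(cohort))
  if (length(missing_cols))
    stop("column(s) absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- names(cohort)[names(cohort) %in% selected]
  cohort[, keep, drop = FALSE]
}
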