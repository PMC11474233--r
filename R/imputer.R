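#' Fit a simple training-set imputer
#'
#' Learns deterministic per-column fill values on the training partition:
#' the median for continuous columns and the mode for binary (0/1) columns,
#' with ties on the mode broken toward the smaller value.
#'
#' @param train_table `data.frame` of numeric feature columns.
#' @return object of class `aki_imputer` (named list of fill values).
#' @export
fit_imputer <- function(train_table) {
  stopifnot(is.data.frame(train_table))
  fills <- lapply(names(train_table), function(nm) {
    x <- train_table[[nm]]
    obs <- x[!is.na(x)]
    if (!length(obs))
      stop("feature '", nm, "' has no observed training values",
           call. = FALSE)
    if (all(obs %in% c(0, 1))) {
      # mode; ties -> 0
      if (mean(obs) > 0.5) 1 else 0
    } else stats::median(obs)
  })
  structure(stats::setNames(fills, names(train_table)),
            class = "aki_imputer")
}

#' Apply an imputer
#'
#' @param imputer an [fit_imputer()] result.
#' @param table `data.frame`; columns without a learned fill are left as-is.
#' @return the table with every `NA` in a learned column replaced.
#' @export
apply_imputer <- function(imputer, table) {
  stopifnot(inherits(imputer, "aki_imputer"), is.data.frame(table))
  for (nm in intersect(names(imputer), names(table))) {
    idx <- is.na(table[[nm]])
    if (any(idx)) table[[nm]][idx] <- imputer[[nm]]
  }
  table
}
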