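#' Planner architecture configuration
#'
#' Both planners share one architecture: a feed-forward regression network
#' with two rectified hidden layers (16 then 8 units) between the 8-feature
#' input and 6-parameter linear output, trained by full-batch adaptive
#' gradient descent (Adam) on mean squared error over standardized targets,
#' with early stopping on a 10% validation slice. All knobs live here so the
#' architecture is overridable in one place.
#'
#' @param hidden integer vector of hidden-layer widths.
#' @param lr learning rate.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param val_frac fraction of the stratum held out for early stopping.
#' @param weight_decay L2 penalty on the layer weights (not biases).
#' @return a named list.
#' @export
planner_arch <- function(hidden = c(16L, 8L), lr = 0.01,
                         max_epochs = 2000L, patience = 50L,
                         val_frac = 0.1, weight_decay = 1e-4) {
  stopifnot(all(hidden >= 1), lr > 0, max_epochs >= 1, patience >= 1,
            val_frac > 0, val_frac < 0.5, weight_decay >= 0)
  list(hidden = as.integer(hidden), lr = lr,
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       val_frac = val_frac, weight_decay = weight_decay)
}

# affine scaler over columns; degenerate SDs replaced by 1 so the transform
# stays invertible
fit_scaler <- function(mat) {
  mu <- colMeans(mat)
  sd <- apply(mat, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}
scale_apply <- function(scaler, mat) {
  sweep(sweep(mat, 2, scaler$mean[colnames(mat)], "-"),
        2, scaler$sd[colnames(mat)], "/")
}
scale_invert <- function(scaler, mat) {
  sweep(sweep(mat, 2, scaler$sd[colnames(mat)], "*"),
        2, scaler$mean[colnames(mat)], "+")
}

#' Train a stratum planner
#'
#' Fits the regression network of [planner_arch()] on one AKI stratum,
#' mapping the eight preoperative features to the six anesthesia parameters.
#' Inputs and targets are standardized by scalers frozen on the training
#' stratum (binary targets enter as 0/1). Training is seeded end-to-end:
#' the same records, architecture and seed give identical weights.
#'
#' @param stratum_records `data.frame` holding the preop feature columns and
#'   plan parameter columns for one stratum, already imputed (no `NA`).
#' @param stratum `"AKI+"` or `"AKI-"` (defaults to the records' `Group`
#'   value when present).
#' @param arch a [planner_arch()].
#' @param seed integer seed.
#' @param plan_ranges named list of `c(min, max)` clip ranges applied to the
#'   continuous predictions (defaults to the ranges of
#'   [default_plan_specs()]).
#' @return object of class `planner_model`.
#' @export
train_planner <- function(stratum_records, stratum = NULL,
                          arch = planner_arch(), seed = 7L,
                          plan_ranges = NULL) {
  stopifnot(is.data.frame(stratum_records))
  need <- c(PREOP_FEATURES, PLAN_PARAMS)
  missing_cols <- setdiff(need, names(stratum_records))
  if (length(missing_cols))
    stop("stratum records lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(stratum_records) < 20L)
    stop("need at least 20 records to train a planner", call. = FALSE)
  X <- as.matrix(stratum_records[, PREOP_FEATURES])
  Y <- as.matrix(stratum_records[, PLAN_PARAMS])
  if (anyNA(X) || anyNA(Y))
    stop("records must be imputed before training (NA present)",
         call. = FALSE)
  if (is.null(stratum))
    stratum <- if ("Group" %in% names(stratum_records))
      unique(stratum_records$Group)[1] else "unlabeled"

  if (is.null(plan_ranges)) {
    sp <- default_plan_specs()
    plan_ranges <- lapply(sp[PLAN_CONTINUOUS],
                          function(s) c(s$min, s$max))
  }

  input_scaler <- fit_scaler(X)
  output_scaler <- fit_scaler(Y)
  Xs <- scale_apply(input_scaler, X)
  Ys <- scale_apply(output_scaler, Y)

  fit <- mlp_train(Xs, Ys, hidden = arch$hidden, seed = seed, lr = arch$lr,
                   max_epochs = arch$max_epochs, patience = arch$patience,
                   val_frac = arch$val_frac,
                   weight_decay = if (is.null(arch$weight_decay)) 1e-4
                                  else arch$weight_decay)

  structure(
    list(stratum = stratum,
         input_scaler = input_scaler,
         output_scaler = output_scaler,
         layers = fit$layers,
         plan_ranges = plan_ranges,
         arch = arch,
         training_meta = list(n = nrow(X), epochs = fit$epochs,
                              val_loss = fit$val_loss,
                              loss_curve = fit$loss_curve, seed = seed)),
    class = "planner_model")
}

#' @export
print.planner_model <- function(x, ...) {
  cat(sprintf("Planner model [%s]: 8 -> %s -> 6\n", x$stratum,
              paste(x$arch$hidden, collapse = " -> ")))
  cat(sprintf("  trained on %d records, %d epochs, val MSE %.4g (seed %d)\n",
              x$training_meta$n, x$training_meta$epochs,
              x$training_meta$val_loss, x$training_meta$seed))
  invisible(x)
}

#' Predict an anesthesia plan for a patient
#'
#' Runs the planner on one or more preoperative feature vectors. Continuous
#' parameters are inverse-scaled to their clinical units and clipped to the
#' configured plausible ranges, with CPB time additionally capped at the
#' predicted anesthesia time. Binary parameters are reported both as a
#' probability in \[0, 1\] (columns `PC`, `FFP`) and thresholded at 0.5
#' (columns `PC_flag`, `FFP_flag`).
#'
#' @param model a [train_planner()] result.
#' @param preop named numeric vector of the 8 preop features, or a
#'   `data.frame` containing those columns.
#' @return `data.frame`, one row per input patient.
#' @export
predict_plan <- function(model, preop) {
  stopifnot(inherits(model, "planner_model"))
  if (is.numeric(preop) && is.null(dim(preop))) {
    if (length(preop) != length(PREOP_FEATURES))
      stop("preop vector must have 8 components", call. = FALSE)
    if (is.null(names(preop))) names(preop) <- PREOP_FEATURES
    preop <- as.data.frame(as.list(preop))
  }
  missing_cols <- setdiff(PREOP_FEATURES, names(preop))
  if (length(missing_cols))
    stop("preop input lacks: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(preop[, PREOP_FEATURES, drop = FALSE])
  if (anyNA(X) || any(!is.finite(X)))
    stop("preop input must be finite and imputed", call. = FALSE)

  Ys <- mlp_predict(model$layers, scale_apply(model$input_scaler, X))
  colnames(Ys) <- PLAN_PARAMS
  Y <- scale_invert(model$output_scaler, Ys)
  for (pm in PLAN_CONTINUOUS) {
    r <- model$plan_ranges[[pm]]
    Y[, pm] <- clip(Y[, pm], r[1], r[2])
  }
  Y[, "CPBTime"] <- pmin(Y[, "CPBTime"], Y[, "AnesthesiaTime"])
  for (pm in PLAN_BINARY) Y[, pm] <- clip(Y[, pm], 0, 1)
  out <- as.data.frame(Y)
  for (pm in PLAN_BINARY) out[[paste0(pm, "_flag")]] <-
    as.integer(out[[pm]] >= 0.5)
  out
}

#' Persist / reload a planner as JSON
#'
#' The full model (scalers, layer weights, architecture, clip ranges,
#' training metadata) is written as plain JSON at full numeric precision, so
#' any runtime can reload it and predictions round-trip exactly.
#'
#' @param model a `planner_model`.
#' @param path file path.
#' @return `load_planner` returns the `planner_model`.
#' @export
save_planner <- function(model, path) {
  stopifnot(inherits(model, "planner_model"))
  obj <- unclass(model)
  obj$layers <- lapply(obj$layers, function(l)
    list(W = l$W, b = l$b, dim = dim(l$W)))
  for (s in c("input_scaler", "output_scaler")) {
    obj[[s]]$mean <- as.list(obj[[s]]$mean)   # keep names in JSON objects
    obj[[s]]$sd <- as.list(obj[[s]]$sd)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_planner
#' @export
load_planner <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  obj$layers <- lapply(obj$layers, function(l) {
    W <- matrix(unlist(l$W), nrow = l$dim[1], ncol = l$dim[2])
    list(W = W, b = as.numeric(l$b))
  })
  for (s in c("input_scaler", "output_scaler")) {
    obj[[s]]$mean <- unlist(obj[[s]]$mean)
    obj[[s]]$sd <- unlist(obj[[s]]$sd)
  }
  obj$plan_ranges <- lapply(obj$plan_ranges, as.numeric)
  structure(obj, class = "planner_model")
}
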