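#' Fit the plan-space scaler
#'
#' Per-parameter mean and SD computed on the pooled training plans. Distances
#' between plans are measured in this z-scored space so minutes on bypass do
#' not dominate liters of crystalloid. Degenerate SDs are replaced by 1.
#'
#' @param plans `data.frame` or matrix with the six plan parameter columns.
#' @return object of class `plan_scaler`.
#' @export
fit_plan_scaler <- function(plans) {
  plans <- as.data.frame(plans)
  missing_cols <- setdiff(PLAN_PARAMS, names(plans))
  if (length(missing_cols))
    stop("plans lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  structure(fit_scaler(as.matrix(plans[, PLAN_PARAMS])),
            class = "plan_scaler")
}

plan_to_z <- function(scaler, plan) {
  if (!inherits(scaler, "plan_scaler"))
    stop("scaler is not fitted (expected a plan_scaler)", call. = FALSE)
  plan <- as.data.frame(plan)[, PLAN_PARAMS, drop = FALSE]
  scale_apply(unclass(scaler), as.matrix(plan))
}

#' Locate a plan relative to the two planners
#'
#' The risk point of an anesthesia plan is the pair of Euclidean distances,
#' in the z-scored 6-parameter plan space, from the plan to the AKI- planner
#' prediction (`d_minus`, horizontal axis) and to the AKI+ planner prediction
#' (`d_plus`, vertical axis). Binary parameters enter with their continuous
#' predicted probabilities.
#'
#' @param plan the evaluated plan (one-row `data.frame` or named vector
#'   with the six parameter columns).
#' @param pred_minus,pred_plus the two planners' predictions for the same
#'   patient.
#' @param scaler a [fit_plan_scaler()] result.
#' @return object of class `risk_point`: list with `d_minus`, `d_plus`.
#' @export
risk_point <- function(plan, pred_minus, pred_plus, scaler) {
  as_row <- function(p) {
    if (is.numeric(p) && is.null(dim(p))) p <- as.data.frame(as.list(p))
    p
  }
  z <- plan_to_z(scaler, as_row(plan))
  zm <- plan_to_z(scaler, as_row(pred_minus))
  zp <- plan_to_z(scaler, as_row(pred_plus))
  structure(list(d_minus = sqrt(sum((z - zm)^2)),
                 d_plus = sqrt(sum((z - zp)^2))),
            class = "risk_point")
}

#' @export
print.risk_point <- function(x, ...) {
  cat(sprintf("risk point: d- = %.4f, d+ = %.4f (%s)\n",
              x$d_minus, x$d_plus, classify_risk(x)))
  invisible(x)
}

#' Classify a risk point by the y = x rule
#'
#' Plans below the y = x line (at least as close to the AKI+ prototype as to
#' the AKI- prototype) are classified AKI+; plans above it AKI-. Ties on the
#' line are conservatively flagged AKI+.
#'
#' @param point a [risk_point()] (or anything with `d_minus`/`d_plus`).
#' @return `"AKI+"` or `"AKI-"`.
#' @export
classify_risk <- function(point) {
  if (point$d_plus <= point$d_minus) "AKI+" else "AKI-"
}

#' Confusion-matrix metrics with the truncation convention
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), accuracy = (TP+TN)/n (all 0
#' when their denominator is 0), each reported at 3 decimals. F1 is the
#' harmonic mean of the already-3-decimal precision and recall, itself then
#' reported at 3 decimals. The default mode truncates rather than rounds:
#' that is the only convention under which published 3-decimal
#' precision/recall/accuracy/F1 rows of this design are jointly consistent.
#'
#' @param TP,FP,FN,TN non-negative integer cell counts.
#' @param mode `"truncate"` (default) or `"round"`.
#' @return named list: `precision`, `recall`, `accuracy`, `f1`.
#' @export
#' @examples
#' compute_metrics(67, 17, 12, 54)  # precision 0.797, recall 0.848,
#'                                  # accuracy 0.806, F1 0.821
compute_metrics <- function(TP, FP, FN, TN, mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  TP <- unname(TP); FP <- unname(FP); FN <- unname(FN); TN <- unname(TN)
  cells <- c(TP, FP, FN, TN)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("confusion-matrix cells must be non-negative integers",
         call. = FALSE)
  n <- sum(cells)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den) if (den == 0) 0 else num / den
  precision <- three_dp(div(TP, TP + FP), mode)
  recall <- three_dp(div(TP, TP + FN), mode)
  accuracy <- three_dp(div(TP + TN, n), mode)
  f1 <- three_dp(div(2 * precision * recall, precision + recall), mode)
  list(precision = precision, recall = recall, accuracy = accuracy, f1 = f1)
}

#' Evaluate the dual-planner classifier on labeled records
#'
#' For every record, both planners predict the plan its preoperative features
#' imply; the administered plan's risk point is computed and classified by
#' the y = x rule; predictions are tallied against the recorded group
#' (AKI+ is the positive class).
#'
#' @param model_minus,model_plus trained [train_planner()] models for the
#'   AKI- and AKI+ strata.
#' @param records labeled, imputed cohort `data.frame`.
#' @param scaler a [fit_plan_scaler()].
#' @param mode metric reporting mode, see [compute_metrics()].
#' @return object of class `eval_report`: confusion counts, metrics, and a
#'   `scatter` `data.frame` (`patient_id`, `d_minus`, `d_plus`, `truth`,
#'   `prediction`).
#' @export
evaluate_planners <- function(model_minus, model_plus, records, scaler,
                              mode = "truncate") {
  if (!nrow(records)) stop("no records to evaluate", call. = FALSE)
  pred_m <- predict_plan(model_minus, records)
  pred_p <- predict_plan(model_plus, records)
  z <- plan_to_z(scaler, records)
  zm <- plan_to_z(scaler, pred_m)
  zp <- plan_to_z(scaler, pred_p)
  d_minus <- sqrt(rowSums((z - zm)^2))
  d_plus <- sqrt(rowSums((z - zp)^2))
  prediction <- ifelse(d_plus <= d_minus, "AKI+", "AKI-")
  truth <- records$Group
  TP <- sum(truth == "AKI+" & prediction == "AKI+")
  FP <- sum(truth == "AKI-" & prediction == "AKI+")
  FN <- sum(truth == "AKI+" & prediction == "AKI-")
  TN <- sum(truth == "AKI-" & prediction == "AKI-")
  structure(
    list(confusion = c(TP = TP, FP = FP, FN = FN, TN = TN),
         metrics = compute_metrics(TP, FP, FN, TN, mode),
         scatter = data.frame(patient_id = records$patient_id,
                              d_minus = d_minus, d_plus = d_plus,
                              truth = truth, prediction = prediction,
                              stringsAsFactors = FALSE)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cm <- x$confusion
  cat("Dual-planner evaluation (positive class AKI+)\n")
  cat(sprintf("  n = %d   TP %d  FP %d  FN %d  TN %d\n", sum(cm),
              cm["TP"], cm["FP"], cm["FN"], cm["TN"]))
  with(x$metrics, cat(sprintf(
    "  precision %.3f  recall %.3f  accuracy %.3f  F1 %.3f\n",
    precision, recall, accuracy, f1)))
  invisible(x)
}

# seeded k-means++ initial centers on a z-scored matrix
kmeanspp_init <- function(Z, k, seed) {
  with_seed(seed, {
    n <- nrow(Z)
    centers <- matrix(NA_real_, k, ncol(Z))
    centers[1, ] <- Z[sample.int(n, 1L), ]
    if (k > 1L) for (j in 2:k) {
      d2 <- apply(Z, 1, function(row)
        min(colSums((t(centers[seq_len(j - 1L), , drop = FALSE]) - row)^2)))
      if (sum(d2) == 0) {
        centers[j, ] <- Z[sample.int(n, 1L), ]
      } else {
        centers[j, ] <- Z[sample.int(n, 1L, prob = d2 / sum(d2)), ]
      }
    }
    centers
  })
}

#' Candidate treatments by k-means on administered plans
#'
#' Clusters the z-scored administered plans (Lloyd iterations from seeded
#' k-means++ initial centers, at most 300 iterations) and labels each cluster
#' low-risk or high-risk by the majority AKI stratum of its members. Centers
#' are reported back in clinical units together with a presentation range
#' (center +/- within-cluster SD) and the binary parameters thresholded at
#' 0.5 into Received / Not received.
#'
#' @param plans `data.frame` of administered plans (six parameter columns).
#' @param strata character vector of the plans' AKI groups.
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @return object of class `treatment_clusters`: list of clusters with
#'   `center`, `range_lo`, `range_hi`, `member_count`, `label`, plus the
#'   assignment vector as attribute `"assignment"`.
#' @export
kmeans_treatments <- function(plans, strata, k = 3L, seed = 7L) {
  plans <- as.data.frame(plans)[, PLAN_PARAMS, drop = FALSE]
  stopifnot(length(strata) == nrow(plans))
  Z <- plan_to_z(fit_plan_scaler(plans), plans)
  if (nrow(unique(as.data.frame(Z))) < k)
    stop("need at least k distinct plans to form k clusters", call. = FALSE)
  init <- kmeanspp_init(Z, k, seed)
  km <- stats::kmeans(Z, centers = init, iter.max = 300L,
                      algorithm = "Lloyd")
  scaler <- fit_plan_scaler(plans)
  centers_raw <- scale_invert(unclass(scaler), km$centers)
  colnames(centers_raw) <- PLAN_PARAMS
  clusters <- lapply(seq_len(k), function(j) {
    members <- which(km$cluster == j)
    sub <- plans[members, , drop = FALSE]
    wsd <- apply(sub, 2, function(x) if (length(x) > 1) stats::sd(x) else 0)
    maj <- names(which.max(table(strata[members])))
    list(center = stats::setNames(as.numeric(centers_raw[j, ]), PLAN_PARAMS),
         range_lo = stats::setNames(as.numeric(centers_raw[j, ]) - wsd,
                                    PLAN_PARAMS),
         range_hi = stats::setNames(as.numeric(centers_raw[j, ]) + wsd,
                                    PLAN_PARAMS),
         member_count = length(members),
         label = if (identical(maj, "AKI-")) "low-risk" else "high-risk")
  })
  structure(clusters, class = "treatment_clusters",
            assignment = km$cluster)
}

#' @export
print.treatment_clusters <- function(x, ...) {
  cat(sprintf("Candidate treatments (%d clusters)\n", length(x)))
  for (j in seq_along(x)) {
    cl <- x[[j]]
    cat(sprintf("  Treatment %d [%s, n = %d]\n", j, cl$label,
                cl$member_count))
    for (pm in PLAN_CONTINUOUS)
      cat(sprintf("    %-16s %.0f - %.0f\n", pm,
                  cl$range_lo[pm], cl$range_hi[pm]))
    for (pm in PLAN_BINARY)
      cat(sprintf("    %-16s %s\n", pm,
                  if (cl$center[pm] >= 0.5) "Received" else "Not received"))
  }
  invisible(x)
}

#' Majority vote over three raters' treatment choices
#'
#' @param votes length-3 vector of treatment identifiers (one per rater).
#' @return list with `choice` and logical `tie`; a 1-1-1 three-way tie
#'   returns the first-listed rater's vote with `tie = TRUE`.
#' @export
majority_vote <- function(votes) {
  if (!length(votes)) stop("no votes", call. = FALSE)
  if (length(votes) != 3L)
    stop("majority vote is defined over exactly 3 raters", call. = FALSE)
  tab <- table(factor(votes, levels = unique(votes)))
  if (max(tab) == 1L) {
    list(choice = votes[[1L]], tie = TRUE)
  } else {
    list(choice = names(tab)[which.max(tab)], tie = FALSE)
  }
}

#' Compare an administered plan with a proposed revision
#'
#' Computes the risk points R1 (before) and R2 (after) of the two plans for
#' the same patient and reports whether the revision improved: the point
#' moved toward/above the y = x line, i.e. the safety margin
#' `d_plus - d_minus` strictly increased.
#'
#' @param patient one-row `data.frame` with the preop feature columns.
#' @param plan_before,plan_after the two plans.
#' @param model_minus,model_plus the trained planners.
#' @param scaler a [fit_plan_scaler()].
#' @return list with `R1`, `R2` (risk points) and logical `improved`.
#' @export
plan_shift <- function(patient, plan_before, plan_after,
                       model_minus, model_plus, scaler) {
  pm <- predict_plan(model_minus, patient)
  pp <- predict_plan(model_plus, patient)
  R1 <- risk_point(plan_before, pm, pp, scaler)
  R2 <- risk_point(plan_after, pm, pp, scaler)
  list(R1 = R1, R2 = R2,
       improved = (R2$d_plus - R2$d_minus) > (R1$d_plus - R1$d_minus))
}

#' Recommend low-risk anesthesia plans for a patient
#'
#' Evaluates the AKI- planner's own prediction plus a seeded random scan of
#' the slider box (uniform draws for continuous parameters, fair coin for the
#' binary transfusion flags) and ranks candidates by descending safety margin
#' `d_plus - d_minus`. Margins above zero are tagged low-risk, the rest
#' high-risk, mirroring the recommender software's two boxes.
#'
#' @param patient one-row `data.frame` of preop features.
#' @param model_minus,model_plus the trained planners.
#' @param scaler a [fit_plan_scaler()].
#' @param slider_ranges named list of `c(min, max)` per continuous parameter
#'   (defaults to the planner's clip ranges).
#' @param grid_density number of random candidates scanned.
#' @param seed integer seed.
#' @return `data.frame` of candidate plans with `margin`, `risk` tag and
#'   `source` (`"planner"` or `"scan"`), sorted by descending margin.
#' @export
recommend_plans <- function(patient, model_minus, model_plus, scaler,
                            slider_ranges = NULL, grid_density = 500L,
                            seed = 7L) {
  if (is.null(slider_ranges)) slider_ranges <- model_minus$plan_ranges
  if (!all(PLAN_CONTINUOUS %in% names(slider_ranges)))
    stop("slider_ranges must bound every continuous parameter",
         call. = FALSE)
  widths <- vapply(slider_ranges[PLAN_CONTINUOUS],
                   function(r) r[2] - r[1], numeric(1))
  if (any(widths <= 0)) stop("empty slider box", call. = FALSE)

  pred_m <- predict_plan(model_minus, patient)
  pred_p <- predict_plan(model_plus, patient)

  cand <- with_seed(seed, {
    cont <- lapply(PLAN_CONTINUOUS, function(pm) {
      r <- slider_ranges[[pm]]
      stats::runif(grid_density, r[1], r[2])
    })
    names(cont) <- PLAN_CONTINUOUS
    bin <- lapply(PLAN_BINARY, function(pm)
      stats::rbinom(grid_density, 1L, 0.5))
    names(bin) <- PLAN_BINARY
    as.data.frame(c(cont, bin))[, PLAN_PARAMS]
  })
  cand$CPBTime <- pmin(cand$CPBTime, cand$AnesthesiaTime)
  cand$source <- "scan"
  own <- pred_m[, PLAN_PARAMS]
  own$source <- "planner"
  cand <- rbind(own, cand)

  z <- plan_to_z(scaler, cand)
  zm <- plan_to_z(scaler, pred_m)[rep(1, nrow(cand)), , drop = FALSE]
  zp <- plan_to_z(scaler, pred_p)[rep(1, nrow(cand)), , drop = FALSE]
  cand$d_minus <- sqrt(rowSums((z - zm)^2))
  cand$d_plus <- sqrt(rowSums((z - zp)^2))
  cand$margin <- cand$d_plus - cand$d_minus
  cand$risk <- ifelse(cand$margin > 0, "low-risk", "high-risk")
  cand[order(-cand$margin), , drop = FALSE]
}
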