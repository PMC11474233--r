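test_that("risk points match hand Euclidean geometry on a unit-SD toy", {
  sc <- unit_scaler()
  base <- c(AnesthesiaTime = 100, CPBTime = 50, DiureticDose = 10,
            CrystalloidDose = 1, PC = 0, FFP = 0)
  plan <- make_plan(base)
  pm <- make_plan(replace(base, "AnesthesiaTime", 103))  # 3 away
  pp <- make_plan(replace(base, "CrystalloidDose", 5))   # 4 away
  rp <- risk_point(plan, pm, pp, sc)
  expect_equal(rp$d_minus, 3.0)
  expect_equal(rp$d_plus, 4.0)
  # identity and symmetry
  expect_equal(risk_point(plan, plan, pp, sc)$d_minus, 0)
  left <- make_plan(replace(base, "CPBTime", 48))
  right <- make_plan(replace(base, "CPBTime", 52))
  sym <- risk_point(plan, left, right, sc)
  expect_equal(sym$d_minus, sym$d_plus)
  expect_error(risk_point(plan, pm, pp, scaler = list(mean = 0)),
               "not fitted")
})

test_that("the y = x rule classifies below-line as AKI+, ties conservatively", {
  expect_identical(classify_risk(list(d_minus = 2, d_plus = 1)), "AKI+")
  expect_identical(classify_risk(list(d_minus = 1, d_plus = 2)), "AKI-")
  expect_identical(classify_risk(list(d_minus = 1, d_plus = 1)), "AKI+")
})

test_that("classifier is equivalent to brute-force nearest-prototype on random fixtures", {
  sc <- unit_scaler()
  set.seed(77)
  for (i in 1:1000) {
    v <- matrix(rnorm(18, 0, 3), 3, 6,
                dimnames = list(NULL, plan_names))
    plan <- make_plan(v[1, ]); pm <- make_plan(v[2, ]); pp <- make_plan(v[3, ])
    got <- classify_risk(risk_point(plan, pm, pp, sc))
    # independent oracle: argmin over the two prototypes in z-space
    d2m <- sum((v[1, ] - v[2, ])^2); d2p <- sum((v[1, ] - v[3, ])^2)
    want <- if (d2p <= d2m) "AKI+" else "AKI-"
    expect_identical(got, want)
    if (got != want) break
  }
})

test_that("distances are invariant to unit rescaling and parameter permutation", {
  set.seed(31)
  plans <- as.data.frame(matrix(rnorm(40 * 6, 100, 15), 40, 6,
                                dimnames = list(NULL, plan_names)))
  plan <- plans[1, ]; pm <- plans[2, ]; pp <- plans[3, ]
  sc <- fit_plan_scaler(plans)
  rp <- risk_point(plan, pm, pp, sc)

  # multiply one raw parameter's unit by a constant and refit the scaler
  rescale <- function(df, col, f) { df[[col]] <- df[[col]] * f; df }
  plans2 <- rescale(plans, "CPBTime", 60)
  sc2 <- fit_plan_scaler(plans2)
  rp2 <- risk_point(rescale(plan, "CPBTime", 60),
                    rescale(pm, "CPBTime", 60),
                    rescale(pp, "CPBTime", 60), sc2)
  expect_equal(rp2$d_minus, rp$d_minus, tolerance = 1e-9)
  expect_equal(rp2$d_plus, rp$d_plus, tolerance = 1e-9)

  # permute the six parameters (columns) everywhere
  perm <- c(4, 2, 6, 1, 3, 5)
  shuffle <- function(df) stats::setNames(df[, perm], plan_names)
  sc3 <- fit_plan_scaler(shuffle(plans))
  rp3 <- risk_point(shuffle(plan), shuffle(pm), shuffle(pp), sc3)
  expect_equal(rp3$d_minus, rp$d_minus, tolerance = 1e-9)

  # and cluster assignments are unchanged under unit rescaling
  strata <- rep(c("AKI-", "AKI+"), 20)
  cl1 <- kmeans_treatments(plans, strata, k = 3, seed = 5)
  cl2 <- kmeans_treatments(plans2, strata, k = 3, seed = 5)
  expect_identical(attr(cl1, "assignment"), attr(cl2, "assignment"))
})

test_that("metrics reproduce the published arithmetic under truncation", {
  m <- compute_metrics(67, 17, 12, 54)
  expect_equal(m$precision, 0.797)
  expect_equal(m$recall, 0.848)
  expect_equal(m$accuracy, 0.806)
  expect_equal(m$f1, 0.821)
  # harmonic mean of already-truncated precision/recall, train-set row
  f1_train <- akiplan:::three_dp(2 * 0.806 * 0.785 / (0.806 + 0.785),
                                 "truncate")
  expect_equal(f1_train, 0.795)
  # degenerate denominators
  z <- compute_metrics(0, 0, 0, 10)
  expect_equal(z, list(precision = 0, recall = 0, accuracy = 1, f1 = 0))
  expect_error(compute_metrics(0, 0, 0, 0), "empty")
  expect_error(compute_metrics(-1, 0, 0, 5), "non-negative")
  # identities on random matrices, both rounding modes
  set.seed(12)
  for (i in 1:50) {
    cm <- as.list(rmultinom(1, 200, c(0.3, 0.2, 0.2, 0.3))[, 1])
    names(cm) <- c("TP", "FP", "FN", "TN")
    for (mode in c("truncate", "round")) {
      mm <- compute_metrics(cm$TP, cm$FP, cm$FN, cm$TN, mode)
      expect_true(all(unlist(mm) >= 0 & unlist(mm) <= 1))
      expect_equal(mm$accuracy,
                   akiplan:::three_dp((cm$TP + cm$TN) / 200, mode))
    }
  }
})

test_that("evaluation tallies the confusion matrix against the truth labels", {
  res <- cached_pipeline(plan_shift = 1.0)
  ev <- res$eval_test
  cm <- ev$confusion
  expect_equal(unname(sum(cm)), nrow(ev$scatter))
  expect_identical(
    unname(cm["TP"]),
    sum(ev$scatter$truth == "AKI+" & ev$scatter$prediction == "AKI+"))
  # classifications in the scatter respect the y = x rule
  expect_identical(ev$scatter$prediction,
                   ifelse(ev$scatter$d_plus <= ev$scatter$d_minus,
                          "AKI+", "AKI-"))
  expect_true(all(ev$scatter$d_minus >= 0 & ev$scatter$d_plus >= 0))
  # a perfectly separable fixture reaches accuracy 1
  res3 <- cached_pipeline(plan_shift = 3.0)
  expect_equal(res3$eval_test$metrics$accuracy, 1.000)
  expect_error(evaluate_planners(res$model_minus, res$model_plus,
                                 res$cohort[0, ], res$scaler),
               "no records")
})

test_that("k-means recovers planted blobs and labels clusters by stratum majority", {
  set.seed(55)
  centers <- rbind(c(340, 110, 30, 1.5, 1, 0),
                   c(380, 135, 50, 2.5, 0, 1),
                   c(300, 90, 25, 1.2, 1, 1))
  colnames(centers) <- plan_names
  n_per <- 60
  noise_sd <- c(4, 3, 2, 0.05, 0.05, 0.05)  # well below the center spread
  plans <- do.call(rbind, lapply(1:3, function(j)
    sweep(matrix(rnorm(n_per * 6), n_per, 6) %*% diag(noise_sd),
          2, centers[j, ], "+")))
  plans <- as.data.frame(plans); names(plans) <- plan_names
  truth <- rep(1:3, each = n_per)
  strata <- ifelse(truth == 2, "AKI+", "AKI-")
  cl <- kmeans_treatments(plans, strata, k = 3, seed = 3)
  expect_length(cl, 3)
  # each recovered center sits close to a distinct true center
  got <- t(vapply(cl, function(x) x$center, numeric(6)))
  matched <- apply(got, 1, function(g)
    which.min(colSums((t(centers) - g)^2)))
  expect_setequal(matched, 1:3)
  for (j in 1:3)
    expect_lt(sqrt(sum(((got[j, ] - centers[matched[j], ]) /
                          apply(plans, 2, sd))^2)), 0.5)
  # the AKI+ blob's cluster is the single high-risk one
  labels <- vapply(cl, function(x) x$label, character(1))
  expect_identical(labels[matched == 2], "high-risk")
  expect_identical(unname(table(labels)["low-risk"]), 2L)
  # k = 1 fixpoint is the component-wise mean
  c1 <- kmeans_treatments(plans, strata, k = 1, seed = 2)
  expect_equal(unname(c1[[1]]$center), unname(colMeans(plans)),
               tolerance = 1e-9)
  dup <- plans[rep(1, 10), ]
  expect_error(kmeans_treatments(dup, rep("AKI-", 10), k = 3), "distinct")
})

test_that("majority vote is modal with the documented three-way tie rule", {
  expect_identical(majority_vote(c("A", "A", "B")),
                   list(choice = "A", tie = FALSE))
  expect_identical(majority_vote(c("C", "C", "C")),
                   list(choice = "C", tie = FALSE))
  expect_identical(majority_vote(c("A", "B", "C")),
                   list(choice = "A", tie = TRUE))
  expect_identical(majority_vote(c("B", "C", "B")),
                   list(choice = "B", tie = FALSE))
  expect_error(majority_vote(character(0)), "no votes")
  expect_error(majority_vote(c("A", "B")), "3 raters")
})

test_that("plan-shift comparison reports margin improvement geometrically", {
  res <- cached_pipeline(plan_shift = 1.0)
  patient <- res$cohort[3, ]
  administered <- patient[, plan_names]
  pm <- predict_plan(res$model_minus, patient)[, plan_names]
  pp <- predict_plan(res$model_plus, patient)[, plan_names]

  # identity: no move, no improvement
  same <- plan_shift(patient, administered, administered,
                     res$model_minus, res$model_plus, res$scaler)
  expect_false(same$improved)
  expect_equal(same$R1$d_minus, same$R2$d_minus)

  # moving onto the AKI- prediction zeroes d_minus and improves whenever the
  # starting margin was beatable
  to_minus <- plan_shift(patient, administered, pm,
                         res$model_minus, res$model_plus, res$scaler)
  expect_equal(to_minus$R2$d_minus, 0)
  margin1 <- to_minus$R1$d_plus - to_minus$R1$d_minus
  margin2 <- to_minus$R2$d_plus - to_minus$R2$d_minus
  expect_identical(to_minus$improved, margin2 > margin1)
  expect_gte(margin2, 0)

  # moving onto the AKI+ prediction lands on/below the line
  to_plus <- plan_shift(patient, administered, pp,
                        res$model_minus, res$model_plus, res$scaler)
  expect_equal(to_plus$R2$d_plus, 0)
  expect_lte(to_plus$R2$d_plus, to_plus$R2$d_minus)
  expect_false(to_plus$improved && (to_plus$R1$d_plus - to_plus$R1$d_minus) >=
                 (to_plus$R2$d_plus - to_plus$R2$d_minus))
})

test_that("the recommender ranks candidates by safety margin", {
  res <- cached_pipeline(plan_shift = 1.0)
  patient <- res$cohort[5, ]
  rec <- recommend_plans(patient, res$model_minus, res$model_plus,
                         res$scaler, grid_density = 200, seed = 9)
  expect_true(all(diff(rec$margin) <= 0))
  expect_identical(rec$risk, ifelse(rec$margin > 0, "low-risk", "high-risk"))
  # the AKI- planner's own prediction has d_minus = 0, margin = d_plus >= 0
  own <- rec[rec$source == "planner", ]
  expect_equal(own$d_minus, 0)
  expect_gte(own$margin, 0)
  expect_identical(own$risk, "low-risk")  # planners do not coincide here
  # hand-placed candidates on the unit toy order by hand-computed margins
  sc <- unit_scaler()
  base <- c(AnesthesiaTime = 0, CPBTime = 0, DiureticDose = 0,
            CrystalloidDose = 0, PC = 0, FFP = 0)
  pm <- make_plan(base)                               # prototype at origin
  pp <- make_plan(replace(base, "CPBTime", 10))       # 10 away
  cands <- list(a = make_plan(replace(base, "CPBTime", 1)),  # margin 8
                b = make_plan(replace(base, "CPBTime", 5)),  # margin 0
                c = make_plan(replace(base, "CPBTime", 9)))  # margin -8
  margins <- vapply(cands, function(p) {
    r <- risk_point(p, pm, pp, sc); r$d_plus - r$d_minus
  }, numeric(1))
  expect_equal(unname(margins), c(8, 0, -8))
  expect_error(recommend_plans(patient, res$model_minus, res$model_plus,
                               res$scaler,
                               slider_ranges = list(AnesthesiaTime = c(1, 1),
                                                    CPBTime = c(0, 1),
                                                    DiureticDose = c(0, 1),
                                                    CrystalloidDose = c(0, 1)),
                               seed = 1),
               "empty slider box")
})
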