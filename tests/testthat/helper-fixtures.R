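# Shared fixtures, all generated in code under fixed seeds.

preop_names <- akiplan::canonical_preop_features()
plan_names <- akiplan::canonical_plan_params()
plan_cont <- setdiff(plan_names, c("PC", "FFP"))

# unbounded clip ranges so planner tests see the raw network output
open_ranges <- stats::setNames(rep(list(c(-1e9, 1e9)), length(plan_cont)),
                               plan_cont)

# A stratum whose targets are a noiseless linear map of the inputs, built to
# respect the plan contracts (CPBTime below AnesthesiaTime, binaries in [0,1])
# so clipping in predict_plan() never binds.
make_linear_stratum <- function(n = 600, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, preop_names))
  B <- matrix(runif(8 * 4, -1, 1), 8, 4)
  Yc <- X %*% B
  colnames(Yc) <- plan_cont
  Yc[, "AnesthesiaTime"] <- Yc[, "AnesthesiaTime"] + 50
  bsmall <- matrix(runif(8 * 2, -0.04, 0.04), 8, 2)
  Yb <- 0.5 + X %*% bsmall            # stays inside [0, 1] with high margin
  colnames(Yb) <- c("PC", "FFP")
  data.frame(X, Yc, Yb, check.names = FALSE)
}

standardized_rmse <- function(model, records) {
  pred <- akiplan::predict_plan(model, records)
  s <- model$output_scaler
  z <- function(m) sweep(sweep(as.matrix(m[, plan_names]), 2,
                               s$mean[plan_names], "-"),
                         2, s$sd[plan_names], "/")
  sqrt(mean((z(records) - z(pred))^2))
}

# a unit-SD plan scaler centered at zero, for hand-geometry tests
unit_scaler <- function() {
  plans <- as.data.frame(matrix(0, 2, length(plan_names),
                                dimnames = list(NULL, plan_names)))
  sc <- akiplan::fit_plan_scaler(plans)  # sd degenerate -> replaced by 1
  sc$mean[] <- 0
  sc
}

make_plan <- function(values) {
  stats::setNames(as.data.frame(as.list(values)), plan_names)
}

# small default cohorts reused across files
small_cohort <- function(n = 200, seed = 11, ...) {
  akiplan::generate_cohort(akiplan::cohort_config(n_patients = n,
                                                  seed = seed, ...))
}

# memoized default-size pipeline runs (shared between the pipeline tests and
# the acceptance suite so the heavy stage runs once per shift)
.pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(plan_shift = 1.0, n = 998, seed = 7) {
  key <- sprintf("s%g_n%d_seed%d", plan_shift, n, seed)
  if (is.null(.pipeline_cache[[key]])) {
    cfg <- akiplan::pipeline_config(
      cohort = akiplan::cohort_config(n_patients = n, plan_shift = plan_shift,
                                      seed = seed),
      seed = seed)
    .pipeline_cache[[key]] <- akiplan::run_pipeline(cfg)
  }
  .pipeline_cache[[key]]
}
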