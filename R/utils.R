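#' @keywords internal
"_PACKAGE"

# Canonical column sets used across modules
PREOP_FEATURES <- c("Age", "BMI", "CCB", "Cr", "Alb", "BS", "HbA1C", "Hct")
PLAN_PARAMS <- c("AnesthesiaTime", "CPBTime", "DiureticDose",
                 "CrystalloidDose", "PC", "FFP")
PLAN_BINARY <- c("PC", "FFP")
PLAN_CONTINUOUS <- setdiff(PLAN_PARAMS, PLAN_BINARY)
COHORT_COLUMNS <- c("patient_id", PREOP_FEATURES, PLAN_PARAMS,
                    "Cr_day1", "Cr_day7", "Group")

#' Truncate or round to three decimals
#'
#' Published evaluation tables in this area are only jointly consistent when
#' precision/recall/accuracy are truncated (not rounded) at the third decimal,
#' so truncation is the package default wherever metrics are reported.
#'
#' @param x numeric vector.
#' @param mode `"truncate"` or `"round"`.
#' @return numeric vector at 3-decimal resolution.
#' @keywords internal
three_dp <- function(x, mode = c("truncate", "round")) {
  mode <- match.arg(mode)
  if (mode == "round") return(round(x, 3))
  # small epsilon guards against 0.806 stored as 0.80599999...
  trunc(x * 1000 + 1e-9 * sign(x)) / 1000
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive per-stage seeds from a single root seed
#'
#' All randomness in the pipeline flows from one root seed; each named stage
#' gets a deterministic sub-seed so stages can be re-run independently.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return a single integer seed.
#' @export
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  # cheap string hash folded with the root seed, kept inside 32-bit range
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root_seed) * 7919 + h * 104729) %% 2147483647L)
}

# run expr under a seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_stage <- function(stage, msg, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(msg, ...)), call. = FALSE)
}

log_msg <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}
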