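#' KDIGO serum-creatinine stage of postoperative kidney injury
#'
#' Applies the KDIGO 2012 serum-creatinine bands, comparing a postoperative
#' creatinine against the preoperative baseline:
#' stage 3 if the ratio reaches 3.0x, or the postoperative value reaches
#' 4.0 mg/dL with an absolute rise of at least 0.3 mg/dL; stage 2 if the ratio
#' reaches 2.0x; stage 1 if the ratio reaches 1.5x or the absolute rise is at
#' least 0.3 mg/dL; stage 0 otherwise. Urine-output and renal-replacement
#' criteria are out of scope (no such data in the schema).
#'
#' @param cr_baseline preoperative serum creatinine, mg/dL (vectorized).
#' @param cr_post postoperative serum creatinine, mg/dL.
#' @return integer stage(s) in 0-3.
#' @export
#' @examples
#' kdigo_stage(1.0, c(1.0, 1.6, 2.2, 3.5))
kdigo_stage <- function(cr_baseline, cr_post) {
  if (any(!is.finite(cr_baseline)) || any(!is.finite(cr_post)) ||
      any(cr_baseline <= 0) || any(cr_post <= 0))
    stop("creatinine values must be positive and finite", call. = FALSE)
  ratio <- cr_post / cr_baseline
  rise <- cr_post - cr_baseline
  stage <- integer(length(ratio))
  stage[ratio >= 1.5 | rise >= 0.3] <- 1L
  stage[ratio >= 2.0] <- 2L
  stage[ratio >= 3.0 | (cr_post >= 4.0 & rise >= 0.3)] <- 3L
  stage
}

#' Assign the AKI group from the creatinine trajectory
#'
#' A patient is AKI+ if kidney injury (KDIGO stage >= 1 against the
#' preoperative baseline) is present on postoperative day 1 or day 7, and
#' AKI- only if both days are stage 0.
#'
#' @param cr_baseline,cr_day1,cr_day7 serum creatinine, mg/dL (vectorized).
#' @return character vector of `"AKI+"` / `"AKI-"`.
#' @export
assign_group <- function(cr_baseline, cr_day1, cr_day7) {
  s <- pmax(kdigo_stage(cr_baseline, cr_day1),
            kdigo_stage(cr_baseline, cr_day7))
  ifelse(s >= 1L, "AKI+", "AKI-")
}

#' Stratified train/test split
#'
#' Splits each AKI stratum separately so prevalence is matched between
#' partitions. Per stratum the training set gets `floor(train_fraction * n)`
#' records and the remainder goes to testing; with the published strata
#' (472 AKI-, 526 AKI+) and an 85/15 ratio this reproduces 401/71 and 447/79.
#'
#' @param cohort cohort `data.frame` with `patient_id` and `Group` columns.
#' @param train_fraction fraction assigned to training, default 0.85.
#' @param seed integer seed randomizing stratum membership.
#' @return `data.frame` with columns `patient_id`, `partition`
#'   (`"train"`/`"test"`), `stratum`.
#' @export
stratified_split <- function(cohort, train_fraction = 0.85, seed = 7L) {
  stopifnot(is.data.frame(cohort),
            all(c("patient_id", "Group") %in% names(cohort)))
  if (any(is.na(cohort$Group)))
    stop("every record must carry a group label", call. = FALSE)
  stopifnot(train_fraction >= 0, train_fraction <= 1)
  out <- lapply(c("AKI-", "AKI+"), function(g) {
    ids <- cohort$patient_id[cohort$Group == g]
    if (!length(ids)) {
      warning("empty stratum: ", g, call. = FALSE)
      return(data.frame(patient_id = character(0), partition = character(0),
                        stratum = character(0), stringsAsFactors = FALSE))
    }
    n_train <- floor(train_fraction * length(ids))
    shuffled <- with_seed(derive_seed(seed, paste0("split", g)), sample(ids))
    data.frame(
      patient_id = shuffled,
      partition = rep(c("train", "test"),
                      c(n_train, length(ids) - n_train)),
      stratum = g, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[match(cohort$patient_id[cohort$Group %in% c("AKI-", "AKI+")],
            res$patient_id), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}
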