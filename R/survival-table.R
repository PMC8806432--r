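#' Clinical survival table
#'
#' One row per patient: overall-survival follow-up time in days, death
#' indicator, and the clinical covariates used for the independence and
#' stratified analyses.
#'
#' @param patient_id character vector of unique patient ids.
#' @param time follow-up in days, > 0.
#' @param event death indicator, 0/1 or logical.
#' @param age years; `gender`, `grade`, `stage` categorical (`stage` in
#'   `"I"`--`"IV"`). Clinical covariates may be `NA`; analyses drop
#'   incomplete rows per use and report how many.
#'
#' @return A data.frame of class `SurvivalTable`.
#' @export
survival_table <- function(patient_id, time, event, age = NA, gender = NA,
                           grade = NA, stage = NA) {
  patient_id <- as.character(patient_id)
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(!is.finite(time) | time <= 0)) stop("`time` must be finite and > 0")
  if (!all(event %in% c(0L, 1L))) stop("`event` must be 0/1")
  out <- data.frame(patient_id = patient_id, time = time, event = event,
                    age = age, gender = as.character(gender),
                    grade = as.character(grade), stage = as.character(stage),
                    stringsAsFactors = FALSE)
  class(out) <- c("SurvivalTable", "data.frame")
  out
}

#' Filter a raw clinical table to the analysis cohort
#'
#' Removes patients whose follow-up is 30 days or shorter and collapses
#' duplicated patient ids to their first occurrence (file order), logging
#' both counts. Idempotent.
#'
#' @param surv a [survival_table()] (possibly with duplicates).
#' @param min_days exclusive lower bound on follow-up; patients with
#'   `time <= min_days` are dropped (default 30).
#' @return The filtered `SurvivalTable`; attributes `n_short_followup` and
#'   `n_duplicates` record the removals.
#' @export
filter_patients <- function(surv, min_days = 30) {
  dup <- duplicated(surv$patient_id)
  out <- surv[!dup, , drop = FALSE]
  short <- out$time <= min_days
  out <- out[!short, , drop = FALSE]
  if (nrow(out) == 0) stop("no patients remain after follow-up filtering")
  rownames(out) <- NULL
  attr(out, "n_short_followup") <- sum(short)
  attr(out, "n_duplicates") <- sum(dup)
  message(sprintf("filter_patients: removed %d duplicate(s), %d with follow-up <= %g days; %d retained",
                  sum(dup), sum(short), min_days, nrow(out)))
  out
}

#' Read / write clinical tables
#'
#' TSV with columns `patient_id`, `time`, `event`, `age`, `gender`,
#' `grade`, `stage`.
#'
#' @param path TSV path.
#' @return A `SurvivalTable` (read) or the input, invisibly (write).
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$patient_id)) {
    # raw tables may carry duplicates; they are resolved by filter_patients
    warning("duplicate patient ids present; run filter_patients()")
  }
  out <- data.frame(patient_id = as.character(tab$patient_id),
                    time = as.numeric(tab$time),
                    event = as.integer(tab$event),
                    age = if ("age" %in% names(tab)) tab$age else NA,
                    gender = if ("gender" %in% names(tab)) as.character(tab$gender) else NA,
                    grade = if ("grade" %in% names(tab)) as.character(tab$grade) else NA,
                    stage = if ("stage" %in% names(tab)) as.character(tab$stage) else NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("SurvivalTable", "data.frame")
  out
}

#' @rdname read_survival
#' @param surv a `SurvivalTable`.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(as.data.frame(surv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(surv)
}

#' Match risk-score sample ids to patients
#'
#' Tumor samples are matched to `surv$patient_id`; when a patient has
#' several tumor samples the first in order is kept (with a message).
#'
#' @param sample_ids character vector of tumor sample ids.
#' @param surv a `SurvivalTable`.
#' @param sample_patient optional named character vector mapping sample id
#'   to patient id; by default sample ids are taken as patient ids.
#' @return data.frame with columns `sample_id`, `patient_id`, `time`,
#'   `event`, one row per matched patient.
#' @export
match_samples <- function(sample_ids, surv, sample_patient = NULL) {
  pid <- if (is.null(sample_patient)) sample_ids else
    unname(sample_patient[sample_ids])
  keep <- !duplicated(pid) & pid %in% surv$patient_id
  if (any(duplicated(pid[pid %in% surv$patient_id]))) {
    message("match_samples: multiple tumor samples for some patients; keeping the first")
  }
  idx <- match(pid[keep], surv$patient_id)
  data.frame(sample_id = sample_ids[keep], patient_id = pid[keep],
             time = surv$time[idx], event = surv$event[idx],
             stringsAsFactors = FALSE)
}
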