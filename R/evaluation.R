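# Product-limit survival estimate evaluated at one time point; used inside
# the ROC cutoff sweep where a full survfit object per subset would be
# wasteful. User-facing Kaplan-Meier curves go through survival::survfit.
km_surv_at <- function(time, event, t0) {
  if (length(time) == 0) return(NA_real_)
  o <- order(time)
  time <- time[o]; event <- event[o]
  n <- length(time)
  at_risk <- n - seq_len(n) + 1
  keep <- event == 1 & time <= t0
  if (!any(keep)) return(1)
  # handle tied event times: product over distinct times of (1 - d/r)
  dt <- time[keep]
  r <- at_risk[keep]
  first <- !duplicated(dt)
  d <- tabulate(match(dt, dt[first]))
  prod(1 - d / r[first])
}

#' Time-dependent ROC curve at a fixed horizon
#'
#' Cumulative/dynamic ROC for a risk score: cases are subjects with an
#' event by the horizon, controls those still event-free. Censoring before
#' the horizon is handled with Kaplan-Meier weighting in the style of the
#' survivalROC KM estimator: for each score cutoff `c`, a product-limit
#' estimate within the subset `score > c` gives
#' `sens = (1 - S_c(t)) P(X > c) / (1 - S(t))` and
#' `spec = 1 - P(X > c) S_c(t) / S(t)`, with `S(t)` the full-cohort
#' Kaplan-Meier. With no censoring this reduces exactly to the empirical
#' ROC, and the trapezoidal AUC to the Mann-Whitney statistic.
#'
#' @param scores named numeric vector (names = sample/patient ids).
#' @param surv a [survival_table()].
#' @param horizon days; must have >= 1 event at or before it.
#' @param sample_patient optional sample-to-patient map.
#' @return list of class `RocCurve`: `horizon`, `cutoffs` (ascending
#'   unique scores), `sensitivity`, `specificity`, `auc`.
#' @export
time_dependent_roc <- function(scores, surv, horizon,
                               sample_patient = NULL) {
  m <- match_samples(names(scores), surv, sample_patient)
  x <- unname(scores[m$sample_id])
  s_all <- km_surv_at(m$time, m$event, horizon)
  if (!any(m$event == 1 & m$time <= horizon)) {
    stop("no events at or before the horizon")
  }
  cutoffs <- sort(unique(x))
  n <- length(x)
  sens <- spec <- numeric(length(cutoffs))
  for (k in seq_along(cutoffs)) {
    above <- x > cutoffs[k]
    p_above <- mean(above)
    s_above <- if (any(above)) {
      km_surv_at(m$time[above], m$event[above], horizon)
    } else 1
    sens[k] <- (1 - s_above) * p_above / (1 - s_all)
    spec[k] <- 1 - p_above * s_above / s_all
  }
  # sweep endpoints: cutoff below min(x) classifies everyone positive.
  # Integrate in sweep order (fpr non-increasing along ascending cutoffs);
  # re-sorting the points would let float noise reorder equal-fpr corners.
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- -sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(horizon = horizon, cutoffs = cutoffs,
                 sensitivity = sens, specificity = spec, auc = auc),
            class = "RocCurve")
}

#' AIC-optimal risk-score cutoff
#'
#' Scans every midpoint between consecutive sorted unique scores, fits a
#' Cox proportional-hazards model on the binary indicator
#' `score > cutoff`, and returns the cutoff minimizing
#' `AIC = -2 log partial likelihood + 2` (one parameter). Exact ties go to
#' the lower cutoff. The scan is exhaustive, so the returned cutoff is the
#' global minimizer over all dichotomizations of the observed scores.
#'
#' @param scores named numeric vector with >= 2 distinct values.
#' @param surv a [survival_table()].
#' @param sample_patient optional sample-to-patient map.
#' @return list of class `CutoffResult`: `cutoff`, `candidates`, `aic`
#'   (one value per candidate).
#' @export
optimal_cutoff_aic <- function(scores, surv, sample_patient = NULL) {
  m <- match_samples(names(scores), surv, sample_patient)
  x <- unname(scores[m$sample_id])
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("scores are constant; no cutoff exists")
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  y <- survival::Surv(m$time, m$event)
  aic <- vapply(cand, function(cc) {
    g <- as.integer(x > cc)
    fit <- suppressWarnings(survival::coxph(y ~ g, ties = "efron"))
    -2 * fit$loglik[2] + 2
  }, numeric(1))
  structure(list(cutoff = cand[which.min(aic)], candidates = cand,
                 aic = aic),
            class = "CutoffResult")
}

#' Kaplan-Meier curves and log-rank test between risk groups
#'
#' Product-limit survival per group (survival::survfit) and the standard
#' log-rank test (hypergeometric variance; survival::survdiff), reported
#' as a chi-square statistic with `k - 1` degrees of freedom.
#'
#' @param groups a [assign_risk_groups()] result, or a named character
#'   vector of group labels (names = patient ids).
#' @param surv a [survival_table()].
#' @return list of class `KmLogRank`: `fit` (a `survfit` object),
#'   `chisq`, `df`, `p`, `n_per_group`.
#' @export
km_logrank <- function(groups, surv) {
  if (inherits(groups, "RiskAssignment") || is.data.frame(groups)) {
    g <- stats::setNames(groups$group, groups$patient_id)
  } else {
    g <- groups
  }
  idx <- match(names(g), surv$patient_id)
  if (anyNA(idx)) stop("group labels for unknown patient id(s)")
  dat <- data.frame(time = surv$time[idx], event = surv$event[idx],
                    group = factor(unname(g)))
  if (nlevels(dat$group) < 2) stop("need >= 2 nonempty groups")
  if (any(table(dat$group) == 0)) stop("a group has zero subjects")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd$n) - 1
  structure(list(fit = fit, chisq = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n_per_group = table(dat$group)),
            class = "KmLogRank")
}

#' Prognostic independence from clinical covariates
#'
#' Univariate Cox regression of survival on the risk score and on each
#' clinical covariate, plus one multivariate model with all of them.
#' Categorical covariates are dummy-coded against their first factor
#' level; rows with missing covariate values are dropped (complete-case,
#' count reported); an aliased (rank-deficient) design is an error naming
#' the offending terms.
#'
#' @param scores named numeric vector of risk scores.
#' @param surv a [survival_table()] carrying the covariate columns.
#' @param covariates columns of `surv` to adjust for.
#' @param sample_patient optional sample-to-patient map.
#' @return data.frame of class `IndependenceResult`, one row per model
#'   term: `term`, `uni_hr`, `uni_ci_low`, `uni_ci_high`, `uni_p`,
#'   `multi_hr`, `multi_ci_low`, `multi_ci_high`, `multi_p`; attribute
#'   `n_dropped` counts incomplete rows removed.
#' @export
independence_analysis <- function(scores, surv,
                                  covariates = c("age", "gender",
                                                 "grade", "stage"),
                                  sample_patient = NULL) {
  m <- match_samples(names(scores), surv, sample_patient)
  idx <- match(m$patient_id, surv$patient_id)
  dat <- data.frame(time = m$time, event = m$event,
                    risk_score = unname(scores[m$sample_id]))
  for (v in covariates) {
    col <- surv[[v]][idx]
    dat[[v]] <- if (is.numeric(col)) col else factor(col)
  }
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(sprintf("independence_analysis: dropped %d incomplete row(s)",
                    n_dropped))
  }
  dat <- dat[cc, , drop = FALSE]
  y <- survival::Surv(dat$time, dat$event)
  vars <- c("risk_score", covariates)

  term_rows <- function(fit) {
    b <- stats::coef(fit)
    se <- sqrt(diag(fit$var))
    data.frame(term = names(b), hr = exp(unname(b)),
               ci_low = exp(unname(b) - 1.96 * se),
               ci_high = exp(unname(b) + 1.96 * se),
               p = 2 * stats::pnorm(abs(unname(b) / se),
                                    lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, lapply(vars, function(v) {
    f <- stats::as.formula(paste("y ~", v))
    term_rows(suppressWarnings(survival::coxph(f, data = dat,
                                               ties = "efron")))
  }))
  mfit <- suppressWarnings(survival::coxph(
    stats::as.formula(paste("y ~", paste(vars, collapse = " + "))),
    data = dat, ties = "efron"))
  if (anyNA(stats::coef(mfit))) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(stats::coef(mfit))[is.na(stats::coef(mfit))],
               collapse = ", "))
  }
  multi <- term_rows(mfit)
  out <- merge(uni, multi, by = "term", suffixes = c("_uni", "_multi"),
               sort = FALSE)
  names(out) <- c("term", "uni_hr", "uni_ci_low", "uni_ci_high", "uni_p",
                  "multi_hr", "multi_ci_low", "multi_ci_high", "multi_p")
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("IndependenceResult", "data.frame")
  out
}

#' Clinical splits used by the stratified analysis
#'
#' Age is split at 65 years (young: <= 65; old: > 65); stage into early
#' (I, II) and late (III, IV).
#'
#' @param age numeric years; `stage` character/factor in `"I"`--`"IV"`.
#' @return Character vector of stratum labels (`NA` preserved).
#' @export
split_by_age <- function(age) {
  ifelse(is.na(age), NA_character_, ifelse(age <= 65, "young", "old"))
}

#' @rdname split_by_age
#' @export
split_by_stage <- function(stage) {
  ifelse(is.na(stage) | !stage %in% c("I", "II", "III", "IV"),
         NA_character_,
         ifelse(stage %in% c("I", "II"), "early", "late"))
}

#' Stratified survival analysis of the risk groups
#'
#' Within each stratum (e.g. young/old, early/late stage), patients are
#' split high/low by the *global* cutoff and compared by log-rank. A
#' stratum containing a single risk group is reported as not testable.
#'
#' @param scores named numeric risk scores.
#' @param surv a [survival_table()].
#' @param stratum `"age"`, `"stage"`, or a named character vector of
#'   stratum labels (names = patient ids).
#' @param cutoff the global risk cutoff.
#' @param sample_patient optional sample-to-patient map.
#' @return Named list, one element per stratum: either a [km_logrank()]
#'   result or the string `"not-testable"`; `NA` strata are dropped.
#' @export
stratified_analysis <- function(scores, surv, stratum, cutoff,
                                sample_patient = NULL) {
  m <- match_samples(names(scores), surv, sample_patient)
  idx <- match(m$patient_id, surv$patient_id)
  lab <- if (is.character(stratum) && length(stratum) == 1) {
    switch(stratum,
           age = split_by_age(surv$age[idx]),
           stage = split_by_stage(surv$stage[idx]),
           stop("unknown stratum variable: ", stratum))
  } else {
    unname(stratum[m$patient_id])
  }
  groups <- assign_risk_groups(stats::setNames(unname(scores[m$sample_id]),
                                               m$patient_id), cutoff)
  out <- list()
  for (s in unique(stats::na.omit(lab))) {
    gs <- groups[lab %in% s, , drop = FALSE]
    if (length(unique(gs$group)) < 2) {
      out[[s]] <- "not-testable"
    } else {
      out[[s]] <- km_logrank(gs, surv)
    }
  }
  out
}

#' Compare competing risk scores by time-dependent AUC
#'
#' @param score_sets named list of score vectors over the same patients.
#' @param surv a [survival_table()].
#' @param horizon days.
#' @param sample_patient optional sample-to-patient map.
#' @return data.frame `signature`, `auc`, sorted as given.
#' @export
compare_signatures <- function(score_sets, surv, horizon,
                               sample_patient = NULL) {
  ids <- lapply(score_sets, function(s) sort(names(s)))
  if (length(unique(ids)) != 1) {
    stop("score sets cover different patients")
  }
  auc <- vapply(score_sets, function(s) {
    time_dependent_roc(s, surv, horizon, sample_patient)$auc
  }, numeric(1))
  data.frame(signature = names(score_sets), auc = unname(auc),
             stringsAsFactors = FALSE)
}
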