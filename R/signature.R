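#' Univariate Cox screen of pair indicators
#'
#' Fits one Cox proportional-hazards model per pair (single binary
#' covariate, Efron tie handling) and retains pairs with two-sided Wald
#' `p < p_max`. Pairs whose indicator is constant across the matched
#' patients, or whose fit does not converge (monotone partial likelihood),
#' are skipped with a message.
#'
#' @param pm a [build_pair_matrix()] result (columns are tumor samples).
#' @param surv a [survival_table()]; samples are matched to patients via
#'   [match_samples()].
#' @param p_max retention threshold on the Wald p (default 0.01).
#' @param sample_patient optional sample-to-patient map (see
#'   [match_samples()]).
#' @return data.frame with columns `pair_id`, `beta`, `hr`, `ci_low`,
#'   `ci_high`, `p` for *all* converged pairs, ordered as in `pm`;
#'   retained pairs are flagged in column `selected` and the retained
#'   subset is attached as attribute `"selected"` for convenience.
#' @export
univariate_cox_screen <- function(pm, surv, p_max = 0.01,
                                  sample_patient = NULL) {
  m <- match_samples(colnames(pm$P), surv, sample_patient)
  if (nrow(m) < 2 || sum(m$event) < 2) stop("need >= 2 matched patients with >= 2 events")
  y <- survival::Surv(m$time, m$event)
  P <- pm$P[, m$sample_id, drop = FALSE]

  rows <- lapply(seq_len(nrow(P)), function(i) {
    x <- P[i, ]
    if (length(unique(x)) < 2) return(NULL)      # constant covariate
    fit <- tryCatch(
      suppressWarnings(survival::coxph(y ~ x, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    b <- unname(stats::coef(fit))
    se <- sqrt(unname(diag(fit$var)))
    if (!is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 50) {
      return(NULL)                               # monotone likelihood
    }
    p <- 2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
    data.frame(pair_id = pm$pairs$pair_id[i], beta = b, hr = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p = p, stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    message(sprintf("univariate_cox_screen: skipped %d constant/non-convergent pair(s)", skipped))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pair_id = character(0), beta = numeric(0),
                      hr = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0))
  }
  rownames(out) <- NULL
  out$selected <- out$p < p_max
  attr(out, "selected") <- out$pair_id[out$selected]
  out
}

#' LASSO-Cox selection over screened pairs
#'
#' L1-penalized Cox regression over a descending lambda grid with
#' repeated k-fold cross-validation of the partial-likelihood deviance;
#' the deviance curves are averaged over repeats on a shared grid and the
#' penalty minimizing the mean deviance (`lambda.min`) is chosen. The
#' selected set is the pairs with nonzero coefficients at that penalty.
#'
#' @param pm pair matrix restricted to the screened candidates (>= 2).
#' @param surv a [survival_table()] providing >= 10 events.
#' @param nfolds,repeats cross-validation settings; `nfolds * repeats`
#'   fold-fits are performed in total.
#' @param seed seed controlling fold assignment.
#' @param sample_patient optional sample-to-patient map.
#' @return list of class `LassoPath`: `lambda` (descending grid),
#'   `coef` (pairs x lambda coefficient matrix), `cvm`/`cvsd` (mean
#'   deviance and its SE per lambda, averaged over repeats),
#'   `lambda_min`, and `selected` (pair ids with nonzero coefficient at
#'   `lambda_min`; may be empty, with a message).
#' @export
lasso_cox_select <- function(pm, surv, nfolds = 10, repeats = 10,
                             seed = 1L, sample_patient = NULL) {
  if (nrow(pm$P) < 2) stop("need >= 2 candidate pairs")
  m <- match_samples(colnames(pm$P), surv, sample_patient)
  if (sum(m$event) < 10) stop("need >= 10 events for cross-validation")
  x <- t(pm$P[, m$sample_id, drop = FALSE])
  y <- survival::Surv(m$time, m$event)

  fit <- glmnet::glmnet(x, y, family = "cox")
  lambda <- fit$lambda
  set.seed(seed)
  cvms <- matrix(NA_real_, nrow = repeats, ncol = length(lambda))
  cvsds <- matrix(NA_real_, nrow = repeats, ncol = length(lambda))
  for (r in seq_len(repeats)) {
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", lambda = lambda,
                            foldid = foldid)
    k <- match(cv$lambda, lambda)
    cvms[r, k] <- cv$cvm
    cvsds[r, k] <- cv$cvsd
  }
  cvm <- colMeans(cvms)
  cvsd <- colMeans(cvsds)
  ok <- which(is.finite(cvm))
  lambda_min <- lambda[ok[which.min(cvm[ok])]]
  beta <- as.matrix(fit$beta)
  sel_coef <- stats::coef(fit, s = lambda_min, exact = FALSE)
  selected <- rownames(sel_coef)[as.numeric(sel_coef) != 0]
  if (length(selected) == 0) {
    message("lasso_cox_select: empty selection (no signal at lambda.min)")
  }
  structure(list(lambda = lambda, coef = beta, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda_min, selected = selected),
            class = "LassoPath")
}

#' Backward stepwise multivariate Cox model
#'
#' Starting from the full multivariate Cox model on the candidate pairs,
#' repeatedly removes the term whose removal most decreases the AIC
#' (AIC = -2 log partial likelihood + 2 x number of terms), until no
#' removal decreases it. Aliased (collinear) candidates are dropped from
#' the full model before stepping, so of two identical covariates exactly
#' one survives.
#'
#' @param pm pair matrix containing the candidates.
#' @param surv a [survival_table()].
#' @param candidates pair ids to start from (nonempty).
#' @param sample_patient optional sample-to-patient map.
#' @return A `PairSignature`: data.frame `pair_id`, `beta`, `hr`,
#'   `ci_low`, `ci_high`, `p` with attributes `n` (patients used),
#'   `loglik` and `AIC` of the final model.
#' @export
stepwise_multivariate_cox <- function(pm, surv, candidates,
                                      sample_patient = NULL) {
  if (length(candidates) == 0) stop("candidate set is empty")
  pm <- subset_pairs(pm, candidates)
  m <- match_samples(colnames(pm$P), surv, sample_patient)
  y <- survival::Surv(m$time, m$event)
  X <- t(pm$P[, m$sample_id, drop = FALSE])

  fit_set <- function(set) {
    suppressWarnings(survival::coxph(y ~ X[, set, drop = FALSE],
                                     ties = "efron"))
  }
  current <- colnames(X)
  fit <- fit_set(current)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    message("dropping aliased candidate(s): ",
            paste(current[aliased], collapse = ", "))
    current <- current[!aliased]
    fit <- fit_set(current)
  }
  aic <- stats::AIC(fit)
  while (length(current) > 1) {
    trials <- vapply(seq_along(current), function(j) {
      stats::AIC(fit_set(current[-j]))
    }, numeric(1))
    j <- which.min(trials)
    if (trials[j] >= aic) break
    current <- current[-j]
    fit <- fit_set(current)
    aic <- trials[j]
  }
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  out <- data.frame(pair_id = current, beta = b, hr = exp(b),
                    ci_low = exp(b - 1.96 * se),
                    ci_high = exp(b + 1.96 * se),
                    p = 2 * stats::pnorm(abs(b / se), lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n") <- nrow(m)
  attr(out, "loglik") <- fit$loglik[2]
  attr(out, "AIC") <- aic
  class(out) <- c("PairSignature", "data.frame")
  out
}

#' Risk score from a fitted pair signature
#'
#' The per-patient risk score is the coefficient-weighted sum of pair
#' indicators, `sum_i beta_i * P_i(patient)`. Because each `P_i` is a
#' within-sample ordering indicator, the score inherits invariance to
#' strictly increasing per-sample transforms of expression.
#'
#' @param sig a `PairSignature` (or data.frame with `pair_id`, `beta`).
#' @param pm a `PairMatrix` containing every signature pair (missing
#'   pairs are an error naming them).
#' @return Named numeric vector of scores, one per column of `pm$P`.
#' @export
risk_score <- function(sig, pm) {
  miss <- setdiff(sig$pair_id, pm$pairs$pair_id)
  if (length(miss) > 0) {
    stop("signature pair(s) missing from pair matrix: ",
         paste(miss, collapse = ", "))
  }
  P <- pm$P[match(sig$pair_id, pm$pairs$pair_id), , drop = FALSE]
  drop(crossprod(P, sig$beta))[colnames(pm$P)]
}

#' Score a new cohort with a fitted signature
#'
#' Computes each signature pair's ordering indicator directly from the
#' expression of a (possibly new) cohort, respecting the pair's fitted
#' orientation, and returns the weighted-sum risk score. This is the
#' function to use on validation cohorts, where [build_pair_matrix()]'s
#' canonical gene order need not reproduce the training orientation.
#'
#' @param sig a `PairSignature` (or data.frame with `pair_id`, `beta`;
#'   pair ids are `geneA|geneB`).
#' @param expr an [expression_matrix()] or bare matrix with gene rownames.
#' @param samples columns to score; defaults to the tumor samples.
#' @return Named numeric vector of risk scores.
#' @export
score_cohort <- function(sig, expr, samples = NULL) {
  X <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (is.null(samples)) {
    samples <- if (inherits(expr, "ExpressionMatrix")) tumor_samples(expr)
               else colnames(X)
  }
  ab <- strsplit(sig$pair_id, "|", fixed = TRUE)
  a <- vapply(ab, `[`, "", 1)
  b <- vapply(ab, `[`, "", 2)
  miss <- setdiff(unique(c(a, b)), rownames(X))
  if (length(miss) > 0) {
    stop("signature gene(s) absent from expression: ",
         paste(miss, collapse = ", "))
  }
  P <- (X[a, samples, drop = FALSE] > X[b, samples, drop = FALSE]) + 0L
  stats::setNames(drop(crossprod(P, sig$beta)), samples)
}

#' Dichotomize scores into risk groups
#'
#' @param scores named numeric vector of risk scores.
#' @param cutoff threshold; `score > cutoff` is high risk.
#' @return data.frame of class `RiskAssignment`: `patient_id`, `score`,
#'   `group` (`"high"`/`"low"`), `cutoff`.
#' @export
assign_risk_groups <- function(scores, cutoff) {
  out <- data.frame(patient_id = names(scores), score = unname(scores),
                    group = ifelse(scores > cutoff, "high", "low"),
                    cutoff = cutoff, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("RiskAssignment", "data.frame")
  out
}

#' Write a fitted signature to TSV
#'
#' @param sig a `PairSignature`; `path` a TSV path.
#' @return The input, invisibly.
#' @export
write_signature <- function(sig, path) {
  utils::write.table(as.data.frame(sig), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sig)
}
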