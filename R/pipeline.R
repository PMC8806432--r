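#' Run the full pair-signature pipeline
#'
#' Orchestrates the complete chain on a cohort: patient filtering,
#' immune-related lncRNA screen, differential expression, pair-matrix
#' construction and validity filtering, univariate Cox screen, repeated
#' cross-validated LASSO-Cox, backward stepwise multivariate Cox, risk
#' scoring, AIC-optimal cutoff, group assignment, and the core evaluation
#' (time-dependent AUCs, KM/log-rank). All randomness flows from
#' `config$seed`, split deterministically per stage, so a run is a pure
#' function of (cohort, config).
#'
#' @param expr an [expression_matrix()].
#' @param surv a raw [survival_table()] (filtering is applied here).
#' @param config a [pipeline_config()].
#' @param evaluate run the evaluation stage (cutoff, KM, AUCs); disable
#'   when only the fitted signature is wanted.
#' @return list of class `PairsigRun`: `signature`, `scores`, `cutoff`,
#'   `groups`, `evaluation` (list: `auc` per horizon, `km`), plus a
#'   `manifest` recording the config, seed and the funnel counts
#'   (`n_lncRNA`, `n_irlncRNA`, `n_DEirlncRNA`, `n_pairs_unfiltered`,
#'   `n_pairs_valid`, `n_pairs_cox`, `n_pairs_lasso`, `n_signature`).
#'   Stages that empty the funnel abort with an explanatory error naming
#'   the stage.
#' @export
run_pipeline <- function(expr, surv, config = pipeline_config(),
                         evaluate = TRUE) {
  validate_config(config)
  t0 <- Sys.time()
  surv <- filter_patients(surv)

  ir <- screen_irlncRNAs(expr, r_min = config$corr_r, p_max = config$corr_p,
                         method = config$corr_method,
                         samples = config$corr_samples)
  if (nrow(ir) == 0) stop("screening stage: no immune-related lncRNAs found")

  de <- differential_expression(expr, ir$lncRNA, fdr_max = config$de_fdr,
                                lfc_min = config$de_log2fc)
  if (nrow(de) < 2) {
    stop("differential-expression stage: fewer than 2 DEirlncRNAs; ",
         "cannot build pairs")
  }

  pm_all <- build_pair_matrix(expr, genes = de$lncRNA)
  pm <- filter_valid_pairs(pm_all, config$pair_low, config$pair_high)
  if (nrow(pm$P) == 0) stop("pairing stage: no valid pairs in the frequency band")

  cox <- univariate_cox_screen(pm, surv, p_max = config$uni_cox_p)
  screened <- attr(cox, "selected")
  if (length(screened) < 2) {
    stop("univariate Cox stage: fewer than 2 prognostic pairs at p < ",
         config$uni_cox_p)
  }

  lasso <- lasso_cox_select(subset_pairs(pm, screened), surv,
                            nfolds = config$cv_folds,
                            repeats = config$cv_repeats,
                            seed = config$seed + 1L)
  if (length(lasso$selected) == 0) {
    stop("LASSO stage: empty selection; no prognostic signal")
  }

  sig <- stepwise_multivariate_cox(pm, surv, lasso$selected)
  scores <- risk_score(sig, pm)

  evaluation <- NULL
  cutoff <- NA_real_
  groups <- NULL
  if (evaluate) {
    # evaluation is per patient: drop scores for samples filtered out of
    # the clinical table (short follow-up)
    scores_eval <- scores[names(scores) %in% surv$patient_id]
    cut <- optimal_cutoff_aic(scores_eval, surv)
    cutoff <- cut$cutoff
    groups <- assign_risk_groups(scores_eval, cutoff)
    km <- km_logrank(groups, surv)
    auc <- vapply(config$horizons, function(h) {
      time_dependent_roc(scores_eval, surv, h)$auc
    }, numeric(1))
    names(auc) <- paste0(round(config$horizons / 365.25, 2), "y")
    evaluation <- list(cutoff = cut, km = km, auc = auc)
  }

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    counts = c(n_lncRNA = length(lncRNA_ids(expr)),
               n_irlncRNA = nrow(ir),
               n_DEirlncRNA = nrow(de),
               n_pairs_unfiltered = nrow(pm_all$P),
               n_pairs_valid = nrow(pm$P),
               n_pairs_cox = length(screened),
               n_pairs_lasso = length(lasso$selected),
               n_signature = nrow(sig)),
    n_patients = nrow(surv),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  structure(list(irlncRNAs = ir, de = de, pairs = pm, cox_screen = cox,
                 lasso = lasso, signature = sig, scores = scores,
                 cutoff = cutoff, groups = groups,
                 evaluation = evaluation, manifest = manifest),
            class = "PairsigRun")
}

#' @method print PairsigRun
#' @export
print.PairsigRun <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("Pair-signature pipeline run\n")
  cat(sprintf("  funnel: %d lncRNA -> %d irlncRNA -> %d DE -> %d pairs -> %d valid -> %d Cox -> %d LASSO -> %d signature\n",
              cnt["n_lncRNA"], cnt["n_irlncRNA"], cnt["n_DEirlncRNA"],
              cnt["n_pairs_unfiltered"], cnt["n_pairs_valid"],
              cnt["n_pairs_cox"], cnt["n_pairs_lasso"], cnt["n_signature"]))
  if (!is.null(x$evaluation)) {
    cat(sprintf("  cutoff %.4f; log-rank p %.3g; AUC: %s\n", x$cutoff,
                x$evaluation$km$p,
                paste(sprintf("%s=%.3f", names(x$evaluation$auc),
                              x$evaluation$auc), collapse = ", ")))
  }
  invisible(x)
}

#' Persist a pipeline run to a directory
#'
#' Writes the per-stage TSV artifacts (irlncRNAs, DE table, valid pairs,
#' Cox screen, signature, scores, groups) and the manifest as JSON.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory.
#' @return File paths, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(run$irlncRNAs, "irlncRNAs.tsv")
  w(run$de, "de.tsv")
  write_pairs(run$pairs, file.path(dir, "pairs.tsv"))
  w(run$cox_screen, "cox_screen.tsv")
  w(as.data.frame(run$signature), "signature.tsv")
  w(data.frame(sample_id = names(run$scores), score = unname(run$scores)),
    "scores.tsv")
  if (!is.null(run$groups)) w(as.data.frame(run$groups), "groups.tsv")
  man <- run$manifest
  man$counts <- as.list(man$counts)   # keep names in the JSON object
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}
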