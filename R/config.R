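#' Analysis configuration
#'
#' Collects every tunable threshold of the pair-signature pipeline in one
#' validated list. Defaults are the conventional screening thresholds for
#' immune-related lncRNA pair signatures: co-expression with an immune gene
#' at |r| > 0.4 and p < 0.001, differential expression at FDR < 0.05 and
#' |log2FC| > 1.5, pair validity band 20--80% one-frequency, univariate Cox
#' screen at p < 0.01, and 1/2/3-year evaluation horizons.
#'
#' @param corr_r minimum absolute Pearson/Spearman correlation between a
#'   lncRNA and an immune gene for the lncRNA to count as immune-related.
#' @param corr_p maximum correlation p-value (two-sided).
#' @param corr_method `"pearson"` (default) or `"spearman"`.
#' @param corr_samples `"tumor"` (default) or `"all"`: samples used for the
#'   co-expression screen.
#' @param de_fdr maximum Benjamini-Hochberg FDR for differential expression.
#' @param de_log2fc minimum |log2 fold change| (tumor minus normal mean of
#'   log2(x+1) values).
#' @param pair_low,pair_high open validity band for the per-pair fraction of
#'   samples scored 1; pairs outside `(pair_low, pair_high)` are discarded
#'   as near-constant.
#' @param uni_cox_p maximum Wald p in the univariate Cox screen.
#' @param cv_folds,cv_repeats cross-validation folds and repeats for the
#'   LASSO-Cox penalty choice; deviance is averaged over repeats.
#' @param horizons evaluation horizons in days (default 1, 2, 3 years at
#'   365.25 days/year).
#' @param log2_transform apply log2(x+1) before correlation and differential
#'   expression (pairing always uses the raw scale; the pair indicator is
#'   rank-invariant so the choice cannot affect it).
#' @param seed root random seed for the pipeline.
#'
#' @return A named list of class `pairsig_config`.
#' @export
pipeline_config <- function(corr_r = 0.4, corr_p = 0.001,
                            corr_method = c("pearson", "spearman"),
                            corr_samples = c("tumor", "all"),
                            de_fdr = 0.05, de_log2fc = 1.5,
                            pair_low = 0.20, pair_high = 0.80,
                            uni_cox_p = 0.01,
                            cv_folds = 10, cv_repeats = 10,
                            horizons = 365.25 * c(1, 2, 3),
                            log2_transform = TRUE,
                            seed = 1L) {
  corr_method <- match.arg(corr_method)
  corr_samples <- match.arg(corr_samples)
  cfg <- list(
    corr_r = corr_r, corr_p = corr_p, corr_method = corr_method,
    corr_samples = corr_samples,
    de_fdr = de_fdr, de_log2fc = de_log2fc,
    pair_low = pair_low, pair_high = pair_high,
    uni_cox_p = uni_cox_p,
    cv_folds = as.integer(cv_folds), cv_repeats = as.integer(cv_repeats),
    horizons = horizons, log2_transform = isTRUE(log2_transform),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pairsig_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$pair_low > 0, cfg$pair_low < cfg$pair_high, cfg$pair_high < 1,
    cfg$corr_p > 0, cfg$corr_p < 1,
    cfg$de_fdr > 0, cfg$de_fdr <= 1,
    cfg$uni_cox_p > 0, cfg$uni_cox_p < 1,
    cfg$corr_r >= 0, cfg$corr_r < 1,
    cfg$cv_folds >= 2, cfg$cv_repeats >= 1,
    all(cfg$horizons > 0)
  )
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys missing from the file keep their [pipeline_config()] defaults;
#' unknown keys are an error.
#'
#' @param path path to a YAML key-value file.
#' @return A `pairsig_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}
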