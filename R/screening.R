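#' Screen for immune-related lncRNAs by co-expression
#'
#' A lncRNA is called immune-related (irlncRNA) when its expression
#' correlates with at least one immune-flagged mRNA beyond `|r| > r_min`
#' at `p < p_max` (two-sided). Correlation is computed on log2(x+1)
#' values; the strongest-|r| immune partner is reported per retained
#' lncRNA. Zero-variance genes are skipped with a warning (their
#' correlation is undefined).
#'
#' @param expr an [expression_matrix()] with >= 1 immune mRNA, >= 1 lncRNA
#'   and >= 3 samples in the chosen sample set.
#' @param r_min minimum |r| (default 0.4).
#' @param p_max maximum p (default 0.001).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param samples `"tumor"` (default) or `"all"`.
#' @return data.frame with one row per retained lncRNA: `lncRNA`,
#'   `best_partner`, `r`, `p`.
#' @export
screen_irlncRNAs <- function(expr, r_min = 0.4, p_max = 0.001,
                             method = c("pearson", "spearman"),
                             samples = c("tumor", "all")) {
  method <- match.arg(method)
  samples <- match.arg(samples)
  sids <- if (samples == "tumor") tumor_samples(expr) else
    names(expr$sample_group)
  lnc <- lncRNA_ids(expr)
  irg <- immune_gene_ids(expr)
  if (length(lnc) < 1 || length(irg) < 1) {
    stop("need at least one lncRNA and one immune-flagged mRNA")
  }
  if (length(sids) < 3) stop("need at least 3 samples")

  X <- log2(expr$values[, sids, drop = FALSE] + 1)
  if (method == "spearman") X <- t(apply(X, 1, rank))
  L <- X[lnc, , drop = FALSE]
  G <- X[irg, , drop = FALSE]
  const_l <- apply(L, 1, stats::sd) == 0
  const_g <- apply(G, 1, stats::sd) == 0
  if (any(const_l) || any(const_g)) {
    warning("skipping zero-variance gene(s): ",
            paste(c(lnc[const_l], irg[const_g]), collapse = ", "))
  }
  L <- L[!const_l, , drop = FALSE]
  G <- G[!const_g, , drop = FALSE]
  if (nrow(L) == 0 || nrow(G) == 0) {
    return(data.frame(lncRNA = character(0), best_partner = character(0),
                      r = numeric(0), p = numeric(0)))
  }
  R <- stats::cor(t(L), t(G))                    # lnc x immune
  n <- length(sids)
  # two-sided t-test p for a correlation coefficient
  tstat <- abs(R) * sqrt(n - 2) / sqrt(pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  P[abs(R) >= 1] <- 0
  hit <- abs(R) > r_min & P < p_max
  keep <- which(rowSums(hit) > 0)
  out <- do.call(rbind, lapply(keep, function(i) {
    j <- which.max(abs(R[i, ]))
    data.frame(lncRNA = rownames(R)[i], best_partner = colnames(R)[j],
               r = R[i, j], p = P[i, j], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(lncRNA = character(0), best_partner = character(0),
                      r = numeric(0), p = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Tumor-vs-normal differential expression of candidate lncRNAs
#'
#' Moderated-t differential expression (limma: linear fit + empirical-Bayes
#' variance moderation) on log2(x+1) values, restricted to the supplied
#' lncRNA subset. Benjamini-Hochberg adjustment is applied within that
#' subset (the tested family). A gene is retained when `fdr < fdr_max` and
#' `|log2FC| > lfc_min`; log2FC is the tumor-minus-normal difference of
#' group means on the log2(x+1) scale.
#'
#' @param expr an [expression_matrix()] with >= 2 tumor and >= 2 normal
#'   samples.
#' @param lnc_subset gene ids to test (e.g. the irlncRNAs).
#' @param fdr_max,lfc_min retention thresholds (defaults 0.05 and 1.5).
#' @return data.frame with one row per *retained* gene: `lncRNA`,
#'   `log2FC`, `p`, `fdr`, `direction`; the full table for all tested
#'   genes is attached as attribute `"all"`.
#' @export
differential_expression <- function(expr, lnc_subset, fdr_max = 0.05,
                                    lfc_min = 1.5) {
  grp <- expr$sample_group
  if (sum(grp == "tumor") < 2 || sum(grp == "normal") < 2) {
    stop("need >= 2 tumor and >= 2 normal samples")
  }
  lnc_subset <- intersect(lnc_subset, rownames(expr$values))
  if (length(lnc_subset) == 0) stop("`lnc_subset` matches no genes")
  X <- log2(expr$values[lnc_subset, , drop = FALSE] + 1)
  design <- stats::model.matrix(~ factor(grp, levels = c("normal", "tumor")))
  colnames(design) <- c("intercept", "tumor")
  fit <- limma::eBayes(limma::lmFit(X, design))
  tab <- limma::topTable(fit, coef = "tumor", number = Inf, sort.by = "none",
                         adjust.method = "BH")
  all <- data.frame(lncRNA = rownames(tab), log2FC = tab$logFC,
                    p = tab$P.Value, fdr = tab$adj.P.Val,
                    direction = ifelse(tab$logFC >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(all) <- NULL
  out <- all[all$fdr < fdr_max & abs(all$log2FC) > lfc_min, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all
  out
}
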