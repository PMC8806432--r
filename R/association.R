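#' Associate risk scores with immune-infiltration estimates
#'
#' For each cell type x deconvolution method in the infiltration table,
#' computes the Spearman correlation of the risk score with the estimated
#' fraction (two-sided p) and a Wilcoxon rank-sum comparison of fractions
#' between the high- and low-risk groups. The infiltration table is an
#' input (xCell/TIMER/QUANTISEQ/MCPcounter/EPIC/CIBERSORT-style output);
#' deconvolution itself is out of scope.
#'
#' @param scores named numeric risk scores.
#' @param groups an [assign_risk_groups()] result.
#' @param infil data.frame with columns `cell_type`, `method`,
#'   `sample_id`, `fraction` (long format).
#' @param min_overlap minimum overlapping samples per feature (default 3).
#' @return data.frame of `AssociationResult` rows: `feature`, `method`,
#'   `test` (`"spearman"`/`"wilcoxon"`), `statistic`, `p`, `direction`,
#'   `fdr` (Benjamini-Hochberg within each test family). Constant
#'   features, or those below the overlap floor, are skipped with a
#'   warning.
#' @export
correlate_infiltration <- function(scores, groups, infil, min_overlap = 3) {
  stopifnot(all(c("cell_type", "method", "sample_id", "fraction")
                %in% names(infil)))
  grp <- stats::setNames(groups$group, groups$patient_id)
  keys <- unique(infil[, c("cell_type", "method")])
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(keys))) {
    sub <- infil[infil$cell_type == keys$cell_type[i] &
                   infil$method == keys$method[i], ]
    ids <- intersect(sub$sample_id, names(scores))
    if (length(ids) < min_overlap) {
      skipped <- c(skipped, paste(keys$cell_type[i], keys$method[i]))
      next
    }
    fr <- sub$fraction[match(ids, sub$sample_id)]
    sc <- unname(scores[ids])
    if (stats::sd(fr) == 0) {
      skipped <- c(skipped, paste(keys$cell_type[i], keys$method[i]))
      next
    }
    ct <- suppressWarnings(stats::cor.test(sc, fr, method = "spearman"))
    rows[[length(rows) + 1]] <- data.frame(
      feature = keys$cell_type[i], method = keys$method[i],
      test = "spearman", statistic = unname(ct$estimate), p = ct$p.value,
      direction = ifelse(ct$estimate >= 0, "positive", "negative"),
      stringsAsFactors = FALSE)
    g <- unname(grp[ids])
    if (length(unique(g)) == 2) {
      wt <- suppressWarnings(
        stats::wilcox.test(fr[g == "high"], fr[g == "low"]))
      rows[[length(rows) + 1]] <- data.frame(
        feature = keys$cell_type[i], method = keys$method[i],
        test = "wilcoxon", statistic = unname(wt$statistic),
        p = wt$p.value,
        direction = ifelse(stats::median(fr[g == "high"]) >=
                             stats::median(fr[g == "low"]),
                           "positive", "negative"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) > 0) {
    warning("skipped feature(s) with no usable data: ",
            paste(skipped, collapse = "; "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(feature = character(0), method = character(0),
                      test = character(0), statistic = numeric(0),
                      p = numeric(0), direction = character(0),
                      fdr = numeric(0)))
  }
  out$fdr <- NA_real_
  for (tt in unique(out$test)) {
    out$fdr[out$test == tt] <- stats::p.adjust(out$p[out$test == tt], "BH")
  }
  rownames(out) <- NULL
  out
}

#' Compare feature values between risk groups
#'
#' Two-sample Wilcoxon rank-sum test per feature (drug IC50 per drug, or
#' expression per immune-checkpoint biomarker such as PDCD1/LAG3/CTLA4)
#' between the high- and low-risk groups. (The rank-sum test is the
#' independent-samples analogue of the signed-rank test, which requires
#' paired data and does not apply to two independent risk groups.)
#'
#' @param groups an [assign_risk_groups()] result.
#' @param value_table numeric matrix/data.frame, features x samples.
#' @param features rownames to test; missing features are an error.
#' @return data.frame: `feature`, `test`, `statistic`, `p`, `direction`
#'   (sign of median(high) - median(low)), `fdr` (BH across features).
#' @export
compare_group_values <- function(groups, value_table,
                                 features = rownames(value_table)) {
  value_table <- as.matrix(value_table)
  miss <- setdiff(features, rownames(value_table))
  if (length(miss) > 0) {
    stop("feature(s) absent from table: ", paste(miss, collapse = ", "))
  }
  grp <- stats::setNames(groups$group, groups$patient_id)
  ids <- intersect(colnames(value_table), names(grp))
  g <- unname(grp[ids])
  if (!all(c("high", "low") %in% g)) stop("both risk groups must be nonempty")
  rows <- lapply(features, function(f) {
    v <- value_table[f, ids]
    wt <- suppressWarnings(stats::wilcox.test(v[g == "high"],
                                              v[g == "low"]))
    dmed <- stats::median(v[g == "high"]) - stats::median(v[g == "low"])
    data.frame(feature = f, test = "wilcoxon",
               statistic = unname(wt$statistic), p = wt$p.value,
               direction = ifelse(dmed >= 0, "positive", "negative"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' qRT-PCR delta-Ct pair call
#'
#' The delta-Ct of a gene (mean Ct minus mean Ct of the reference gene,
#' e.g. GAPDH) is inversely related to expression, so the pair-ordering
#' indicator translates to: call 1 iff the former gene's delta-Ct is
#' *lower* than the latter's; equality gives 0, matching the expression
#' tie rule. When delta-Ct equals `-log2(expression) + constant`, the call
#' agrees exactly with the expression-based pair indicator.
#'
#' @param dct_former,dct_latter finite delta-Ct values (vectors allowed).
#' @return Integer 0/1 call(s).
#' @export
pcr_pair_call <- function(dct_former, dct_latter) {
  if (any(!is.finite(dct_former)) || any(!is.finite(dct_latter))) {
    stop("missing or non-finite delta-Ct value")
  }
  as.integer(dct_former < dct_latter)
}

#' Chi-square test of pair calls across stage groups
#'
#' Builds the 2x2 table of pair call (0/1) against stage group (e.g.
#' I-III vs IV) and applies Pearson's chi-square test, without continuity
#' correction by default. A zero row or column margin makes the table
#' untestable.
#'
#' @param calls integer 0/1 vector of [pcr_pair_call()] results.
#' @param stage_group character vector (two levels), same length.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return data.frame: `test`, `statistic`, `p`, `direction` and the
#'   table as attribute `"table"`; or `statistic`/`p` `NA` with
#'   `direction = "not-testable"` when a margin is zero.
#' @export
pcr_stage_test <- function(calls, stage_group, correct = FALSE) {
  stopifnot(length(calls) == length(stage_group))
  tab <- table(factor(calls, levels = c(0, 1)), stage_group)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out <- data.frame(test = "chisq", statistic = NA_real_, p = NA_real_,
                      direction = "not-testable", stringsAsFactors = FALSE)
    attr(out, "table") <- tab
    return(out)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  p1 <- prop.table(tab, 2)["1", ]
  out <- data.frame(test = "chisq", statistic = unname(ct$statistic),
                    p = ct$p.value,
                    direction = ifelse(p1[1] >= p1[2], "positive",
                                       "negative"),
                    stringsAsFactors = FALSE)
  attr(out, "table") <- tab
  out
}
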