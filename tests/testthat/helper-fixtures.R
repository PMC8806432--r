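# Small cohort specs and hand-built objects shared across test files.

tiny_spec <- function(n_tumor = 100, n_normal = 20, seed = 1L,
                      beta = 1.0, censor_rate = 0.2, ...) {
  simulation_spec(
    n_tumor = n_tumor, n_normal = n_normal,
    n_lncRNA = 12, n_mRNA = 8, n_immune_genes = 5, n_irlnc = 5, n_de = 4,
    planted_pairs = data.frame(a = 1L, b = 2L, beta = beta, mu_offset = 0),
    censor_rate = censor_rate, seed = seed, ...)
}

# ExpressionMatrix whose log2(x+1) values equal the given matrix.
expr_from_log <- function(logmat, group = NULL, immune = NULL) {
  if (is.null(group)) group <- rep("tumor", ncol(logmat))
  if (is.null(immune)) immune <- rep(FALSE, nrow(logmat))
  biotype <- ifelse(grepl("^LNC", rownames(logmat)), "lncRNA", "mRNA")
  expression_matrix(2^logmat - 1, group,
                    data.frame(gene_id = rownames(logmat),
                               biotype = biotype, immune_flag = immune))
}

# PairMatrix with a single given indicator row, for feeding Cox helpers.
pm_from_indicator <- function(x, ids = NULL, pair_id = "A|B") {
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(x))
  P <- matrix(as.integer(x), nrow = 1,
              dimnames = list(pair_id, ids))
  structure(list(pairs = data.frame(pair_id = pair_id,
                                    gene_a = sub("\\|.*", "", pair_id),
                                    gene_b = sub(".*\\|", "", pair_id),
                                    stringsAsFactors = FALSE),
                 P = P, freq1 = rowMeans(P)),
            class = "PairMatrix")
}

# Stack several indicator rows into a PairMatrix.
pm_from_rows <- function(M, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(ncol(M)))
  colnames(M) <- ids
  ab <- strsplit(rownames(M), "|", fixed = TRUE)
  structure(list(pairs = data.frame(pair_id = rownames(M),
                                    gene_a = vapply(ab, `[`, "", 1),
                                    gene_b = vapply(ab, `[`, "", 2),
                                    stringsAsFactors = FALSE),
                 P = M, freq1 = rowMeans(M)),
            class = "PairMatrix")
}

surv_from <- function(time, event, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(time))
  survival_table(ids, time, event, ...)
}
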