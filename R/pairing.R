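#' Binary relative-ordering pair matrix
#'
#' The core encoding of the pair-signature method: every unordered gene
#' pair (taken once, in canonical gene order) becomes a row of a 0/1
#' matrix whose entry for sample `s` is 1 when the first gene's expression
#' strictly exceeds the second gene's in `s`, and 0 otherwise (ties score
#' 0). The indicator depends only on the within-sample ordering of the two
#' genes, so it is invariant to any strictly increasing per-sample
#' transform of the expression values -- no normalization across samples
#' or platforms is required.
#'
#' @param expr an [expression_matrix()] (or bare numeric matrix with gene
#'   rownames) restricted to the genes of interest, e.g. the DE
#'   irlncRNAs. Raw-scale values are used; the result is identical on any
#'   monotone scale.
#' @param genes gene ids to pair, in canonical order; default all rows.
#' @param samples sample ids (columns) to score; default the tumor
#'   samples when `expr` is an `ExpressionMatrix`, else all columns.
#' @return An object of class `PairMatrix`: list with `pairs` (data.frame
#'   `pair_id`, `gene_a`, `gene_b`), `P` (binary pairs x samples matrix,
#'   rownames `geneA|geneB`), and `freq1` (row means of `P`). The
#'   unfiltered pair count is `choose(n_genes, 2)`.
#' @export
build_pair_matrix <- function(expr, genes = NULL, samples = NULL) {
  X <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (is.null(samples)) {
    samples <- if (inherits(expr, "ExpressionMatrix")) tumor_samples(expr)
               else colnames(X)
  }
  if (is.null(genes)) genes <- rownames(X)
  genes <- genes[genes %in% rownames(X)]
  if (length(genes) < 2) stop("need at least 2 genes to build pairs")
  if (length(samples) < 1) stop("need at least 1 sample")
  X <- X[genes, samples, drop = FALSE]

  idx <- utils::combn(length(genes), 2)            # canonical i < j sweep
  ia <- idx[1, ]; ib <- idx[2, ]
  P <- (X[ia, , drop = FALSE] > X[ib, , drop = FALSE]) + 0L
  pair_id <- paste(genes[ia], genes[ib], sep = "|")
  rownames(P) <- pair_id
  pairs <- data.frame(pair_id = pair_id, gene_a = genes[ia],
                      gene_b = genes[ib], stringsAsFactors = FALSE)
  structure(list(pairs = pairs, P = P, freq1 = rowMeans(P)),
            class = "PairMatrix")
}

#' @method print PairMatrix
#' @export
print.PairMatrix <- function(x, ...) {
  cat(sprintf("PairMatrix: %d pairs x %d samples (freq1 range %.3f-%.3f)\n",
              nrow(x$P), ncol(x$P),
              if (nrow(x$P)) min(x$freq1) else NA,
              if (nrow(x$P)) max(x$freq1) else NA))
  invisible(x)
}

#' Keep pairs with informative one-frequency
#'
#' A pair whose indicator is (nearly) constant across the cohort carries
#' no ordering information; only pairs with a one-frequency strictly
#' inside `(low, high)` are retained (default band 0.20--0.80, strict on
#' both sides). Idempotent; an empty result is allowed and logged.
#'
#' @param pm a [build_pair_matrix()] result.
#' @param low,high open band bounds, `low < high`.
#' @return The filtered `PairMatrix`.
#' @export
filter_valid_pairs <- function(pm, low = 0.20, high = 0.80) {
  stopifnot(inherits(pm, "PairMatrix"), low < high)
  keep <- pm$freq1 > low & pm$freq1 < high
  if (!any(keep)) message("filter_valid_pairs: no pairs retained")
  structure(list(pairs = pm$pairs[keep, , drop = FALSE],
                 P = pm$P[keep, , drop = FALSE],
                 freq1 = pm$freq1[keep]),
            class = "PairMatrix")
}

#' Subset a pair matrix by pair id
#'
#' @param pm a `PairMatrix`.
#' @param pair_ids pair ids to keep, in the given order.
#' @return The subset `PairMatrix`; missing ids are an error.
#' @export
subset_pairs <- function(pm, pair_ids) {
  miss <- setdiff(pair_ids, pm$pairs$pair_id)
  if (length(miss) > 0) {
    stop("pair(s) not present: ", paste(miss, collapse = ", "))
  }
  i <- match(pair_ids, pm$pairs$pair_id)
  structure(list(pairs = pm$pairs[i, , drop = FALSE],
                 P = pm$P[i, , drop = FALSE],
                 freq1 = pm$freq1[i]),
            class = "PairMatrix")
}

#' Write / read a pair matrix as TSV
#'
#' Columns: `pair_id`, `gene_a`, `gene_b`, `freq1`, then one 0/1 column
#' per sample.
#'
#' @param pm a `PairMatrix`; `path` a TSV path.
#' @return The object (read) or input invisibly (write).
#' @export
write_pairs <- function(pm, path) {
  tab <- data.frame(pm$pairs, freq1 = pm$freq1, pm$P, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pm)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  P <- as.matrix(tab[, -(1:4), drop = FALSE])
  storage.mode(P) <- "integer"
  rownames(P) <- tab$pair_id
  structure(list(pairs = tab[, c("pair_id", "gene_a", "gene_b")],
                 P = P, freq1 = tab$freq1),
            class = "PairMatrix")
}
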