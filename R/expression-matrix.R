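#' Expression matrix with sample groups and gene annotation
#'
#' Container tying together a genes-by-samples matrix of non-negative
#' expression values (FPKM/TPM-like), a tumor/normal label per sample, and
#' per-gene metadata distinguishing mRNAs from lncRNAs and flagging the
#' immune-related mRNAs. All downstream stages consume this object.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); finite and >= 0.
#' @param sample_group character/factor vector, one of `"tumor"`/`"normal"`
#'   per column of `values`.
#' @param gene_meta data.frame with columns `gene_id`, `biotype`
#'   (`"mRNA"`/`"lncRNA"`) and logical `immune_flag`, one row per row of
#'   `values`, in the same order (this order is the canonical gene order
#'   used for pairing).
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `sample_group` (named character) and `gene_meta`.
#' @export
expression_matrix <- function(values, sample_group, gene_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  }
  if (anyDuplicated(gid)) {
    stop("duplicated gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-finite or negative expression at gene '%s', sample '%s'",
                 gid[bad[1, 1]], sid[bad[1, 2]]))
  }
  sample_group <- as.character(sample_group)
  if (length(sample_group) != ncol(values)) {
    stop("`sample_group` must have one entry per sample")
  }
  if (!all(sample_group %in% c("tumor", "normal"))) {
    stop("`sample_group` entries must be 'tumor' or 'normal'")
  }
  names(sample_group) <- sid
  gene_meta <- as.data.frame(gene_meta)
  need <- c("gene_id", "biotype", "immune_flag")
  if (!all(need %in% names(gene_meta))) {
    stop("`gene_meta` needs columns: ", paste(need, collapse = ", "))
  }
  if (!identical(as.character(gene_meta$gene_id), gid)) {
    stop("`gene_meta$gene_id` must match rownames(values) in order")
  }
  if (!all(gene_meta$biotype %in% c("mRNA", "lncRNA"))) {
    stop("`biotype` must be 'mRNA' or 'lncRNA'")
  }
  gene_meta$immune_flag <- as.logical(gene_meta$immune_flag)
  structure(list(values = values, sample_group = sample_group,
                 gene_meta = gene_meta),
            class = "ExpressionMatrix")
}

#' @method print ExpressionMatrix
#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_group == "tumor"), sum(x$sample_group == "normal")))
  cat(sprintf("  %d lncRNA, %d mRNA (%d immune-flagged)\n",
              sum(x$gene_meta$biotype == "lncRNA"),
              sum(x$gene_meta$biotype == "mRNA"),
              sum(x$gene_meta$immune_flag, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Convenience accessors
#'
#' @param expr an [expression_matrix()].
#' @return Character vectors of ids.
#' @export
tumor_samples <- function(expr) {
  names(expr$sample_group)[expr$sample_group == "tumor"]
}

#' @rdname tumor_samples
#' @export
lncRNA_ids <- function(expr) {
  expr$gene_meta$gene_id[expr$gene_meta$biotype == "lncRNA"]
}

#' @rdname tumor_samples
#' @export
immune_gene_ids <- function(expr) {
  m <- expr$gene_meta
  m$gene_id[m$biotype == "mRNA" & m$immune_flag %in% TRUE]
}

#' Log2(x+1) view of the expression values
#'
#' @param expr an [expression_matrix()].
#' @return Numeric matrix of the same shape.
#' @export
log2_values <- function(expr) log2(expr$values + 1)

#' Read an expression matrix from TSV files
#'
#' The expression TSV has a header row of sample ids and gene ids in the
#' first column; the companion files supply per-gene metadata and per-sample
#' group labels. Raw values are stored untransformed; use [log2_values()]
#' for the log scale.
#'
#' @param path expression TSV (first column `gene_id`, then one column per
#'   sample).
#' @param gene_meta_path TSV with columns `gene_id`, `biotype`,
#'   `immune_flag`.
#' @param sample_group_path TSV with columns `sample_id`, `group`.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, gene_meta_path, sample_group_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c("character"), row.names = NULL)
  gid <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  nonnum <- which(is.na(vals) & !is.na(as.matrix(tab[, -1, drop = FALSE])),
                  arr.ind = TRUE)
  if (nrow(nonnum) > 0) {
    stop(sprintf("non-numeric expression at gene '%s', sample '%s'",
                 gid[nonnum[1, 1]], colnames(vals)[nonnum[1, 2]]))
  }
  rownames(vals) <- gid
  meta <- utils::read.delim(gene_meta_path, check.names = FALSE)
  meta$gene_id <- as.character(meta$gene_id)
  meta <- meta[match(gid, meta$gene_id), , drop = FALSE]
  if (anyNA(meta$gene_id)) stop("gene metadata missing for some genes")
  grp <- utils::read.delim(sample_group_path, check.names = FALSE)
  sg <- as.character(grp$group)[match(colnames(vals), as.character(grp$sample_id))]
  if (anyNA(sg)) stop("sample group missing for some samples")
  expression_matrix(vals, sg, meta)
}

#' Write an expression matrix to TSV files
#'
#' Inverse of [read_expression()]; the three files round-trip the object.
#'
#' @param expr an `ExpressionMatrix`.
#' @param path,gene_meta_path,sample_group_path output TSV paths.
#' @return `expr`, invisibly.
#' @export
write_expression <- function(expr, path, gene_meta_path, sample_group_path) {
  tab <- data.frame(gene_id = rownames(expr$values), expr$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$gene_meta, gene_meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  grp <- data.frame(sample_id = names(expr$sample_group),
                    group = unname(expr$sample_group))
  utils::write.table(grp, sample_group_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr)
}
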