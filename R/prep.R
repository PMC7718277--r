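#' Library-size normalized log expression
#'
#' Counts per 10,000 per cell, then `log1p`. This is the convention under
#' which the variable-gene thresholds (mean window 0.0125-4, log dispersion
#' > 0.5) are interpreted; it follows the Seurat variable-gene convention.
#' Cells with zero total counts are left at zero.
#'
#' @param counts Cells x genes non-negative matrix.
#' @return Matrix of the same shape.
#' @export
normalize_log_cp10k <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  log1p(counts / lib * 1e4)
}

#' Select highly variable genes
#'
#' A gene is retained when its mean (normalized log expression) lies strictly
#' inside `mean_range` and the natural log of its dispersion
#' (variance / mean) exceeds `min_log_dispersion`. Genes with zero mean have
#' undefined dispersion and are excluded (they fail the lower mean bound
#' anyway).
#'
#' @param counts Cells x genes non-negative count matrix with column names.
#' @param mean_range Length-2 exclusive window for the gene mean.
#' @param min_log_dispersion Threshold on `log(variance/mean)`.
#' @param normalize If `TRUE` (default) compute the statistics on
#'   [normalize_log_cp10k()] of the counts; if `FALSE` use the matrix as
#'   given (e.g. already-normalized input).
#' @return Character vector of gene names passing both filters (in column
#'   order).
#' @export
select_variable_genes <- function(counts, mean_range = c(0.0125, 4),
                                  min_log_dispersion = 0.5,
                                  normalize = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("dispersion undefined with fewer than 2 cells")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(colnames(counts))) stop("counts must have gene column names")
  x <- if (normalize) normalize_log_cp10k(counts) else counts
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  keep <- mu > mean_range[1] & mu < mean_range[2] &
    disp > 0 & log(disp) > min_log_dispersion
  colnames(counts)[keep]
}

#' Keep only unambiguous (one-to-one) ortholog pairs
#'
#' A pair survives iff its source gene and its target gene each occur exactly
#' once in the input table: any gene involved in a one-to-many mapping drops
#' out together with all its pairs.
#'
#' @param orthologs data.frame with columns `source_gene`, `target_gene`.
#' @return Filtered data.frame (possibly empty), row order preserved.
#' @export
filter_unambiguous <- function(orthologs) {
  stopifnot(all(c("source_gene", "target_gene") %in% names(orthologs)))
  src_n <- table(orthologs$source_gene)
  tgt_n <- table(orthologs$target_gene)
  keep <- src_n[orthologs$source_gene] == 1 & tgt_n[orthologs$target_gene] == 1
  out <- orthologs[keep, c("source_gene", "target_gene"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binarize an expression matrix
#'
#' Entry 1 iff the raw value is strictly positive. Idempotent.
#'
#' @param m Numeric matrix.
#' @return Integer 0/1 matrix of the same shape and dimnames.
#' @export
binarize <- function(m) {
  out <- (as.matrix(m) > 0) * 1L
  dimnames(out) <- dimnames(m)
  out
}

#' A binarized dataset
#'
#' Cells x genes 0/1 matrix with per-cell class labels and a species tag.
#'
#' @param matrix Cells x genes matrix with entries in `{0, 1}`.
#' @param labels Per-cell class labels (length = rows).
#' @param species Species tag string.
#' @param gene_names Column gene names (defaults to `colnames(matrix)`).
#' @return Object of class `binarized_dataset`.
#' @export
binarized_dataset <- function(matrix, labels, species = "unknown",
                              gene_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (!all(matrix %in% c(0, 1))) stop("matrix entries must be 0/1")
  if (length(labels) != nrow(matrix)) stop("labels length != number of cells")
  if (is.null(gene_names) || length(gene_names) != ncol(matrix)) {
    stop("gene_names must align with matrix columns")
  }
  if (anyDuplicated(gene_names)) stop("duplicate gene names")
  storage.mode(matrix) <- "integer"
  colnames(matrix) <- gene_names
  structure(list(matrix = matrix, labels = as.character(labels),
                 species = species, gene_names = gene_names),
            class = "binarized_dataset")
}

#' @export
print.binarized_dataset <- function(x, ...) {
  cat(sprintf("binarized_dataset (%s): %d cells x %d genes, %d classes\n",
              x$species, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$labels))))
  invisible(x)
}

#' Build the aligned cross-species feature space
#'
#' The machine-learning feature set is the union of genes variable in the
#' source and genes variable in the target (the latter mapped to source
#' names), restricted to unambiguous ortholog pairs. Both outputs share the
#' same column order (sorted by source gene name) and entries are binarized
#' (1 iff raw count > 0); target columns are the orthologous target genes in
#' matching positions.
#'
#' @param source_counts,target_counts Cells x genes count matrices with gene
#'   column names.
#' @param orthologs Ortholog table (filtered internally with
#'   [filter_unambiguous()]).
#' @param source_labels,target_labels Per-cell class labels.
#' @param ... Passed to [select_variable_genes()].
#' @return List with `source` and `target` `binarized_dataset`s and
#'   `features` (data.frame source_gene, target_gene of the columns).
#' @export
build_feature_space <- function(source_counts, target_counts, orthologs,
                                source_labels = rep(NA_character_, nrow(source_counts)),
                                target_labels = rep(NA_character_, nrow(target_counts)),
                                ...) {
  orth <- filter_unambiguous(orthologs)
  var_src <- select_variable_genes(source_counts, ...)
  var_tgt <- select_variable_genes(target_counts, ...)
  # map target-variable genes to source names through the 1:1 table
  tgt2src <- stats::setNames(orth$source_gene, orth$target_gene)
  src2tgt <- stats::setNames(orth$target_gene, orth$source_gene)
  union_src <- union(intersect(var_src, orth$source_gene),
                     unname(tgt2src[intersect(var_tgt, orth$target_gene)]))
  union_src <- sort(union_src)
  # restrict to genes actually present in both matrices
  union_src <- union_src[union_src %in% colnames(source_counts) &
                           src2tgt[union_src] %in% colnames(target_counts)]
  if (length(union_src) == 0) {
    stop("empty feature set after variable-gene and ortholog filtering")
  }
  cols_tgt <- unname(src2tgt[union_src])
  list(
    source = binarized_dataset(binarize(source_counts[, union_src, drop = FALSE]),
                               source_labels, species = "source"),
    target = binarized_dataset(binarize(target_counts[, cols_tgt, drop = FALSE]),
                               target_labels, species = "target"),
    features = data.frame(source_gene = union_src, target_gene = cols_tgt,
                          stringsAsFactors = FALSE)
  )
}
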