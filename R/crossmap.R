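#' Stand-in normalization for cross-species similarity analysis
#'
#' Produces a residual-like matrix from raw counts: log1p of counts per
#' 10,000, then per-gene centering and unit-variance scaling. Externally
#' computed residual matrices (e.g. from a variance-stabilizing model) can be
#' supplied to the downstream functions instead; this helper only keeps the
#' pipeline self-contained. Genes with zero variance are left centered at 0.
#'
#' @param counts Cells x genes count matrix.
#' @return Cells x genes residual matrix.
#' @export
normalize_residuals <- function(counts) {
  x <- normalize_log_cp10k(counts)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(x, 2, mu, `-`), 2, sd, `/`)
}

#' Fit source-domain PCA
#'
#' Standard PCA of the source residual matrix. The number of retained
#' components is either fixed (default 16) or chosen by the scree inflection
#' rule: the largest second difference of the sorted eigenvalue curve.
#'
#' @param residuals Cells x genes source residual matrix.
#' @param n_pc Components to keep, or `"scree"` for the inflection rule.
#' @return Object of class `pc_space`: `loadings` (genes x n_pc, orthonormal
#'   columns), `center` (source gene means), `explained_variance`, `n_pc`.
#' @export
fit_pca_source <- function(residuals, n_pc = 16) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 2) stop("need >= 2 cells for PCA")
  pr <- stats::prcomp(residuals, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  if (identical(n_pc, "scree")) {
    # inflection: max second difference of the eigenvalue curve
    if (length(ev) < 3) stop("scree rule needs >= 3 components")
    d2 <- diff(ev, differences = 2)
    # d2[i] is the curvature at component i + 1; keep up to the sharpest bend
    n_pc <- which.max(d2) + 1L
  }
  avail <- sum(ev > 1e-12)
  if (n_pc > avail) {
    warning("requested ", n_pc, " components but rank is ", avail,
            "; reducing")
    n_pc <- avail
  }
  structure(list(loadings = pr$rotation[, seq_len(n_pc), drop = FALSE],
                 center = pr$center,
                 explained_variance = ev[seq_len(n_pc)],
                 n_pc = as.integer(n_pc)),
            class = "pc_space")
}

#' @export
print.pc_space <- function(x, ...) {
  cat(sprintf("pc_space: %d genes -> %d components\n",
              nrow(x$loadings), x$n_pc))
  invisible(x)
}

#' Project data onto a source principal-component space
#'
#' Scores = (X - source gene means) %*% loadings. Both species are centered
#' with the SOURCE means so target cells land in the source frame; the gene
#' columns must match the loadings' gene order.
#'
#' @param residuals Cells x genes matrix, gene columns aligned with the
#'   space's loadings.
#' @param space A `pc_space`.
#' @return Cells x n_pc score matrix.
#' @export
project_target <- function(residuals, space) {
  stopifnot(inherits(space, "pc_space"))
  residuals <- as.matrix(residuals)
  if (ncol(residuals) != nrow(space$loadings)) {
    stop(sprintf("gene mismatch: space has %d genes, data has %d",
                 nrow(space$loadings), ncol(residuals)))
  }
  if (!is.null(colnames(residuals)) && !is.null(rownames(space$loadings)) &&
      !identical(colnames(residuals), rownames(space$loadings))) {
    bad <- which(colnames(residuals) != rownames(space$loadings))
    stop("gene order mismatch at column(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  sweep(residuals, 2, space$center, `-`) %*% space$loadings
}

#' L1 mediancentre of a point set
#'
#' The point minimizing the sum of L1 distances to the rows of `points`.
#' Because the L1 objective separates by coordinate, the minimizer is the
#' coordinate-wise median; for an even number of points the midpoint of the
#' two central order statistics is returned (any point between them is
#' optimal).
#'
#' @param points n x d numeric matrix (n >= 1).
#' @return Object of class `mediancentre`: `centre` (length-d vector) and
#'   `objective` (the minimal L1 distance sum).
#' @export
mediancentre <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point set")
  centre <- apply(points, 2, stats::median)
  objective <- sum(abs(sweep(points, 2, centre, `-`)))
  structure(list(centre = centre, objective = objective),
            class = "mediancentre")
}

#' Per-cell-type mediancentres of PC scores
#'
#' @param scores Cells x n_pc score matrix.
#' @param labels Per-cell type labels.
#' @return Named list of centre vectors (one per type).
#' @export
type_mediancentres <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(scores))
  lapply(split(seq_along(labels), labels), function(ix) {
    mediancentre(scores[ix, , drop = FALSE])$centre
  })
}

#' Cosine similarity between source and target cell-type centres
#'
#' `s(u, v) = u . v / (|u| |v|)` over all source x target type pairs. A zero
#' vector gets similarity 0 with a warning.
#'
#' @param centres_source,centres_target Named lists of equal-dimension
#'   numeric vectors.
#' @return Matrix (source types x target types) of similarities in
#'   `[-1, 1]`.
#' @export
cosine_similarity_matrix <- function(centres_source, centres_target) {
  d <- unique(c(lengths(centres_source), lengths(centres_target)))
  if (length(d) != 1) stop("centre vectors differ in dimension")
  sim <- matrix(0, length(centres_source), length(centres_target),
                dimnames = list(names(centres_source), names(centres_target)))
  warned <- FALSE
  for (i in seq_along(centres_source)) {
    for (j in seq_along(centres_target)) {
      u <- centres_source[[i]]; v <- centres_target[[j]]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0) {
        if (!warned) { warning("zero-length centre vector; similarity set to 0") }
        warned <- TRUE
        sim[i, j] <- 0
      } else {
        sim[i, j] <- sum(u * v) / (nu * nv)
      }
    }
  }
  sim
}

#' Cross-species cell-type similarity from counts
#'
#' End-to-end convenience wrapper: normalizes both species (stand-in
#' residuals), fits PCA in the source domain, projects both species onto the
#' source components, computes per-type L1 mediancentres and returns their
#' cosine-similarity matrix. Target labels may come from unsupervised
#' clustering or from model predictions — both variants are just label
#' vectors here.
#'
#' @param source_counts,target_counts Cells x genes count matrices on
#'   aligned ortholog columns (same column count and order).
#' @param source_labels,target_labels Per-cell type labels.
#' @param n_pc Principal components to keep (default 16) or `"scree"`.
#' @return List: `similarity` (source x target types), `space` (`pc_space`),
#'   `centres_source`, `centres_target`.
#' @export
crossmap_similarity <- function(source_counts, target_counts,
                                source_labels, target_labels, n_pc = 16) {
  if (ncol(source_counts) != ncol(target_counts)) {
    stop("source and target must share the aligned ortholog columns")
  }
  src_res <- normalize_residuals(source_counts)
  tgt_res <- normalize_residuals(target_counts)
  colnames(tgt_res) <- colnames(src_res)  # aligned ortholog columns
  space <- fit_pca_source(src_res, n_pc = n_pc)
  src_scores <- project_target(src_res, space)
  tgt_scores <- project_target(tgt_res, space)
  cs <- type_mediancentres(src_scores, source_labels)
  ct <- type_mediancentres(tgt_scores, target_labels)
  list(similarity = cosine_similarity_matrix(cs, ct), space = space,
       centres_source = cs, centres_target = ct)
}
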