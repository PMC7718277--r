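#' Rank genes by multinomial-regression weight
#'
#' For an MLR on binarized inputs all features share the same scale, so the
#' input-to-class weight vector reads directly as per-class feature
#' importance. Genes are sorted per class by descending signed weight; ties
#' break alphabetically by gene name.
#'
#' @param model A `classifier_model` with `hidden_units = 0`.
#' @return Object of class `sensitivity_matrix`: `values` (genes x classes
#'   score matrix) and `ranked_lists` (per class, gene names in descending
#'   importance).
#' @export
rank_genes_mlr <- function(model) {
  stopifnot(inherits(model, "classifier_model"))
  if (model$spec$hidden_units != 0) {
    stop("model has a hidden layer; use mi_sensitivity() for ANN importance")
  }
  W <- model$weights$W
  genes <- model$gene_names
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(W)))
  dimnames(W) <- list(genes, model$class_names)
  ranked <- lapply(stats::setNames(model$class_names, model$class_names),
                   function(k) genes[order(-W[, k], genes)])
  structure(list(values = W, ranked_lists = ranked, method = "mlr_weights"),
            class = "sensitivity_matrix")
}

#' Discretize posterior probabilities into three bins
#'
#' Bin 1 for y in `[0, 1/3]`, bin 2 for `(1/3, 2/3]`, bin 3 for `(2/3, 1]`
#' (closed on the right). Entries outside `[0, 1]` beyond a 1e-9 tolerance
#' are an error.
#'
#' @param Y Posterior matrix with entries in `[0, 1]`.
#' @return Integer matrix of the same shape with entries in `{1, 2, 3}`.
#' @export
discretize_posteriors <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < -1e-9 | Y > 1 + 1e-9)) {
    stop("posterior entries outside [0, 1]")
  }
  B <- matrix(1L, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  B[Y > 1 / 3] <- 2L
  B[Y > 2 / 3] <- 3L
  B
}

# Plug-in MI (nats) between a binary column x and a ternary column y from
# the empirical 2 x 3 joint table; 0 log 0 := 0.
plugin_mi_counts <- function(joint) {
  n <- sum(joint)
  if (n == 0) return(0)
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  terms <- p * log(p / outer(px, py))
  sum(terms[is.finite(terms)])
}

#' Mutual-information sensitivity of class assignments to genes
#'
#' For every gene g and class c, computes the plug-in mutual information (in
#' nats) between the binary expression vector of g and the three-binned
#' posterior for class c, from the empirical 2 x 3 joint frequency table.
#' High MI marks genes whose expression state is strongly associated with
#' assignment to the class. Per class, genes are ranked by descending MI
#' (ties alphabetical).
#'
#' @param X Cells x genes 0/1 matrix (or `binarized_dataset`).
#' @param Ybin Cells x classes matrix of bins in `{1, 2, 3}` from
#'   [discretize_posteriors()].
#' @return A `sensitivity_matrix` (`values` genes x classes, all >= 0).
#' @export
mi_sensitivity <- function(X, Ybin) {
  if (inherits(X, "binarized_dataset")) X <- X$matrix
  X <- as.matrix(X)
  Ybin <- as.matrix(Ybin)
  if (nrow(X) != nrow(Ybin)) stop("X and Ybin must have equal row counts")
  if (!all(X %in% c(0, 1))) stop("X entries must be 0/1")
  if (!all(Ybin %in% 1:3)) stop("Ybin entries must be in {1, 2, 3}")
  n <- nrow(X)
  genes <- colnames(X)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(X)))
  classes <- colnames(Ybin)
  if (is.null(classes)) classes <- sprintf("c%d", seq_len(ncol(Ybin)))
  vals <- matrix(0, ncol(X), ncol(Ybin), dimnames = list(genes, classes))
  ones <- colSums(X)
  for (c_ix in seq_len(ncol(Ybin))) {
    # counts n(x = 1, y = b) for all genes at once
    ind <- cbind(Ybin[, c_ix] == 1L, Ybin[, c_ix] == 2L, Ybin[, c_ix] == 3L)
    n1 <- crossprod(X, ind)                       # genes x 3
    nb <- colSums(ind)
    n0 <- matrix(nb, ncol(X), 3, byrow = TRUE) - n1
    px1 <- ones / n
    pb <- nb / n
    mi <- rep(0, ncol(X))
    for (b in 1:3) {
      for (counts in list(list(nc = n1[, b], pmarg = px1),
                          list(nc = n0[, b], pmarg = 1 - px1))) {
        pj <- counts$nc / n
        term <- pj * log(pj / (counts$pmarg * pb[b]))
        term[!is.finite(term)] <- 0
        mi <- mi + term
      }
    }
    vals[, c_ix] <- pmax(mi, 0)
  }
  ranked <- lapply(stats::setNames(classes, classes),
                   function(k) genes[order(-vals[, k], genes)])
  structure(list(values = vals, ranked_lists = ranked, method = "mi"),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("sensitivity_matrix (%s): %d genes x %d classes\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Overlap between the heads of two ranked gene lists
#'
#' `|top_n(A) intersect top_n(B)| / top_n` — the fraction of shared genes
#' among the top `top_n` of both rankings.
#'
#' @param listA,listB Character vectors ranking the same gene universe.
#' @param top_n Head size (>= 1, <= list length).
#' @return Overlap fraction in `[0, 1]`.
#' @export
ranked_overlap <- function(listA, listB, top_n) {
  if (top_n < 1) stop("top_n must be >= 1")
  if (top_n > length(listA) || top_n > length(listB)) {
    stop("top_n exceeds list length")
  }
  length(intersect(listA[seq_len(top_n)], listB[seq_len(top_n)])) / top_n
}
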