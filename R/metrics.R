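#' Construct a cell lineage tree
#'
#' A lineage tree is a directed acyclic graph whose nodes are cell types and
#' whose edges are direct developmental transitions (parent -> child).
#' Misclassification topology is scored on the undirected skeleton of this
#' graph: a parent mistaken for its child and a child mistaken for its parent
#' are both one edge away, hence both proximal.
#'
#' @param nodes Character vector of cell-type names (unique).
#' @param edges Two-column matrix or data.frame of parent/child node names,
#'   or a list of length-2 character vectors.
#' @return An object of class `lineage_tree` with elements `nodes`, `edges`
#'   (character matrix with columns parent, child) and `graph` (an igraph
#'   representation used for distance queries).
#' @export
lineage_tree <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names in lineage tree")
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) as.character(e)))
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns (parent, child)")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("parent", "child")
  missing <- setdiff(unique(c(edges)), nodes)
  if (length(missing)) {
    stop("edge endpoints not in node set: ", paste(missing, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) stop("lineage tree edges contain a cycle")
  if (length(nodes) > 1L && !igraph::is_connected(g, mode = "weak")) {
    stop("lineage tree must be connected (as an undirected graph)")
  }
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree:", length(x$nodes), "cell types,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read or write a lineage tree as JSON
#'
#' The on-disk format is `{"nodes": [...], "edges": [[parent, child], ...]}`.
#'
#' @param path File path.
#' @return `read_tree_json` returns a `lineage_tree`.
#' @export
read_tree_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  edges <- x$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  lineage_tree(x$nodes, edges)
}

#' @rdname read_tree_json
#' @param tree A `lineage_tree`.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "lineage_tree"))
  edges <- lapply(seq_len(nrow(tree$edges)), function(i) unname(tree$edges[i, ]))
  jsonlite::write_json(list(nodes = tree$nodes, edges = edges), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Graph distance between two cell types on the lineage tree
#'
#' Shortest-path edge count on the undirected skeleton of the tree.
#' `d = 0` means the labels agree, `d = 1` is a proximal pair (direct
#' developmental neighbours) and `d > 1` is distal.
#'
#' @param tree A `lineage_tree`.
#' @param a,b Node names (vectorized; recycled to common length).
#' @return Integer vector of distances.
#' @export
lineage_distance <- function(tree, a, b) {
  stopifnot(inherits(tree, "lineage_tree"))
  a <- as.character(a); b <- as.character(b)
  unknown <- setdiff(unique(c(a, b)), tree$nodes)
  if (length(unknown)) {
    stop("unknown lineage tree node(s): ", paste(unknown, collapse = ", "))
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  dm <- lineage_distance_matrix(tree)
  as.integer(dm[cbind(match(a, tree$nodes), match(b, tree$nodes))])
}

# Full pairwise node distance matrix (edge counts, undirected skeleton).
lineage_distance_matrix <- function(tree) {
  dm <- igraph::distances(tree$graph, mode = "all")
  dm[tree$nodes, tree$nodes, drop = FALSE]
}

#' Multiclass confusion matrix
#'
#' @param true_labels,pred_labels Character vectors of equal length.
#' @param class_order Character vector giving row/column order; both label
#'   vectors must be subsets of it.
#' @return K x K integer matrix; entry `[a, b]` counts cells of true class `a`
#'   predicted as class `b`.
#' @export
confusion_matrix <- function(true_labels, pred_labels,
                             class_order = sort(unique(c(true_labels, pred_labels)))) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors differ in length")
  }
  unknown <- setdiff(unique(c(true_labels, pred_labels)), class_order)
  if (length(unknown)) {
    stop("label(s) not in class_order: ", paste(unknown, collapse = ", "))
  }
  tt <- table(factor(true_labels, levels = class_order),
              factor(pred_labels, levels = class_order))
  cm <- matrix(as.integer(tt), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  cm
}

# one-vs-rest counts per class from a confusion matrix
ovr_counts <- function(confusion) {
  n <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- n - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Multiclass balanced accuracy
#'
#' Per class, one-vs-rest balanced accuracy is the arithmetic mean of
#' sensitivity (true-positive rate) and specificity (true-negative rate).
#' The overall value is the unweighted (macro) mean over classes, which makes
#' it robust to the extreme class imbalance typical of bone marrow data.
#' Classes with no true examples have undefined sensitivity and are excluded
#' from the overall mean with a warning.
#'
#' @param confusion K x K confusion matrix (rows true, columns predicted).
#' @return List with `per_class` (named numeric) and `overall` (scalar).
#' @export
balanced_accuracy <- function(confusion) {
  if (sum(confusion) == 0) stop("confusion matrix is all zero")
  ct <- ovr_counts(confusion)
  sens <- ct$tp / (ct$tp + ct$fn)
  spec <- ct$tn / (ct$tn + ct$fp)
  ba <- (sens + spec) / 2
  present <- (ct$tp + ct$fn) > 0
  if (any(!present)) {
    warning("class(es) with no true examples excluded from overall BA: ",
            paste(rownames(confusion)[!present], collapse = ", "))
  }
  list(per_class = ba, overall = mean(ba[present]))
}

#' Multiclass F1 scores
#'
#' Per class, F1 is the harmonic mean of precision and sensitivity; overall F1
#' is the macro average. A class with zero true positives and zero predicted
#' positives (or zero true examples) gets F1 = 0 with a warning — the
#' conventional pessimistic fallback.
#'
#' @inheritParams balanced_accuracy
#' @return List with `per_class` and `overall`.
#' @export
f1_scores <- function(confusion) {
  if (sum(confusion) == 0) stop("confusion matrix is all zero")
  ct <- ovr_counts(confusion)
  sens <- ct$tp / (ct$tp + ct$fn)
  prec <- ct$tp / (ct$tp + ct$fp)
  f1 <- 2 * prec * sens / (prec + sens)
  undef <- !is.finite(f1)
  if (any(undef)) {
    warning("F1 undefined (no true and/or predicted positives) set to 0 for: ",
            paste(rownames(confusion)[undef], collapse = ", "))
    f1[undef] <- 0
  }
  present <- (ct$tp + ct$fn) > 0
  list(per_class = f1, overall = mean(f1[present]))
}

#' Proximal and distal misclassification rates on the lineage tree
#'
#' A misclassified cell is proximal if its predicted class sits one edge from
#' the true class on the lineage tree, and distal if it sits further away.
#' Rates are fractions of each class's true (known-positive) examples, so per
#' class correct + proximal + distal = 1.
#'
#' @param tree A `lineage_tree`.
#' @param true_labels,pred_labels Character label vectors.
#' @return List with `per_class` data.frame (class, n, correct, proximal,
#'   distal) and `overall` named vector (rates over all cells of represented
#'   classes).
#' @export
misclassification_topology <- function(tree, true_labels, pred_labels) {
  stopifnot(inherits(tree, "lineage_tree"))
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors differ in length")
  }
  d <- lineage_distance(tree, true_labels, pred_labels)
  cls <- tree$nodes[tree$nodes %in% unique(true_labels)]
  per <- do.call(rbind, lapply(cls, function(k) {
    sel <- true_labels == k
    n <- sum(sel)
    data.frame(class = k, n = n,
               correct = sum(d[sel] == 0) / n,
               proximal = sum(d[sel] == 1) / n,
               distal = sum(d[sel] > 1) / n,
               stringsAsFactors = FALSE)
  }))
  overall <- c(correct = sum(d == 0), proximal = sum(d == 1),
               distal = sum(d > 1)) / length(d)
  list(per_class = per, overall = overall)
}

#' Full evaluation report for a set of predictions
#'
#' Bundles the confusion matrix, per-class sensitivity/specificity/precision,
#' balanced accuracy and F1 (per class and macro-averaged), and — when a
#' lineage tree is supplied — proximal/distal misclassification rates.
#'
#' @param true_labels,pred_labels Character label vectors.
#' @param class_order Class order for the confusion matrix.
#' @param tree Optional `lineage_tree` for misclassification topology.
#' @return An object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(true_labels, pred_labels,
                                 class_order = sort(unique(c(true_labels, pred_labels))),
                                 tree = NULL) {
  cm <- confusion_matrix(true_labels, pred_labels, class_order)
  ct <- ovr_counts(cm)
  ba <- withCallingHandlers(balanced_accuracy(cm),
                            warning = function(w) invokeRestart("muffleWarning"))
  f1 <- withCallingHandlers(f1_scores(cm),
                            warning = function(w) invokeRestart("muffleWarning"))
  per_class <- data.frame(
    class = rownames(cm),
    n = as.integer(ct$tp + ct$fn),
    sensitivity = ct$tp / (ct$tp + ct$fn),
    specificity = ct$tn / (ct$tn + ct$fp),
    precision = ct$tp / (ct$tp + ct$fp),
    balanced_accuracy = ba$per_class,
    f1 = f1$per_class,
    stringsAsFactors = FALSE, row.names = NULL
  )
  topo <- if (!is.null(tree)) {
    misclassification_topology(tree, true_labels, pred_labels)
  }
  structure(list(confusion = cm, per_class = per_class,
                 overall_ba = ba$overall, overall_f1 = f1$overall,
                 topology = topo),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d classes, %d cells\n",
              nrow(x$confusion), sum(x$confusion)))
  cat(sprintf("  overall balanced accuracy: %.3f\n", x$overall_ba))
  cat(sprintf("  overall macro F1:          %.3f\n", x$overall_f1))
  if (!is.null(x$topology)) {
    ov <- x$topology$overall
    cat(sprintf("  proximal %.3f / distal %.3f misclassification\n",
                ov[["proximal"]], ov[["distal"]]))
  }
  invisible(x)
}
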