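# Shared fixtures, built in code at test time.

# Small paired dataset for pipeline tests (fast to generate).
small_pair <- function(seed = 7, ...) {
  generate_pair(default_sim_config(
    seed = seed, n_genes = 300, n_cells_source = 900, n_cells_target = 700,
    ...))
}

# Linearly separable three-class toy: disjoint gene programs, no noise
# overlap between programs.
separable_toy <- function(n_per_class = 100, n_genes = 30, seed = 1) {
  set.seed(seed)
  classes <- c("A", "B", "C")
  third <- n_genes %/% 3
  prog <- list(A = 1:(third - 2),
               B = (third + 1):(2 * third - 2),
               C = (2 * third + 1):(3 * third - 2))
  rows <- lapply(classes, function(k) {
    p <- rep(0.02, n_genes)
    p[prog[[k]]] <- 0.9
    matrix(stats::rbinom(n_per_class * n_genes, 1, rep(p, each = n_per_class)),
           nrow = n_per_class)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("g%02d", seq_len(n_genes))
  binarized_dataset(m, rep(classes, each = n_per_class), species = "toy")
}

# Simple four-node chain used in the lineage-distance examples.
chain_tree <- function() {
  lineage_tree(c("HSPC", "Myeloblast", "Myelocyte", "Neutrophil"),
               rbind(c("HSPC", "Myeloblast"),
                     c("Myeloblast", "Myelocyte"),
                     c("Myelocyte", "Neutrophil")))
}

# Random connected tree over n nodes (each node's parent drawn among its
# predecessors), for property tests.
random_tree <- function(n_nodes) {
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  edges <- do.call(rbind, lapply(2:n_nodes, function(i) {
    c(nodes[sample.int(i - 1, 1)], nodes[i])
  }))
  lineage_tree(nodes, edges)
}

# Breadth-first-search distance oracle, independent of igraph.
bfs_distance <- function(tree, a, b) {
  if (a == b) return(0L)
  adj <- list()
  for (i in seq_len(nrow(tree$edges))) {
    p <- tree$edges[i, 1]; ch <- tree$edges[i, 2]
    adj[[p]] <- c(adj[[p]], ch)
    adj[[ch]] <- c(adj[[ch]], p)
  }
  dist <- stats::setNames(rep(NA_integer_, length(tree$nodes)), tree$nodes)
  dist[a] <- 0L
  queue <- a
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        if (nb == b) return(dist[nb])
        queue <- c(queue, nb)
      }
    }
  }
  dist[b]
}

# Brute-force plug-in mutual information by double sum over the joint table.
mi_bruteforce <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (xv in unique(x)) {
    for (yv in unique(y)) {
      pxy <- sum(x == xv & y == yv) / n
      if (pxy > 0) {
        mi <- mi + pxy * log(pxy / ((sum(x == xv) / n) * (sum(y == yv) / n)))
      }
    }
  }
  mi
}

# A classifier_model that always predicts `label` (huge bias on one class).
constant_model <- function(class_names, label, n_inputs = 4, bias = 50) {
  spec <- architecture_spec(n_inputs, 0, length(class_names))
  m <- init_classifier(spec, class_names)
  m$weights$W[] <- 0
  m$weights$b <- rep(0, length(class_names))
  m$weights$b[match(label, class_names)] <- bias
  m
}
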