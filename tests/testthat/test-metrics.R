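test_that("confusion matrix counts true/predicted pairs exactly", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(cm, matrix(c(1L, 0L, 1L, 1L),
                              nrow = 2,
                              dimnames = list(true = c("A", "B"),
                                              predicted = c("A", "B"))))

  # perfect predictions give a diagonal matrix
  lab <- rep(c("x", "y", "z"), times = c(3, 2, 5))
  cm2 <- confusion_matrix(lab, lab, c("x", "y", "z"))
  expect_equal(cm2, diag(c(3L, 2L, 5L)), ignore_attr = TRUE)

  # 1000 random pairs against a dictionary-counting oracle
  set.seed(42)
  classes <- LETTERS[1:6]
  tr <- sample(classes, 1000, replace = TRUE)
  pr <- sample(classes, 1000, replace = TRUE)
  cm3 <- confusion_matrix(tr, pr, classes)
  oracle <- matrix(0L, 6, 6, dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(tr)) oracle[tr[i], pr[i]] <- oracle[tr[i], pr[i]] + 1L
  expect_equal(unname(cm3), unname(oracle))

  expect_error(confusion_matrix(c("A", "Q"), c("A", "A"), "A"), "Q")
})

test_that("balanced accuracy matches hand arithmetic and chance level", {
  expect_equal(balanced_accuracy(diag(5L) * 3L)$overall, 1)

  cm <- matrix(c(8, 4, 2, 6), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ba <- balanced_accuracy(cm)
  expect_equal(unname(ba$per_class), c(0.7, 0.7))
  expect_equal(ba$overall, 0.7)

  # uniformly random predictions on balanced classes sit at chance (0.5)
  set.seed(1)
  classes <- letters[1:4]
  tr <- rep(classes, each = 2500)
  pr <- sample(classes, 10000, replace = TRUE)
  expect_equal(balanced_accuracy(confusion_matrix(tr, pr, classes))$overall,
               0.5, tolerance = 0.02)

  expect_error(balanced_accuracy(matrix(0, 2, 2)), "all zero")
  expect_warning(
    balanced_accuracy(matrix(c(2, 0, 1, 0), 2,
                             dimnames = list(c("a", "b"), c("a", "b")))),
    "no true examples")
})

test_that("F1 matches hand arithmetic with the documented zero convention", {
  expect_equal(f1_scores(diag(3L) + 0L * diag(3L))$overall, 1)

  cm <- matrix(c(8, 4, 2, 6), 2, dimnames = list(c("a", "b"), c("a", "b")))
  f1 <- f1_scores(cm)
  # class a: precision 8/12, sensitivity 0.8
  expect_equal(f1$per_class[["a"]], 2 * (8 / 12) * 0.8 / (8 / 12 + 0.8),
               tolerance = 1e-12)

  # class never predicted and never true-positive -> F1 = 0, with warning
  cm0 <- matrix(c(5, 3, 0, 0, 4, 0, 0, 0, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(f1 <- f1_scores(cm0), "set to 0")
  expect_equal(f1$per_class[["c"]], 0)
})

test_that("balanced accuracy and F1 agree with a brute-force one-vs-rest oracle", {
  set.seed(99)
  for (case in 1:60) {
    K <- sample(2:6, 1)
    classes <- letters[1:K]
    n <- sample(20:100, 1)
    tr <- sample(classes, n, replace = TRUE)
    pr <- sample(classes, n, replace = TRUE)
    present <- classes[classes %in% tr]
    cm <- confusion_matrix(tr, pr, classes)
    ba_o <- f1_o <- numeric(0)
    for (k in present) {
      tp <- sum(tr == k & pr == k); fn <- sum(tr == k & pr != k)
      fp <- sum(tr != k & pr == k); tn <- sum(tr != k & pr != k)
      sens <- tp / (tp + fn); spec <- tn / (tn + fp)
      prec <- if (tp + fp > 0) tp / (tp + fp) else NaN
      ba_o <- c(ba_o, (sens + spec) / 2)
      f1k <- 2 * prec * sens / (prec + sens)
      f1_o <- c(f1_o, ifelse(is.finite(f1k), f1k, 0))
    }
    expect_equal(suppressWarnings(balanced_accuracy(cm))$overall, mean(ba_o),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(f1_scores(cm))$overall, mean(f1_o),
                 tolerance = 1e-12)
  }
})

test_that("lineage distance matches the chain examples and a BFS oracle", {
  tree <- chain_tree()
  expect_identical(lineage_distance(tree, "HSPC", "HSPC"), 0L)
  expect_identical(lineage_distance(tree, "HSPC", "Myeloblast"), 1L)
  expect_identical(lineage_distance(tree, "HSPC", "Neutrophil"), 3L)
  expect_identical(lineage_distance(tree, "Neutrophil", "HSPC"), 3L)
  expect_error(lineage_distance(tree, "HSPC", "Basophil"), "Basophil")

  set.seed(7)
  for (rep_i in 1:20) {
    tr <- random_tree(sample(4:10, 1))
    a <- sample(tr$nodes, 1); b <- sample(tr$nodes, 1)
    expect_identical(lineage_distance(tr, a, b), as.integer(bfs_distance(tr, a, b)))
  }
})

test_that("lineage distance is a metric on tree nodes", {
  set.seed(11)
  for (rep_i in 1:15) {
    tr <- random_tree(sample(4:8, 1))
    dm <- outer(tr$nodes, tr$nodes,
                Vectorize(function(a, b) lineage_distance(tr, a, b)))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm == t(dm)))
    expect_true(all(dm[upper.tri(dm)] > 0))
    for (i in seq_along(tr$nodes)) {
      for (j in seq_along(tr$nodes)) {
        expect_true(all(dm[i, j] <= dm[i, ] + dm[, j]))
      }
    }
  }
})

test_that("misclassification topology splits errors into proximal and distal", {
  tree <- chain_tree()
  # perfect predictions: both rates zero
  lab <- rep(tree$nodes, each = 3)
  mt <- misclassification_topology(tree, lab, lab)
  expect_true(all(mt$per_class$proximal == 0) && all(mt$per_class$distal == 0))

  # 10 HSPCs: one to the adjacent class, one three edges away
  tr <- rep("HSPC", 10)
  pr <- c(rep("HSPC", 8), "Myeloblast", "Neutrophil")
  mt2 <- misclassification_topology(tree, tr, pr)
  expect_equal(mt2$per_class$proximal, 0.1)
  expect_equal(mt2$per_class$distal, 0.1)
  expect_equal(mt2$per_class$correct, 0.8)

  # correct + proximal + distal = 1 per class, on random data
  set.seed(3)
  rt <- random_tree(6)
  tr2 <- sample(rt$nodes, 200, replace = TRUE)
  pr2 <- sample(rt$nodes, 200, replace = TRUE)
  mt3 <- misclassification_topology(rt, tr2, pr2)
  expect_equal(mt3$per_class$correct + mt3$per_class$proximal +
                 mt3$per_class$distal, rep(1, nrow(mt3$per_class)))

  # dual computation: rates via confusion matrix + pairwise distances
  cm <- confusion_matrix(tr2, pr2, rt$nodes)
  dm <- outer(rt$nodes, rt$nodes,
              Vectorize(function(a, b) lineage_distance(rt, a, b)))
  for (ki in seq_along(rt$nodes)) {
    k <- rt$nodes[ki]
    n_k <- sum(cm[ki, ])
    if (n_k == 0) next
    row <- mt3$per_class[mt3$per_class$class == k, ]
    expect_equal(row$proximal, sum(cm[ki, dm[ki, ] == 1]) / n_k)
    expect_equal(row$distal, sum(cm[ki, dm[ki, ] > 1]) / n_k)
  }
})

test_that("per-class metrics are equivariant under class relabeling", {
  set.seed(5)
  classes <- c("A", "B", "C", "D")
  tr <- sample(classes, 300, replace = TRUE)
  pr <- sample(classes, 300, replace = TRUE)
  r1 <- evaluate_predictions(tr, pr, classes)
  perm <- c(A = "W", B = "X", C = "Y", D = "Z")
  r2 <- evaluate_predictions(unname(perm[tr]), unname(perm[pr]), unname(perm))
  expect_equal(r1$overall_ba, r2$overall_ba)
  expect_equal(r1$overall_f1, r2$overall_f1)
  expect_equal(r1$per_class$f1, r2$per_class$f1)
})

test_that("tree JSON round-trips", {
  tree <- bone_marrow_tree()
  path <- tempfile(fileext = ".json")
  write_tree_json(tree, path)
  tree2 <- read_tree_json(path)
  expect_identical(tree$nodes, tree2$nodes)
  expect_identical(tree$edges, tree2$edges)
})
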