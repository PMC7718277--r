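test_that("parameter counts match the architecture arithmetic", {
  expect_identical(count_parameters(architecture_spec(4372, 0, 14)), 61222L)
  expect_identical(count_parameters(architecture_spec(4372, 16, 14)), 70206L)
  expect_identical(count_parameters(architecture_spec(2, 0, 2)), 6L)

  # agreement with direct enumeration of weight-array sizes, random specs
  set.seed(10)
  for (rep_i in 1:20) {
    spec <- architecture_spec(sample(1:200, 1), sample(c(0, 1:32), 1),
                              sample(2:15, 1))
    m <- init_classifier(spec, sprintf("c%d", seq_len(spec$n_classes)))
    expect_identical(count_parameters(spec),
                     as.integer(sum(vapply(m$weights, length, numeric(1)))))
  }
})

test_that("balanced batches re-sample per class with replacement", {
  labels <- rep(c("A", "B", "C"), times = c(50, 30, 1))
  set.seed(1)
  nb <- make_balanced_batches(labels, per_class = 5)
  for (i in 1:20) {
    ix <- nb()
    expect_length(ix, 15)
    expect_equal(unname(table(labels[ix])), rep(5L, 3), ignore_attr = TRUE)
    # singleton class: its only index appears 5 times
    expect_identical(ix[labels[ix] == "C"], rep(81L, 5))
  }
  expect_error(make_balanced_batches(labels, 5, classes = c("A", "B", "C", "D")),
               "D")
})

test_that("balanced-batch selection frequencies match the binomial expectation", {
  labels <- rep(c("A", "B"), each = 20)
  set.seed(123)
  nb <- make_balanced_batches(labels, per_class = 5)
  counts <- integer(40)
  n_batches <- 10000
  for (i in seq_len(n_batches)) {
    ix <- nb()
    tt <- tabulate(ix, 40)
    counts <- counts + tt
  }
  # each cell: Binomial(n_batches * 5, 1/20) draws
  expected <- n_batches * 5 / 20
  se <- sqrt(n_batches * 5 * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - expected) < 4 * se))
})

test_that("the forward pass matches an affine+softmax oracle", {
  spec <- architecture_spec(6, 0, 4)
  set.seed(3)
  m <- init_classifier(spec, letters[1:4])
  X <- matrix(rbinom(60, 1, 0.5), 10, 6)
  p <- predict_posterior(m, X)
  expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-9)
  # independent forward pass
  z <- X %*% m$weights$W + matrix(m$weights$b, 10, 4, byrow = TRUE)
  oracle <- t(apply(z, 1, function(r) exp(r) / sum(exp(r))))
  expect_lt(max(abs(p - oracle)), 1e-6)

  # zero weights -> uniform posterior
  m0 <- m; m0$weights$W[] <- 0; m0$weights$b[] <- 0
  expect_equal(unname(predict_posterior(m0, X)), matrix(0.25, 10, 4))

  # dominance: huge weight from gene 2 to class c
  md <- m0
  md$weights$W[2, 3] <- 50
  on <- matrix(0, 1, 6); on[1, 2] <- 1
  expect_identical(predict_labels(md, on), "c")

  # ANN forward pass against an explicit two-layer oracle
  spec_h <- architecture_spec(6, 5, 4)
  mh <- init_classifier(spec_h, letters[1:4])
  ph <- predict_posterior(mh, X)
  H <- pmax(X %*% mh$weights$W1 + matrix(mh$weights$b1, 10, 5, byrow = TRUE), 0)
  zh <- H %*% mh$weights$W2 + matrix(mh$weights$b2, 10, 4, byrow = TRUE)
  oh <- t(apply(zh, 1, function(r) exp(r) / sum(exp(r))))
  expect_lt(max(abs(ph - oh)), 1e-6)

  expect_error(predict_posterior(m, X[, 1:3]), "expects 6 inputs, got 3")
})

test_that("posterior columns permute with the class order", {
  spec <- architecture_spec(5, 0, 3)
  set.seed(6)
  m <- init_classifier(spec, c("a", "b", "c"))
  X <- matrix(rbinom(40, 1, 0.4), 8, 5)
  p <- predict_posterior(m, X)
  perm <- c(3, 1, 2)
  m2 <- m
  m2$weights$W <- m$weights$W[, perm]
  m2$weights$b <- m$weights$b[perm]
  m2$class_names <- m$class_names[perm]
  p2 <- predict_posterior(m2, X)
  expect_equal(unname(p2), unname(p[, perm]))
})

test_that("ensemble plurality vote uses the documented tie-break", {
  cn <- c("A", "B", "C")
  X <- matrix(rbinom(8, 1, 0.5), 2, 4)
  models <- lapply(c("A", "A", "B", "A", "C"), constant_model, class_names = cn)
  expect_identical(predict_ensemble(models, X), rep("A", 2))

  # unanimous ensemble equals a single model
  models_u <- lapply(rep("B", 5), constant_model, class_names = cn)
  expect_identical(predict_ensemble(models_u, X),
                   predict_labels(models_u[[1]], X))

  # tie A-A-B-B-C resolved by larger summed posterior (B has larger bias)
  models_t <- list(constant_model(cn, "A", bias = 5),
                   constant_model(cn, "A", bias = 5),
                   constant_model(cn, "B", bias = 9),
                   constant_model(cn, "B", bias = 9),
                   constant_model(cn, "C", bias = 5))
  expect_identical(predict_ensemble(models_t, X), rep("B", 2))

  bad <- list(constant_model(cn, "A"), constant_model(c("A", "B", "D"), "A"))
  expect_error(predict_ensemble(bad, X), "inconsistent class_names")
})

test_that("cross-validation separates a linearly separable toy perfectly", {
  toy <- separable_toy(n_per_class = 100, seed = 1)
  spec <- architecture_spec(ncol(toy$matrix), 0, 3)
  cfg <- train_config(seed = 1, epochs = 10)
  cv <- train_crossval(toy, spec, cfg)
  for (fold in cv) {
    expect_equal(fold$report$overall_ba, 1.0)
    # stratification arithmetic: 100 cells/class, 5 folds -> 20 per class
    expect_equal(unname(table(toy$labels[fold$fold_idx])), rep(20L, 3),
                 ignore_attr = TRUE)
  }
})

test_that("training is deterministic under a fixed seed", {
  toy <- separable_toy(n_per_class = 25, seed = 2)
  spec <- architecture_spec(ncol(toy$matrix), 0, 3)
  cfg <- train_config(seed = 42, epochs = 3)
  cv1 <- train_crossval(toy, spec, cfg)
  cv2 <- train_crossval(toy, spec, cfg)
  expect_identical(lapply(cv1, function(x) x$model$weights),
                   lapply(cv2, function(x) x$model$weights))
  expect_identical(lapply(cv1, function(x) x$fold_idx),
                   lapply(cv2, function(x) x$fold_idx))
})

test_that("rare classes are spread so every training split keeps them", {
  toy <- separable_toy(n_per_class = 20, seed = 3)
  # shrink class C to 3 cells (< 5 folds)
  keep <- c(which(toy$labels != "C"), which(toy$labels == "C")[1:3])
  data <- binarized_dataset(toy$matrix[keep, ], toy$labels[keep], "toy")
  spec <- architecture_spec(ncol(data$matrix), 0, 3)
  cfg <- train_config(seed = 9, epochs = 2)
  expect_warning(cv <- train_crossval(data, spec, cfg), "round-robin")
  # every fold could train (C present in every training split)
  expect_length(cv, 5)
  for (fold in cv) expect_s3_class(fold$model, "classifier_model")
})

test_that("MLR predictions agree with an independent multinomial fit", {
  skip_if_not_installed("nnet")
  toy <- separable_toy(n_per_class = 60, n_genes = 21, seed = 5)
  spec <- architecture_spec(21, 0, 3)
  cfg <- train_config(seed = 2, epochs = 21)
  set.seed(2)
  model <- train_classifier(init_classifier(spec, c("A", "B", "C")),
                            toy$matrix, toy$labels, cfg)
  ours <- predict_labels(model, toy$matrix)
  ref <- nnet::multinom(y ~ ., data = data.frame(y = factor(toy$labels),
                                                 toy$matrix), trace = FALSE)
  theirs <- as.character(predict(ref, data.frame(toy$matrix)))
  expect_gt(mean(ours == theirs), 0.98)
})
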