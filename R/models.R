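#' Classifier architecture specification
#'
#' Describes the two architectures used for cell-type classification on
#' binarized expression: a multinomial logistic regression (`hidden_units =
#' 0`: input straight into a softmax output layer) and a single-hidden-layer
#' feedforward network (`hidden_units = 16` with ReLU activation and 50%
#' dropout on the hidden layer during training). Both carry an L1 weight
#' penalty (default 0.001) on all weight matrices (not biases).
#'
#' @param n_inputs Number of input genes (>= 1).
#' @param hidden_units 0 for MLR, or the hidden layer width.
#' @param n_classes Number of output classes (>= 2).
#' @param dropout_rate Dropout fraction on the hidden layer, training only.
#' @param l1_penalty Non-negative L1 regularization weight.
#' @return Object of class `architecture_spec`.
#' @export
architecture_spec <- function(n_inputs, hidden_units = 0, n_classes,
                              dropout_rate = 0.5, l1_penalty = 0.001) {
  stopifnot(n_inputs >= 1, n_classes >= 2, hidden_units >= 0,
            dropout_rate >= 0, dropout_rate < 1, l1_penalty >= 0)
  structure(list(n_inputs = as.integer(n_inputs),
                 hidden_units = as.integer(hidden_units),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate, l1_penalty = l1_penalty),
            class = "architecture_spec")
}

#' Number of trainable parameters of an architecture
#'
#' MLR: `n_inputs * n_classes + n_classes`. With a hidden layer of width h:
#' `n_inputs * h + h + h * n_classes + n_classes`. The default input width of
#' 4372 genes gives the reference sizes 61,222 (MLR) and 70,206 (h = 16).
#'
#' @param spec An `architecture_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  h <- spec$hidden_units
  if (h == 0) {
    spec$n_inputs * spec$n_classes + spec$n_classes
  } else {
    spec$n_inputs * h + h + h * spec$n_classes + spec$n_classes
  }
}

#' Training protocol configuration
#'
#' The source-domain protocol: 21 epochs of 42 steps, each step a
#' class-balanced batch re-sampling five training examples per class (with
#' replacement), cross-entropy loss, RMSprop optimization. RMSprop settings
#' are pinned to `lr = 0.001`, `rho = 0.9`, `epsilon = 1e-7`.
#'
#' @param epochs Training epochs.
#' @param steps_per_epoch Batches per epoch.
#' @param per_class_per_step Examples re-sampled per class per batch.
#' @param seed Integer seed driving fold assignment, weight initialization
#'   and batch sampling.
#' @param learning_rate,rho,epsilon RMSprop settings.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 21, steps_per_epoch = 42,
                         per_class_per_step = 5, seed = 1L,
                         learning_rate = 0.001, rho = 0.9, epsilon = 1e-7) {
  stopifnot(epochs >= 1, steps_per_epoch >= 1, per_class_per_step >= 1)
  structure(list(epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 per_class_per_step = as.integer(per_class_per_step),
                 seed = as.integer(seed), learning_rate = learning_rate,
                 rho = rho, epsilon = epsilon),
            class = "train_config")
}

#' Class-balanced batch generator
#'
#' Returns a closure drawing index batches with exactly `per_class` indices
#' per present class, sampled uniformly with replacement, so rare classes are
#' up-sampled to the same per-batch representation as abundant ones. Batch
#' size is `per_class * n_classes`. Sampling consumes the calling R RNG
#' stream, so a fixed seed gives a fixed batch sequence.
#'
#' @param labels Per-example class labels.
#' @param per_class Examples per class per batch.
#' @param classes Classes to draw (default: all observed). A named class with
#'   zero examples is an error.
#' @return Function of no arguments returning an integer index vector.
#' @export
make_balanced_batches <- function(labels, per_class,
                                  classes = sort(unique(as.character(labels)))) {
  labels <- as.character(labels)
  idx_by_class <- lapply(stats::setNames(classes, classes),
                         function(k) which(labels == k))
  empty <- classes[lengths(idx_by_class) == 0]
  if (length(empty)) {
    stop("class(es) with zero examples: ", paste(empty, collapse = ", "))
  }
  function() {
    unlist(lapply(idx_by_class, function(ix) {
      ix[sample.int(length(ix), per_class, replace = TRUE)]
    }), use.names = FALSE)
  }
}

# Glorot-uniform initialization of one weight matrix.
glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

#' Initialize a classifier with Glorot-uniform weights
#'
#' @param spec An `architecture_spec`.
#' @param class_names Ordered class names (length `n_classes`).
#' @param gene_names Optional input feature names (length `n_inputs`).
#' @return Object of class `classifier_model` with a `weights` list:
#'   `W`/`b` for the MLR, `W1`/`b1`/`W2`/`b2` with a hidden layer.
#' @export
init_classifier <- function(spec, class_names, gene_names = NULL) {
  stopifnot(inherits(spec, "architecture_spec"),
            length(class_names) == spec$n_classes)
  if (!is.null(gene_names)) stopifnot(length(gene_names) == spec$n_inputs)
  h <- spec$hidden_units
  weights <- if (h == 0) {
    list(W = glorot(spec$n_inputs, spec$n_classes),
         b = rep(0, spec$n_classes))
  } else {
    list(W1 = glorot(spec$n_inputs, h), b1 = rep(0, h),
         W2 = glorot(h, spec$n_classes), b2 = rep(0, spec$n_classes))
  }
  structure(list(spec = spec, weights = weights,
                 class_names = as.character(class_names),
                 gene_names = gene_names),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  arch <- if (x$spec$hidden_units == 0) "MLR" else
    sprintf("ANN(%d hidden)", x$spec$hidden_units)
  cat(sprintf("classifier_model %s: %d inputs -> %d classes, %d parameters\n",
              arch, x$spec$n_inputs, x$spec$n_classes,
              count_parameters(x$spec)))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

relu <- function(z) (z > 0) * z

check_features <- function(model, X) {
  if (ncol(X) != model$spec$n_inputs) {
    stop(sprintf("feature mismatch: model expects %d inputs, got %d",
                 model$spec$n_inputs, ncol(X)))
  }
}

#' Posterior class probabilities
#'
#' Softmax forward pass with dropout disabled; rows sum to 1.
#'
#' @param model A `classifier_model`.
#' @param X Cells x genes 0/1 matrix (or a `binarized_dataset`).
#' @return Cells x classes posterior matrix.
#' @export
predict_posterior <- function(model, X) {
  stopifnot(inherits(model, "classifier_model"))
  if (inherits(X, "binarized_dataset")) X <- X$matrix
  X <- as.matrix(X)
  check_features(model, X)
  w <- model$weights
  z <- if (model$spec$hidden_units == 0) {
    sweep(X %*% w$W, 2, w$b, `+`)
  } else {
    H <- relu(sweep(X %*% w$W1, 2, w$b1, `+`))
    sweep(H %*% w$W2, 2, w$b2, `+`)
  }
  p <- softmax_rows(z)
  colnames(p) <- model$class_names
  p
}

#' Hard label predictions (argmax of the posterior)
#'
#' @inheritParams predict_posterior
#' @return Character vector of predicted class names.
#' @export
predict_labels <- function(model, X) {
  p <- predict_posterior(model, X)
  model$class_names[max.col(p, ties.method = "first")]
}

#' Ensemble prediction by plurality vote
#'
#' Each model votes with its argmax label; the label predicted by the most
#' models wins. Ties are broken by the largest posterior summed over the
#' ensemble.
#'
#' @param models List of `classifier_model`s sharing class names and feature
#'   space.
#' @param X Cells x genes 0/1 matrix (or `binarized_dataset`).
#' @return Character vector of predicted class names.
#' @export
predict_ensemble <- function(models, X) {
  stopifnot(length(models) >= 1)
  cn <- models[[1]]$class_names
  for (m in models) {
    if (!identical(m$class_names, cn)) {
      stop("models have inconsistent class_names")
    }
  }
  if (inherits(X, "binarized_dataset")) X <- X$matrix
  posts <- lapply(models, function(m) predict_posterior(m, X))
  votes <- matrix(0L, nrow = nrow(X), ncol = length(cn))
  for (p in posts) {
    win <- max.col(p, ties.method = "first")
    votes[cbind(seq_len(nrow(X)), win)] <- votes[cbind(seq_len(nrow(X)), win)] + 1L
  }
  psum <- Reduce(`+`, posts)
  # plurality vote; ties resolved by summed posterior among tied classes
  pick <- vapply(seq_len(nrow(X)), function(i) {
    v <- votes[i, ]
    tied <- which(v == max(v))
    if (length(tied) == 1L) tied else tied[which.max(psum[i, tied])]
  }, integer(1))
  cn[pick]
}

# One SGD step core shared by all training entry points. Returns updated
# model + RMSprop state.
sgd_step <- function(model, state, Xb, yb, cfg) {
  spec <- model$spec
  w <- model$weights
  n <- nrow(Xb)
  Y <- matrix(0, n, spec$n_classes)
  Y[cbind(seq_len(n), yb)] <- 1
  l1 <- spec$l1_penalty
  grads <- if (spec$hidden_units == 0) {
    P <- softmax_rows(sweep(Xb %*% w$W, 2, w$b, `+`))
    dZ <- (P - Y) / n
    list(W = crossprod(Xb, dZ) + l1 * sign(w$W), b = colSums(dZ))
  } else {
    A <- sweep(Xb %*% w$W1, 2, w$b1, `+`)
    H <- relu(A)
    keep <- 1 - spec$dropout_rate
    mask <- (matrix(stats::runif(n * spec$hidden_units), n) < keep) / keep
    Hd <- H * mask
    P <- softmax_rows(sweep(Hd %*% w$W2, 2, w$b2, `+`))
    dZ <- (P - Y) / n
    dH <- (dZ %*% t(w$W2)) * mask * (A > 0)
    list(W1 = crossprod(Xb, dH) + l1 * sign(w$W1), b1 = colSums(dH),
         W2 = crossprod(Hd, dZ) + l1 * sign(w$W2), b2 = colSums(dZ))
  }
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- cfg$rho * state[[nm]] + (1 - cfg$rho) * g^2
    w[[nm]] <- w[[nm]] - cfg$learning_rate * g / (sqrt(state[[nm]]) + cfg$epsilon)
  }
  model$weights <- w
  list(model = model, state = state)
}

#' Run the training loop on a fixed training set
#'
#' `epochs x steps_per_epoch` class-balanced batches, cross-entropy loss with
#' the architecture's L1 penalty, RMSprop updates, inverted dropout on the
#' hidden layer. Consumes the calling RNG stream (callers seed it).
#'
#' @param model Starting `classifier_model` (fresh or pre-trained).
#' @param X Training matrix (cells x genes, 0/1).
#' @param labels Training labels; classes absent from `model$class_names`
#'   are an error.
#' @param cfg A `train_config`.
#' @param epochs,steps_per_epoch Override the config's schedule (used for
#'   target-domain re-training).
#' @return The trained `classifier_model`.
#' @export
train_classifier <- function(model, X, labels, cfg,
                             epochs = cfg$epochs,
                             steps_per_epoch = cfg$steps_per_epoch) {
  stopifnot(inherits(model, "classifier_model"), inherits(cfg, "train_config"))
  if (inherits(X, "binarized_dataset")) { labels <- X$labels; X <- X$matrix }
  X <- as.matrix(X)
  check_features(model, X)
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), model$class_names)
  if (length(unknown)) {
    stop("training labels not in model classes: ", paste(unknown, collapse = ", "))
  }
  present <- model$class_names[model$class_names %in% labels]
  next_batch <- make_balanced_batches(labels, cfg$per_class_per_step,
                                      classes = present)
  y_all <- match(labels, model$class_names)
  state <- lapply(model$weights, function(w) w * 0)
  for (step in seq_len(epochs * steps_per_epoch)) {
    ix <- next_batch()
    upd <- sgd_step(model, state, X[ix, , drop = FALSE], y_all[ix], cfg)
    model <- upd$model
    state <- upd$state
  }
  model
}

# Stratified k-fold assignment. Returns integer fold id per example, NA for
# examples held in every training split (classes with < 2 members).
stratified_folds <- function(labels, k_folds) {
  labels <- as.character(labels)
  fold <- rep(NA_integer_, length(labels))
  for (kl in unique(labels)) {
    ix <- which(labels == kl)
    n <- length(ix)
    if (n < k_folds) {
      warning("class '", kl, "' has ", n, " < ", k_folds,
              " cells; assigning round-robin so every training split keeps >= 1")
      if (n >= 2) {
        fold[sample(ix)] <- seq_len(n)  # each lands in one validation fold
      }
      # n == 1: stays NA -> always in training
    } else {
      fold[sample(ix)] <- rep_len(seq_len(k_folds), n)
    }
  }
  fold
}

#' Fivefold cross-validated training
#'
#' Splits the data by class into `k_folds` stratified parts and trains one
#' model per fold on the remaining 80%, evaluating on the held-out 20%.
#' Classes with fewer members than folds are spread round-robin so that every
#' fold's training split retains at least one example (with a warning). A
#' fixed `cfg$seed` makes fold assignment, initialization and batch sampling
#' reproducible.
#'
#' @param data A `binarized_dataset`.
#' @param spec An `architecture_spec` (its `n_inputs` must match the data).
#' @param cfg A `train_config`.
#' @param k_folds Number of folds.
#' @param tree Optional `lineage_tree` for topology in the fold reports.
#' @return List of `k_folds` elements, each `list(model, report, fold_idx)`
#'   where `report` is the validation `evaluation_report`.
#' @export
train_crossval <- function(data, spec, cfg, k_folds = 5, tree = NULL) {
  stopifnot(inherits(data, "binarized_dataset"))
  class_names <- sort(unique(data$labels))
  if (length(class_names) != spec$n_classes) {
    stop(sprintf("spec has %d classes but data has %d",
                 spec$n_classes, length(class_names)))
  }
  set.seed(cfg$seed)
  fold <- stratified_folds(data$labels, k_folds)
  lapply(seq_len(k_folds), function(f) {
    train_ix <- which(is.na(fold) | fold != f)
    val_ix <- which(!is.na(fold) & fold == f)
    model <- init_classifier(spec, class_names,
                             gene_names = data$gene_names)
    model <- train_classifier(model, data$matrix[train_ix, , drop = FALSE],
                              data$labels[train_ix], cfg)
    report <- if (length(val_ix)) {
      evaluate_predictions(data$labels[val_ix],
                           predict_labels(model, data$matrix[val_ix, , drop = FALSE]),
                           class_order = class_names, tree = tree)
    }
    list(model = model, report = report, fold_idx = val_ix)
  })
}
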