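# Per-fold, per-class permutations of target-cell indices. Taking the first
# k entries of each permutation yields nested training subsets across k, so
# the set used at k = 5 contains the set used at k = 4.
target_pools <- function(labels, classes, n_folds, seed) {
  set.seed(seed)
  lapply(seq_len(n_folds), function(f) {
    lapply(stats::setNames(classes, classes), function(kl) {
      ix <- which(labels == kl)
      ix[sample.int(length(ix))]
    })
  })
}

# First k of each class's pool for one fold; sampling with replacement (and
# a warning) when a class has fewer than k cells.
pool_take <- function(pool_fold, k) {
  unlist(lapply(names(pool_fold), function(kl) {
    ix <- pool_fold[[kl]]
    if (length(ix) >= k) ix[seq_len(k)]
    else {
      warning("class '", kl, "' has only ", length(ix),
              " target cells; sampling ", k, " with replacement")
      ix[sample.int(length(ix), k, replace = TRUE)]
    }
  }), use.names = FALSE)
}

# Widen a trained model's output layer with randomly initialized columns for
# classes seen in the target domain but never in the source.
widen_model <- function(model, new_classes) {
  if (!length(new_classes)) return(model)
  spec <- model$spec
  w <- model$weights
  n_new <- length(new_classes)
  if (spec$hidden_units == 0) {
    w$W <- cbind(w$W, glorot(spec$n_inputs, spec$n_classes + n_new)[, seq_len(n_new), drop = FALSE])
    w$b <- c(w$b, rep(0, n_new))
  } else {
    w$W2 <- cbind(w$W2, glorot(spec$hidden_units, spec$n_classes + n_new)[, seq_len(n_new), drop = FALSE])
    w$b2 <- c(w$b2, rep(0, n_new))
  }
  model$weights <- w
  model$spec$n_classes <- spec$n_classes + n_new
  model$class_names <- c(model$class_names, new_classes)
  model
}

# Target-domain steps per epoch: proportional to the number of training
# examples (one step per example), capped at 30 steps per epoch. The cap
# binds from small k, so few-shot re-training still gets enough updates to
# overwrite confidently wrong source weights.
target_steps <- function(k, n_classes) {
  max(1L, min(30L, as.integer(k) * as.integer(n_classes)))
}

#' Re-train source models on k target examples per class
#'
#' Fine-tunes each cross-validation model from the source domain by
#' continuing optimization from its trained weights on `k` examples per
#' represented target class (`k = 0` returns the source models unchanged —
#' the naive transfer setting). Classes present in the target labels but
#' unknown to the source model get a fresh randomly initialized output
#' column before re-training. Steps per epoch are proportional to the number
#' of training examples, capped at 30.
#'
#' The k examples are drawn once per fold from a seeded permutation, nested
#' across k (the k+1 set contains the k set).
#'
#' @param source_models List of trained `classifier_model`s (one per fold).
#' @param target_data A `binarized_dataset` in the aligned feature space.
#' @param k Target examples per class (>= 0).
#' @param cfg A `train_config`.
#' @param seed Seed for example selection and re-training.
#' @return List of re-trained `classifier_model`s.
#' @export
retrain <- function(source_models, target_data, k, cfg, seed = cfg$seed) {
  stopifnot(inherits(target_data, "binarized_dataset"), k >= 0)
  if (k == 0) return(source_models)
  classes <- sort(unique(target_data$labels))
  pools <- target_pools(target_data$labels, classes, length(source_models), seed)
  set.seed(seed + 1L)
  lapply(seq_along(source_models), function(f) {
    model <- source_models[[f]]
    novel <- setdiff(classes, model$class_names)
    model <- widen_model(model, novel)
    ix <- pool_take(pools[[f]], k)
    train_classifier(model, target_data$matrix[ix, , drop = FALSE],
                     target_data$labels[ix], cfg,
                     steps_per_epoch = target_steps(k, length(classes)))
  })
}

#' Train naive target-domain models on k examples per class
#'
#' The control arm for transfer learning: identical data, schedule and
#' optimizer as [retrain()], but weights start from random initial
#' conditions. `k = 0` returns zero-weight models, i.e. uniform-posterior
#' predictors whose balanced accuracy is at chance level.
#'
#' @param target_data A `binarized_dataset`.
#' @param k Target examples per class (>= 0).
#' @param spec An `architecture_spec`; its `n_classes` is overridden by the
#'   number of target classes.
#' @param cfg A `train_config`.
#' @param n_folds Number of models (matched to the transfer arm).
#' @param seed Seed; the example pools match [retrain()] at equal seed.
#' @return List of `classifier_model`s.
#' @export
train_naive <- function(target_data, k, spec, cfg, n_folds = 5,
                        seed = cfg$seed) {
  stopifnot(inherits(target_data, "binarized_dataset"), k >= 0)
  classes <- sort(unique(target_data$labels))
  spec <- architecture_spec(spec$n_inputs, spec$hidden_units,
                            length(classes), spec$dropout_rate,
                            spec$l1_penalty)
  if (k == 0) {
    return(lapply(seq_len(n_folds), function(f) {
      m <- init_classifier(spec, classes, gene_names = target_data$gene_names)
      m$weights <- lapply(m$weights, function(w) w * 0)
      m
    }))
  }
  pools <- target_pools(target_data$labels, classes, n_folds, seed)
  set.seed(seed + 2L)
  lapply(seq_len(n_folds), function(f) {
    model <- init_classifier(spec, classes, gene_names = target_data$gene_names)
    ix <- pool_take(pools[[f]], k)
    train_classifier(model, target_data$matrix[ix, , drop = FALSE],
                     target_data$labels[ix], cfg,
                     steps_per_epoch = target_steps(k, length(classes)))
  })
}

# Evaluate a list of fold models on their fold test sets; returns overall F1
# and per-class F1 averaged over folds.
eval_folds <- function(models, target_data, test_ix_by_fold, classes) {
  per_fold <- lapply(seq_along(models), function(f) {
    ix <- test_ix_by_fold[[f]]
    pred <- predict_labels(models[[f]], target_data$matrix[ix, , drop = FALSE])
    order_all <- sort(unique(c(classes, models[[f]]$class_names)))
    er <- suppressWarnings(
      evaluate_predictions(target_data$labels[ix], pred, class_order = order_all))
    f1c <- er$per_class$f1[match(classes, er$per_class$class)]
    f1c[er$per_class$n[match(classes, er$per_class$class)] == 0] <- NA
    list(overall = er$overall_f1, per_class = f1c)
  })
  list(overall = mean(vapply(per_fold, `[[`, numeric(1), "overall")),
       per_class = rowMeans(do.call(cbind, lapply(per_fold, `[[`, "per_class")),
                            na.rm = TRUE))
}

#' Transfer versus naive learning curves
#'
#' For every k in the schedule, re-trains the source models on k target
#' examples per class and trains naive models from random initialization on
#' the same examples, then evaluates both arms on a fixed held-out test set
#' (all cells never used at any k, per fold) and averages F1 over folds and
#' seeds. Summarizes the curves by the initial performance deficit
#' `A = 1 - F1_0` (F1 of the un-tuned source models on target data) and the
#' final deficit `C = 1 - F1_end` (F1 of the naive model at the largest k).
#'
#' @param source_models List of trained source-domain `classifier_model`s.
#' @param target_data A `binarized_dataset`.
#' @param schedule Increasing vector of k values starting at 0.
#' @param cfg A `train_config`.
#' @param seeds Integer vector; curves are averaged over these seeds.
#' @return Object of class `learning_curve`: `schedule`, `overall`
#'   (data.frame k, f1_transfer, f1_naive), `per_class_transfer` /
#'   `per_class_naive` (class x k matrices), `f1_0`, `f1_end`,
#'   `deficit_initial`, `deficit_final`.
#' @export
learning_curves <- function(source_models, target_data,
                            schedule = c(0:10, 15, 20, 25, 30),
                            cfg = train_config(), seeds = 1L) {
  stopifnot(all(diff(schedule) > 0), schedule[1] == 0)
  classes <- sort(unique(target_data$labels))
  spec <- source_models[[1]]$spec
  k_max <- max(schedule)
  acc <- NULL
  for (seed in seeds) {
    pools <- target_pools(target_data$labels, classes,
                          length(source_models), seed)
    test_ix <- lapply(pools, function(pf) {
      used <- unlist(lapply(pf, function(ix) ix[seq_len(min(k_max, length(ix)))]))
      setdiff(seq_len(nrow(target_data$matrix)), used)
    })
    res <- lapply(schedule, function(k) {
      tr <- retrain(source_models, target_data, k, cfg, seed = seed)
      nv <- train_naive(target_data, k, spec, cfg,
                        n_folds = length(source_models), seed = seed)
      list(transfer = eval_folds(tr, target_data, test_ix, classes),
           naive = eval_folds(nv, target_data, test_ix, classes))
    })
    cur <- list(
      overall_transfer = vapply(res, function(r) r$transfer$overall, numeric(1)),
      overall_naive = vapply(res, function(r) r$naive$overall, numeric(1)),
      pc_transfer = do.call(cbind, lapply(res, function(r) r$transfer$per_class)),
      pc_naive = do.call(cbind, lapply(res, function(r) r$naive$per_class))
    )
    acc <- if (is.null(acc)) cur else {
      Map(function(a, b) a + b, acc, cur)
    }
  }
  acc <- lapply(acc, function(a) a / length(seeds))
  dimnames(acc$pc_transfer) <- list(classes, schedule)
  dimnames(acc$pc_naive) <- list(classes, schedule)
  f1_0 <- acc$overall_transfer[1]
  f1_end <- acc$overall_naive[length(schedule)]
  structure(list(
    schedule = schedule,
    overall = data.frame(k = schedule,
                         f1_transfer = acc$overall_transfer,
                         f1_naive = acc$overall_naive),
    per_class_transfer = acc$pc_transfer,
    per_class_naive = acc$pc_naive,
    f1_0 = f1_0, f1_end = f1_end,
    deficit_initial = 1 - f1_0, deficit_final = 1 - f1_end
  ), class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf(paste0("learning_curve: k in [%d, %d]; F1_0 = %.3f (A = %.3f), ",
                     "F1_end = %.3f (C = %.3f)\n"),
              min(x$schedule), max(x$schedule), x$f1_0, x$deficit_initial,
              x$f1_end, x$deficit_final))
  invisible(x)
}

#' Group cell types by their learning-curve shape
#'
#' Applies a 2x2 rule on each class's initial performance deficit
#' `A = 1 - F1_transfer(0)` and its improvement
#' `F1_transfer(k_max) - F1_transfer(0)`:
#' group 1 — small deficit, small improvement (conserved, homogeneous);
#' group 2 — moderate deficit, small improvement (conserved, heterogeneous);
#' group 3 — large improvement (divergent but learnable);
#' group 4 — large deficit, small improvement (divergent, heterogeneous).
#'
#' @param curve A `learning_curve` with per-class values.
#' @param thresholds List with `a_small`, `a_large` (deficit cut points) and
#'   `improvement` (minimum improvement for group 3).
#' @return data.frame class, deficit_initial, improvement, group; attribute
#'   `thresholds`.
#' @export
assign_groups <- function(curve,
                          thresholds = list(a_small = 0.15, a_large = 0.40,
                                            improvement = 0.20)) {
  stopifnot(inherits(curve, "learning_curve"))
  pc <- curve$per_class_transfer
  if (anyNA(pc[, 1]) || anyNA(pc[, ncol(pc)])) {
    stop("per-class curve incomplete for: ",
         paste(rownames(pc)[is.na(pc[, 1]) | is.na(pc[, ncol(pc)])],
               collapse = ", "))
  }
  a <- 1 - pc[, 1]
  improvement <- pc[, ncol(pc)] - pc[, 1]
  group <- ifelse(improvement >= thresholds$improvement, 3L,
                  ifelse(a < thresholds$a_small, 1L,
                         ifelse(a < thresholds$a_large, 2L, 4L)))
  out <- data.frame(class = rownames(pc), deficit_initial = unname(a),
                    improvement = unname(improvement), group = unname(group),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  out
}
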