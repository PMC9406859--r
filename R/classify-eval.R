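# Cubic SVM training/prediction, the two validation protocols, and the
# six-metric panel (accuracy, UAR, UAP, macro F1, Cohen's kappa, G-mean).

#' Cubic-SVM configuration
#'
#' Kernel `K(u, v) = (coef0 + u.v / kernel_scale)^kernel_degree`, one-vs-one
#' multiclass, inputs standardized inside the SVM. The published model uses
#' degree 3; other degrees are accepted but flagged with a warning.
#'
#' @param kernel_degree polynomial degree (default 3, the cubic SVM).
#' @param box_constraint positive misclassification cost C (default 1).
#' @param kernel_scale positive scale `s`, or `"auto"` for the `1/D` heuristic
#'   on the feature count (i.e. gamma `= 1/D`).
#' @param coef0 additive kernel constant (default 1).
#' @param standardize_inputs center/scale features inside the SVM (default TRUE).
#' @param seed integer seed recorded with the config (training itself is
#'   deterministic; the seed governs data splits in the evaluators).
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel_degree = 3L, box_constraint = 1,
                       kernel_scale = "auto", coef0 = 1,
                       standardize_inputs = TRUE, seed = 1L) {
  if (kernel_degree != 3L) {
    warning("svm_config: kernel_degree != 3 departs from the published cubic SVM")
  }
  if (box_constraint <= 0) stop("svm_config: `box_constraint` must be > 0")
  if (!identical(kernel_scale, "auto") && kernel_scale <= 0) {
    stop("svm_config: `kernel_scale` must be > 0 or \"auto\"")
  }
  structure(list(kernel_degree = as.integer(kernel_degree),
                 box_constraint = box_constraint, kernel_scale = kernel_scale,
                 coef0 = coef0, standardize_inputs = isTRUE(standardize_inputs),
                 seed = as.integer(seed)),
            class = "svm_config")
}

#' Train a cubic SVM
#'
#' Fits a one-vs-one C-classification SVM with the polynomial kernel of
#' [svm_config()] via libsvm (package e1071). Deterministic for fixed inputs
#' and configuration.
#'
#' @param X numeric feature matrix (rows = samples), all entries finite.
#' @param y class labels, at least two classes.
#' @param cfg an [svm_config()].
#' @return Object of class `svm_model` wrapping the fit, usable with
#'   [predict_svm()].
#' @export
train_svm <- function(X, y, cfg = svm_config()) {
  stopifnot(inherits(cfg, "svm_config"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("train_svm: `X` must be finite")
  y <- factor(y)
  if (length(y) != nrow(X)) stop("train_svm: labels must align with rows of `X`")
  if (nlevels(droplevels(y)) < 2L) stop("train_svm: need at least 2 classes")
  gamma <- if (identical(cfg$kernel_scale, "auto")) 1 / ncol(X)
           else 1 / cfg$kernel_scale
  fit <- suppressWarnings(            # constant columns: libsvm warns on scale
    e1071::svm(x = X, y = droplevels(y), type = "C-classification",
               kernel = "polynomial", degree = cfg$kernel_degree,
               gamma = gamma, coef0 = cfg$coef0, cost = cfg$box_constraint,
               scale = cfg$standardize_inputs)
  )
  structure(list(fit = fit, cfg = cfg, levels = levels(droplevels(y))),
            class = "svm_model")
}

#' @rdname train_svm
#' @param model a fitted `svm_model`.
#' @param newdata numeric matrix of samples to classify.
#' @return Factor of predicted labels with the training levels.
#' @export
predict_svm <- function(model, newdata) {
  stopifnot(inherits(model, "svm_model"))
  factor(as.character(predict(model$fit, as.matrix(newdata))),
         levels = model$levels)
}

#' Six-metric panel from a confusion matrix
#'
#' Rows index the true class, columns the predicted class. Metrics (as
#' proportions): accuracy `trace/N`; UAR/UAP the unweighted means of
#' class-wise recall `cm[c,c]/rowsum_c` and precision `cm[c,c]/colsum_c`
#' (0 when the denominator is 0); macro F1 the mean of `2PR/(P+R)` (0 when
#' `P+R = 0`); Cohen's kappa `(p_o - p_e)/(1 - p_e)` with
#' `p_e = sum_c rowsum_c * colsum_c / N^2` (1 when `p_o = p_e = 1`); G-mean
#' the geometric mean of class-wise recalls (0 if any class is entirely
#' missed — no smoothing).
#'
#' @param cm square matrix of nonnegative integer counts, total > 0.
#' @return Named list: `accuracy`, `uar`, `uap`, `macro_f1`, `kappa`, `gmean`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("metrics_from_confusion: matrix must be square")
  if (any(cm < 0) || any(cm != round(cm))) {
    stop("metrics_from_confusion: entries must be nonnegative integers")
  }
  N <- sum(cm)
  if (N <= 0) stop("metrics_from_confusion: total count must be > 0")
  C <- nrow(cm)
  diagc <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  recall <- ifelse(rs > 0, diagc / rs, 0)
  precision <- ifelse(cs > 0, diagc / cs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  p_o <- sum(diagc) / N
  p_e <- sum(rs * cs) / N^2
  kappa <- if (p_e >= 1) 1 else (p_o - p_e) / (1 - p_e)
  list(accuracy = p_o,
       uar = mean(recall),
       uap = mean(precision),
       macro_f1 = mean(f1),
       kappa = kappa,
       gmean = prod(recall)^(1 / C))
}

# Stratified hold-out assignment by largest-remainder apportionment: the
# test set has round((1-p) n) members, spread over classes proportionally
# (floor per class, remainders to the largest fractional parts, ties by
# class order). Returns the test indices; sampling within class is seeded.
.stratified_test_idx <- function(y, train_fraction, seed) {
  q <- 1 - train_fraction
  n_c <- table(y)
  target <- round(q * length(y))
  base <- floor(q * n_c)
  frac <- q * n_c - base
  need <- target - sum(base)
  if (need > 0) {
    bump <- order(-frac, seq_along(frac))[seq_len(need)]
    base[bump] <- base[bump] + 1
  }
  .with_preserved_rng(seed, {
    unlist(lapply(seq_along(n_c), function(k) {
      idx <- which(y == names(n_c)[k])
      sample(idx, base[k])
    }), use.names = FALSE)
  })
}

# Confusion matrix with a fixed, shared level set.
.confusion <- function(truth, pred, levels) {
  table(factor(truth, levels = levels), factor(pred, levels = levels),
        dnn = c("truth", "predicted"))
}

.eval_report <- function(confusion, protocol, seed, per_fold = NULL) {
  structure(list(confusion = unclass(confusion),
                 metrics = metrics_from_confusion(confusion),
                 protocol = protocol, seed = as.integer(seed),
                 per_fold = per_fold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (seed %d), n = %d\n",
              x$protocol, x$seed, sum(x$confusion)))
  print(x$confusion)
  m <- x$metrics
  cat(sprintf(paste0("accuracy %.2f%%  UAR %.2f%%  UAP %.2f%%  ",
                     "macro-F1 %.2f%%  kappa %.2f%%  G-mean %.2f%%\n"),
              100 * m$accuracy, 100 * m$uar, 100 * m$uap,
              100 * m$macro_f1, 100 * m$kappa, 100 * m$gmean))
  invisible(x)
}

#' Evaluate with a stratified 80:20 hold-out split
#'
#' Splits once, stratified by class: the test set holds `round((1-p) n)`
#' samples apportioned across classes by largest remainder, so per-class
#' proportions are preserved up to rounding. Trains on the training fraction
#' and scores the held-out rest.
#' An optional `preprocess(X_train, y_train)` hook — returning a function that
#' transforms a feature matrix — lets normalization and feature selection be
#' fit inside the training partition only (leakage-safe mode); by default the
#' features are used as given.
#'
#' @param X numeric feature matrix.
#' @param y class labels; every class needs at least 2 samples.
#' @param train_fraction training share of the split (default 0.8).
#' @param cfg an [svm_config()].
#' @param seed integer seed for the split.
#' @param preprocess optional `function(X_train, y_train) -> function(X)`.
#' @return An `eval_report` with `protocol = "holdout8020"`.
#' @export
evaluate_holdout <- function(X, y, train_fraction = 0.8, cfg = svm_config(),
                             seed = 1L, preprocess = NULL) {
  X <- as.matrix(X); y <- droplevels(factor(y))
  tab <- table(y)
  if (any(tab < 2L)) {
    stop(sprintf("evaluate_holdout: class '%s' has < 2 samples, cannot stratify",
                 names(tab)[which(tab < 2L)[1L]]))
  }
  test_idx <- sort(.stratified_test_idx(y, train_fraction, seed))
  if (length(test_idx) == 0L) {
    stop("evaluate_holdout: hold-out fraction leaves no test samples")
  }
  train_idx <- setdiff(seq_along(y), test_idx)
  transform <- if (is.null(preprocess)) function(Z) Z
               else preprocess(X[train_idx, , drop = FALSE], y[train_idx])
  Xtr <- transform(X[train_idx, , drop = FALSE])
  Xte <- transform(X[test_idx, , drop = FALSE])
  model <- train_svm(Xtr, y[train_idx], cfg)
  pred <- predict_svm(model, Xte)
  .eval_report(.confusion(y[test_idx], pred, levels(y)), "holdout8020", seed)
}

#' Evaluate with stratified 10-fold cross-validation
#'
#' Partitions the data into 10 stratified folds (per-class fold sizes differ
#' by at most one), tests each fold against a model trained on the other
#' nine, and pools the out-of-fold predictions into a single confusion
#' matrix; per-fold confusions are retained. The `preprocess` hook works as
#' in [evaluate_holdout()], refit inside every training partition.
#'
#' @inheritParams evaluate_holdout
#' @param n_folds number of folds (default 10).
#' @return An `eval_report` with `protocol = "cv10"` and `per_fold` confusions.
#' @export
evaluate_cv10 <- function(X, y, cfg = svm_config(), seed = 1L,
                          n_folds = 10L, preprocess = NULL) {
  X <- as.matrix(X); y <- droplevels(factor(y))
  tab <- table(y)
  if (any(tab < n_folds)) {
    stop(sprintf("evaluate_cv10: class '%s' has %d < %d samples, folds degenerate",
                 names(tab)[which(tab < n_folds)[1L]],
                 min(tab[tab < n_folds]), n_folds))
  }
  folds <- .with_preserved_rng(seed, caret::createFolds(y, k = n_folds))
  pred_all <- factor(rep(NA_character_, length(y)), levels = levels(y))
  per_fold <- vector("list", n_folds)
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    transform <- if (is.null(preprocess)) function(Z) Z
                 else preprocess(X[train_idx, , drop = FALSE], y[train_idx])
    model <- train_svm(transform(X[train_idx, , drop = FALSE]), y[train_idx], cfg)
    pred <- predict_svm(model, transform(X[test_idx, , drop = FALSE]))
    pred_all[test_idx] <- pred
    per_fold[[f]] <- unclass(.confusion(y[test_idx], pred, levels(y)))
  }
  .eval_report(.confusion(y, pred_all, levels(y)), "cv10", seed,
               per_fold = per_fold)
}
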