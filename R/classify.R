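#' Cross-validation configuration
#'
#' @param folds Number of stratified folds (default 10).
#' @param repeats Number of times the whole fold assignment is
#'   re-randomized and the CV repeated (default 100; the reported metrics
#'   are averaged over repeats).
#' @param seed Integer seed driving fold assignment and every stochastic
#'   classifier.
#' @param classifier One of `"random_forest"`, `"svm"`, `"mlp"`, `"knn"`,
#'   `"naive_bayes"`.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(folds = 10, repeats = 100, seed = 1,
                      classifier = c("random_forest", "svm", "mlp", "knn",
                                     "naive_bayes")) {
  classifier <- match.arg(classifier)
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), classifier = classifier),
            class = "cv_config")
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold sizes differ by at most one per class.
.stratified_folds <- function(y, folds) {
  assignment <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    assignment[idx[sample.int(length(idx))]] <-
      rep_len(sample.int(folds), length(idx))
  }
  assignment
}

# Fit one classifier and return a per-class score matrix for newdata.
.fit_predict_scores <- function(xtr, ytr, xte, classifier) {
  classes <- levels(ytr)
  scores <- switch(classifier,
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr)
      stats::predict(fit, xte, type = "prob")
    },
    svm = {
      fit <- e1071::svm(xtr, ytr, probability = TRUE)
      attr(stats::predict(fit, xte, probability = TRUE), "probabilities")
    },
    mlp = {
      fit <- nnet::nnet(xtr, stats::model.matrix(~ ytr - 1), size = 16,
                        softmax = TRUE, maxit = 200, trace = FALSE,
                        MaxNWts = 1e6)
      p <- stats::predict(fit, xte)
      colnames(p) <- classes
      p
    },
    knn = .knn_scores(xtr, ytr, xte, k = 5L),
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, xte, type = "raw")
    },
    stop("unknown classifier: ", classifier))
  scores <- scores[, classes, drop = FALSE]
  rownames(scores) <- rownames(xte)
  scores
}

# k-nearest-neighbor class-vote fractions.  Written here because the
# standard knn interfaces return only the winning class, not the full
# per-class vote matrix needed for ROC analysis.
.knn_scores <- function(xtr, ytr, xte, k = 5L) {
  classes <- levels(ytr)
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * xte %*% t(xtr)
  scores <- matrix(0, nrow(xte), length(classes),
                   dimnames = list(rownames(xte), classes))
  for (i in seq_len(nrow(xte))) {
    nb <- ytr[order(d2[i, ])[seq_len(min(k, ncol(d2)))]]
    tab <- table(nb) / length(nb)
    scores[i, names(tab)] <- as.numeric(tab)
  }
  scores
}

#' Per-class confusion counts from hard predictions
#'
#' @param truth,predicted Factors (or vectors) of the same length.
#' @param classes Class labels; defaults to the union of observed labels.
#' @return A data frame with one row per class and columns `TP`, `TN`,
#'   `FP`, `FN` (each row sums to the number of samples).
#' @export
confusion_counts <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- sort(union(truth, predicted))
  out <- t(vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- sum(truth != cl & predicted != cl)
    c(TP = tp, TN = tn, FP = fp, FN = fn)
  }, c(TP = 0, TN = 0, FP = 0, FN = 0)))
  data.frame(class = classes, out, row.names = NULL)
}

#' Multiclass accuracy, precision, recall and F-measure
#'
#' Accuracy is the mean over classes of the per-class one-vs-rest accuracy
#' (TP_i + TN_i) / n; precision and recall are micro-pooled across classes
#' (sum TP / sum(TP + FP) and sum TP / sum(TP + FN)); the F-measure is
#' their harmonic mean (0 when both vanish).
#'
#' @param counts Output of [confusion_counts()].
#' @return A named list with `accuracy`, `precision`, `recall`,
#'   `f_measure`.
#' @export
multiclass_metrics <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  accuracy <- mean((counts$TP + counts$TN) / n)
  tp <- sum(counts$TP)
  precision <- if (tp + sum(counts$FP) == 0) 0 else tp / (tp + sum(counts$FP))
  recall <- if (tp + sum(counts$FN) == 0) 0 else tp / (tp + sum(counts$FN))
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = accuracy, precision = precision, recall = recall,
       f_measure = f)
}

# TPR/FPR of one one-vs-rest problem at a decreasing threshold sweep.
.rates_at_thresholds <- function(scores, positive, thresholds) {
  pos <- sort(scores[positive])
  neg <- sort(scores[!positive])
  # count of values >= t  (findInterval with left.open counts values < t)
  n_ge <- function(x, t) length(x) - findInterval(t, x, left.open = TRUE)
  tpr <- vapply(thresholds, function(t) n_ge(pos, t), 0) / max(length(pos), 1L)
  fpr <- vapply(thresholds, function(t) n_ge(neg, t), 0) / max(length(neg), 1L)
  list(tpr = tpr, fpr = fpr)
}

.trapezoid <- function(x, y) {
  ord <- order(x, y)
  sum(diff(x[ord]) * (utils::head(y[ord], -1L) + utils::tail(y[ord], -1L)) / 2)
}

#' One-vs-rest, micro- and macro-averaged ROC areas
#'
#' Sweeps a shared decreasing threshold over all scores.  For each class
#' the one-vs-rest TPR/FPR curve gives `auc_per_class`.  The micro curve
#' pools TP and FP counts across classes at every threshold before
#' forming rates; the macro curve averages the per-class TPR and FPR at
#' every threshold.  Areas are trapezoidal.
#'
#' @param scores Samples-by-classes score matrix (column names are class
#'   labels).
#' @param truth Vector of true class labels.
#' @return A list with `auc_per_class`, `auc_micro`, `auc_macro` and the
#'   `curves` (per-threshold rates).
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.character(truth)
  stopifnot(nrow(scores) == length(truth), !is.null(colnames(scores)))
  classes <- colnames(scores)
  thresholds <- c(Inf, sort(unique(as.vector(scores)), decreasing = TRUE), -Inf)
  per <- lapply(classes, function(cl)
    .rates_at_thresholds(scores[, cl], truth == cl, thresholds))
  names(per) <- classes
  auc_per_class <- vapply(classes, function(cl)
    .trapezoid(per[[cl]]$fpr, per[[cl]]$tpr), 0)
  tpr_macro <- rowMeans(vapply(per, `[[`, numeric(length(thresholds)), "tpr"))
  fpr_macro <- rowMeans(vapply(per, `[[`, numeric(length(thresholds)), "fpr"))
  n_pos <- vapply(classes, function(cl) sum(truth == cl), 0)
  n_neg <- length(truth) - n_pos
  tp_pool <- rowSums(vapply(seq_along(classes), function(j)
    per[[j]]$tpr * n_pos[j], numeric(length(thresholds))))
  fp_pool <- rowSums(vapply(seq_along(classes), function(j)
    per[[j]]$fpr * n_neg[j], numeric(length(thresholds))))
  tpr_micro <- tp_pool / sum(n_pos)
  fpr_micro <- fp_pool / sum(n_neg)
  list(auc_per_class = auc_per_class,
       auc_micro = .trapezoid(fpr_micro, tpr_micro),
       auc_macro = .trapezoid(fpr_macro, tpr_macro),
       curves = list(thresholds = thresholds, per_class = per,
                     tpr_macro = tpr_macro, fpr_macro = fpr_macro,
                     tpr_micro = tpr_micro, fpr_micro = fpr_micro))
}

#' Repeated stratified cross-validation of subtype prediction
#'
#' Repeats stratified k-fold cross-validation `repeats` times with
#' re-randomized fold assignments.  Within each repeat the out-of-fold
#' hard predictions and per-class scores are pooled, the confusion-based
#' metrics and ROC areas computed, and finally all metrics are averaged
#' over repeats.
#'
#' @param X Feature matrix (tumors by genes), typically the propagated
#'   profiles.
#' @param labels Partition of the tumors into subtypes.
#' @param config A [cv_config()].
#' @return A list of class `eval_report` with averaged `accuracy`,
#'   `precision`, `recall`, `f_measure`, `auc_per_class`, `auc_micro`,
#'   `auc_macro`, and `per_repeat` (a data frame of per-repeat values).
#' @export
cross_validate <- function(X, labels, config = cv_config()) {
  labels <- as_partition(labels)
  ids <- intersect(rownames(X), names(labels))
  if (length(ids) < 2L) stop("feature matrix and labels share too few tumors")
  X <- X[ids, , drop = FALSE]
  y <- factor(unclass(labels)[ids])
  sizes <- table(y)
  too_small <- names(sizes)[sizes < config$folds]
  if (length(too_small) > 0L) {
    stop(sprintf("class '%s' has %d members, fewer than %d folds",
                 too_small[1L], sizes[too_small[1L]], config$folds))
  }
  set.seed(config$seed)
  classes <- levels(y)
  rep_rows <- vector("list", config$repeats)
  auc_class_acc <- matrix(0, config$repeats, length(classes),
                          dimnames = list(NULL, classes))
  for (r in seq_len(config$repeats)) {
    fold <- .stratified_folds(y, config$folds)
    scores <- matrix(NA_real_, length(y), length(classes),
                     dimnames = list(ids, classes))
    for (f in seq_len(config$folds)) {
      te <- fold == f
      sc <- .fit_predict_scores(X[!te, , drop = FALSE], droplevels(y[!te]),
                                X[te, , drop = FALSE], config$classifier)
      scores[te, colnames(sc)] <- sc
    }
    scores[is.na(scores)] <- 0
    pred <- classes[max.col(scores, ties.method = "first")]
    cm <- multiclass_metrics(confusion_counts(y, pred, classes))
    roc <- roc_auc(scores, y)
    auc_class_acc[r, ] <- roc$auc_per_class
    rep_rows[[r]] <- data.frame(repeat_id = r, accuracy = cm$accuracy,
                                precision = cm$precision, recall = cm$recall,
                                f_measure = cm$f_measure,
                                auc_micro = roc$auc_micro,
                                auc_macro = roc$auc_macro)
  }
  per_repeat <- do.call(rbind, rep_rows)
  structure(list(
    accuracy = mean(per_repeat$accuracy),
    precision = mean(per_repeat$precision),
    recall = mean(per_repeat$recall),
    f_measure = mean(per_repeat$f_measure),
    auc_per_class = colMeans(auc_class_acc),
    auc_micro = mean(per_repeat$auc_micro),
    auc_macro = mean(per_repeat$auc_macro),
    classifier = config$classifier,
    per_repeat = per_repeat), class = "eval_report")
}

#' Gini-importance gene selection with a random forest
#'
#' Fits a random forest on the full cohort, normalizes the mean decrease
#' in Gini impurity to sum to one, and flags genes whose normalized
#' importance exceeds `threshold`.
#'
#' @param X Feature matrix (tumors by genes).
#' @param labels Subtype partition of the tumors.
#' @param threshold Selection cutoff on normalized importance
#'   (default 0.01).
#' @param seed Integer seed for the forest.
#' @param ntree Number of trees.
#' @return A data frame (`importance_table`) with columns `gene`,
#'   `importance` (summing to 1) and `selected`, sorted by decreasing
#'   importance.
#' @export
feature_importance <- function(X, labels, threshold = 0.01, seed = 1,
                               ntree = 500) {
  labels <- as_partition(labels)
  ids <- intersect(rownames(X), names(labels))
  y <- factor(unclass(labels)[ids])
  set.seed(seed)
  fit <- randomForest::randomForest(X[ids, , drop = FALSE], y, ntree = ntree,
                                    importance = FALSE)
  imp <- fit$importance[, "MeanDecreaseGini"]
  imp <- imp / sum(imp)
  out <- data.frame(gene = names(imp), importance = unname(imp),
                    selected = unname(imp) > threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", class(out))
  out
}
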