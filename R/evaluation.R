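#' Leave-one-out cross-validation
#'
#' Each unit -- a single window, or all windows of one subject -- is
#' predicted by a model trained on all remaining units. Window-level LOOCV
#' mirrors common practice with overlapping windows but leaks subject
#' identity across folds (neighboring windows of one subject share 2/3 of
#' their samples); subject-level LOOCV gives the honest generalization
#' estimate. Reports therefore always carry the unit used.
#'
#' @param fm a [feature_matrix()] with labels set; `groups` required for
#'   `unit = "subject"`.
#' @param unit `"window"` or `"subject"`.
#' @param spec an [svm_spec()].
#' @return data frame with one row per sample: `truth`, `pred`, `fold`,
#'   `group`, and `score` (binary tasks only), plus attribute `unit`.
#' @export
loocv <- function(fm, unit = c("window", "subject"), spec = svm_spec()) {
  stopifnot(inherits(fm, "feature_matrix"))
  unit <- match.arg(unit)
  if (is.null(fm$labels)) stop_invalid("feature matrix has no labels")
  n <- nrow(fm$F)
  y <- droplevels(fm$labels)
  if (nlevels(y) < 2) stop_invalid("need >= 2 classes for cross-validation")
  groups <- fm$groups
  if (unit == "subject") {
    if (is.null(groups)) stop_invalid("unit = 'subject' requires groups")
    folds <- split(seq_len(n), factor(groups, levels = unique(groups)))
  } else {
    folds <- as.list(seq_len(n))
  }
  binary <- nlevels(y) == 2
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_id <- integer(n)
  score <- if (binary) rep(NA_real_, n) else NULL
  for (k in seq_along(folds)) {
    test <- folds[[k]]
    train <- setdiff(seq_len(n), test)
    ytr <- droplevels(y[train])
    if (nlevels(ytr) < 2)
      stop_invalid("degenerate fold %d: training data contain a single class",
                   k)
    model <- train_svm(fm$F[train, , drop = FALSE], y[train], spec)
    pred[test] <- predict(model, fm$F[test, , drop = FALSE])
    if (binary)
      score[test] <- predict(model, fm$F[test, , drop = FALSE],
                             type = "score")
    fold_id[test] <- k
  }
  out <- data.frame(truth = y, pred = pred, fold = fold_id,
                    group = if (is.null(groups)) NA_character_ else groups,
                    stringsAsFactors = FALSE)
  if (binary) out$score <- score
  attr(out, "unit") <- unit
  out
}

#' Confusion matrix (rows = truth, columns = prediction)
#'
#' @param truth,pred aligned label vectors.
#' @param levels optional explicit class order.
#' @return integer matrix of counts.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- union(levels(factor(truth)),
                                       levels(factor(pred)))
  t1 <- factor(truth, levels = levels)
  t2 <- factor(pred, levels = levels)
  unclass(table(truth = t1, pred = t2))
}

#' Youden's J statistic
#'
#' `J = sensitivity + specificity - 1`. `J = 1` characterizes a perfect
#' test, `J = 0` one that is no better than chance.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return numeric J in `[-1, 1]`.
#' @export
youden <- function(sensitivity, specificity) {
  if (!is.numeric(sensitivity) || !is.numeric(specificity))
    stop_invalid("sensitivity and specificity must be numeric")
  if (any(!is.finite(sensitivity)) || any(!is.finite(specificity)) ||
      any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop_invalid("sensitivity and specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' Rank (trapezoidal) AUC from decision scores
#'
#' Mann--Whitney probability that a positive scores above a negative, with
#' ties counted half.
#'
#' @param scores numeric decision values (higher = more positive).
#' @param truth class labels aligned with `scores`.
#' @param positive the positive class label.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
rank_auc <- function(scores, truth, positive) {
  pos <- truth == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Binary classification metrics
#'
#' Computes accuracy, sensitivity (true-positive rate among the disease
#' class), specificity (true-negative rate among controls), Youden's J and
#' two AUC variants from a 2x2 confusion matrix: `auc_balanced =
#' (sensitivity + specificity) / 2`, which reproduces published
#' LOOCV tables that report a single AUC per hard-label classifier, and
#' `auc_rank`, the trapezoidal AUC from decision scores when available.
#' By convention the disease class is positive and HC negative; for
#' disease-vs-disease tasks the first-named class is positive.
#'
#' A side with zero samples yields `NA` for the affected rate and is listed
#' in `flags` rather than silently reported as 0.
#'
#' @param confusion 2x2 count matrix, rows = truth, columns = prediction.
#' @param positive name of the positive class (must be a row name).
#' @param scores,truth optional decision scores and aligned truth labels for
#'   `auc_rank`.
#' @return object of class `eval_metrics`.
#' @export
binary_metrics <- function(confusion, positive, scores = NULL,
                           truth = NULL) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == 2))
  if (!(positive %in% rownames(confusion)))
    stop_invalid("positive class '%s' is not a row of the confusion matrix",
                 positive)
  negative <- setdiff(rownames(confusion), positive)
  tp <- confusion[positive, positive]
  fn <- confusion[positive, negative]
  tn <- confusion[negative, negative]
  fp <- confusion[negative, positive]
  total <- tp + fn + tn + fp
  if (total == 0) stop_invalid("empty confusion matrix")
  flags <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    flags <- c(flags, "no positive samples: sensitivity undefined")
    NA_real_
  }
  spc <- if (tn + fp > 0) tn / (tn + fp) else {
    flags <- c(flags, "no negative samples: specificity undefined")
    NA_real_
  }
  aucr <- if (!is.null(scores) && !is.null(truth))
    rank_auc(scores, truth, positive) else NA_real_
  structure(list(
    positive = positive, negative = negative,
    confusion = confusion, n = total,
    accuracy = (tp + tn) / total,
    sensitivity = sens, specificity = spc,
    auc_balanced = if (is.na(sens) || is.na(spc)) NA_real_
                   else (sens + spc) / 2,
    auc_rank = aucr,
    youden = if (is.na(sens) || is.na(spc)) NA_real_ else youden(sens, spc),
    flags = flags
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "<eval_metrics %s vs %s> acc %.2f%%, sens %.2f%%, spec %.2f%%, AUC %.4f, J %.4f (n = %d)\n",
    x$positive, paste(x$negative, collapse = "+"),
    100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
    x$auc_balanced, x$youden, x$n))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Per-class metrics for a multiclass confusion matrix
#'
#' Collapses the K x K confusion matrix one-vs-rest for every class and
#' applies [binary_metrics()]; overall accuracy is the diagonal fraction.
#'
#' @param confusion K x K count matrix (K >= 3), rows = truth.
#' @return list with `overall_accuracy`, `per_class` (named list of
#'   `eval_metrics`) and the input `confusion`.
#' @export
multiclass_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  K <- nrow(confusion)
  if (K < 3) stop_invalid("multiclass metrics need K >= 3 classes")
  classes <- rownames(confusion) %||% paste0("class", seq_len(K))
  per <- lapply(seq_len(K), function(k) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, -k])
    fp <- sum(confusion[-k, k])
    tn <- sum(confusion[-k, -k])
    cm <- matrix(c(tp, fp, fn, tn), 2, 2,
                 dimnames = list(c(classes[k], "rest"),
                                 c(classes[k], "rest")))
    binary_metrics(cm, positive = classes[k])
  })
  names(per) <- classes
  list(overall_accuracy = sum(diag(confusion)) / sum(confusion),
       per_class = per, confusion = confusion)
}

#' Select the best force channel by Youden's index
#'
#' Argmax of J over the evaluated channels; ties are broken by accuracy and
#' then by the fixed order LF < RF < CF.
#'
#' @param metrics named list of `eval_metrics`, names in
#'   `c("LF", "RF", "CF")`.
#' @return the selected channel name.
#' @export
select_best_channel <- function(metrics) {
  stopifnot(length(metrics) >= 1, !is.null(names(metrics)))
  chans <- names(metrics)
  order_rank <- match(chans, c("LF", "RF", "CF"))
  J <- vapply(metrics, function(m) m$youden, numeric(1))
  acc <- vapply(metrics, function(m) m$accuracy, numeric(1))
  best <- order(-J, -acc, order_rank)[1]
  chans[best]
}
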