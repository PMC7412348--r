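#' Linear SVM specification
#'
#' Configuration for the classifier stage: a linear support vector machine
#' trained in the primal with squared hinge loss (deterministic L-BFGS-B
#' optimization, no sampling), with one-vs-one pairwise coupling for more
#' than two classes. Feature scaling is off by default; set `scale = TRUE`
#' for z-scoring using training-fold statistics.
#'
#' @param kernel only `"linear"` is implemented.
#' @param C regularization strength (> 0), default 1.
#' @param multiclass only `"one-vs-one"` is implemented.
#' @param scale z-score features using training statistics.
#' @param seed seed recorded for provenance (training itself is
#'   deterministic).
#' @param maxit optimizer iteration cap.
#' @return object of class `svm_spec`.
#' @export
svm_spec <- function(kernel = "linear", C = 1, multiclass = "one-vs-one",
                     scale = FALSE, seed = 1L, maxit = 300L) {
  if (!identical(kernel, "linear"))
    stop_invalid("only the linear kernel is implemented")
  if (!identical(multiclass, "one-vs-one"))
    stop_invalid("only one-vs-one multiclass coupling is implemented")
  if (!is_number(C) || C <= 0) stop_invalid("C must be > 0")
  structure(list(kernel = kernel, C = C, multiclass = multiclass,
                 scale = isTRUE(scale), seed = as.integer(seed),
                 maxit = as.integer(maxit)),
            class = "svm_spec")
}

# Squared-hinge linear SVM in the primal:
#   min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w.x_i)^2
# with a bias absorbed as an appended constant feature. Smooth objective,
# solved by L-BFGS-B; fully deterministic.
svm_binary_fit <- function(X, y, C, maxit) {
  obj <- function(w) {
    m <- pmax(0, 1 - y * as.numeric(X %*% w))
    0.5 * sum(w^2) + C * sum(m^2)
  }
  grad <- function(w) {
    m <- pmax(0, 1 - y * as.numeric(X %*% w))
    w - 2 * C * as.numeric(crossprod(X, m * y))
  }
  fit <- stats::optim(numeric(ncol(X)), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  fit$par
}

#' Train a linear SVM
#'
#' @param x samples x features matrix, or a [feature_matrix()] (whose labels
#'   are used when `y` is missing).
#' @param y class labels, one per row; at least two classes must be present.
#' @param spec an [svm_spec()].
#' @return object of class `gait_svm` with one weight vector per class pair.
#' @export
train_svm <- function(x, y = NULL, spec = svm_spec()) {
  stopifnot(inherits(spec, "svm_spec"))
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$labels
    x <- x$F
  }
  x <- as.matrix(x)
  if (is.null(y)) stop_invalid("labels y are required")
  y <- factor(y)
  if (length(y) != nrow(x)) stop_invalid("y length must match rows of x")
  y <- droplevels(y)
  if (nlevels(y) < 2)
    stop_invalid("training data contain a single class ('%s'); need >= 2",
                 levels(y)[1])
  center <- scl <- NULL
  if (spec$scale) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scl, "/")
  }
  Xa <- cbind(x, 1)  # bias feature
  levs <- levels(y)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  weights <- lapply(pairs, function(p) {
    keep <- y %in% p
    yy <- ifelse(y[keep] == p[1], 1, -1)
    svm_binary_fit(Xa[keep, , drop = FALSE], yy, spec$C, spec$maxit)
  })
  names(weights) <- vapply(pairs, paste, character(1), collapse = "|")
  structure(list(weights = weights, pairs = pairs, levels = levs,
                 n_features = ncol(x), spec = spec,
                 center = center, scale = scl),
            class = "gait_svm")
}

#' @export
print.gait_svm <- function(x, ...) {
  cat(sprintf("<gait_svm linear> %d class(es): %s; %d feature(s), C = %g\n",
              length(x$levels), paste(x$levels, collapse = ", "),
              x$n_features, x$spec$C))
  invisible(x)
}

#' Predict classes (or decision scores) from a trained SVM
#'
#' One-vs-one voting; ties are broken in favor of the earliest class in the
#' training level order. For binary models `type = "score"` returns the
#' signed decision value of the single pairwise classifier (positive means
#' the first level).
#'
#' @param object a `gait_svm`.
#' @param newdata matrix (or [feature_matrix()]) with the training feature
#'   width; may have zero rows.
#' @param type `"class"` or `"score"`.
#' @param ... unused.
#' @return factor of predicted labels, or numeric scores.
#' @export
predict.gait_svm <- function(object, newdata, type = c("class", "score"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$F
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) {
    return(if (type == "class") factor(character(0),
                                       levels = object$levels)
           else numeric(0))
  }
  if (ncol(newdata) != object$n_features)
    stop_invalid("newdata has %d features but the model was trained on %d",
                 ncol(newdata), object$n_features)
  if (!is.null(object$center))
    newdata <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  Xa <- cbind(newdata, 1)
  scores <- vapply(object$weights, function(w) as.numeric(Xa %*% w),
                   numeric(nrow(Xa)))
  if (nrow(Xa) == 1) scores <- matrix(scores, nrow = 1)
  if (type == "score") {
    if (length(object$levels) != 2)
      stop_invalid("decision scores are defined for binary models only")
    return(as.numeric(scores[, 1]))
  }
  votes <- matrix(0L, nrow(Xa), length(object$levels),
                  dimnames = list(NULL, object$levels))
  for (k in seq_along(object$pairs)) {
    p <- object$pairs[[k]]
    win <- ifelse(scores[, k] > 0, p[1], p[2])
    for (lev in p) votes[, lev] <- votes[, lev] + (win == lev)
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
         levels = object$levels)
}
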