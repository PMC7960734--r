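# Linear SVM training via dual coordinate descent, with inner-CV cost
# tuning. The solver optimizes the L1-loss (hinge) primal
#   0.5 ||w||^2 + 0.5 (b / S)^2 + C * sum_i max(0, 1 - y_i (w.x_i + b))
# in its dual by randomized coordinate sweeps; the bias enters as an
# augmented constant feature of value S (`bias_scale`), i.e. it carries a
# weak penalty of its own — the standard fast-linear-SVM formulation.

svm_bias_scale <- function() 10

# One solver call. y must be +/-1 with +1 the positive class, so the
# returned decision score s(x) = w.x + b is oriented by construction.
svm_fit_raw <- function(x, y_pm, C, eps = 1e-6, max_sweeps = 20000, seed = 1) {
  fit <- .svm_dcd(x, y_pm, C, eps = eps, max_sweeps = max_sweeps,
                  bias_scale = svm_bias_scale(), seed = as.integer(seed))
  p <- ncol(x)
  list(w = fit$w[seq_len(p)], b = fit$w[p + 1], sweeps = fit$sweeps)
}

#' Linear-kernel SVM with inner-CV regularization tuning
#'
#' Trains a soft-margin linear SVM at every cost value of a log-spaced grid,
#' picks the cost maximizing stratified inner-CV accuracy (ties broken
#' toward the smaller, more regularized cost), and refits at that cost on
#' all provided rows. The optimizer is dual coordinate descent on the hinge
#' loss (the standard algorithm for linear SVMs), with the bias handled as
#' a weakly regularized augmented feature. The decision score is
#' \eqn{s(x) = w \cdot x + b}, oriented so larger scores favour the
#' positive (remitted) class.
#'
#' @param x Feature matrix or tibble (rows = subjects); no missing values.
#' @param y Binary outcome (see [fit_lasso_cv()] for the coding).
#' @param C_grid Cost grid; default 10 log-spaced values in \[1e-3, 1e3\].
#' @param inner_folds Folds of the inner tuning CV (default 5).
#' @param seed Seed for the inner fold assignment and coordinate ordering.
#' @return Object of class `remit_svm`: weights `w` (named), bias `b`,
#'   chosen `C`, the grid and its CV accuracies, and the positive class.
#' @export
train_svm <- function(x, y, C_grid = 10^seq(-3, 3, length.out = 10),
                      inner_folds = 5, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  assert_that(ncol(x) >= 1, "feature matrix must be non-empty")
  assert_that(all(is.finite(x)), "non-finite values in feature matrix")
  if (nrow(unique(as.data.frame(x))) == 1) {
    stop("degenerate feature matrix: all rows identical", call. = FALSE)
  }
  pos <- positive_class(y)
  y_pm <- 2 * encode_label(y) - 1
  assert_that(length(unique(y_pm)) == 2, "both classes must be present in y")
  C_grid <- sort(C_grid)
  foldid <- stratified_folds(y_pm, inner_folds, substream_seed(seed, "svm_folds"))
  cv_acc <- vapply(C_grid, function(C) {
    accs <- vapply(seq_len(inner_folds), function(f) {
      tr <- foldid != f
      if (length(unique(y_pm[tr])) < 2 || !any(!tr)) return(NA_real_)
      m <- svm_fit_raw(x[tr, , drop = FALSE], y_pm[tr], C,
                       eps = 1e-3, max_sweeps = 2000,
                       seed = substream_seed(seed, paste0("dcd", f)))
      s <- drop(x[!tr, , drop = FALSE] %*% m$w) + m$b
      mean(sign(s) == y_pm[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  C_star <- C_grid[which.max(cv_acc)] # which.max takes first tie -> smaller C
  fit <- svm_fit_raw(x, y_pm, C_star, eps = 1e-7, max_sweeps = 50000,
                     seed = substream_seed(seed, "dcd_final"))
  w <- fit$w
  names(w) <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  structure(list(w = w, b = fit$b, C = C_star, C_grid = C_grid,
                 cv_accuracy = cv_acc, positive = pos,
                 bias_scale = svm_bias_scale()),
            class = "remit_svm")
}

#' @export
print.remit_svm <- function(x, ...) {
  cat(sprintf("<remit_svm> linear SVM, %d features, C = %.4g (positive class: %s)\n",
              length(x$w), x$C, x$positive))
  invisible(x)
}

#' Decision scores and predicted labels of a linear SVM
#'
#' @param object A [train_svm()] model.
#' @param newx Feature matrix with the model's feature columns.
#' @param type `"score"` (default) for the decision value `w.x + b` or
#'   `"class"` for 0/1 labels.
#' @param ... Unused.
#' @return Numeric scores or 0/1 predictions.
#' @export
predict.remit_svm <- function(object, newx, type = c("score", "class"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (!is.null(colnames(newx))) newx <- newx[, names(object$w), drop = FALSE]
  s <- drop(newx %*% object$w) + object$b
  if (type == "score") s else as.numeric(s > 0)
}

#' Rank features by absolute SVM weight
#'
#' Orders a trained model's features by decreasing absolute weight (ties
#' broken by feature name); rank 1 is the most important feature in the
#' prediction model, mirroring the weight-ranking convention used to report
#' discriminative features.
#'
#' @param model A [train_svm()] model (or a named weight vector).
#' @return Tibble: `feature`, `weight`, `rank`.
#' @export
rank_features <- function(model) {
  w <- if (inherits(model, "remit_svm")) model$w else model
  assert_that(!is.null(names(w)), "weights must be named")
  ord <- order(-abs(w), names(w))
  tibble::tibble(feature = names(w)[ord], weight = unname(w[ord]),
                 rank = seq_along(w))
}
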