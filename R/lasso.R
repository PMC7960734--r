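#' Cross-validated LASSO on a binary label
#'
#' Fits an L1-penalized squared-error regression of the 0/1 outcome label on
#' the (Z-normalized) features — the classical LASSO used as a feature
#' screen before classification. The penalty path is 100 log-spaced values
#' from \eqn{\lambda_{max} = \max_j |x_j^T (y - \bar y)| / n} (the smallest
#' penalty with an all-zero solution) down to `lambda_min_ratio` times it;
#' the fit is solved by cyclic coordinate descent (glmnet), and the penalty
#' minimizing 10-fold cross-validated squared error is selected (ties broken
#' toward the larger, i.e. sparser, penalty).
#'
#' @param x Numeric matrix or tibble of features (rows = subjects). Should
#'   already be Z-normalized; no missing values allowed.
#' @param y Binary outcome: factor, character or 0/1. The second factor
#'   level (or `"remitted"` when present) is coded 1.
#' @param n_folds Folds for the internal CV (default 10).
#' @param lambda Optional explicit penalty grid (decreasing).
#' @param nlambda,lambda_min_ratio Grid size and lower end relative to
#'   \eqn{\lambda_{max}} (defaults 100 and 1e-3).
#' @param seed Seed for the fold assignment.
#' @param thresh Coordinate-descent convergence threshold (passed to
#'   glmnet; default 1e-12 so Karush–Kuhn–Tucker residuals are tight).
#' @return Object of class `lasso_fit`: coefficients `beta` (named),
#'   `intercept`, selected `lambda`, the grid `lambda_grid`, per-penalty CV
#'   loss `cvm`, and `selected` (names of nonzero-coefficient features).
#' @export
fit_lasso_cv <- function(x, y, n_folds = 10, lambda = NULL, nlambda = 100,
                         lambda_min_ratio = 1e-3, seed = 1, thresh = 1e-12) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  assert_that(all(is.finite(x)), "non-finite values in feature matrix")
  y01 <- encode_label(y)
  assert_that(length(unique(y01)) == 2, "both classes must be present in y")
  n <- nrow(x)
  if (is.null(lambda)) {
    lmax <- max(abs(crossprod(x, y01 - mean(y01)))) / n
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
  }
  foldid <- stratified_folds(y01, n_folds, substream_seed(seed, "lasso_folds"))
  # CV path at moderate precision; the returned coefficients are refit below
  # on the warm-started path truncated at the selected penalty, at `thresh`,
  # so they satisfy the KKT conditions tightly without paying for
  # high-precision solutions at penalties that are never selected.
  cvfit <- suppressWarnings(
    glmnet::cv.glmnet(x, y01, family = "gaussian", lambda = lambda,
                      foldid = foldid, standardize = FALSE, maxit = 10^6))
  # grid is decreasing: the first index attaining the minimum CV loss is the
  # largest (sparsest) penalty among ties
  cvm <- cvfit$cvm
  lam_star <- cvfit$lambda[which(cvm <= min(cvm) + 1e-12)[1]]
  path <- lambda[lambda >= lam_star * (1 - 1e-9)]
  refit <- suppressWarnings(
    glmnet::glmnet(x, y01, family = "gaussian", lambda = path,
                   standardize = FALSE, thresh = thresh, maxit = 10^6))
  cf <- coef(refit, s = lam_star, exact = FALSE)
  beta <- as.numeric(cf)[-1]
  names(beta) <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  structure(list(beta = beta, intercept = as.numeric(cf)[1],
                 lambda = lam_star, lambda_grid = cvfit$lambda, cvm = cvm,
                 selected = names(beta)[beta != 0], n = n),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> %d/%d features selected at lambda = %.4g\n",
              length(x$selected), length(x$beta), x$lambda))
  invisible(x)
}

#' Features selected by a LASSO fit
#'
#' Names of the nonzero-coefficient features in original column order. An
#' empty selection is returned as a zero-length vector with attribute
#' `empty_selection = TRUE`, so callers can fall back (e.g. to all
#' features) with a warning rather than failing silently.
#'
#' @param fit A [fit_lasso_cv()] result.
#' @return Character vector of feature names.
#' @export
select_features <- function(fit) {
  assert_that(inherits(fit, "lasso_fit"), "fit must be a lasso_fit")
  sel <- names(fit$beta)[fit$beta != 0]
  if (!length(sel)) attr(sel, "empty_selection") <- TRUE
  sel
}

# 0/1 outcome coding; "remitted" is the positive class when present,
# otherwise the second factor level.
encode_label <- function(y) {
  if (is.numeric(y)) {
    u <- sort(unique(y))
    assert_that(all(u %in% c(0, 1)) || all(u %in% c(-1, 1)),
                "numeric y must be 0/1 or -1/+1")
    return(as.numeric(y == max(u)))
  }
  y <- as.character(y)
  lev <- sort(unique(y))
  pos <- if ("remitted" %in% lev) "remitted" else lev[length(lev)]
  as.numeric(y == pos)
}

positive_class <- function(y) {
  if (is.numeric(y)) return(max(y))
  lev <- sort(unique(as.character(y)))
  if ("remitted" %in% lev) "remitted" else lev[length(lev)]
}
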