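#' Classification metrics for a binary outcome
#'
#' Counts true/false positives and negatives with the remitted group as the
#' positive class: sensitivity is the fraction of remitted subjects
#' correctly identified, specificity the fraction of continued-AUD subjects
#' correctly identified, and accuracy `(TP + TN) / n`. The AUC is computed
#' from the rank of the continuous decision scores with half credit for
#' ties (the Mann–Whitney statistic). When a class is absent from `truth`
#' the corresponding rate is undefined and reported as `NA`, never 0.
#'
#' @param truth True labels.
#' @param pred Predicted labels (same coding).
#' @param scores Optional continuous decision scores (larger = more
#'   positive) for the AUC.
#' @param positive Positive class (default `"remitted"` when present).
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc`.
#' @examples
#' compute_metrics(rep(c("remitted", "continued"), c(10, 10)),
#'                 rep(c("remitted", "continued"), c(12, 8)))
#' @export
compute_metrics <- function(truth, pred, scores = NULL, positive = NULL) {
  assert_that(length(truth) == length(pred), "truth and pred must have equal length")
  pos <- positive %||% positive_class(truth)
  t1 <- truth == pos
  p1 <- pred == pos
  tp <- sum(t1 & p1); tn <- sum(!t1 & !p1)
  fp <- sum(!t1 & p1); fn <- sum(t1 & !p1)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = if (!is.null(scores)) auc_rank(t1, scores) else NA_real_)
}

# Rank-based AUC (Mann-Whitney with midranks for ties); NA if one class absent.
auc_rank <- function(is_pos, scores) {
  assert_that(length(is_pos) == length(scores), "scores must match labels")
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Shared fit-and-score primitive: normalize -> LASSO-select -> SVM, fit on
# training rows only, scored on test rows. `preselected` skips the
# normalization/selection (paper-faithful mode, already done globally).
fit_score_fold <- function(X, y, train, test, seed,
                           preselected = NULL, C_grid = 10^seq(-3, 3, length.out = 10),
                           inner_folds = 5, lasso_folds = 10) {
  Xtr <- X[train, , drop = FALSE]
  Xte <- X[test, , drop = FALSE]
  if (is.null(preselected)) {
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2, sd)
    sg[sg == 0] <- Inf # constant in training fold -> zeroed
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    fit <- fit_lasso_cv(Xtr, y[train], n_folds = lasso_folds, seed = seed)
    sel <- select_features(fit)
    if (!length(sel)) {
      warning("empty LASSO selection; falling back to all features")
      sel <- colnames(Xtr)
    }
  } else {
    sel <- preselected
  }
  model <- train_svm(Xtr[, sel, drop = FALSE], y[train], C_grid = C_grid,
                     inner_folds = inner_folds, seed = seed)
  scores <- predict(model, Xte[, sel, drop = FALSE])
  pos <- model$positive
  lev <- sort(unique(as.character(y)))
  neg <- setdiff(lev, pos)[1]
  pred <- ifelse(scores > 0, pos, neg)
  list(metrics = compute_metrics(y[test], pred, scores, positive = pos),
       selected = sel, model = model)
}

#' Repeated stratified k-fold cross-validation of the LASSO->SVM pipeline
#'
#' Evaluates the full classification pipeline on a stratum feature table by
#' shuffled, stratified `outer_folds`-fold cross-validation repeated
#' `repeats` times (a fresh shuffle before every repeat), in one of two
#' modes:
#'
#' * `"paper_faithful"` — Z-normalization and LASSO feature selection are
#'   performed once on the whole stratum, and only the SVM is
#'   cross-validated on the selected columns. This mirrors the published
#'   order of operations but lets the selection see the test folds
#'   (optimistic on null data; see the methods vignette).
#' * `"nested"` — normalization statistics and the LASSO selection are refit
#'   inside every training fold, giving leakage-free estimates.
#'
#' Per-fold metrics are aggregated per repeat; the summary reports the mean
#' and standard deviation of each metric across the repeat means. A final
#' normalize-select-train fit on the full stratum provides the reported
#' feature weights and ranks; nested mode additionally records how often
#' each feature was selected across folds (`selection_freq`).
#'
#' @param table Stratum feature table (metadata columns + features), e.g.
#'   from [stratify()]/[complete_cases()]. Features need not be normalized.
#' @param mode `"paper_faithful"` (default) or `"nested"`.
#' @param outer_folds,repeats CV geometry (defaults 10 and 10).
#' @param seed Master seed; fold shuffles for repeat r use a derived stream.
#' @param C_grid,inner_folds SVM tuning settings (see [train_svm()]).
#' @param lasso_folds Folds of the LASSO's internal CV (default 10).
#' @return Object of class `remit_cv_result`; see [tidy.remit_cv_result()]
#'   and [glance.remit_cv_result()].
#' @export
repeated_cv_evaluate <- function(table, mode = c("paper_faithful", "nested"),
                                 outer_folds = 10, repeats = 10, seed = 1,
                                 C_grid = 10^seq(-3, 3, length.out = 10),
                                 inner_folds = 5, lasso_folds = 10) {
  mode <- match.arg(mode)
  dat <- extract_xy(table)
  X <- dat$X; y <- dat$y
  assert_that(min(table(y)) >= outer_folds,
              "need at least outer_folds subjects per class")

  preselected <- NULL
  if (mode == "paper_faithful") {
    norm <- znormalize(table)
    X <- as.matrix(norm[names(feature_modalities(norm))])
    fit <- fit_lasso_cv(X, y, n_folds = lasso_folds,
                        seed = substream_seed(seed, "global_lasso"))
    preselected <- select_features(fit)
    if (!length(preselected)) {
      warning("empty LASSO selection on full stratum; falling back to all features")
      preselected <- colnames(X)
    }
  }

  fold_metrics <- list()
  sel_counts <- setNames(numeric(ncol(X)), colnames(X))
  n_folds_total <- 0
  for (r in seq_len(repeats)) {
    rep_seed <- substream_seed(seed, paste0("repeat", r))
    foldid <- stratified_folds(y, outer_folds, rep_seed)
    for (f in seq_len(outer_folds)) {
      res <- fit_score_fold(X, y, foldid != f, foldid == f,
                            seed = substream_seed(rep_seed, paste0("fold", f)),
                            preselected = preselected, C_grid = C_grid,
                            inner_folds = inner_folds, lasso_folds = lasso_folds)
      fold_metrics[[length(fold_metrics) + 1]] <-
        dplyr::bind_cols(tibble::tibble(repeat_ = r, fold = f), res$metrics)
      sel_counts[res$selected] <- sel_counts[res$selected] + 1
      n_folds_total <- n_folds_total + 1
    }
  }
  metrics <- dplyr::bind_rows(fold_metrics)

  # reporting fit on the full stratum
  final <- fit_score_fold(as.matrix(table[names(feature_modalities(table))]), y,
                          rep(TRUE, nrow(table)), rep(TRUE, nrow(table)),
                          seed = substream_seed(seed, "final_fit"),
                          C_grid = C_grid, inner_folds = inner_folds,
                          lasso_folds = lasso_folds)
  selected <- rank_features(final$model)
  selected$selection_freq <- unname(sel_counts[selected$feature] / n_folds_total)

  structure(list(metrics = metrics,
                 summary = summarize_cv(metrics),
                 mode = mode, outer_folds = outer_folds, repeats = repeats,
                 selected = selected, n = nrow(table), seed = seed),
            class = "remit_cv_result")
}

summarize_cv <- function(metrics) {
  per_repeat <- dplyr::summarise(
    dplyr::group_by(metrics, .data$repeat_),
    dplyr::across(c("accuracy", "sensitivity", "specificity", "auc"),
                  ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  tidyr::pivot_longer(per_repeat, -"repeat_", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
}

extract_xy <- function(table) {
  feats <- names(feature_modalities(table))
  assert_that(length(feats) > 0, "table has no feature columns")
  assert_that("label" %in% names(table), "table needs a label column")
  X <- as.matrix(table[feats])
  storage.mode(X) <- "double"
  assert_that(all(is.finite(X)),
              "missing/non-finite feature values; run complete_cases() first")
  list(X = X, y = table$label)
}

#' Stratified 70:30 holdout validation
#'
#' Splits the stratum into stratified train/test portions, fits the full
#' pipeline (normalize, LASSO-select, SVM with tuning) on the training rows
#' only, and reports metrics on the held-out rows. Intended as a
#' confirmatory check on larger strata.
#'
#' @inheritParams repeated_cv_evaluate
#' @param train_fraction Training proportion (default 0.70).
#' @return One-row metrics tibble with attribute `selected`.
#' @export
holdout_evaluate <- function(table, train_fraction = 0.70, seed = 1,
                             C_grid = 10^seq(-3, 3, length.out = 10),
                             inner_folds = 5, lasso_folds = 10) {
  dat <- extract_xy(table)
  y <- dat$y
  if (min(table(y)) < 10) {
    stop("fewer than 10 subjects in a class; use repeated_cv_evaluate() instead",
         call. = FALSE)
  }
  train <- logical(length(y))
  with_seed(substream_seed(seed, "holdout"), {
    for (lev in unique(y)) {
      idx <- which(y == lev)
      train[sample(idx, round(train_fraction * length(idx)))] <- TRUE
    }
  })
  res <- fit_score_fold(dat$X, y, train, !train,
                        seed = substream_seed(seed, "holdout_fit"),
                        C_grid = C_grid, inner_folds = inner_folds,
                        lasso_folds = lasso_folds)
  out <- res$metrics
  attr(out, "selected") <- res$selected
  out
}

#' Compare two cross-validated models on accuracy
#'
#' Paired two-sided t test on the per-repeat mean accuracies of two
#' [repeated_cv_evaluate()] results (pairing by repeat index, which is
#' meaningful when both runs used a shared seed/fold schedule). Repeat-level
#' pairing reuses the same subjects across repeats, so the test is
#' anti-conservative; the result carries a caveat flag saying so.
#'
#' @param a,b `remit_cv_result` objects with equal repeat counts.
#' @return Tibble: `p_value`, `direction` (`"a"`, `"b"` or `"none"`),
#'   `mean_diff` (a minus b), `caveat`.
#' @export
compare_models <- function(a, b) {
  assert_that(inherits(a, "remit_cv_result") && inherits(b, "remit_cv_result"),
              "both arguments must be remit_cv_result objects")
  assert_that(a$repeats == b$repeats, "repeat counts differ")
  acc <- function(r) {
    dplyr::summarise(dplyr::group_by(r$metrics, .data$repeat_),
                     acc = mean(.data$accuracy), .groups = "drop")$acc
  }
  xa <- acc(a); xb <- acc(b)
  d <- xa - xb
  if (all(abs(d) < 1e-15)) {
    return(tibble::tibble(p_value = 1, direction = "none", mean_diff = 0,
                          caveat = "repeat-level, anti-conservative"))
  }
  if (sd(d) < 1e-15) {
    # constant nonzero difference: the paired t statistic diverges
    return(tibble::tibble(p_value = 0,
                          direction = if (mean(d) > 0) "a" else "b",
                          mean_diff = mean(d),
                          caveat = "repeat-level, anti-conservative"))
  }
  tt <- t.test(xa, xb, paired = TRUE)
  tibble::tibble(p_value = tt$p.value,
                 direction = if (mean(d) > 0) "a" else if (mean(d) < 0) "b" else "none",
                 mean_diff = mean(d),
                 caveat = "repeat-level, anti-conservative")
}

#' @export
print.remit_cv_result <- function(x, ...) {
  cat(sprintf("<remit_cv_result> %s mode, %d x %d-fold CV, n = %d\n",
              x$mode, x$repeats, x$outer_folds, x$n))
  s <- x$summary
  for (m in c("accuracy", "sensitivity", "specificity", "auc")) {
    row <- s[s$metric == m, ]
    cat(sprintf("  %-12s %.3f +/- %.3f\n", m, row$mean, row$sd))
  }
  cat(sprintf("  %d feature(s) in the final model\n",
              sum(x$selected$weight != 0)))
  invisible(x)
}
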