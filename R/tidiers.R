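#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold metrics of a cross-validation result
#'
#' @param x A `remit_cv_result` from [repeated_cv_evaluate()].
#' @param ... Unused.
#' @return Tibble with one row per repeat x fold: `repeat_`, `fold`,
#'   counts and metrics.
#' @method tidy remit_cv_result
#' @export
tidy.remit_cv_result <- function(x, ...) x$metrics

#' One-row summary of a cross-validation result
#'
#' @param x A `remit_cv_result`.
#' @param ... Unused.
#' @return One-row tibble: mean and SD (across repeats) of accuracy,
#'   sensitivity, specificity and AUC, plus mode and sample size.
#' @method glance remit_cv_result
#' @export
glance.remit_cv_result <- function(x, ...) {
  s <- x$summary
  wide <- setNames(as.list(c(s$mean, s$sd)),
                   c(s$metric, paste0(s$metric, "_sd")))
  dplyr::bind_cols(tibble::as_tibble(wide),
                   tibble::tibble(mode = x$mode, n = x$n,
                                  repeats = x$repeats, folds = x$outer_folds))
}

#' Tidy LASSO coefficients
#'
#' @param x A `lasso_fit`.
#' @param all_terms Include zero coefficients (default FALSE).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`.
#' @method tidy lasso_fit
#' @export
tidy.lasso_fit <- function(x, all_terms = FALSE, ...) {
  out <- tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
  if (!all_terms) out <- out[out$estimate != 0, ]
  out
}

#' @rdname tidy.lasso_fit
#' @param x A `lasso_fit`.
#' @method glance lasso_fit
#' @export
glance.lasso_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_selected = length(x$selected),
                 n_features = length(x$beta), n = x$n,
                 cv_loss = min(x$cvm))
}

#' Tidy SVM weights as a feature ranking
#'
#' @param x A `remit_svm`.
#' @param ... Unused.
#' @return [rank_features()] output: `feature`, `weight`, `rank`.
#' @method tidy remit_svm
#' @export
tidy.remit_svm <- function(x, ...) rank_features(x)

#' Plot per-fold metric distributions of a cross-validation result
#'
#' Boxplots of the per-fold accuracy, sensitivity, specificity and AUC
#' across all repeats.
#'
#' @param object A `remit_cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot remit_cv_result
#' @export
autoplot.remit_cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics,
                              c("accuracy", "sensitivity", "specificity", "auc"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = sprintf("%s mode, %d x %d-fold CV",
                                  object$mode, object$repeats, object$outer_folds)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Heatmaps of band coherence matrices
#'
#' @param object A `band_coherence` result from
#'   [estimate_band_coherence()].
#' @param ... Unused.
#' @return A ggplot object, one facet per band.
#' @method autoplot band_coherence
#' @export
autoplot.band_coherence <- function(object, ...) {
  long <- purrr::imap_dfr(unclass(object), function(m, band) {
    df <- as.data.frame(as.table(m))
    names(df) <- c("roi_a", "roi_b", "msc")
    df$band <- band
    df
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$roi_a, y = .data$roi_b,
                                     fill = .data$msc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~band) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "MSC") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Scatter plot of the first two ancestry principal components
#'
#' @param object An `ancestry_pca` result.
#' @param labels Optional tibble `subject_id`, `ancestry` used to colour
#'   points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ancestry_pca
#' @export
autoplot.ancestry_pca <- function(object, labels = NULL, ...) {
  df <- object$scores
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, tibble::as_tibble(labels), by = "subject_id")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$ancestry), size = 1)
  } else {
    p + ggplot2::geom_point(size = 1)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])) +
    ggplot2::theme_minimal()
}
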