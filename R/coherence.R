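#' ROI time-series container
#'
#' Bundles per-subject region-of-interest (ROI) signal matrices with their
#' common sampling rate and ROI names. All subjects must share the same ROI
#' order and sampling rate.
#'
#' @param signals Named list of numeric matrices, one per subject, each
#'   `n_rois x n_samples`.
#' @param fs Sampling rate in Hz.
#' @param roi_names Character vector of ROI names, length `n_rois`.
#' @return An object of class `roi_ts_set`.
#' @export
roi_ts_set <- function(signals, fs, roi_names) {
  assert_that(is.list(signals) && length(signals) > 0, "signals must be a non-empty list")
  assert_that(!is.null(names(signals)) && !anyDuplicated(names(signals)),
              "signals must be named by unique subject ids")
  n_rois <- length(roi_names)
  ok <- vapply(signals, function(m) is.matrix(m) && nrow(m) == n_rois, logical(1))
  assert_that(all(ok), "every signal matrix must have n_rois rows")
  structure(list(signals = signals, fs = as.numeric(fs),
                 roi_names = as.character(roi_names)),
            class = "roi_ts_set")
}

#' @export
print.roi_ts_set <- function(x, ...) {
  ns <- ncol(x$signals[[1]])
  cat(sprintf("<roi_ts_set> %d subjects, %d ROIs, %d samples @ %g Hz (%.1f s)\n",
              length(x$signals), length(x$roi_names), ns, x$fs, ns / x$fs))
  invisible(x)
}

# Welch-averaged one-sided auto- and cross-spectra of a multichannel signal.
# Returns list(freq, S) where S is an nbins x (R*R) matrix holding
# S[f, (j-1)*R + i] = mean over segments of Z_i(f) * Conj(Z_j(f)).
welch_cross_spectra <- function(x, fs, segment_length = 2, overlap = 0.5,
                                window = c("hann", "rect")) {
  window <- match.arg(window)
  R <- nrow(x); N <- ncol(x)
  L <- round(segment_length * fs)
  assert_that(L >= 8, "segment_length too short: fewer than 8 samples per segment")
  if (N < L) {
    stop(sprintf(
      "signal too short for one spectral segment: need >= %.3f s (%d samples), have %.3f s",
      L / fs, L, N / fs), call. = FALSE)
  }
  if (anyNA(x)) stop("NaN/NA samples in signal matrix", call. = FALSE)
  v <- apply(x, 1, var)
  if (any(v == 0)) {
    stop(sprintf("constant (zero-variance) channel: %s",
                 paste(rownames(x)[v == 0] %||% which(v == 0), collapse = ", ")),
         call. = FALSE)
  }
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, N - L + 1L, by = step)
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L)) else rep(1, L)
  nb <- L %/% 2 + 1L
  ii <- rep(seq_len(R), times = R)
  jj <- rep(seq_len(R), each = R)
  S <- matrix(0 + 0i, nb, R * R)
  for (s0 in starts) {
    seg <- x[, s0:(s0 + L - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)              # detrend (constant) per segment
    Z <- mvfft(t(seg * rep(w, each = R)))[seq_len(nb), , drop = FALSE]
    if (R == 1L) Z <- matrix(Z, ncol = 1L)
    S <- S + Z[, ii, drop = FALSE] * Conj(Z[, jj, drop = FALSE])
  }
  S <- S / length(starts)
  list(freq = (0:(nb - 1L)) * fs / L, S = S, n_segments = length(starts))
}

#' Band-averaged magnitude-squared coherence of one subject
#'
#' Estimates the magnitude-squared coherence (MSC)
#' \deqn{C_{ij}(f) = |S_{ij}(f)|^2 / (S_{ii}(f) S_{jj}(f))}
#' between every pair of ROI signals from Welch-averaged (cross-)spectra,
#' then averages the per-bin MSC over the frequency bins falling in each
#' band's half-open interval `[low, high)`. MSC lies in \[0, 1\]; the
#' diagonal is exactly 1 and the matrix is symmetric by construction.
#'
#' Note the estimator's small-sample bias: for independent signals the
#' expected MSC is approximately `1 / K` for `K` (effectively independent)
#' Welch segments, not 0. Longer recordings reduce the bias.
#'
#' @param x Numeric matrix, `n_rois x n_samples`, one subject's ROI signals.
#'   Row names, if present, name the ROIs.
#' @param fs Sampling rate (Hz).
#' @param bands Band definition tibble, see [band_definitions()].
#' @param segment_length Welch segment length in seconds (default 2).
#' @param overlap Fractional segment overlap in \[0, 1) (default 0.5).
#' @param window Taper applied per segment: `"hann"` (default) or `"rect"`.
#' @return A named list of symmetric `n_rois x n_rois` MSC matrices, one per
#'   band, with unit diagonal; class `band_coherence`.
#' @examples
#' x <- matrix(rnorm(2 * 2048), 2)
#' estimate_band_coherence(x, fs = 128, bands = default_bands()[1:2, ])
#' @export
estimate_band_coherence <- function(x, fs, bands = default_bands(),
                                    segment_length = 2, overlap = 0.5,
                                    window = "hann") {
  assert_that(is.matrix(x) && nrow(x) >= 1, "x must be a matrix of ROI signals")
  ws <- welch_cross_spectra(x, fs, segment_length, overlap, window)
  R <- nrow(x)
  diag_idx <- (seq_len(R) - 1L) * R + seq_len(R)
  P <- Re(ws$S[, diag_idx, drop = FALSE])          # auto-spectra, nbins x R
  ii <- rep(seq_len(R), times = R)
  jj <- rep(seq_len(R), each = R)
  num <- Mod(ws$S)^2                                # nbins x R^2
  den <- P[, ii, drop = FALSE] * P[, jj, drop = FALSE]
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  rn <- rownames(x) %||% paste0("roi", seq_len(R))
  for (b in seq_len(nrow(bands))) {
    sel <- ws$freq >= bands$low[b] & ws$freq < bands$high[b]
    if (!any(sel)) {
      stop(sprintf("no frequency bins fall in band %s [%g, %g); use longer segments",
                   bands$name[b], bands$low[b], bands$high[b]), call. = FALSE)
    }
    nb <- num[sel, , drop = FALSE]
    db <- den[sel, , drop = FALSE]
    msc_bins <- ifelse(db > 0, nb / db, 0)          # no shared power -> 0
    m <- matrix(colMeans(msc_bins), R, R, dimnames = list(rn, rn))
    m <- pmin(pmax(m, 0), 1)
    m <- (m + t(m)) / 2                             # exact symmetry
    diag(m) <- 1
    out[[b]] <- m
  }
  structure(out, class = "band_coherence", fs = fs, bands = bands,
            n_segments = ws$n_segments)
}

# Canonical feature names: "ROIa-ROIb@band" with a < b in ROI order.
coherence_feature_names <- function(roi_names, bands) {
  R <- length(roi_names)
  pairs <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  unlist(lapply(bands$name, function(b) {
    paste0(roi_names[pairs[, 1]], "-", roi_names[pairs[, 2]], "@", b)
  }), use.names = FALSE)
}

#' Coherence feature extraction for a cohort
#'
#' Computes band-averaged MSC for every subject in a [roi_ts_set()] and
#' flattens the upper triangle of each band's ROI-pair matrix into a named
#' feature vector. Features are ordered band-major, then by ROI pair
#' (lexicographic in ROI order), and named `"ROIa-ROIb@band"`. With 68 ROIs
#' and 4 bands this yields `4 * choose(68, 2) = 9112` features per subject.
#'
#' @param set A [roi_ts_set()].
#' @param bands Band definitions (default [default_bands()]).
#' @param segment_length,overlap,window Welch settings, see
#'   [estimate_band_coherence()].
#' @return A tibble with `subject_id` and one column per coherence feature
#'   (columns prefixed `eeg_`, marking the modality).
#' @export
coherence_features <- function(set, bands = default_bands(),
                               segment_length = 2, overlap = 0.5,
                               window = "hann") {
  assert_that(inherits(set, "roi_ts_set"), "set must be a roi_ts_set")
  feat_names <- paste0("eeg_", coherence_feature_names(set$roi_names, bands))
  R <- length(set$roi_names)
  ut <- upper.tri(matrix(0, R, R))
  rows <- purrr::map(set$signals, function(x) {
    rownames(x) <- set$roi_names
    bc <- estimate_band_coherence(x, set$fs, bands, segment_length, overlap, window)
    # upper.tri extracts column-major == (row < col) pairs ordered by column;
    # reorder to row-major lexicographic (a < b, a fastest-varying last)
    unlist(lapply(bc, function(m) t(m)[t(ut)]), use.names = FALSE)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- feat_names
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(subject_id = names(set$signals)), out)
  attr(out, "bands") <- bands
  attr(out, "roi_names") <- set$roi_names
  out
}
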