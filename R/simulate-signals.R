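# Band-limited Gaussian noise whose in-band power spectral density equals
# that of unit-variance white noise (total variance = bandwidth fraction).
# Built in the frequency domain: FFT of white noise with out-of-band bins
# zeroed, so the in-band PSD is untouched.
band_limited_noise <- function(n, fs, low, high) {
  z <- rnorm(n)
  Z <- fft(z)
  freq <- (0:(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)               # two-sided -> folded frequency
  keep <- freq >= low & freq < high
  Z[!keep] <- 0
  Re(fft(Z, inverse = TRUE)) / n
}

#' Simulate ROI time series with planted band-limited coherence
#'
#' Generates per-subject multichannel Gaussian signals in which selected ROI
#' pairs carry a target band-averaged magnitude-squared coherence (MSC) that
#' depends on the subject's outcome label, emulating resting-state
#' functional-connectivity differences between continued-AUD and
#' remitted-AUD groups.
#'
#' For a pair with target MSC \eqn{m} in band \eqn{b}, the two channels are
#' \deqn{x = \alpha s + \sqrt{1-\alpha^2}\, e_1, \quad
#'       y = \alpha s + \sqrt{1-\alpha^2}\, e_2}
#' with \eqn{s} band-limited noise in \eqn{b} and \eqn{e_1, e_2, s}
#' independent. \eqn{s} is scaled so its in-band PSD equals that of the white
#' noise \eqn{e_k}; the in-band cross-spectrum is then
#' \eqn{S_{xy} = \alpha^2 S_s} and each auto-spectrum
#' \eqn{S_{xx} = \alpha^2 S_s + (1-\alpha^2) S_e = S_e}, so the theoretical
#' band MSC is \eqn{\alpha^4 S_s^2 / S_e^2 = \alpha^4}. Hence
#' \eqn{\alpha = m^{1/4}}. At \eqn{m = 1} the two channels are identical in
#' the band. Pairs without a planted effect receive independent white noise.
#'
#' @param subjects Tibble with columns `subject_id` and `label`
#'   (`"continued"` / `"remitted"`).
#' @param coherence_effects Tibble with columns `roi_i`, `roi_j` (1-based ROI
#'   indices), `band` (name in `bands`), `msc_continued`, `msc_remitted`
#'   (target band MSC per group, each in \[0, 1\]); or `NULL` for no effects.
#'   Each ROI may participate in at most one effect.
#' @param n_rois Number of ROIs (default 68).
#' @param fs Sampling rate in Hz (default 256).
#' @param duration Recording length in seconds (default 240, i.e. 4 min of
#'   resting EEG).
#' @param seed Integer seed; the signal stream is fully reproducible from it.
#' @param bands Band definitions used to resolve effect band names.
#' @param roi_names Optional ROI names (defaults to [dk_roi_names()] when
#'   `n_rois == 68`, else `roi1..roiR`).
#' @return A [roi_ts_set()].
#' @export
simulate_roi_signals <- function(subjects, coherence_effects = NULL,
                                 n_rois = 68, fs = 256, duration = 240,
                                 seed = 1, bands = default_bands(),
                                 roi_names = NULL) {
  assert_that(n_rois >= 2, "n_rois must be >= 2")
  assert_that(all(c("subject_id", "label") %in% names(subjects)),
              "subjects must have subject_id and label columns")
  n <- round(duration * fs)
  roi_names <- roi_names %||%
    (if (n_rois == 68) dk_roi_names() else paste0("roi", seq_len(n_rois)))
  eff <- validate_coherence_effects(coherence_effects, n_rois, bands)

  sigs <- with_seed(substream_seed(seed, "roi_signals"), {
    lapply(seq_len(nrow(subjects)), function(k) {
      x <- matrix(rnorm(n_rois * n), n_rois, n)
      if (nrow(eff)) {
        for (e in seq_len(nrow(eff))) {
          m <- if (subjects$label[k] == "remitted") eff$msc_remitted[e] else eff$msc_continued[e]
          alpha <- m^(1 / 4)
          s <- band_limited_noise(n, fs, eff$low[e], eff$high[e])
          beta <- sqrt(1 - alpha^2)
          x[eff$roi_i[e], ] <- alpha * s + beta * x[eff$roi_i[e], ]
          x[eff$roi_j[e], ] <- alpha * s + beta * x[eff$roi_j[e], ]
        }
      }
      rownames(x) <- roi_names
      x
    })
  })
  names(sigs) <- subjects$subject_id
  roi_ts_set(sigs, fs, roi_names)
}

validate_coherence_effects <- function(effects, n_rois, bands) {
  if (is.null(effects) || nrow(as.data.frame(effects)) == 0) {
    return(tibble::tibble(roi_i = integer(), roi_j = integer(), band = character(),
                          msc_continued = numeric(), msc_remitted = numeric(),
                          low = numeric(), high = numeric()))
  }
  effects <- tibble::as_tibble(effects)
  need <- c("roi_i", "roi_j", "band", "msc_continued", "msc_remitted")
  assert_that(all(need %in% names(effects)),
              paste("coherence_effects needs columns:", paste(need, collapse = ", ")))
  bad <- effects$msc_continued < 0 | effects$msc_continued > 1 |
    effects$msc_remitted < 0 | effects$msc_remitted > 1
  if (any(bad)) {
    stop(sprintf("coherence targets outside [0,1] for pair(s): %s",
                 paste(sprintf("(%d,%d)@%s", effects$roi_i[bad], effects$roi_j[bad],
                               effects$band[bad]), collapse = ", ")), call. = FALSE)
  }
  assert_that(all(effects$roi_i != effects$roi_j), "effect pairs must have roi_i != roi_j")
  assert_that(all(c(effects$roi_i, effects$roi_j) >= 1) &&
                all(c(effects$roi_i, effects$roi_j) <= n_rois),
              "effect ROI indices out of range")
  rois_used <- c(effects$roi_i, effects$roi_j)
  assert_that(!anyDuplicated(rois_used),
              "each ROI may appear in at most one coherence effect")
  assert_that(all(effects$band %in% bands$name), "unknown band name in coherence_effects")
  b <- match(effects$band, bands$name)
  effects$low <- bands$low[b]
  effects$high <- bands$high[b]
  effects
}
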