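#' Frequency band definitions
#'
#' Bands are half-open intervals `[low, high)` in Hz so that adjacent bands
#' share no frequency bin. The defaults are the four classical resting-state
#' bands used for coherence feature extraction: theta (4–8 Hz), alpha
#' (8–12 Hz), beta (12–30 Hz) and gamma (30–60 Hz).
#'
#' @param name Character vector of band names.
#' @param low,high Numeric vectors of band edges in Hz; `low` inclusive,
#'   `high` exclusive. All edges must satisfy `0 < low < high` and bands must
#'   be pairwise disjoint.
#' @return A tibble with columns `name`, `low`, `high`.
#' @examples
#' default_bands()
#' band_definitions("slow", 1, 4)
#' @export
band_definitions <- function(name, low, high) {
  assert_that(length(name) == length(low) && length(low) == length(high),
              "name, low and high must have equal length")
  assert_that(all(low > 0) && all(high > low),
              "band edges must satisfy 0 < low < high")
  assert_that(!anyDuplicated(name), "band names must be unique")
  bands <- tibble::tibble(name = as.character(name),
                          low = as.numeric(low), high = as.numeric(high))
  # pairwise disjoint: sort by low edge and require high_i <= low_{i+1}
  srt <- bands[order(bands$low), ]
  if (nrow(srt) > 1 && any(srt$high[-nrow(srt)] > srt$low[-1] + 1e-12)) {
    stop("bands overlap; intervals [low, high) must be pairwise disjoint",
         call. = FALSE)
  }
  bands
}

#' @rdname band_definitions
#' @export
default_bands <- function() {
  band_definitions(c("theta", "alpha", "beta", "gamma"),
                   c(4, 8, 12, 30), c(8, 12, 30, 60))
}

#' Desikan–Killiany cortical region names
#'
#' The 68 cortical regions of interest (34 per hemisphere, prefixed `lh_` /
#' `rh_`) of the Desikan–Killiany parcellation, in a fixed canonical order.
#' Synthetic cohorts use these names so that feature names match runs on real
#' source-localised data.
#'
#' @return Character vector of length 68.
#' @examples
#' head(dk_roi_names())
#' @export
dk_roi_names <- function() {
  path <- system.file("extdata", "desikan_killiany_rois.txt",
                      package = "remitpredict")
  assert_that(nzchar(path), "Desikan-Killiany region list not found")
  readLines(path)
}
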