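#' Ground-truth configuration for a synthetic cohort
#'
#' Records every knob the generator uses — group size, planted coherence
#' effects, causal SNPs, covariate effects and the master seed — so that the
#' ground truth travels with the generated data and any downstream estimate
#' can be checked against it.
#'
#' @param n_per_group Subjects per outcome group (balanced design, mirroring
#'   a case-control cohort of equal continued/remitted groups).
#' @param coherence_effects Tibble (`roi_i`, `roi_j`, `band`,
#'   `msc_continued`, `msc_remitted`) or `NULL`; see
#'   [simulate_roi_signals()].
#' @param causal_snps Tibble (`snp`, `log_odds`) or `NULL`; see
#'   [simulate_genetics()].
#' @param covariate_effects Named vector of log-odds of remission per
#'   covariate, or `NULL`; see [simulate_demographics()].
#' @param baseline_log_odds Baseline log-odds of remission (0 keeps the
#'   design exactly balanced).
#' @param seed Master seed; all modality streams are derived from it.
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(n_per_group, coherence_effects = NULL,
                         causal_snps = NULL, covariate_effects = NULL,
                         baseline_log_odds = 0, seed = 1) {
  assert_that(n_per_group >= 2, "n_per_group must be >= 2")
  if (!is.null(coherence_effects)) {
    coherence_effects <- tibble::as_tibble(coherence_effects)
    bad <- coherence_effects$msc_continued < 0 | coherence_effects$msc_continued > 1 |
      coherence_effects$msc_remitted < 0 | coherence_effects$msc_remitted > 1
    if (any(bad)) {
      stop(sprintf("coherence targets outside [0,1] for pair(s): %s",
                   paste(sprintf("(%d,%d)@%s", coherence_effects$roi_i[bad],
                                 coherence_effects$roi_j[bad],
                                 coherence_effects$band[bad]), collapse = ", ")),
           call. = FALSE)
    }
    assert_that(all(coherence_effects$roi_i != coherence_effects$roi_j),
                "coherence effects need roi_i != roi_j")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 coherence_effects = coherence_effects,
                 causal_snps = if (is.null(causal_snps)) NULL else tibble::as_tibble(causal_snps),
                 covariate_effects = covariate_effects,
                 baseline_log_odds = baseline_log_odds,
                 seed = as.integer(seed)),
            class = "cohort_truth")
}

#' Generate a complete synthetic multimodal cohort
#'
#' Label-first generation: the balanced outcome labels are fixed first and
#' every modality (ROI signals, genotypes + discovery summary statistics +
#' LD reference panel, demographics/medications) is generated conditional on
#' them, with effect sizes taken from the [cohort_truth()]. The truth object
#' is embedded in the result, and the whole cohort is reproducible from its
#' seed.
#'
#' @param truth A [cohort_truth()].
#' @param n_rois,fs,duration Signal dimensions; defaults 68 ROIs, 256 Hz,
#'   240 s (4-minute resting recording).
#' @param n_snps,n_blocks,block_r2,n_ref Genetics dimensions; see
#'   [simulate_genetics()].
#' @param bands Band definitions for the coherence effects.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `subjects` (tibble of subject records), `signals` ([roi_ts_set()]),
#'   `genotypes`, `summary_stats`, `reference` and `truth`.
#' @examples
#' tr <- cohort_truth(n_per_group = 3, seed = 7)
#' co <- generate_cohort(tr, n_rois = 4, duration = 8, n_snps = 20,
#'                       n_blocks = 4, n_ref = 40)
#' co$subjects
#' @export
generate_cohort <- function(truth, n_rois = 68, fs = 256, duration = 240,
                            n_snps = 200, n_blocks = 20, block_r2 = 0.5,
                            n_ref = 200, bands = default_bands()) {
  assert_that(inherits(truth, "cohort_truth"), "truth must be a cohort_truth")
  n <- 2L * truth$n_per_group
  ids <- sprintf("S%04d", seq_len(n))
  labels <- with_seed(substream_seed(truth$seed, "labels"), {
    sample(rep(c("continued", "remitted"), truth$n_per_group))
  })
  subjects <- tibble::tibble(subject_id = ids, label = labels)

  demo <- simulate_demographics(subjects, truth$covariate_effects,
                                seed = truth$seed)
  signals <- simulate_roi_signals(subjects, truth$coherence_effects,
                                  n_rois = n_rois, fs = fs, duration = duration,
                                  seed = truth$seed, bands = bands)
  gen <- simulate_genetics(subjects, truth$causal_snps, n_snps = n_snps,
                           n_blocks = n_blocks, block_r2 = block_r2,
                           seed = truth$seed, n_ref = n_ref)
  if (!is.null(truth$causal_snps)) {
    assert_that(all(truth$causal_snps$snp %in% gen$summary_stats$snp),
                "every causal SNP must appear in the summary statistics")
  }
  structure(list(subjects = demo, signals = signals,
                 genotypes = gen$genotypes, summary_stats = gen$summary_stats,
                 reference = gen$reference, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d per group), %d ROIs, %d SNPs, seed %d\n",
              nrow(x$subjects), x$truth$n_per_group,
              length(x$signals$roi_names), ncol(x$genotypes$dosage),
              x$truth$seed))
  invisible(x)
}
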