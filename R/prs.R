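#' Linkage-disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of allele dosages over subjects with complete
#' data for the pair, estimated in a reference panel. Monomorphic (zero
#' variance) SNPs cannot clump others; their r-squared is defined as 0 with
#' a warning.
#'
#' @param reference A [genotype_matrix()] reference panel.
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(reference, snp_a, snp_b) {
  assert_that(inherits(reference, "genotype_matrix"), "reference must be a genotype_matrix")
  assert_that(all(c(snp_a, snp_b) %in% colnames(reference$dosage)),
              "both SNPs must be present in the reference panel")
  if (snp_a == snp_b) return(1)
  a <- reference$dosage[, snp_a]
  b <- reference$dosage[, snp_b]
  ok <- stats::complete.cases(a, b)
  assert_that(sum(ok) >= 2, "need >= 2 subjects with complete data for the pair")
  if (var(a[ok]) == 0 || var(b[ok]) == 0) {
    warning(sprintf("monomorphic SNP in pair (%s, %s); r2 set to 0", snp_a, snp_b))
    return(0)
  }
  cor(a[ok], b[ok])^2
}

#' Greedy LD clumping of summary statistics
#'
#' Standard clumping-and-thresholding pruning: repeatedly take the
#' still-unclumped SNP with the smallest discovery p-value as an index SNP,
#' retain it, and remove every other unclumped SNP on the same chromosome
#' within `window_kb` whose r-squared with the index (in the reference
#' panel) is at or above `r2_threshold`. Ties on p are broken by
#' (chromosome, position), then SNP id, so the output is deterministic.
#' SNPs absent from the reference panel cannot be clumped (r-squared is not
#' computable) and are retained with a warning.
#'
#' @param stats Summary-statistics tibble with columns `snp`, `chr`, `pos`,
#'   `a1`, `a2`, `beta`, `p`.
#' @param reference A [genotype_matrix()] reference panel.
#' @param r2_threshold Removal threshold on r-squared (boundary inclusive;
#'   default 0.25).
#' @param window_kb Window half-width in kb around the index SNP
#'   (default 500).
#' @return Character vector of retained SNP ids.
#' @export
clump <- function(stats, reference, r2_threshold = 0.25, window_kb = 500) {
  stats <- tibble::as_tibble(stats)
  if (nrow(stats) == 0) return(character())
  assert_that(all(c("snp", "chr", "pos", "p") %in% names(stats)),
              "stats needs columns snp, chr, pos, p")
  in_ref <- stats$snp %in% colnames(reference$dosage)
  if (any(!in_ref)) {
    warning(sprintf("%d SNP(s) absent from reference panel retained unclumped: %s",
                    sum(!in_ref), paste(head(stats$snp[!in_ref], 5), collapse = ", ")))
  }
  ord <- order(stats$p, stats$chr, stats$pos, stats$snp)
  st <- stats[ord, ]
  state <- rep("free", nrow(st)) # free -> index (retained) or clumped (removed)
  window_bp <- window_kb * 1000
  ref_dos <- reference$dosage
  for (i in seq_len(nrow(st))) {
    if (state[i] != "free") next
    state[i] <- "index"
    if (!st$snp[i] %in% colnames(ref_dos)) next
    cand <- which(state == "free" & st$chr == st$chr[i] &
                    abs(st$pos - st$pos[i]) <= window_bp)
    cand <- cand[st$snp[cand] %in% colnames(ref_dos)]
    if (!length(cand)) next
    a <- ref_dos[, st$snp[i]]
    if (var(a, na.rm = TRUE) == 0) next # monomorphic index clumps nothing
    for (j in cand) {
      b <- ref_dos[, st$snp[j]]
      ok <- stats::complete.cases(a, b)
      if (sum(ok) < 2 || var(b[ok]) == 0 || var(a[ok]) == 0) next
      if (cor(a[ok], b[ok])^2 >= r2_threshold) state[j] <- "clumped"
    }
  }
  retained <- st$snp[state == "index"]
  stats$snp[stats$snp %in% retained] # original order
}

#' Polygenic risk scores by p-value thresholding
#'
#' For each threshold `t`, a subject's raw score is the weighted sum of
#' allele dosages over retained SNPs with discovery `p < t` (strict), with
#' per-SNP weight `sign(beta) * (-log10 p)`. Missing dosages are mean-imputed
#' per SNP before scoring so score scales stay comparable across subjects.
#'
#' @param genotypes A [genotype_matrix()] of target-sample dosages.
#' @param stats Summary-statistics tibble (`snp`, `beta`, `p`, ...).
#' @param retained SNP ids to score (typically [clump()] output); must be a
#'   subset of `stats$snp`.
#' @param thresholds Numeric vector of p-value cutoffs; default the nine
#'   standard cutoffs 1e-4 ... 0.5.
#' @param phenotype Label used to name score columns (`"<phenotype>@<t>"`).
#' @return Tibble: `subject_id` plus one raw-score column per threshold
#'   (columns prefixed `prs_`).
#' @export
prs_scores <- function(genotypes, stats, retained,
                       thresholds = prs_thresholds(), phenotype = "pheno") {
  assert_that(length(thresholds) > 0, "threshold set must be non-empty")
  stats <- tibble::as_tibble(stats)
  assert_that(all(retained %in% stats$snp), "retained must be a subset of stats SNP ids")
  st <- stats[match(retained, stats$snp), ]
  dos <- genotypes$dosage[, retained, drop = FALSE]
  # per-SNP mean imputation
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- mu[idx[, 2]]
  }
  w <- sign(st$beta) * (-log10(st$p))
  score_mat <- vapply(thresholds, function(t) {
    use <- st$p < t
    as.numeric(dos[, use, drop = FALSE] %*% w[use])
  }, numeric(nrow(dos)))
  if (!is.matrix(score_mat)) score_mat <- matrix(score_mat, nrow = nrow(dos))
  colnames(score_mat) <- paste0("prs_", phenotype, "@",
                                vapply(thresholds, format, character(1),
                                       trim = TRUE, scientific = FALSE))
  dplyr::bind_cols(tibble::tibble(subject_id = rownames(genotypes$dosage)),
                   tibble::as_tibble(score_mat))
}

#' Standard p-value thresholds for PRS construction
#' @return The nine cutoffs 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5.
#' @export
prs_thresholds <- function() c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Convert raw PRS columns to Z-scores
#'
#' Centers and scales every score column to mean 0, unit sample standard
#' deviation (denominator n-1). Constant columns are set to 0 with a
#' warning.
#'
#' @param prs Tibble from [prs_scores()] (`subject_id` + score columns).
#' @return Tibble of the same shape, standardized.
#' @export
standardize_prs <- function(prs) {
  assert_that(nrow(prs) >= 2, "standardization needs >= 2 subjects")
  cols <- setdiff(names(prs), "subject_id")
  for (cl in cols) {
    v <- prs[[cl]]
    s <- sd(v)
    if (s == 0) {
      warning(sprintf("constant PRS column %s set to 0", cl))
      prs[[cl]] <- rep(0, length(v))
    } else {
      prs[[cl]] <- (v - mean(v)) / s
    }
  }
  prs
}

#' Clump-and-threshold PRS for one or more phenotypes
#'
#' Convenience wrapper chaining [clump()], [prs_scores()] and
#' [standardize_prs()] for a list of discovery summary-statistics tables
#' sharing one target genotype matrix and reference panel.
#'
#' @param genotypes,reference [genotype_matrix()] objects.
#' @param stats_list Named list of summary-statistics tibbles (one per
#'   discovery phenotype); a single tibble is treated as one phenotype named
#'   `"pheno"`.
#' @param r2_threshold,window_kb Clumping parameters (defaults 0.25 / 500).
#' @param thresholds p-value cutoffs (default [prs_thresholds()]).
#' @param standardize Z-score the columns (default TRUE).
#' @return Tibble: `subject_id` + `prs_<phenotype>@<threshold>` columns.
#' @export
compute_prs <- function(genotypes, stats_list, reference,
                        r2_threshold = 0.25, window_kb = 500,
                        thresholds = prs_thresholds(), standardize = TRUE) {
  if (is.data.frame(stats_list)) stats_list <- list(pheno = stats_list)
  assert_that(!is.null(names(stats_list)) && all(nzchar(names(stats_list))),
              "stats_list must be a named list")
  blocks <- purrr::imap(stats_list, function(st, nm) {
    kept <- clump(st, reference, r2_threshold, window_kb)
    prs_scores(genotypes, st, kept, thresholds, phenotype = nm)
  })
  out <- purrr::reduce(blocks, dplyr::inner_join, by = "subject_id")
  if (standardize) out <- standardize_prs(out)
  out
}
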