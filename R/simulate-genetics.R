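#' Genotype dosage container
#'
#' @param dosage Numeric matrix, subjects x SNPs, allele-1 dosages in
#'   \[0, 2\] (NA allowed). Row names are subject ids, column names SNP ids.
#' @param snps Tibble of SNP metadata: `snp`, `chr`, `pos`, `a1`, `a2`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps) {
  snps <- tibble::as_tibble(snps)
  assert_that(is.matrix(dosage), "dosage must be a matrix")
  assert_that(all(c("snp", "chr", "pos", "a1", "a2") %in% names(snps)),
              "snps needs columns snp, chr, pos, a1, a2")
  assert_that(!anyDuplicated(snps$snp), "SNP ids must be unique")
  assert_that(ncol(dosage) == nrow(snps), "dosage columns must match snps rows")
  rng <- range(dosage, na.rm = TRUE)
  assert_that(rng[1] >= 0 && rng[2] <= 2, "dosages must lie in [0, 2]")
  colnames(dosage) <- snps$snp
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d subjects x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

# Bivariate standard-normal CDF P(Z1 < a, Z2 < b) with correlation rho,
# by 1-D quadrature of the conditional probit.
pbinorm <- function(a, b, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    return(if (rho > 0) pnorm(min(a, b)) else max(0, pnorm(a) - pnorm(-b)))
  }
  integrate(function(z) dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2)),
            -Inf, a, rel.tol = 1e-10)$value
}

# Latent-Gaussian correlation needed so two thresholded-Gaussian alleles with
# common frequency f have allele (hence dosage) correlation r.
latent_rho_for_allele_corr <- function(r, f) {
  if (r <= 0) return(0)
  if (r >= 1) return(1)
  t <- qnorm(f)
  g <- function(rho) (pbinorm(t, t, rho) - f^2) / (f * (1 - f)) - r
  uniroot(g, c(0, 1 - 1e-7), tol = 1e-9)$root
}

# Haplotype alleles for one LD block: equicorrelated latent Gaussians (shared
# factor) thresholded at qnorm(f). n haplotypes x m SNPs, 0/1.
draw_block_haplotypes <- function(n, m, f, rho) {
  if (rho >= 1) {
    z <- matrix(rnorm(n), n, m)
  } else {
    u <- rnorm(n)
    z <- sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
  }
  (z < qnorm(f)) + 0
}

#' Simulate LD-blocked genotypes, discovery summary statistics and a
#' reference panel
#'
#' Genotypes are allele dosages in \{0, 1, 2\} built from two thresholded
#' latent-Gaussian haplotypes per subject. Non-causal SNPs are arranged in
#' LD blocks: within a block all SNPs share one allele frequency (drawn from
#' `maf_range`) and an equicorrelated latent structure calibrated (via the
#' thresholded-Gaussian allele correlation) so the pairwise dosage r-squared
#' matches `block_r2`; across blocks SNPs are independent. Block positions
#' are laid out so each block spans well under 500 kb while distinct blocks
#' are further apart than a clumping window.
#'
#' Causal SNPs are appended as independent SNPs whose dosage distribution is
#' drawn conditionally on the outcome label via a logistic model with the
#' stated per-dosage log-odds of remission (intercept solved so the marginal
#' remission probability is 1/2, matching the balanced design). The summary
#' statistics table gives causal SNPs small p-values with the stated effect
#' sign; null SNPs get uniform p-values and small zero-centred betas.
#'
#' @param subjects Tibble with `subject_id` and `label` columns.
#' @param causal_snps Tibble with columns `snp` and `log_odds` (per-dosage
#'   log-odds of remission), or `NULL`.
#' @param n_snps Total SNP count (null + causal).
#' @param n_blocks Number of LD blocks for the null SNPs.
#' @param block_r2 Target within-block pairwise dosage r-squared in \[0, 1\].
#' @param seed Integer seed.
#' @param n_ref Reference-panel size (haplotype-independent draws from the
#'   same LD process; no label effects).
#' @param maf_range Allele-frequency range for the uniform draw.
#' @param allele_freqs Optional explicit per-SNP allele frequencies for the
#'   null SNPs (length `n_snps - nrow(causal_snps)`). Supplying distinct
#'   frequencies within a block together with `block_r2 = 1` is rejected:
#'   perfect dosage correlation is unattainable across different
#'   frequencies.
#' @return List with elements `genotypes`, `summary_stats`, `reference`.
#' @export
simulate_genetics <- function(subjects, causal_snps = NULL, n_snps = 200,
                              n_blocks = 20, block_r2 = 0.5, seed = 1,
                              n_ref = 200, maf_range = c(0.1, 0.5),
                              allele_freqs = NULL) {
  assert_that(block_r2 >= 0 && block_r2 <= 1, "block_r2 must lie in [0, 1]")
  n_causal <- if (is.null(causal_snps)) 0L else nrow(causal_snps)
  if (n_causal) {
    causal_snps <- tibble::as_tibble(causal_snps)
    assert_that(all(c("snp", "log_odds") %in% names(causal_snps)),
                "causal_snps needs columns snp, log_odds")
  }
  n_null <- n_snps - n_causal
  assert_that(n_null >= 0, "n_snps must be at least the number of causal SNPs")
  n_sub <- nrow(subjects)
  block_of <- if (n_null) sort(rep_len(seq_len(n_blocks), n_null)) else integer()

  with_seed(substream_seed(seed, "genetics"), {
    # per-block shared allele frequency (one draw per block keeps the target
    # r2 exactly attainable after thresholding)
    f_block <- runif(n_blocks, maf_range[1], maf_range[2])
    f_null <- f_block[block_of]
    if (!is.null(allele_freqs)) {
      assert_that(length(allele_freqs) == n_null,
                  "allele_freqs must have one entry per null SNP")
      f_null <- allele_freqs
      if (block_r2 == 1) {
        distinct <- tapply(f_null, block_of, function(v) length(unique(v)) > 1)
        if (any(distinct)) {
          stop("block_r2 = 1 with distinct allele frequencies within a block is unattainable",
               call. = FALSE)
        }
      }
    }
    r_allele <- sqrt(block_r2)
    rho_block <- vapply(f_block, function(f)
      latent_rho_for_allele_corr(r_allele, f), numeric(1))

    draw_null <- function(n) {
      out <- matrix(0, n, n_null)
      for (b in seq_len(n_blocks)) {
        idx <- which(block_of == b)
        if (!length(idx)) next
        f <- f_null[idx[1]]
        rho <- if (!is.null(allele_freqs)) latent_rho_for_allele_corr(r_allele, f) else rho_block[b]
        h1 <- draw_block_haplotypes(n, length(idx), f, rho)
        h2 <- draw_block_haplotypes(n, length(idx), f, rho)
        out[, idx] <- h1 + h2
      }
      out
    }

    G_null <- draw_null(n_sub)
    R_null <- draw_null(n_ref)

    # causal SNPs: independent, label-conditional dosage distributions
    G_causal <- matrix(0, n_sub, n_causal)
    R_causal <- matrix(0, n_ref, n_causal)
    f_causal <- if (n_causal) runif(n_causal, maf_range[1], maf_range[2]) else numeric()
    for (k in seq_len(n_causal)) {
      f <- f_causal[k]
      p_hwe <- c((1 - f)^2, 2 * f * (1 - f), f^2)
      beta <- causal_snps$log_odds[k]
      b0 <- uniroot(function(b) sum(p_hwe * plogis(b + beta * 0:2)) - 0.5,
                    c(-20, 20), tol = 1e-10)$root
      p_rem <- p_hwe * plogis(b0 + beta * 0:2) / 0.5
      p_con <- p_hwe * (1 - plogis(b0 + beta * 0:2)) / 0.5
      is_rem <- subjects$label == "remitted"
      G_causal[is_rem, k] <- sample(0:2, sum(is_rem), TRUE, prob = p_rem)
      G_causal[!is_rem, k] <- sample(0:2, sum(!is_rem), TRUE, prob = p_con)
      R_causal[, k] <- sample(0:2, n_ref, TRUE, prob = p_hwe)
    }

    # SNP metadata: null blocks on chr 1, 2 kb spacing within a block, 2 Mb
    # between block starts; causal SNPs on chr 2, 1 Mb apart
    null_ids <- sprintf("snp%04d", seq_len(n_null))
    within <- if (n_null) stats::ave(seq_len(n_null), block_of, FUN = seq_along) else integer()
    snps <- tibble::tibble(
      snp = c(null_ids, if (n_causal) causal_snps$snp else character()),
      chr = c(rep("1", n_null), rep("2", n_causal)),
      pos = c(if (n_null) (block_of - 1L) * 2000000L + within * 2000L else integer(),
              if (n_causal) seq_len(n_causal) * 1000000L else integer()),
      a1 = "A", a2 = "G")

    # discovery summary statistics
    stats_tbl <- snps
    stats_tbl$beta <- c(rnorm(n_null, 0, 0.02),
                        if (n_causal) causal_snps$log_odds else numeric())
    stats_tbl$p <- c(runif(n_null),
                     if (n_causal) 10^runif(n_causal, -8, -6) else numeric())

    dos <- cbind(G_null, G_causal)
    ref <- cbind(R_null, R_causal)
    rownames(dos) <- subjects$subject_id
    rownames(ref) <- sprintf("ref%04d", seq_len(n_ref))
    list(genotypes = genotype_matrix(dos, snps),
         summary_stats = stats_tbl,
         reference = genotype_matrix(ref, snps))
  })
}
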