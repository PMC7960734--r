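# Independent brute-force oracles, written from first principles and kept
# deliberately separate from the package implementations they check.

# Literal replay of the greedy clumping definition using only base R data
# frames: order by (p, chr, pos, id); take the head as index; drop everything
# unclumped on the same chromosome within the window whose r2 >= threshold.
brute_clump <- function(stats, ref_dosage, r2_threshold, window_kb) {
  df <- as.data.frame(stats)
  df <- df[order(df$p, df$chr, df$pos, df$snp), ]
  retained <- character()
  while (nrow(df) > 0) {
    idx <- df[1, ]
    retained <- c(retained, idx$snp)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0 || !(idx$snp %in% colnames(ref_dosage))) next
    drop <- logical(nrow(df))
    for (r in seq_len(nrow(df))) {
      cand <- df[r, ]
      if (cand$chr != idx$chr) next
      if (abs(cand$pos - idx$pos) > window_kb * 1000) next
      if (!(cand$snp %in% colnames(ref_dosage))) next
      a <- ref_dosage[, idx$snp]; b <- ref_dosage[, cand$snp]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2) next
      if (sd(a[ok]) == 0 || sd(b[ok]) == 0) next
      if (cor(a[ok], b[ok])^2 >= r2_threshold) drop[r] <- TRUE
    }
    df <- df[!drop, , drop = FALSE]
  }
  sort(retained)
}

# Exhaustive pairwise AUC with half credit for ties.
brute_auc <- function(is_pos, scores) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  if (!length(sp) || !length(sn)) return(NA_real_)
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# Soft-threshold operator (closed-form LASSO solution on orthonormal designs).
soft_threshold <- function(z, lam) sign(z) * pmax(abs(z) - lam, 0)

# Primal soft-margin linear SVM objective with the augmented-bias penalty
# used by the trainer: 0.5 ||w||^2 + 0.5 (b/S)^2 + C sum hinge.
svm_objective <- function(w, b, X, y_pm, C, bias_scale = 1) {
  margins <- y_pm * (as.numeric(X %*% w) + b)
  0.5 * sum(w^2) + 0.5 * (b / bias_scale)^2 + C * sum(pmax(0, 1 - margins))
}

# KKT residuals of a gaussian LASSO fit at (intercept, beta, lambda):
# max violation over zero coefficients of |x_j' r| / n <= lambda, and over
# nonzero ones of x_j' r / n = lambda * sign(beta_j).
lasso_kkt_residual <- function(X, y, fit) {
  n <- nrow(X)
  r <- y - fit$intercept - as.numeric(X %*% fit$beta)
  g <- as.numeric(crossprod(X, r)) / n
  z <- fit$beta == 0
  viol_zero <- if (any(z)) max(pmax(abs(g[z]) - fit$lambda, 0)) else 0
  viol_nz <- if (any(!z)) max(abs(g[!z] - fit$lambda * sign(fit$beta[!z]))) else 0
  max(viol_zero, viol_nz)
}

# Random small clumping instance: <= max_snps SNPs on up to two chromosomes
# with factor-structured LD in the reference panel.
random_clump_instance <- function(max_snps = 12, n_ref = 80) {
  m <- sample(2:max_snps, 1)
  chr <- sample(c("1", "2"), m, replace = TRUE)
  pos <- sample(1:2000, m) * 1000L
  # factor model: groups of SNPs share a latent variable -> varied r2
  grp <- sample(1:3, m, replace = TRUE)
  lat <- matrix(rnorm(n_ref * 3), n_ref, 3)
  load <- runif(m, 0, 1)
  dos <- sapply(seq_len(m), function(j) {
    z <- load[j] * lat[, grp[j]] + sqrt(1 - load[j]^2) * rnorm(n_ref)
    f <- runif(1, 0.15, 0.5)
    (z < qnorm(f)) + (rnorm(n_ref) < qnorm(f))
  })
  colnames(dos) <- paste0("s", seq_len(m))
  rownames(dos) <- paste0("r", seq_len(n_ref))
  stats <- tibble::tibble(snp = colnames(dos), chr = chr, pos = pos,
                          a1 = "A", a2 = "G", beta = rnorm(m),
                          p = runif(m))
  list(stats = stats, dosage = dos,
       ref = genotype_matrix(dos, stats[, c("snp", "chr", "pos", "a1", "a2")]))
}
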