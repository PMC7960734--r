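# Small fixture builders used across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

make_subjects <- function(n_per_group, seed = 1) {
  n <- 2 * n_per_group
  withr::with_seed(seed, {
    tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)),
                   label = sample(rep(c("continued", "remitted"), n_per_group)))
  })
}

# Feature table with planted mean-shifted features among Gaussian noise.
make_planted_table <- function(n_per_group, p_noise, p_signal = 0, delta = 0,
                               seed = 1, prefix = "eeg_f") {
  n <- 2 * n_per_group
  withr::with_seed(seed, {
    y <- rep(c("continued", "remitted"), each = n_per_group)
    X <- matrix(rnorm(n * (p_noise + p_signal)), n)
    if (p_signal > 0) {
      X[y == "remitted", seq_len(p_signal)] <- X[y == "remitted", seq_len(p_signal)] + delta
    }
    colnames(X) <- c(if (p_signal > 0) paste0(prefix, "sig", seq_len(p_signal)),
                     paste0(prefix, "noise", seq_len(p_noise)))
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)),
                     label = y,
                     sex = "male", ancestry = "EA",
                     age = rnorm(n, 30.7, 9.4)),
      tibble::as_tibble(X))
  })
}

# Two-population genotype matrix with allele-frequency divergence.
make_two_pop_genotypes <- function(n_per_pop = 100, n_snps = 200,
                                   divergence = 0.25, seed = 1) {
  withr::with_seed(seed, {
    f1 <- runif(n_snps, 0.1, 0.4)
    f2 <- pmin(f1 + divergence, 0.9)
    pop <- rep(c("EA", "AA"), each = n_per_pop)
    dos <- t(sapply(seq_along(pop), function(i) {
      rbinom(n_snps, 2, if (pop[i] == "EA") f1 else f2)
    }))
    rownames(dos) <- sprintf("P%04d", seq_along(pop))
    snps <- tibble::tibble(snp = paste0("s", seq_len(n_snps)), chr = "1",
                           pos = seq_len(n_snps) * 1000L, a1 = "A", a2 = "G")
    list(genotypes = genotype_matrix(dos, snps), population = pop)
  })
}

# The worked 4-SNP clumping example: SNP2 within the window and in LD with
# SNP1, SNP3 within the window but nearly independent, SNP4 in strong LD but
# outside the 500 kb window.
make_clump_example <- function(n_ref = 2000, seed = 1) {
  stats <- tibble::tibble(snp = paste0("SNP", 1:4), chr = "1",
                          pos = c(1000000L, 1100000L, 1200000L, 1600000L),
                          a1 = "A", a2 = "G", beta = 1,
                          p = c(1e-6, 1e-5, 1e-4, 0.2))
  withr::with_seed(seed, {
    z1 <- rnorm(n_ref)
    mk <- function(r2) {
      a <- sqrt(sqrt(r2)) # latent loading; thresholding attenuates towards target
      a * z1 + sqrt(1 - a^2) * rnorm(n_ref)
    }
    lat <- cbind(z1, mk(0.5), mk(0.1), mk(0.9))
    dos <- apply(lat, 2, function(z) {
      as.numeric(cut(z, c(-Inf, qnorm(0.25), qnorm(0.75), Inf))) - 1
    })
    colnames(dos) <- stats$snp
    rownames(dos) <- paste0("r", seq_len(n_ref))
    list(stats = stats,
         ref = genotype_matrix(dos, stats[, c("snp", "chr", "pos", "a1", "a2")]))
  })
}
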