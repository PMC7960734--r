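# LD r2, greedy clumping, PRS scoring and standardization.

test_that("ld_r2 handles identity, perfect anticorrelation and simulation", {
  ex <- make_clump_example()
  expect_equal(ld_r2(ex$ref, "SNP1", "SNP1"), 1)
  # perfect anticorrelation squares to 1
  dos <- cbind(a = c(0, 1, 2, 0), b = c(2, 1, 0, 2))
  rownames(dos) <- paste0("s", 1:4)
  g <- genotype_matrix(dos, tibble::tibble(snp = c("a", "b"), chr = "1",
                                           pos = c(1L, 2L), a1 = "A", a2 = "G"))
  expect_equal(ld_r2(g, "a", "b"), 1)
  # block-simulated pair with target r2 0.5 at n = 500
  subs <- make_subjects(250, seed = 30)
  sim <- simulate_genetics(subs, NULL, n_snps = 2, n_blocks = 1, block_r2 = 0.5,
                           seed = 31, n_ref = 500)
  r2 <- ld_r2(sim$reference, "snp0001", "snp0002")
  expect_gt(r2, 0.42)
  expect_lt(r2, 0.58)
  # monomorphic SNP: r2 defined 0 with warning
  dos2 <- cbind(m = c(1, 1, 1, 1), n = c(0, 1, 2, 1))
  rownames(dos2) <- paste0("s", 1:4)
  g2 <- genotype_matrix(dos2, tibble::tibble(snp = c("m", "n"), chr = "1",
                                             pos = c(1L, 2L), a1 = "A", a2 = "G"))
  expect_warning(r0 <- ld_r2(g2, "m", "n"), "monomorphic")
  expect_equal(r0, 0)
})

test_that("clumping reproduces the worked 4-SNP example", {
  ex <- make_clump_example()
  expect_identical(clump(ex$stats, ex$ref), c("SNP1", "SNP3", "SNP4"))
})

test_that("single SNP and zero-LD instances are retained in full", {
  ex <- make_clump_example()
  expect_identical(clump(ex$stats[1, ], ex$ref), "SNP1")
  # independent reference: all retained regardless of distance
  withr::with_seed(32, {
    dos <- sapply(1:4, function(i) rbinom(600, 2, 0.3))
    colnames(dos) <- ex$stats$snp
    rownames(dos) <- paste0("r", 1:600)
  })
  ref0 <- genotype_matrix(dos, ex$stats[, c("snp", "chr", "pos", "a1", "a2")])
  expect_setequal(clump(ex$stats, ref0), ex$stats$snp)
  expect_identical(clump(ex$stats[0, ], ex$ref), character())
})

test_that("greedy clumping equals brute-force replay on random instances", {
  withr::with_seed(33, {
    for (k in 1:200) {
      inst <- random_clump_instance()
      got <- sort(clump(inst$stats, inst$ref, r2_threshold = 0.25,
                        window_kb = 500))
      want <- brute_clump(inst$stats, inst$dosage, 0.25, 500)
      expect_identical(got, want)
    }
  })
})

test_that("SNPs missing from the reference are retained with a warning", {
  ex <- make_clump_example()
  ref_small <- genotype_matrix(ex$ref$dosage[, c("SNP1", "SNP3", "SNP4")],
                               ex$ref$snps[c(1, 3, 4), ])
  expect_warning(kept <- clump(ex$stats, ref_small), "absent")
  expect_true("SNP2" %in% kept)
})

test_that("PRS hand example gives 8 at t = 0.001 and 10 at t = 0.05", {
  st <- tibble::tibble(snp = c("a", "b"), chr = "1", pos = c(1L, 2L),
                       a1 = "A", a2 = "G", beta = c(1, 1), p = c(1e-4, 0.01))
  g <- genotype_matrix(matrix(c(2, 1), 1, 2, dimnames = list("s1", c("a", "b"))),
                       st[, 1:5])
  sc <- prs_scores(g, st, c("a", "b"), thresholds = c(0.001, 0.05))
  expect_equal(sc[[2]], 8)  # -log10(1e-4) * 2
  expect_equal(sc[[3]], 10) # 8 + (-log10(0.01)) * 1
  # all dosages zero -> zero at every threshold
  g0 <- genotype_matrix(matrix(0, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b"))),
                        st[, 1:5])
  sc0 <- prs_scores(g0, st, c("a", "b"))
  expect_true(all(as.matrix(sc0[, -1]) == 0))
  expect_error(prs_scores(g, st, c("a", "b"), thresholds = numeric()),
               "non-empty")
})

test_that("threshold nesting makes scores non-decreasing for positive weights", {
  withr::with_seed(34, {
    for (k in 1:25) {
      m <- sample(3:12, 1)
      n <- sample(3:8, 1)
      st <- tibble::tibble(snp = paste0("v", 1:m), chr = "1",
                           pos = seq_len(m) * 1000L, a1 = "A", a2 = "G",
                           beta = abs(rnorm(m)), p = runif(m))
      dos <- matrix(sample(0:2, n * m, TRUE), n, m,
                    dimnames = list(paste0("s", 1:n), st$snp))
      g <- genotype_matrix(dos, st[, 1:5])
      sc <- as.matrix(prs_scores(g, st, st$snp)[, -1])
      expect_true(all(diff(t(sc)) >= -1e-12))
    }
  })
})

test_that("scoring is linear in dosage and allele-flip invariant", {
  st <- tibble::tibble(snp = paste0("v", 1:4), chr = "1", pos = 1:4 * 1000L,
                       a1 = "A", a2 = "G", beta = c(0.5, -0.2, 1, -1),
                       p = c(1e-3, 0.02, 0.2, 0.4))
  withr::with_seed(35, {
    da <- matrix(sample(0:1, 12, TRUE), 3, 4)
    db <- matrix(sample(0:1, 12, TRUE), 3, 4)
  })
  dimnames(da) <- dimnames(db) <- list(paste0("s", 1:3), st$snp)
  score <- function(d) as.matrix(prs_scores(genotype_matrix(d, st[, 1:5]),
                                            st, st$snp)[, -1])
  expect_equal(score(da + db), score(da) + score(db))
  # flipping a1/a2 with dosage 2-d and beta sign flip leaves scores shifted
  # by a per-threshold constant only (2 * sum of weights), i.e. identical
  # after centring
  st_f <- st
  st_f$beta <- -st$beta
  st_f$a1 <- st$a2
  st_f$a2 <- st$a1
  g1 <- genotype_matrix(da, st[, 1:5])
  g2 <- genotype_matrix(2 - da, st_f[, 1:5])
  s1 <- suppressWarnings(standardize_prs(prs_scores(g1, st, st$snp)))
  s2 <- suppressWarnings(standardize_prs(prs_scores(g2, st_f, st$snp)))
  expect_equal(as.matrix(s1[, -1]), as.matrix(s2[, -1]), tolerance = 1e-9)
})

test_that("standardization centers, scales, and is idempotent", {
  prs <- tibble::tibble(subject_id = paste0("s", 1:3), `prs_x@0.5` = c(1, 2, 3))
  z <- standardize_prs(prs)
  expect_equal(z[[2]], c(-1, 0, 1))
  z2 <- standardize_prs(z)
  expect_equal(z2[[2]], z[[2]], tolerance = 1e-12)
  withr::with_seed(36, {
    many <- tibble::tibble(subject_id = paste0("s", 1:20),
                           `prs_a@0.1` = rnorm(20), `prs_b@0.5` = runif(20))
  })
  zz <- standardize_prs(many)
  for (cl in names(zz)[-1]) {
    expect_equal(mean(zz[[cl]]), 0, tolerance = 1e-9)
    expect_equal(sd(zz[[cl]]), 1, tolerance = 1e-9)
  }
  expect_error(standardize_prs(prs[1, ]), ">= 2 subjects")
  cst <- tibble::tibble(subject_id = paste0("s", 1:3), `prs_c@0.5` = c(2, 2, 2))
  expect_warning(zc <- standardize_prs(cst), "constant")
  expect_true(all(zc[[2]] == 0))
})

test_that("compute_prs chains clump, score and standardize per phenotype", {
  subs <- make_subjects(40, seed = 37)
  sim <- simulate_genetics(subs, NULL, n_snps = 20, n_blocks = 5,
                           block_r2 = 0.4, seed = 38, n_ref = 150)
  out <- suppressWarnings(
    compute_prs(sim$genotypes, list(neuroticism = sim$summary_stats),
                sim$reference, thresholds = c(0.2, 0.5)))
  expect_identical(names(out), c("subject_id", "prs_neuroticism@0.2",
                                 "prs_neuroticism@0.5"))
  expect_equal(nrow(out), 80)
  expect_equal(mean(out[[2]]), 0, tolerance = 1e-9)
})
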